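item_id,stratum,word_en,in_short_form
low_02,low,Eye,FALSE
low_06,low,Fiber,TRUE
low_08,low,Meat,TRUE
low_12,low,Heart,FALSE
low_13,low,Blood,TRUE
low_15,low,Hospital,TRUE
low_16,low,Vision,FALSE
low_17,low,Snack,FALSE
low_19,low,Insulin,TRUE
low_20,low,Alcohol,TRUE
low_23,low,Diet,TRUE
low_27,low,Nerve,FALSE
low_28,low,Cut,FALSE
low_29,low,Sore,FALSE
medium_01,medium,Dizzy,FALSE
medium_02,medium,Fatigue,TRUE
medium_08,medium,Fluid,TRUE
medium_09,medium,Portion,TRUE
medium_13,medium,Calorie,FALSE
medium_14,medium,Infection,FALSE
medium_15,medium,Stroke,TRUE
medium_16,medium,Fasting,FALSE
medium_17,medium,Glucose,TRUE
medium_19,medium,Nutrition,FALSE
medium_20,medium,Vegetable,TRUE
medium_22,medium,Swelling,FALSE
medium_23,medium,Sweating,FALSE
medium_24,medium,Appointment,TRUE
high_02,high,Circulation,FALSE
high_04,high,Hypoglycemia,FALSE
high_05,high,Endocrinologist,TRUE
high_10,high,Hyperglycemia,TRUE
high_11,high,Dialysis,TRUE
high_13,high,Prescription,TRUE
high_14,high,Amputation,TRUE
high_15,high,Pharmacist,FALSE
high_16,high,Medication,FALSE
high_17,high,Lancet,FALSE
high_18,high,Pancreas,FALSE
high_25,high,Hemoglobin A1C,TRUE
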