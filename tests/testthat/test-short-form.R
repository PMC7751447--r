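test_that("largest-remainder quotas reproduce the published allocations", {
  q40 <- allocate_quotas(c(low = 29, medium = 28, high = 25), 40)
  expect_equal(q40$quota, c(14L, 14L, 12L))
  q20 <- allocate_quotas(c(low = 29, medium = 28, high = 25), 20)
  expect_equal(q20$quota, c(7L, 7L, 6L))
})

test_that("quota allocation edge cases and the tie-break rule", {
  full <- allocate_quotas(c(low = 10, medium = 10, high = 10), 30)
  expect_equal(full$quota, c(10L, 10L, 10L))

  # floors (1,1,2), remainders (.5,.5,0): the leftover seat goes to 'low'
  tie <- allocate_quotas(c(low = 3, medium = 3, high = 4), 5)
  expect_equal(tie$quota, c(2L, 1L, 2L))

  expect_error(allocate_quotas(c(low = 3, medium = 3, high = 4), 11), "exceeds")
  expect_error(allocate_quotas(c(low = 0, medium = 3, high = 4), 5), "positive")

  # quotas always sum to L
  set.seed(12)
  for (i in 1:25) {
    sizes <- c(low = sample(1:40, 1), medium = sample(1:40, 1),
               high = sample(1:40, 1))
    L <- sample(seq_len(sum(sizes)), 1)
    q <- allocate_quotas(sizes, L)
    expect_equal(sum(q$quota), L)
    expect_true(all(q$quota <= q$n_items))
  }
})

test_that("the mean curve interpolates noiseless linear data", {
  stats <- tibble::tibble(
    item_id = paste0("w", 1:20),
    p = seq(20, 90, length.out = 20),
    r_it = 0.3 + 0.002 * seq(20, 90, length.out = 20)
  )
  curve <- fit_mean_curve(stats)
  expect_lt(max(abs(tidy(curve)$residual)), 1e-6)
  expect_lt(max(abs(tidy(curve)$fitted - stats$r_it)), 1e-6)
})

test_that("the mean curve tracks a smooth generating function under noise", {
  set.seed(88)
  truth_fn <- function(p) 0.4 + 0.3 * sin(p / 30)
  p <- runif(60, 20, 95)
  noise_sd <- 0.03
  stats <- tibble::tibble(
    item_id = paste0("w", 1:60),
    p = p,
    r_it = truth_fn(p) + rnorm(60, 0, noise_sd)
  )
  curve <- fit_mean_curve(stats)
  expect_lt(max(abs(predict_curve(curve, p) - truth_fn(p))), 3 * noise_sd)
})

test_that("mean curve handles ties in p and refuses tiny inputs", {
  stats <- tibble::tibble(
    item_id = paste0("w", 1:10),
    p = rep(c(30, 45, 60, 75, 90), each = 2),
    r_it = c(.40, .44, .5, .52, .6, .58, .55, .57, .5, .48)
  )
  expect_no_error(curve <- fit_mean_curve(stats))
  expect_equal(nrow(tidy(curve)), 10)

  expect_error(fit_mean_curve(stats[1:4, ]), "at least 5")
})

test_that("selection takes the top residuals per stratum with stated tie-breaks", {
  bank <- tibble::tibble(item_id = paste0("w", 1:6), stratum = "low",
                         word_en = paste0("word", 1:6))
  residuals <- c(.05, -.02, .03, .00, -.01, .04)
  # build stats whose residuals against a flat curve are exactly `residuals`
  stats <- tibble::tibble(
    item_id = bank$item_id,
    p = seq(30, 80, length.out = 6),
    r_it = 0.5 + residuals
  )
  flat_stats <- tibble::tibble(item_id = paste0("f", 1:6),
                               p = seq(30, 80, length.out = 6), r_it = 0.5)
  curve <- fit_mean_curve(flat_stats)
  quotas <- tibble::tibble(stratum = "low", n_items = 6L, quota = 3L)
  sel <- select_items(stats, curve, quotas, bank, p_range = NULL)
  expect_equal(sel$item_id, c("w1", "w6", "w3"))
  expect_equal(sel$rank, 1:3)

  # quota equal to the stratum size selects everything
  quotas_all <- tibble::tibble(stratum = "low", n_items = 6L, quota = 6L)
  sel_all <- select_items(stats, curve, quotas_all, bank, p_range = NULL)
  expect_setequal(sel_all$item_id, bank$item_id)
  expect_true(any(sel_all$quota_fill)) # below-curve items had to fill the quota
})

test_that("nested selection is a subset with the nested quotas", {
  study <- generate_study(small_config(seed = 31))
  bank <- study$bank
  stats <- item_statistics(study$responses, bank = bank)
  en_stats <- stats[stats$language == "en", ]
  curve <- fit_mean_curve(en_stats)

  q10 <- allocate_quotas(stratum_sizes(bank), 10)
  sel10 <- select_items(en_stats, curve, q10, bank)
  q5 <- allocate_quotas(setNames(
    as.integer(table(factor(sel10$stratum, levels = c("low", "medium", "high")))),
    c("low", "medium", "high")
  ), 5)
  sel5 <- select_items(en_stats, curve, q5, bank, parent = sel10)
  expect_true(all(sel5$item_id %in% sel10$item_id))
  expect_equal(nrow(sel5), 5)
  expect_equal(attr(sel5, "parent_L"), attr(sel10, "L"))
})

test_that("selection is optimal per stratum and invariant to item order", {
  study <- generate_study(small_config(seed = 77))
  bank <- study$bank
  stats <- item_statistics(study$responses, bank = bank)
  en_stats <- stats[stats$language == "en", ]
  curve <- fit_mean_curve(en_stats)
  quotas <- allocate_quotas(stratum_sizes(bank), 10)
  sel <- select_items(en_stats, curve, quotas, bank, p_range = NULL)

  # brute force: every selected residual >= every unselected same-stratum one
  all_resid <- tibble::tibble(
    item_id = en_stats$item_id,
    residual = en_stats$r_it - predict_curve(curve, en_stats$p)
  ) |> dplyr::left_join(dplyr::select(bank, "item_id", "stratum"), by = "item_id")
  for (s in unique(sel$stratum)) {
    sel_min <- min(sel$residual[sel$stratum == s])
    uns <- all_resid[all_resid$stratum == s &
                       !(all_resid$item_id %in% sel$item_id), ]
    if (nrow(uns) > 0) expect_gte(sel_min, max(uns$residual) - 1e-12)
  }

  shuffled <- en_stats[sample(nrow(en_stats)), ]
  sel2 <- select_items(shuffled, curve, quotas, bank, p_range = NULL)
  expect_equal(sel2$item_id, sel$item_id)
})

test_that("the percent-correct window excludes extreme items", {
  bank <- tibble::tibble(item_id = paste0("w", 1:8), stratum = "low",
                         word_en = paste0("word", 1:8))
  stats <- tibble::tibble(
    item_id = bank$item_id,
    p = c(2, 98, 30, 40, 50, 60, 70, 80),
    r_it = c(.9, .9, .5, .5, .5, .5, .5, .5)
  )
  curve <- fit_mean_curve(stats[3:8, ])
  quotas <- tibble::tibble(stratum = "low", n_items = 8L, quota = 4L)
  sel <- select_items(stats, curve, quotas, bank, p_range = c(5, 95))
  expect_false(any(c("w1", "w2") %in% sel$item_id))
})

test_that("cross-language review lists selected items below other languages' curves", {
  study <- generate_study(small_config(seed = 13))
  bank <- study$bank
  stats <- item_statistics(study$responses, bank = bank)
  en_stats <- stats[stats$language == "en", ]
  curve <- fit_mean_curve(en_stats)
  quotas <- allocate_quotas(stratum_sizes(bank), 10)
  sel <- select_items(en_stats, curve, quotas, bank, language = "en")

  review <- multi_language_review(sel, stats)
  n_other <- length(setdiff(unique(stats$language), "en"))
  expect_equal(nrow(review), nrow(sel) * n_other)
  expect_equal(review$review_candidate, review$below_curve)
  expect_true(all(review$language != "en"))
})
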