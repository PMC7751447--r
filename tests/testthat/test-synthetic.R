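test_that("generated banks honour the configured strata and parameter structure", {
  gen <- generate_item_bank(sim_config(seed = 2))
  expect_equal(stratum_sizes(gen$bank), c(low = 29L, medium = 28L, high = 25L))
  expect_equal(nrow(gen$bank), 82)
  expect_setequal(unique(gen$truth$language), c("en", "es", "ko"))
  expect_true(all(gen$truth$a >= 0.8 & gen$truth$a <= 2))

  expect_error(generate_item_bank(sim_config(lambda = 0)), "lambda")
  expect_error(generate_item_bank(sim_config(lambda = 1.2)), "lambda")
})

test_that("lambda = 1 removes compression; smaller lambda shrinks separation", {
  gen1 <- generate_item_bank(small_config(seed = 5, lambda = 1))
  en <- gen1$truth[gen1$truth$language == "en", ]
  es <- gen1$truth[gen1$truth$language == "es", ]
  expect_equal(es$b, en$b)

  gen2 <- generate_item_bank(small_config(seed = 5, lambda = 0.4))
  es2 <- gen2$truth[gen2$truth$language == "es", ]
  sep_en <- difficulty_separation(gen2$truth[gen2$truth$language == "en", ])
  sep_es <- difficulty_separation(es2)
  expect_gt(sep_en$separation, sep_es$separation)
})

test_that("dif_spec shifts exactly the targeted item and language", {
  ds <- tibble::tibble(item_id = "w_low_01", language = "es",
                       delta_a = 0.3, delta_b = 0.9)
  base <- generate_item_bank(small_config(seed = 3))
  shifted <- generate_item_bank(small_config(seed = 3, dif_spec = ds))
  b0 <- base$truth
  b1 <- shifted$truth
  hit <- b1$item_id == "w_low_01" & b1$language == "es"
  expect_equal(b1$b[hit], b0$b[hit] + 0.9)
  expect_equal(b1$a[hit], b0$a[hit] + 0.3)
  expect_equal(b1$b[!hit], b0$b[!hit])
  expect_equal(b1$a[!hit], b0$a[!hit])
})

test_that("response generation is seed-deterministic and matches the 2PL marginal", {
  truth <- tibble::tibble(item_id = c("easy", "mid", "hard"), language = "en",
                          stratum = c("low", "medium", "high"),
                          a = c(1, 1, 1.5), b = c(-1.5, 0, 1.5))
  r1 <- generate_responses(truth, "en", n = 500, seed = 10)
  r2 <- generate_responses(truth, "en", n = 500, seed = 10)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- generate_responses(truth, "en", n = 500, seed = 11)
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))

  # symmetric item: empirical proportion near 0.5
  big <- generate_responses(truth, "en", n = 10000, seed = 12)
  expect_lt(abs(mean(big$mid) - 0.5), 0.02)

  # every item within 3 Monte Carlo SEs of the quadrature-integrated marginal
  th <- seq(-6, 6, length.out = 201)
  w <- dnorm(th)
  w <- w / sum(w)
  for (item in truth$item_id) {
    pars <- truth[truth$item_id == item, ]
    p_marg <- sum(w * irf(th, pars$a, pars$b))
    mc_se <- sqrt(p_marg * (1 - p_marg) / nrow(big))
    expect_lt(abs(mean(big[[item]]) - p_marg), 3 * mc_se + 1e-3)
  }

  expect_error(generate_responses(truth, "en", n = 0), "at least 1")
  expect_error(generate_responses(truth, "fr", n = 5), "fr")
})

test_that("longitudinal generation injects the configured ability drifts", {
  cfg <- small_config(seed = 8)
  gen <- generate_item_bank(cfg)

  # null drift: mean change stays near zero at every follow-up
  cfg_null <- cfg
  cfg_null$delta <- list(
    intervention = c(baseline = 0, m3 = 0, m6 = 0, m12 = 0),
    control = c(baseline = 0, m3 = 0, m6 = 0, m12 = 0)
  )
  long0 <- generate_longitudinal(gen$truth, "en", n_per_arm = 200,
                                 config = cfg_null, seed = 4)
  sc0 <- form_scores(long0)
  sens0 <- sensitivity_analysis(sc0)
  expect_true(all(abs(sens0$difference[sens0$timepoint != "baseline"]) < 4))

  # injected drift at m12 produces a clear starred difference
  cfg_eff <- cfg
  cfg_eff$delta <- list(
    intervention = c(baseline = 0, m3 = 0, m6 = 0, m12 = 0.5),
    control = c(baseline = 0, m3 = 0, m6 = 0, m12 = 0)
  )
  long1 <- generate_longitudinal(gen$truth, "en", n_per_arm = 300,
                                 config = cfg_eff, seed = 5)
  sens1 <- sensitivity_analysis(form_scores(long1))
  m12 <- sens1[sens1$timepoint == "m12", ]
  expect_gt(m12$difference, 0)
  expect_true(m12$sig != "")

  cfg_bad <- cfg
  cfg_bad$timepoints <- c("m3", "m6")
  expect_error(generate_longitudinal(gen$truth, "en", 10, config = cfg_bad),
               "baseline")
})

test_that("covariates carry the configured ability loading", {
  set.seed(14)
  theta <- rnorm(2000)
  spec <- tibble::tibble(name = c("exact", "none", "mid"),
                         rho = c(1, 0, 0.6), levels = NA)
  covs <- generate_covariates(theta, spec, seed = 15)
  expect_equal(cor(covs$cov_exact, theta), 1, tolerance = 1e-10)
  expect_lt(abs(cor(covs$cov_none, theta)), 0.05)
  expect_lt(abs(cor(covs$cov_mid, theta) - 0.6), 0.05)

  lev <- generate_covariates(theta, tibble::tibble(name = "edu", rho = 0.5,
                                                   levels = 4), seed = 16)
  expect_setequal(sort(unique(lev$cov_edu)), 1:4)

  expect_error(
    generate_covariates(theta, tibble::tibble(name = "x", rho = 1.5, levels = NA)),
    "rho"
  )
})

test_that("whole studies are reproducible from the seed", {
  s1 <- generate_study(small_config(seed = 99))
  s2 <- generate_study(small_config(seed = 99))
  expect_identical(as.data.frame(s1$responses), as.data.frame(s2$responses))
  expect_identical(s1$truth, s2$truth)
})
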