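test_that("mean/sigma equating: identity, hand-computed constants, forced moments", {
  pars <- tibble::tibble(item_id = paste0("w", 1:3), a = c(1, 1.5, 2),
                         b = c(0, 1, 2))
  self <- mean_sigma_equate(pars, pars)
  expect_equal(self$transform$A, 1)
  expect_equal(self$transform$B, 0)
  expect_equal(self$params$b, pars$b)
  expect_equal(self$params$a, pars$a)

  ref <- tibble::tibble(item_id = paste0("w", 1:3), a = 1, b = c(-1, 1, 3))
  eq <- mean_sigma_equate(pars, ref)
  expect_equal(eq$transform$A, 2)
  expect_equal(eq$transform$B, -1)
  expect_equal(eq$params$b, c(-1, 1, 3))

  set.seed(17)
  for (i in 1:10) {
    f <- tibble::tibble(item_id = paste0("w", 1:12), a = runif(12, 0.5, 2),
                        b = rnorm(12, 0, 1.3))
    r <- tibble::tibble(item_id = paste0("w", 1:12), a = runif(12, 0.5, 2),
                        b = rnorm(12, 0.4, 0.8))
    tr <- mean_sigma_equate(f, r)
    expect_lt(abs(mean(tr$params$b) - mean(r$b)), 1e-8)
    expect_lt(abs(sd(tr$params$b) - sd(r$b)), 1e-8)
    # the transformed IRFs are the originals under theta' = A theta + B
    theta <- rnorm(5)
    for (j in c(1, 7)) {
      expect_equal(
        irf(tr$transform$A * theta + tr$transform$B,
            tr$params$a[j], tr$params$b[j]),
        irf(theta, f$a[j], f$b[j]),
        tolerance = 1e-10
      )
    }
  }
})

test_that("equating is idempotent and composes across forms", {
  set.seed(23)
  f <- tibble::tibble(item_id = paste0("w", 1:10), a = runif(10, 0.5, 2),
                      b = rnorm(10))
  r1 <- tibble::tibble(item_id = f$item_id, a = f$a, b = rnorm(10, 1, 2))
  r2 <- tibble::tibble(item_id = f$item_id, a = f$a, b = rnorm(10, -0.5, 0.7))

  once <- mean_sigma_equate(f, r1)
  again <- mean_sigma_equate(once$params, r1)
  expect_lt(abs(again$transform$A - 1), 1e-8)
  expect_lt(abs(again$transform$B), 1e-8)

  chained <- mean_sigma_equate(mean_sigma_equate(f, r1)$params, r2)
  direct <- mean_sigma_equate(f, r2)
  expect_equal(chained$params$b, direct$params$b, tolerance = 1e-10)
  expect_equal(chained$params$a, direct$params$a, tolerance = 1e-10)
})

test_that("equating input validation", {
  f <- tibble::tibble(item_id = paste0("w", 1:3), a = 1, b = c(1, 1, 1))
  r <- tibble::tibble(item_id = paste0("w", 1:3), a = 1, b = c(0, 1, 2))
  expect_error(mean_sigma_equate(f, r), "zero standard deviation")
  r_off <- tibble::tibble(item_id = c("w1", "w2", "x9"), a = 1, b = c(0, 1, 2))
  expect_error(mean_sigma_equate(r, r_off), "x9")
  expect_error(mean_sigma_equate(r[1:2, ], r[1:2, ]), "at least 3")
})

test_that("difficulty separation index: sign, zero and generator contrast", {
  pars <- tibble::tibble(
    item_id = c("l1", "l2", "h1", "h2"),
    stratum = c("low", "low", "high", "high"),
    b = c(-1, -1, 2, 2)
  )
  rep1 <- difficulty_separation(pars)
  expect_true(is.finite(rep1$separation) || rep1$separation > 0)
  expect_gt(rep1$separation, 0)

  flat <- pars
  flat$b <- 1
  expect_equal(difficulty_separation(flat)$separation, 0)

  one_item <- pars[c(1, 3), ]
  rep2 <- difficulty_separation(one_item)
  expect_true(all(is.na(rep2$strata$sd_b)))

  # separated truth shows larger separation than compressed truth, same seed
  gen <- generate_item_bank(small_config(seed = 42, lambda = 0.5))
  sep_en <- difficulty_separation(gen$truth[gen$truth$language == "en", ])
  sep_es <- difficulty_separation(gen$truth[gen$truth$language == "es", ])
  expect_gt(sep_en$separation, sep_es$separation)
})

test_that("DIF statistic vanishes when the groups are literally identical", {
  gen <- generate_item_bank(small_config(seed = 20))
  resp <- generate_responses(gen$truth, "en", n = 250, seed = 21)
  twin <- resp
  twin$language <- "es"
  twin$person_id <- paste0("x", twin$person_id)
  res <- suppressWarnings(dif_test(dplyr::bind_rows(resp, twin),
                                   focal = "es", reference = "en"))
  expect_true(all(res$statistic < 0.01))
  expect_false(any(res$flagged))
})

test_that("DIF results are invariant to item order; direction flips with group labels", {
  cfg <- small_config(
    seed = 9, n_en = 250, n_es = 250,
    dif_spec = tibble::tibble(item_id = "w_medium_03", language = "es",
                              delta_a = 0, delta_b = 1.2)
  )
  st <- generate_study(cfg)
  res <- suppressWarnings(dif_test(st$responses, focal = "es", reference = "en"))

  shuffled_items <- c("person_id", "language", "arm", "timepoint",
                      grep("^cov_", names(st$responses), value = TRUE),
                      sample(st$bank$item_id))
  res_shuf <- suppressWarnings(
    dif_test(st$responses[shuffled_items], focal = "es", reference = "en")
  )
  m <- match(res$item_id, res_shuf$item_id)
  expect_lt(max(abs(res_shuf$statistic[m] - res$statistic)), 0.1)

  swapped <- suppressWarnings(dif_test(st$responses, focal = "en", reference = "es"))
  target <- "w_medium_03"
  expect_true(res$flagged[res$item_id == target])
  expect_true(swapped$flagged[swapped$item_id == target])
  expect_equal(swapped$direction[swapped$item_id == target],
               -res$direction[res$item_id == target])
  expect_equal(swapped$statistic[swapped$item_id == target],
               res$statistic[res$item_id == target],
               tolerance = 0.2 * res$statistic[res$item_id == target])
})

test_that("degenerate items in either group are reported not-testable", {
  x <- random_binary_matrix(150, 6, seed = 66)
  d1 <- as_response_tibble(x, language = "en", prefix = "r")
  x2 <- random_binary_matrix(150, 6, seed = 67)
  x2[, 2] <- 1 # perfect column in the focal group only
  d2 <- as_response_tibble(x2, language = "es", prefix = "f")
  res <- suppressWarnings(dif_test(dplyr::bind_rows(d1, d2),
                                   focal = "es", reference = "en"))
  expect_true(res$not_testable[res$item_id == "it2"])
  expect_true(is.na(res$statistic[res$item_id == "it2"]))
  expect_false(any(res$not_testable[res$item_id != "it2"]))
})
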