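test_that("the item response function behaves like a 2PL", {
  expect_equal(irf(0, a = 1, b = 0), 0.5)
  expect_equal(irf(1, a = 2, b = 1), 0.5)
  expect_equal(irf(0.5, a = 1.7, b = -0.5), 1 / (1 + exp(-1.7)), tolerance = 1e-12)
  expect_equal(irf(50, a = 2, b = 1), 1, tolerance = 1e-10)
  expect_error(irf(0, a = -1, b = 0), "positive")

  # bisection: P(theta = b) = 0.5 for any a, b
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 0.1, 5)
    b <- runif(1, -4, 4)
    expect_equal(irf(b, a, b), 0.5)
  }
  # strictly increasing in theta
  th <- seq(-4, 4, length.out = 50)
  expect_true(all(diff(irf(th, a = 1.3, b = 0.2)) > 0))
})

test_that("degenerate items are excluded and flagged, not estimated", {
  x <- random_binary_matrix(150, 6, seed = 10)
  x <- cbind(x, all1 = rep(1, 150))
  fit <- suppressWarnings(fit_2pl(x))
  pars <- tidy(fit)
  expect_equal(pars$flags[pars$item_id == "all1"], "excluded_degenerate")
  expect_true(is.na(pars$b[pars$item_id == "all1"]))
  expect_true(all(is.finite(pars$b[pars$item_id != "all1"])))
})

test_that("EM solution dominates a brute-force grid on a tiny dataset", {
  # 2 items, 8 persons; grid-search oracle over (a1,b1,a2,b2) is infeasible,
  # so hold each item's parameters on a grid in turn with the other at the EM
  # solution: the EM marginal log-likelihood must be >= every grid point's
  x <- cbind(i1 = c(1, 1, 1, 0, 0, 1, 0, 0), i2 = c(1, 0, 1, 1, 0, 0, 1, 0))
  fit <- suppressWarnings(fit_2pl(x, n_quad = 61))
  pars <- tidy(fit)

  grid <- quadgrid <- seq(-6, 6, length.out = 61)
  w <- dnorm(quadgrid)
  w <- w / sum(w)
  marg_ll <- function(a, b) {
    p <- t(plogis(outer(quadgrid, b, "-") * rep(a, each = 61))) # J x Q
    llq <- x %*% log(p) + (1 - x) %*% log(1 - p)
    sum(log(exp(llq) %*% w))
  }
  em_ll <- marg_ll(pars$a, pars$b)
  expect_equal(em_ll, fit$loglik, tolerance = 1e-6)

  a_grid <- seq(0.1, 4, length.out = 15)
  b_grid <- seq(-3, 3, length.out = 15)
  for (j in 1:2) {
    for (aa in a_grid) {
      for (bb in b_grid) {
        a_try <- pars$a
        b_try <- pars$b
        a_try[j] <- aa
        b_try[j] <- bb
        expect_lte(marg_ll(a_try, b_try), em_ll + 1e-6)
      }
    }
  }
})

test_that("2PL parameter recovery on simulated data", {
  set.seed(1234)
  n <- 1000
  J <- 40
  a_true <- runif(J, 0.8, 2)
  b_true <- runif(J, -2, 2)
  theta <- rnorm(n)
  p <- plogis(outer(theta, b_true, "-") * rep(a_true, each = n))
  x <- matrix(rbinom(n * J, 1, p), n, J)
  colnames(x) <- paste0("it", 1:J)
  fit <- fit_2pl(x)
  pars <- tidy(fit)
  expect_gt(cor(pars$b, b_true), 0.95)
  expect_lt(sqrt(mean((pars$b - b_true)^2)), 0.25)
  expect_gt(cor(pars$a, a_true), 0.6)
  expect_true(all(diff(fit$trace$loglik) >= -1e-8))
  expect_true(all(is.finite(pars$se_b)))
})

test_that("refitting identical data reproduces identical estimates", {
  x <- random_binary_matrix(200, 10, seed = 55)
  f1 <- suppressWarnings(fit_2pl(x))
  f2 <- suppressWarnings(fit_2pl(x))
  expect_identical(tidy(f1), tidy(f2))
})

test_that("b recovery improves with sample size on matched seeds", {
  rmse_at_n <- function(n, seed) {
    set.seed(seed)
    J <- 15
    a_true <- runif(J, 0.8, 2)
    b_true <- runif(J, -2, 2)
    theta <- rnorm(2000)
    p <- plogis(outer(theta, b_true, "-") * rep(a_true, each = 2000))
    x <- matrix(rbinom(2000 * J, 1, p), 2000, J)
    colnames(x) <- paste0("it", 1:J)
    big <- fit_2pl(x)
    small <- fit_2pl(x[1:500, , drop = FALSE])
    c(
      big = sqrt(mean((tidy(big)$b - b_true)^2)),
      small = sqrt(mean((tidy(small)$b - b_true)^2))
    )
  }
  res <- sapply(1:5, function(s) rmse_at_n(2000, seed = 400 + s))
  expect_lt(mean(res["big", ]), mean(res["small", ]))
})

test_that("EAP scoring: prior fallback, mirror symmetry, quadrature accuracy", {
  params <- tibble::tibble(
    item_id = paste0("it", 1:20),
    a = rep(1.4, 20),
    b = c(seq(-2, 2, length.out = 10), -seq(-2, 2, length.out = 10))
  )
  # person with no responses gets the prior
  x <- matrix(NA_real_, 1, 20, dimnames = list("p0", params$item_id))
  e0 <- eap_scores(x, params)
  expect_equal(e0$theta_eap, 0)
  expect_equal(e0$theta_sd, 1)
  expect_true(e0$flagged)

  # mirrored response patterns on b-symmetric items give mirrored EAPs
  pat <- c(rep(1, 10), rep(0, 10))
  x2 <- rbind(p1 = pat, p2 = 1 - pat)
  colnames(x2) <- params$item_id
  e2 <- eap_scores(x2, params)
  expect_equal(e2$theta_eap[1], -e2$theta_eap[2], tolerance = 1e-10)

  # against a 10x-resolution quadrature oracle
  set.seed(99)
  pattern <- rbinom(20, 1, 0.5)
  x3 <- matrix(pattern, 1, 20, dimnames = list("p3", params$item_id))
  e3 <- eap_scores(x3, params)
  th <- seq(-6, 6, length.out = 610)
  wq <- dnorm(th)
  wq <- wq / sum(wq)
  lik <- sapply(th, function(t) {
    pr <- plogis(params$a * (t - params$b))
    prod(pr^pattern * (1 - pr)^(1 - pattern))
  })
  post <- lik * wq / sum(lik * wq)
  expect_equal(e3$theta_eap, sum(post * th), tolerance = 1e-4)
  expect_equal(e3$theta_sd, sqrt(sum(post * th^2) - sum(post * th)^2),
               tolerance = 1e-4)
})

test_that("EAP requires parameters for every non-degenerate item", {
  params <- tibble::tibble(item_id = c("it1", "it2"), a = 1, b = 0)
  x <- random_binary_matrix(5, 3, seed = 2)
  expect_error(eap_scores(x, params), "it3")
})
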