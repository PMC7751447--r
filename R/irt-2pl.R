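#' Two-parameter logistic item response function
#'
#' Probability of a correct response under the 2PL model,
#' `P(X = 1 | theta) = 1 / (1 + exp(-a (theta - b)))`, with discrimination
#' `a > 0` and difficulty `b` on the latent (logit) scale. At `theta = b` the
#' probability is exactly 0.5.
#'
#' @param theta Latent ability value(s).
#' @param a Discrimination (must be positive).
#' @param b Difficulty.
#' @return Probabilities in (0, 1), vectorized over the inputs.
#' @export
#' @examples
#' irf(0, a = 1, b = 0)      # 0.5
#' irf(0.5, a = 1.7, b = -0.5)
irf <- function(theta, a, b) {
  if (any(a <= 0)) abort("discrimination a must be positive")
  plogis(a * (theta - b))
}

# quadrature grid with renormalized standard-normal weights
quad_grid <- function(n_quad = 61, range = c(-6, 6), mean = 0, sd = 1) {
  nodes <- seq(range[1], range[2], length.out = n_quad)
  w <- dnorm(nodes, mean, sd)
  list(nodes = nodes, weights = w / sum(w))
}

# E-step for one group of persons: marginal log-likelihood, expected counts
# rbar/nbar (J x Q) and optionally the posterior node weights per person.
# x0: responses with NA -> 0; m: observed indicator. Thin wrapper around the
# compiled fused E-step.
estep_group <- function(x0, m, a, b, nodes, log_w, want_posterior = FALSE) {
  estep_core(x0, m, a, b, nodes, log_w, want_posterior)
}

# expected complete-data log-likelihood per item (vector over items)
mstep_objective <- function(a, b, rbar, nbar, nodes, a_prior_sd) {
  z <- tcrossprod(a, nodes) - a * b
  o <- rowSums(rbar * plogis(z, log.p = TRUE) + (nbar - rbar) * plogis(-z, log.p = TRUE))
  if (!is.null(a_prior_sd)) o <- o - (log(a))^2 / (2 * a_prior_sd^2)
  o
}

# Safeguarded Newton maximization of the expected complete-data
# log-likelihood, jointly in (a_j, b_j) for every item (compiled). Items where
# the damped Newton step fails to improve keep their previous values
# (generalized EM); a bounded quasi-Newton fallback cleans up any item left
# off a stationary point.
mstep_items <- function(a, b, rbar, nbar, nodes, a_bounds, b_bounds,
                        a_prior_sd = NULL, max_newton = 10) {
  up <- mstep_core(a, b, rbar, nbar, nodes,
                   a_bounds[1], a_bounds[2], b_bounds[1], b_bounds[2],
                   !is.null(a_prior_sd), a_prior_sd %||% 1, max_newton)
  for (j in which(up$grad_norm > 1e-4)) {
    fit <- optim(
      c(up$a[j], up$b[j]),
      fn = function(par) {
        -mstep_objective(par[1], par[2], rbar[j, , drop = FALSE],
                         nbar[j, , drop = FALSE], nodes, a_prior_sd)
      },
      method = "L-BFGS-B",
      lower = c(a_bounds[1], b_bounds[1]), upper = c(a_bounds[2], b_bounds[2])
    )
    if (-fit$value >= up$obj[j]) {
      up$a[j] <- fit$par[1]
      up$b[j] <- fit$par[2]
    }
  }
  list(a = drop(up$a), b = drop(up$b))
}

#' Fit the 2PL model by marginal maximum likelihood EM
#'
#' Bock-Aitkin marginal maximum likelihood: the latent ability is integrated
#' out over a fixed standard-normal prior on an equally spaced quadrature
#' grid, and item parameters are updated by a safeguarded Newton M-step on the
#' expected complete-data log-likelihood (with a bounded quasi-Newton
#' fallback). The N(0,1) prior fixes the latent scale, so the fit is
#' deterministic given the data and settings. Standard errors come from the
#' outer product of the per-person scores of the marginal likelihood (BHHH).
#'
#' Items with all-0 or all-1 observed responses carry no information about
#' their parameters (the likelihood is unbounded) and are excluded with flag
#' `excluded_degenerate`. Estimates landing on a bound are flagged
#' `boundary`.
#'
#' @param data Wide response tibble (one language form) or persons x items
#'   matrix with values 0/1/NA.
#' @param items Optional item ids restricting/ordering the columns used.
#' @param n_quad Number of quadrature nodes (default 61 on `quad_range`).
#' @param quad_range Quadrature interval (default `c(-6, 6)`).
#' @param a_bounds,b_bounds Box constraints on the estimates.
#' @param tol_param,tol_loglik Convergence: maximum absolute parameter change
#'   and relative marginal log-likelihood change.
#' @param max_iter Maximum EM cycles.
#' @param a_prior_sd Optional standard deviation of a log-normal penalty on
#'   `a` (off by default; useful for very small samples).
#' @return An object of class `irt2pl`: use [tidy()] for the item-parameter
#'   tibble (`item_id`, `a`, `b`, `se_a`, `se_b`, `flags`), [glance()] for the
#'   fit summary, and [autoplot()] for item characteristic curves. The
#'   iteration log-likelihood trace is in `$trace`.
#' @export
fit_2pl <- function(data, items = NULL, n_quad = 61, quad_range = c(-6, 6),
                    a_bounds = c(0.05, 6), b_bounds = c(-6, 6),
                    tol_param = 1e-4, tol_loglik = 1e-7, max_iter = 500L,
                    a_prior_sd = NULL) {
  x <- response_values(data, item_ids = items)
  if (ncol(x) < 2) abort("2PL estimation needs at least 2 items")
  if (ncol(x) < 5) warn("fewer than 5 items; estimates will be unstable")
  if (nrow(x) < 100) warn("fewer than 100 persons; estimates will be unstable")

  n_obs <- colSums(!is.na(x))
  col_mean <- colMeans(x, na.rm = TRUE)
  degenerate <- n_obs == 0 | col_mean == 0 | col_mean == 1
  ids <- colnames(x)
  xs <- x[, !degenerate, drop = FALSE]
  if (ncol(xs) < 2) abort("fewer than 2 non-degenerate items")

  grid <- quad_grid(n_quad, quad_range)
  nodes <- grid$nodes
  log_w <- log(grid$weights)
  x0 <- xs
  x0[is.na(xs)] <- 0
  m <- (!is.na(xs)) * 1

  p0 <- colMeans(xs, na.rm = TRUE)
  a <- rep(1, ncol(xs))
  b <- pmin(pmax(qlogis(1 - p0), b_bounds[1]), b_bounds[2])

  trace <- numeric(max_iter)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    es <- estep_group(x0, m, a, b, nodes, log_w)
    trace[iter] <- es$loglik
    up <- mstep_items(a, b, es$rbar, es$nbar, nodes, a_bounds, b_bounds,
                      a_prior_sd)
    delta <- max(abs(c(up$a - a, up$b - b)))
    a <- up$a
    b <- up$b
    rel_ll <- abs(es$loglik - ll_old) / (abs(es$loglik) + 1e-10)
    if (iter > 1 && delta < tol_param && rel_ll < tol_loglik) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- es$loglik
  }
  trace <- trace[seq_len(iter)]

  # final E-step quantities at the converged parameters for loglik and SEs
  es <- estep_group(x0, m, a, b, nodes, log_w, want_posterior = TRUE)
  se <- bhhh_se(a, b, x0, m, es$posterior, nodes)

  at_bound <- (abs(a - a_bounds[1]) < 1e-6 | abs(a - a_bounds[2]) < 1e-6 |
                 abs(b - b_bounds[1]) < 1e-6 | abs(b - b_bounds[2]) < 1e-6)
  flags <- ifelse(at_bound, "boundary", if (converged) "converged" else "not_converged")

  params <- tibble::tibble(
    item_id = ids,
    a = NA_real_, b = NA_real_, se_a = NA_real_, se_b = NA_real_,
    flags = "excluded_degenerate"
  )
  keep <- which(!degenerate)
  params$a[keep] <- a
  params$b[keep] <- b
  params$se_a[keep] <- se$se_a
  params$se_b[keep] <- se$se_b
  params$flags[keep] <- flags

  structure(
    list(
      params = params,
      trace = tibble::tibble(iteration = seq_along(trace), loglik = trace),
      loglik = es$loglik,
      converged = converged,
      n_iter = iter,
      n_quad = n_quad,
      quad_range = quad_range,
      n_persons = nrow(x),
      n_items = ncol(x),
      n_excluded = sum(degenerate),
      settings = list(a_bounds = a_bounds, b_bounds = b_bounds,
                      tol_param = tol_param, tol_loglik = tol_loglik,
                      a_prior_sd = a_prior_sd)
    ),
    class = "irt2pl"
  )
}

# BHHH (outer product of per-person marginal score contributions), per-item
# 2 x 2 blocks
bhhh_se <- function(a, b, x0, m, posterior, nodes) {
  p <- plogis(tcrossprod(a, nodes) - a * b) # J x Q
  a1 <- posterior %*% t(p) # n x J: E_post[P_j]
  a2 <- posterior %*% t(p * rep(nodes, each = length(a))) # E_post[P_j theta]
  t1 <- drop(posterior %*% nodes) # E_post[theta]
  s_b <- -m * (x0 - a1) * rep(a, each = nrow(x0))
  s_a <- m * (x0 * (t1 - rep(b, each = nrow(x0))) -
                (a2 - rep(b, each = nrow(x0)) * a1))
  saa <- colSums(s_a^2)
  sbb <- colSums(s_b^2)
  sab <- colSums(s_a * s_b)
  det <- saa * sbb - sab^2
  bad <- !is.finite(det) | det <= 0
  list(
    se_a = ifelse(bad, NA_real_, sqrt(sbb / det)),
    se_b = ifelse(bad, NA_real_, sqrt(saa / det))
  )
}

#' @export
print.irt2pl <- function(x, ...) {
  cat(sprintf(
    "2PL fit: %d persons, %d items (%d excluded), logLik %.2f, %d EM cycles%s\n",
    x$n_persons, x$n_items, x$n_excluded, x$loglik, x$n_iter,
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  print(x$params, n = 10)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.irt2pl <- function(x, ...) x$params

#' @exportS3Method generics::glance
glance.irt2pl <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    n_persons = x$n_persons, n_items = x$n_items, n_excluded = x$n_excluded,
    n_quad = x$n_quad
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.irt2pl <- function(object, ...) {
  params <- dplyr::filter(object$params, is.finite(.data$a))
  theta <- seq(object$quad_range[1], object$quad_range[2], length.out = 101)
  curves <- tidyr::expand_grid(item_id = params$item_id, theta = theta) |>
    dplyr::left_join(params, by = "item_id") |>
    dplyr::mutate(p = irf(.data$theta, .data$a, .data$b))
  ggplot2::ggplot(curves, ggplot2::aes(.data$theta, .data$p, group = .data$item_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = expression(theta), y = "P(correct)",
                  title = "Item characteristic curves") +
    ggplot2::theme_minimal()
}

#' EAP ability scores
#'
#' Expected a posteriori latent ability per person under the fitted 2PL item
#' parameters and a standard-normal prior, computed on the same kind of
#' quadrature grid as the calibration. A person with no non-missing responses
#' gets the prior back (`theta_eap = 0`, `theta_sd = 1`) and is flagged.
#'
#' @param data Wide response tibble or persons x items matrix.
#' @param params An `irt2pl` fit or an item-parameter tibble with `item_id`,
#'   `a`, `b`. Items flagged `excluded_degenerate` (NA parameters) are
#'   ignored; all other item columns in `data` must be covered.
#' @param n_quad,quad_range Quadrature settings (default 61 nodes on
#'   `[-6, 6]`).
#' @return Tibble `person_id`, `theta_eap`, `theta_sd`, `n_answered`,
#'   `flagged`.
#' @export
eap_scores <- function(data, params, n_quad = 61, quad_range = c(-6, 6)) {
  if (inherits(params, "irt2pl")) params <- params$params
  params <- tibble::as_tibble(params)
  x <- response_values(data)
  uncovered <- setdiff(colnames(x), params$item_id)
  if (length(uncovered) > 0) {
    abort(paste0("no parameters for item(s): ", paste(uncovered, collapse = ", ")))
  }
  # items excluded as degenerate (NA parameters) are dropped from scoring
  params <- dplyr::filter(params, is.finite(.data$a), is.finite(.data$b))
  usable <- intersect(colnames(x), params$item_id)
  if (length(usable) == 0) abort("no item in the data has parameters")
  x <- x[, usable, drop = FALSE]
  params <- params[match(usable, params$item_id), ]
  grid <- quad_grid(n_quad, quad_range)
  x0 <- x
  x0[is.na(x)] <- 0
  m <- (!is.na(x)) * 1
  es <- estep_group(x0, m, params$a, params$b, grid$nodes, log(grid$weights),
                    want_posterior = TRUE)
  eap <- unname(drop(es$posterior %*% grid$nodes))
  e2 <- unname(drop(es$posterior %*% grid$nodes^2))
  sd_post <- sqrt(pmax(e2 - eap^2, 0))
  n_answered <- unname(rowSums(m))
  tibble::tibble(
    person_id = rownames(x),
    theta_eap = ifelse(n_answered == 0, 0, eap),
    theta_sd = ifelse(n_answered == 0, 1, sd_post),
    n_answered = as.integer(n_answered),
    flagged = n_answered == 0
  )
}
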