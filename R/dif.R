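# Two-group 2PL MML-EM used by the likelihood-ratio DIF test.
#
# The reference group's ability distribution is fixed at N(0,1); the focal
# group's mean and standard deviation are estimated by EM moment updates so
# that true group impact (a mean/variance difference) is absorbed by the
# distribution rather than by the item parameters. Items in `free` get
# separate parameters per group; all other items (the anchors) share one
# parameter pair across groups, which identifies the focal metric.
fit_2pl_two_group <- function(x_ref, x_foc, free = NULL,
                              n_quad = 61, quad_range = c(-6, 6),
                              a_bounds = c(0.05, 6), b_bounds = c(-6, 6),
                              tol_param = 1e-4, tol_loglik = 1e-7,
                              max_iter = 500L, start = NULL) {
  stopifnot(identical(colnames(x_ref), colnames(x_foc)))
  J <- ncol(x_ref)
  free <- free %||% rep(FALSE, J)
  grid <- quad_grid(n_quad, quad_range)
  nodes <- grid$nodes
  log_w_ref <- log(grid$weights)

  prep <- function(x) {
    x0 <- x
    x0[is.na(x)] <- 0
    list(x0 = x0, m = (!is.na(x)) * 1)
  }
  r <- prep(x_ref)
  f <- prep(x_foc)

  if (is.null(start)) {
    p0 <- colMeans(rbind(x_ref, x_foc), na.rm = TRUE)
    start <- list(
      a_ref = rep(1, J),
      b_ref = pmin(pmax(qlogis(1 - p0), b_bounds[1]), b_bounds[2]),
      a_foc = NULL, b_foc = NULL, mu = 0, sigma = 1
    )
  }
  a_ref <- start$a_ref
  b_ref <- start$b_ref
  a_foc <- start$a_foc %||% a_ref
  b_foc <- start$b_foc %||% b_ref
  a_foc[!free] <- a_ref[!free]
  b_foc[!free] <- b_ref[!free]
  mu <- start$mu
  sigma <- start$sigma

  n_foc <- nrow(x_foc)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  loglik <- NA_real_
  repeat {
    iter <- iter + 1L
    w_foc <- dnorm(nodes, mu, sigma)
    log_w_foc <- log(w_foc / sum(w_foc))
    es_r <- estep_group(r$x0, r$m, a_ref, b_ref, nodes, log_w_ref)
    es_f <- estep_group(f$x0, f$m, a_foc, b_foc, nodes, log_w_foc)
    loglik <- es_r$loglik + es_f$loglik

    # stack shared items (pooled counts) and per-group rows for free items so
    # one vectorized Newton M-step updates everything at once
    shared <- which(!free)
    fr <- which(free)
    rbar <- rbind(es_r$rbar[shared, , drop = FALSE] + es_f$rbar[shared, , drop = FALSE],
                  es_r$rbar[fr, , drop = FALSE],
                  es_f$rbar[fr, , drop = FALSE])
    nbar <- rbind(es_r$nbar[shared, , drop = FALSE] + es_f$nbar[shared, , drop = FALSE],
                  es_r$nbar[fr, , drop = FALSE],
                  es_f$nbar[fr, , drop = FALSE])
    a_stack <- c(a_ref[shared], a_ref[fr], a_foc[fr])
    b_stack <- c(b_ref[shared], b_ref[fr], b_foc[fr])
    up <- mstep_items(a_stack, b_stack, rbar, nbar, nodes, a_bounds, b_bounds)

    a_new_ref <- a_ref
    b_new_ref <- b_ref
    a_new_foc <- a_foc
    b_new_foc <- b_foc
    k <- length(shared)
    a_new_ref[shared] <- up$a[seq_len(k)]
    b_new_ref[shared] <- up$b[seq_len(k)]
    a_new_foc[shared] <- a_new_ref[shared]
    b_new_foc[shared] <- b_new_ref[shared]
    if (length(fr) > 0) {
      a_new_ref[fr] <- up$a[k + seq_along(fr)]
      b_new_ref[fr] <- up$b[k + seq_along(fr)]
      a_new_foc[fr] <- up$a[k + length(fr) + seq_along(fr)]
      b_new_foc[fr] <- up$b[k + length(fr) + seq_along(fr)]
    }

    # focal latent distribution: posterior moments (EM update)
    pw <- drop(es_f$pw)
    mu_new <- sum(pw * nodes) / n_foc
    sigma_new <- sqrt(max(sum(pw * nodes^2) / n_foc - mu_new^2, 0.01))
    mu_new <- min(max(mu_new, -3), 3)
    sigma_new <- min(max(sigma_new, 0.1), 3)

    delta <- max(abs(c(a_new_ref - a_ref, b_new_ref - b_ref,
                       a_new_foc - a_foc, b_new_foc - b_foc,
                       mu_new - mu, sigma_new - sigma)))
    a_ref <- a_new_ref
    b_ref <- b_new_ref
    a_foc <- a_new_foc
    b_foc <- b_new_foc
    mu <- mu_new
    sigma <- sigma_new
    rel_ll <- abs(loglik - ll_old) / (abs(loglik) + 1e-10)
    if (iter > 1 && delta < tol_param && rel_ll < tol_loglik) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- loglik
  }
  # log-likelihood at the final parameter values
  w_foc <- dnorm(nodes, mu, sigma)
  es_r <- estep_group(r$x0, r$m, a_ref, b_ref, nodes, log_w_ref)
  es_f <- estep_group(f$x0, f$m, a_foc, b_foc, nodes, log(w_foc / sum(w_foc)))
  list(
    a_ref = a_ref, b_ref = b_ref, a_foc = a_foc, b_foc = b_foc,
    mu = mu, sigma = sigma,
    loglik = es_r$loglik + es_f$loglik,
    converged = converged, n_iter = iter
  )
}

#' Likelihood-ratio test of differential item functioning
#'
#' IRT likelihood-ratio DIF with all-other-items anchoring: for each studied
#' item, a constrained two-group 2PL (every item's parameters equal across
#' groups) is compared with an augmented model in which the studied item's
#' discrimination and difficulty are freed per group while the remaining
#' items stay anchored. In both models the reference group's ability is
#' N(0,1) and the focal group's mean and standard deviation are estimated, so
#' group impact is separated from item-level DIF. The statistic
#' `2 (logL_free - logL_constrained)` is referred to a chi-square with 2
#' degrees of freedom (both `a` and `b` freed).
#'
#' With `purify = TRUE` a single purification pass is run: items flagged in
#' the first round are removed from the anchor set (freed across groups in
#' both models) and every item is retested.
#'
#' @param data Wide response tibble holding both groups.
#' @param focal,reference Values of `group_col` identifying the two groups.
#' @param group_col Name of the grouping column (default `"language"`).
#' @param items Optional item ids restricting the analysis.
#' @param alpha Flagging level (default 0.05), applied to the adjusted p.
#' @param adjustment `"BH"` (Benjamini-Hochberg, default) or `"none"`.
#' @param purify Run one anchor-purification pass (default `FALSE`).
#' @param ... Estimation settings passed to the underlying two-group EM
#'   (`n_quad`, bounds, tolerances, `max_iter`).
#' @return Tibble of class `dif_result`: `item_id`, `statistic`, `df`,
#'   `p_value`, `adjusted_p`, `flagged`, `direction` (sign of
#'   `b_focal - b_reference` on the common metric), `not_testable`.
#'   Attributes carry the constrained log-likelihood and the estimated focal
#'   ability mean/sd.
#' @export
dif_test <- function(data, focal, reference, group_col = "language",
                     items = NULL, alpha = 0.05,
                     adjustment = c("BH", "none"), purify = FALSE, ...) {
  adjustment <- match.arg(adjustment)
  data <- tibble::as_tibble(data)
  if (!group_col %in% names(data)) {
    abort(paste0("grouping column '", group_col, "' not found"))
  }
  x_ref <- response_values(data[data[[group_col]] == reference, , drop = FALSE],
                           item_ids = items)
  x_foc <- response_values(data[data[[group_col]] == focal, , drop = FALSE],
                           item_ids = items)
  common <- intersect(colnames(x_ref), colnames(x_foc))
  x_ref <- x_ref[, common, drop = FALSE]
  x_foc <- x_foc[, common, drop = FALSE]
  if (nrow(x_ref) == 0 || nrow(x_foc) == 0) abort("a group has no rows")
  if (min(nrow(x_ref), nrow(x_foc)) < 100) {
    warn("fewer than 100 persons in a group; DIF tests will be unstable")
  }

  degen <- function(x) {
    cm <- colMeans(x, na.rm = TRUE)
    colSums(!is.na(x)) == 0 | cm == 0 | cm == 1
  }
  not_testable <- degen(x_ref) | degen(x_foc)
  ids <- common
  keep <- which(!not_testable)
  if (length(keep) < 2) abort("fewer than 2 testable items")
  xr <- x_ref[, keep, drop = FALSE]
  xf <- x_foc[, keep, drop = FALSE]

  res <- dif_round(xr, xf, free_base = rep(FALSE, length(keep)), ...)
  out <- res$table
  out$adjusted_p <- if (adjustment == "BH") p.adjust(out$p_value, "BH") else out$p_value
  out$flagged <- !is.na(out$adjusted_p) & out$adjusted_p < alpha

  if (purify && any(out$flagged)) {
    free_base <- out$flagged
    res <- dif_round(xr, xf, free_base = free_base, ...)
    out <- res$table
    out$adjusted_p <- if (adjustment == "BH") p.adjust(out$p_value, "BH") else out$p_value
    out$flagged <- !is.na(out$adjusted_p) & out$adjusted_p < alpha
  }

  full <- tibble::tibble(
    item_id = ids, statistic = NA_real_, df = 2L, p_value = NA_real_,
    adjusted_p = NA_real_, flagged = FALSE, direction = NA_real_,
    not_testable = not_testable
  )
  idx <- match(out$item_id, full$item_id)
  full$statistic[idx] <- out$statistic
  full$p_value[idx] <- out$p_value
  full$adjusted_p[idx] <- out$adjusted_p
  full$flagged[idx] <- out$flagged
  full$direction[idx] <- out$direction
  attr(full, "loglik_constrained") <- res$loglik_constrained
  attr(full, "focal_mu") <- res$mu
  attr(full, "focal_sigma") <- res$sigma
  class(full) <- c("dif_result", class(full))
  full
}

# one round of per-item LR tests given a base set of freed (non-anchor) items
dif_round <- function(xr, xf, free_base, ...) {
  J <- ncol(xr)
  # constrained fit for items outside free_base shares one fit; for studied
  # items inside free_base the constrained model still holds that item equal
  base_fit <- fit_2pl_two_group(xr, xf, free = free_base, ...)
  rows <- purrr::map(seq_len(J), function(j) {
    free_con <- free_base
    free_con[j] <- FALSE
    con <- if (identical(free_con, free_base)) {
      base_fit
    } else {
      fit_2pl_two_group(xr, xf, free = free_con, ...,
                        start = warm_start(base_fit, free_con))
    }
    free_aug <- free_base
    free_aug[j] <- TRUE
    aug <- fit_2pl_two_group(xr, xf, free = free_aug, ...,
                             start = warm_start(con, free_aug))
    stat <- max(0, 2 * (aug$loglik - con$loglik))
    tibble::tibble(
      item_id = colnames(xr)[j],
      statistic = stat,
      df = 2L,
      p_value = pchisq(stat, df = 2, lower.tail = FALSE),
      direction = sign(aug$b_foc[j] - aug$b_ref[j])
    )
  })
  list(
    table = purrr::list_rbind(rows),
    loglik_constrained = base_fit$loglik,
    mu = base_fit$mu,
    sigma = base_fit$sigma
  )
}

warm_start <- function(fit, free) {
  list(a_ref = fit$a_ref, b_ref = fit$b_ref,
       a_foc = fit$a_foc, b_foc = fit$b_foc,
       mu = fit$mu, sigma = fit$sigma)
}
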