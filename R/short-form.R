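#' Fit the selection mean curve
#'
#' Fits a cubic smoothing spline of the corrected item-total correlation on
#' percent correct across items — the mean curve of the discrimination vs
#' difficulty scatter. Items above this curve discriminate better than the
#' average item of their difficulty, which is the short-form selection
#' criterion. Smoothing is chosen by generalized cross-validation; with fewer
#' than 15 usable points GCV is unstable, so a fixed effective
#' degrees-of-freedom fit (default 4) is used instead.
#'
#' @param stats Item statistics tibble from [item_statistics()] (one
#'   language), with columns `item_id`, `p`, `r_it`.
#' @param df Fixed effective degrees of freedom; `NULL` (default) lets GCV
#'   choose when there are at least 15 points.
#' @param fallback_df Effective df used when GCV is not attempted (default 4).
#' @return Object of class `selection_curve`: the spline fit, the per-item
#'   tibble with fitted values and residuals (`residual = r_it - f(p)`), and
#'   the smoothing actually used. [tidy()] returns the per-item tibble;
#'   [autoplot()] draws the scatter with the curve.
#' @export
fit_mean_curve <- function(stats, df = NULL, fallback_df = 4) {
  stats <- tibble::as_tibble(stats)
  usable <- dplyr::filter(stats, is.finite(.data$p), is.finite(.data$r_it))
  if (nrow(usable) < 5) {
    abort(paste0(
      "mean curve needs at least 5 items with defined item-total correlation ",
      "(got ", nrow(usable), "); consider a fixed-df linear fit on more data"
    ))
  }
  n_unique <- length(unique(usable$p))
  gcv_used <- is.null(df) && n_unique >= 15
  if (gcv_used) {
    fit <- smooth.spline(usable$p, usable$r_it, cv = FALSE, keep.data = FALSE)
  } else {
    df_use <- min(df %||% fallback_df, n_unique - 1)
    df_use <- max(df_use, 2)
    fit <- smooth.spline(usable$p, usable$r_it, df = df_use, keep.data = FALSE)
  }
  fitted_r <- predict(fit, usable$p)$y
  usable$fitted <- fitted_r
  usable$residual <- usable$r_it - fitted_r
  structure(
    list(
      spline = fit,
      data = usable,
      gcv_used = gcv_used,
      df_used = fit$df,
      p_range = range(usable$p)
    ),
    class = "selection_curve"
  )
}

#' Evaluate a selection curve
#'
#' @param curve A `selection_curve`.
#' @param p Percent-correct values.
#' @return Expected item-total correlation at `p`.
#' @export
predict_curve <- function(curve, p) {
  predict(curve$spline, p)$y
}

#' @exportS3Method generics::tidy
tidy.selection_curve <- function(x, ...) x$data

#' @export
print.selection_curve <- function(x, ...) {
  cat(sprintf(
    "selection mean curve: %d items, %s (effective df %.2f), p in [%.1f, %.1f]\n",
    nrow(x$data), if (x$gcv_used) "GCV smoothing" else "fixed-df smoothing",
    x$df_used, x$p_range[1], x$p_range[2]
  ))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.selection_curve <- function(object, ...) {
  grid <- tibble::tibble(p = seq(object$p_range[1], object$p_range[2],
                                 length.out = 200))
  grid$fitted <- predict_curve(object, grid$p)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$p, .data$r_it)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$p, .data$fitted),
                       colour = "steelblue") +
    ggplot2::labs(x = "Percent correct", y = "Item-total correlation",
                  title = "Item discrimination vs difficulty with mean curve") +
    ggplot2::theme_minimal()
}

#' Largest-remainder quota allocation
#'
#' Allocates a target form length over the difficulty strata proportionally
#' to the stratum sizes, so the short form keeps the difficulty distribution
#' of the full scale: each stratum gets the floor of its proportional share,
#' and leftover seats go to the largest fractional remainders (ties broken in
#' stratum order low, medium, high). For an 82-item bank split 29/28/25 this
#' yields 14/14/12 at length 40 and 7/7/6 at length 20.
#'
#' @param sizes Named (or low/medium/high ordered) integer vector of stratum
#'   sizes, all positive.
#' @param L Target form length, at most `sum(sizes)`.
#' @return Tibble `stratum`, `n_items`, `quota`.
#' @export
#' @examples
#' allocate_quotas(c(low = 29, medium = 28, high = 25), 40)
allocate_quotas <- function(sizes, L) {
  if (is.null(names(sizes))) names(sizes) <- .strata[seq_along(sizes)]
  sizes <- sizes[.strata[.strata %in% names(sizes)]]
  if (any(sizes <= 0)) abort("all stratum sizes must be positive")
  if (L > sum(sizes)) {
    abort(sprintf("target length %d exceeds the %d available items", L, sum(sizes)))
  }
  share <- L * sizes / sum(sizes)
  quota <- floor(share)
  rem <- share - quota
  left <- L - sum(quota)
  if (left > 0) {
    # stable order: descending remainder, ties in stratum order low->medium->high
    ord <- order(-rem, seq_along(rem))
    quota[ord[seq_len(left)]] <- quota[ord[seq_len(left)]] + 1
  }
  quota <- pmin(quota, sizes)
  # seats lost to the size cap (rare) go to the next largest remainders
  while (sum(quota) < L) {
    room <- which(quota < sizes)
    ord <- room[order(-rem[room], room)]
    quota[ord[1]] <- quota[ord[1]] + 1
  }
  tibble::tibble(
    stratum = names(sizes),
    n_items = as.integer(sizes),
    quota = as.integer(quota)
  )
}

#' Select short-form items above the mean curve
#'
#' The item-reduction rule: within each difficulty stratum, rank candidate
#' items by their residual above the mean curve (ties broken by higher
#' item-total correlation, then by earlier bank position) and take the top
#' items up to the stratum quota. Items whose percent correct falls outside
#' `p_range` are excluded first. If a stratum has too few above-curve items,
#' the best below-curve residuals fill the quota and the form is flagged.
#' Passing a parent selection restricts candidates to the parent's items,
#' which yields nested forms (e.g. a 20-item form inside the 40-item form).
#'
#' @param stats Item statistics tibble (one language) with `item_id`, `p`,
#'   `r_it`.
#' @param curve A `selection_curve` from [fit_mean_curve()] on the same
#'   statistics.
#' @param quotas Quota tibble from [allocate_quotas()].
#' @param bank Item bank supplying strata and the bank order for
#'   tie-breaking.
#' @param p_range Acceptable percent-correct bounds (default `c(5, 95)`);
#'   `NULL` disables the restriction.
#' @param parent Optional parent `short_form` result for nesting.
#' @param language Label recorded on the result.
#' @return Tibble of class `short_form` with one row per selected item:
#'   `item_id`, `stratum`, `p`, `r_it`, `residual`, `rank` (within stratum),
#'   `above_curve`, `quota_fill`. Attributes: `L`, `quotas`, `parent_L`,
#'   `flagged_strata`, `language`.
#' @export
select_items <- function(stats, curve, quotas, bank, p_range = c(5, 95),
                         parent = NULL, language = NULL) {
  stats <- tibble::as_tibble(stats)
  cand <- dplyr::inner_join(
    dplyr::select(stats, "item_id", "p", "r_it"),
    dplyr::mutate(dplyr::select(bank, "item_id", "stratum"),
                  bank_pos = dplyr::row_number()),
    by = "item_id"
  )
  cand <- dplyr::filter(cand, is.finite(.data$p), is.finite(.data$r_it))
  if (!is.null(parent)) {
    cand <- dplyr::filter(cand, .data$item_id %in% parent$item_id)
  }
  if (!is.null(p_range)) {
    cand <- dplyr::filter(cand, .data$p >= p_range[1], .data$p <= p_range[2])
  }
  cand$residual <- cand$r_it - predict_curve(curve, cand$p)

  flagged <- character(0)
  pick_stratum <- function(s, q) {
    pool <- cand[cand$stratum == s, , drop = FALSE]
    if (nrow(pool) < q) {
      abort(sprintf(
        "stratum '%s': quota %d cannot be filled from %d candidate item(s)",
        s, q, nrow(pool)
      ))
    }
    pool <- pool[order(-pool$residual, -pool$r_it, pool$bank_pos), , drop = FALSE]
    sel <- utils::head(pool, q)
    sel$rank <- seq_len(nrow(sel))
    sel$above_curve <- sel$residual > 0
    sel$quota_fill <- !sel$above_curve
    sel
  }
  parts <- purrr::map2(quotas$stratum, quotas$quota, pick_stratum)
  flagged <- quotas$stratum[purrr::map_lgl(parts, ~ any(.x$quota_fill))]
  out <- purrr::list_rbind(parts) |>
    dplyr::select("item_id", "stratum", "p", "r_it", "residual", "rank",
                  "above_curve", "quota_fill")
  attr(out, "L") <- sum(quotas$quota)
  attr(out, "quotas") <- quotas
  attr(out, "parent_L") <- if (is.null(parent)) NA_integer_ else attr(parent, "L")
  attr(out, "flagged_strata") <- flagged
  attr(out, "language") <- language %||% (if ("language" %in% names(stats)) stats$language[1] else NA_character_)
  class(out) <- c("short_form", class(out))
  out
}

#' @export
print.short_form <- function(x, ...) {
  q <- attr(x, "quotas")
  cat(sprintf("%d-item form (quotas %s)%s\n", attr(x, "L"),
              paste(q$quota, collapse = "/"),
              if (is.na(attr(x, "parent_L"))) "" else
                sprintf(", nested in %d-item form", attr(x, "parent_L"))))
  if (length(attr(x, "flagged_strata")) > 0) {
    cat("below-curve quota fill in strata:",
        paste(attr(x, "flagged_strata"), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Cross-language review of a selection
#'
#' The selection is driven by the reference language's statistics; this
#' advisory report recomputes each selected item's residual from the mean
#' curve of every other language and lists items that fall below the curve in
#' any of them as review candidates. No automatic swaps are made.
#'
#' @param selection A `short_form` result.
#' @param stats_by_language Item statistics for the other languages: a tibble
#'   with a `language` column (reference-language rows, matching the
#'   selection's `language` attribute, are ignored).
#' @param ... Passed to [fit_mean_curve()] for the per-language curves.
#' @return Tibble with one row per selected item x other language:
#'   `item_id`, `stratum`, `language`, `residual`, `below_curve`,
#'   `review_candidate` (below the curve in that language).
#' @export
multi_language_review <- function(selection, stats_by_language, ...) {
  stats_by_language <- tibble::as_tibble(stats_by_language)
  if (!"language" %in% names(stats_by_language)) {
    abort("stats_by_language needs a language column")
  }
  ref_lang <- attr(selection, "language")
  others <- dplyr::filter(stats_by_language,
                          is.na(ref_lang) | .data$language != ref_lang)
  if (nrow(others) == 0) abort("no other-language statistics supplied")
  per_lang <- split(others, others$language)
  rows <- purrr::imap(per_lang, function(s, lang) {
    curve <- fit_mean_curve(s, ...)
    sel <- dplyr::inner_join(
      dplyr::select(tibble::as_tibble(selection), "item_id", "stratum"),
      dplyr::select(s, "item_id", "p", "r_it"),
      by = "item_id"
    )
    sel$language <- lang
    sel$residual <- sel$r_it - predict_curve(curve, sel$p)
    sel$below_curve <- sel$residual < 0
    sel
  })
  out <- purrr::list_rbind(rows)
  out$review_candidate <- out$below_curve
  dplyr::select(out, "item_id", "stratum", "language", "p", "r_it",
                "residual", "below_curve", "review_candidate")
}
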