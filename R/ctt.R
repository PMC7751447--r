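#' Cronbach's alpha
#'
#' Internal-consistency reliability by the variance decomposition
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`, with
#' sample (n-1) variances. On dichotomous items this equals KR-20. Rows with
#' any missing response are dropped (listwise deletion) because the
#' decomposition needs complete total scores.
#'
#' @param data Wide response tibble or a persons x items numeric matrix.
#' @param items Optional item ids restricting to a form.
#' @return Alpha as a single number; `NA` (with a warning) when the total
#'   score has zero variance or fewer than 2 complete rows remain.
#' @export
cronbach_alpha <- function(data, items = NULL) {
  x <- response_values(data, item_ids = items)
  if (ncol(x) < 2) abort("Cronbach's alpha needs at least 2 items")
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2) {
    warn("fewer than 2 complete rows; alpha undefined")
    return(NA_real_)
  }
  total_var <- var(rowSums(x))
  if (total_var == 0) {
    warn("total score has zero variance; alpha undefined")
    return(NA_real_)
  }
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' Per-item classical statistics
#'
#' Percent correct (`p`, the CTT difficulty index: higher = easier) and the
#' corrected item-total correlation (`r_it`, the CTT discrimination index:
#' Pearson correlation of the item with the rest-score, the total over the
#' remaining items). Both use the persons with a non-missing response on the
#' item (pairwise handling); the rest-score sums the items each such person
#' answered. When a `language` column is present, statistics are computed per
#' language.
#'
#' @param data Wide response tibble or numeric matrix.
#' @param bank Optional item bank; adds the `stratum` column and validates ids.
#' @param items Optional item ids restricting to a form.
#' @param corrected Use the rest-score (default `TRUE`); `FALSE` correlates
#'   the item with the full total including itself.
#' @return Tibble `item_id`, `language`, `n_used`, `p`, `r_it` (NA when the
#'   item or rest-score is constant), plus `stratum` when `bank` is given.
#' @export
item_statistics <- function(data, bank = NULL, items = NULL, corrected = TRUE) {
  if (!is.matrix(data) && "language" %in% names(data)) {
    groups <- split(tibble::as_tibble(data), data$language)
    out <- purrr::list_rbind(purrr::imap(groups, function(d, lang) {
      s <- item_statistics_matrix(response_values(d, item_ids = items), corrected)
      s$language <- lang
      s
    }))
  } else {
    out <- item_statistics_matrix(response_values(data, item_ids = items), corrected)
    out$language <- NA_character_
  }
  out <- dplyr::relocate(out, "item_id", "language")
  if (!is.null(bank)) {
    unknown <- setdiff(out$item_id, bank$item_id)
    if (length(unknown) > 0) {
      abort(paste0("items not in bank: ", paste(unknown, collapse = ", ")))
    }
    out <- dplyr::left_join(out, dplyr::select(bank, "item_id", "stratum"),
                            by = "item_id")
  }
  out
}

item_statistics_matrix <- function(x, corrected = TRUE) {
  totals <- rowSums(x, na.rm = TRUE)
  stats_one <- function(j) {
    obs <- !is.na(x[, j])
    xj <- x[obs, j]
    rest <- if (corrected) totals[obs] - xj else totals[obs]
    r <- if (length(xj) < 2 || sd(xj) == 0 || sd(rest) == 0) NA_real_ else cor(xj, rest)
    tibble::tibble(
      item_id = colnames(x)[j],
      n_used = sum(obs),
      p = 100 * mean(xj),
      r_it = r
    )
  }
  purrr::list_rbind(purrr::map(seq_len(ncol(x)), stats_one))
}

#' Summarise a form's reliability
#'
#' Collapses per-item statistics to the conventional reporting layout: the
#' median and range of the item-total correlations and of percent correct,
#' with Cronbach's alpha attached.
#'
#' @param stats Tibble from [item_statistics()] (one language/form).
#' @param alpha Cronbach's alpha for the same form (from [cronbach_alpha()]).
#' @return One-row tibble: `language`, `k`, `alpha`, and median/min/max of
#'   `r_it` and `p`.
#' @export
summarize_scale <- function(stats, alpha = NA_real_) {
  if (nrow(stats) == 0) abort("empty item statistics")
  r <- stats$r_it[is.finite(stats$r_it)]
  p <- stats$p[is.finite(stats$p)]
  tibble::tibble(
    language = if ("language" %in% names(stats)) stats$language[1] else NA_character_,
    k = nrow(stats),
    alpha = alpha,
    r_it_median = median(r), r_it_min = min(r), r_it_max = max(r),
    p_median = median(p), p_min = min(p), p_max = max(p)
  )
}

#' Alpha if item deleted
#'
#' @param data Wide response tibble or matrix.
#' @param items Optional item ids restricting to a form.
#' @return Tibble `item_id`, `alpha_if_deleted`.
#' @export
alpha_if_deleted <- function(data, items = NULL) {
  x <- response_values(data, item_ids = items)
  ids <- colnames(x)
  purrr::list_rbind(purrr::map(seq_along(ids), function(j) {
    tibble::tibble(
      item_id = ids[j],
      alpha_if_deleted = suppressWarnings(cronbach_alpha(x[, -j, drop = FALSE]))
    )
  }))
}
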