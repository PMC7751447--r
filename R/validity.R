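#' Convergent-validity correlation matrix
#'
#' Pairwise Pearson correlations between form scores and external criterion
#' measures (e.g. a functional health-literacy score, education level,
#' disease knowledge), with two-sided p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. Pairs
#' use pairwise-complete observations; when a `language` column is present
#' the matrix is computed per language.
#'
#' @param data Person-level tibble holding the score and covariate columns.
#' @param vars Character vector of column names to correlate.
#' @return Tibble with one row per unordered pair (lower triangle):
#'   `language`, `var1`, `var2`, `n`, `r`, `p_value`, `undefined` (`TRUE`
#'   when a variable is constant in the pairwise-complete set).
#' @export
convergent_validity <- function(data, vars) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("variables not in data: ", paste(missing_cols, collapse = ", ")))
  }
  groups <- if ("language" %in% names(data)) split(data, data$language) else list(data)
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  rows <- purrr::imap(groups, function(d, lang) {
    purrr::map(pairs, function(pr) {
      x <- d[[pr[1]]]
      y <- d[[pr[2]]]
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        return(tibble::tibble(
          language = if (is.character(lang)) lang else NA_character_,
          var1 = pr[1], var2 = pr[2], n = n,
          r = NA_real_, p_value = NA_real_, undefined = TRUE
        ))
      }
      r <- cor(x[ok], y[ok])
      t_stat <- r * sqrt((n - 2) / (1 - r^2))
      tibble::tibble(
        language = if (is.character(lang)) lang else NA_character_,
        var1 = pr[1], var2 = pr[2], n = n, r = r,
        p_value = 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE),
        undefined = FALSE
      )
    }) |> purrr::list_rbind()
  })
  purrr::list_rbind(rows)
}

#' Intervention-sensitivity difference-in-change analysis
#'
#' Summarises a two-arm longitudinal administration the way sensitivity
#' tables are reported: per timepoint, the mean percent score and its
#' standard error overall and per arm; at baseline, the raw between-arm gap;
#' at each follow-up, the between-arm difference in mean change from baseline
#' (each person's follow-up score minus their own baseline score), with a
#' Welch two-sample test on the change scores. Stars mark `p < .05` (`*`) and
#' `p < .01` (`**`).
#'
#' @param scores Person-level long scores: columns `person_id`, `arm`
#'   (`intervention`/`control`), `timepoint` (`baseline` first), and the
#'   score column named by `value`.
#' @param value Name of the score column (default `"percent"`).
#' @param form Optional label copied into the output.
#' @return Tibble of class `sensitivity_table`, one row per timepoint:
#'   overall/intervention/control mean and SE, `difference`, `difference_se`,
#'   `p_value`, `sig`. A cell with fewer than 2 persons yields `NA` SE and is
#'   flagged in `low_n`.
#' @export
sensitivity_analysis <- function(scores, value = "percent", form = NULL) {
  scores <- tibble::as_tibble(scores)
  needed <- c("person_id", "arm", "timepoint", value)
  missing_cols <- setdiff(needed, names(scores))
  if (length(missing_cols) > 0) {
    abort(paste0("scores lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  scores$score <- scores[[value]]
  arms <- setdiff(unique(scores$arm), "none")
  if (!all(c("intervention", "control") %in% arms)) {
    abort("sensitivity analysis needs both an intervention and a control arm")
  }
  tps <- intersect(.timepoints, unique(scores$timepoint))
  tps <- setdiff(tps, "none")
  if (!"baseline" %in% tps) abort("no baseline timepoint present")
  if (length(tps) < 2) abort("need baseline plus at least one follow-up")

  baseline <- scores |>
    dplyr::filter(.data$timepoint == "baseline") |>
    dplyr::select("person_id", baseline_score = "score")
  scores <- dplyr::left_join(scores, baseline, by = "person_id") |>
    dplyr::mutate(change = .data$score - .data$baseline_score)

  mse <- function(v) {
    v <- v[is.finite(v)]
    tibble::tibble(
      mean = if (length(v) > 0) mean(v) else NA_real_,
      se = if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_,
      n = length(v)
    )
  }
  rows <- purrr::map(tps, function(tp) {
    d <- scores[scores$timepoint == tp, , drop = FALSE]
    all_s <- mse(d$score)
    int_s <- mse(d$score[d$arm == "intervention"])
    ctl_s <- mse(d$score[d$arm == "control"])
    if (tp == "baseline") {
      di <- d$score[d$arm == "intervention"]
      dc <- d$score[d$arm == "control"]
    } else {
      di <- d$change[d$arm == "intervention"]
      dc <- d$change[d$arm == "control"]
    }
    di <- di[is.finite(di)]
    dc <- dc[is.finite(dc)]
    if (length(di) >= 2 && length(dc) >= 2 && (sd(di) > 0 || sd(dc) > 0)) {
      tt <- t.test(di, dc)
      diff <- mean(di) - mean(dc)
      diff_se <- sqrt(sd(di)^2 / length(di) + sd(dc)^2 / length(dc))
      p <- tt$p.value
    } else {
      diff <- if (length(di) > 0 && length(dc) > 0) mean(di) - mean(dc) else NA_real_
      diff_se <- NA_real_
      p <- if (!is.na(diff) && diff == 0) 1 else NA_real_
    }
    tibble::tibble(
      form = form %||% NA_character_,
      timepoint = tp,
      overall_mean = all_s$mean, overall_se = all_s$se,
      intervention_mean = int_s$mean, intervention_se = int_s$se,
      control_mean = ctl_s$mean, control_se = ctl_s$se,
      difference = diff, difference_se = diff_se,
      p_value = p,
      sig = dplyr::case_when(
        is.na(p) ~ "",
        p < 0.01 ~ "**",
        p < 0.05 ~ "*",
        TRUE ~ ""
      ),
      low_n = int_s$n < 2 | ctl_s$n < 2
    )
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("sensitivity_table", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.sensitivity_table <- function(object, ...) {
  long <- object |>
    dplyr::select("timepoint", intervention = "intervention_mean",
                  control = "control_mean") |>
    tidyr::pivot_longer(-"timepoint", names_to = "arm", values_to = "mean")
  long$timepoint <- factor(long$timepoint, levels = .timepoints)
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$mean,
                                     group = .data$arm, colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "Mean percent score",
                  title = "Arm means by timepoint") +
    ggplot2::theme_minimal()
}
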