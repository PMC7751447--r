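#' Run the full scale-development pipeline
#'
#' Orchestrates the analysis stages in their natural order on one study's
#' data: content-validity screening (when expert ratings are supplied),
#' classical statistics per language, 2PL calibration per language, mean/sigma
#' equating of every focal language to the reference, likelihood-ratio DIF
#' tests against the reference, the difficulty-separation report, nested
#' short-form selection driven by the reference language (with the
#' cross-language advisory review), reliability summaries for every form, and
#' — when the data carry covariates or a longitudinal design — the
#' convergent-validity and sensitivity analyses. The run is deterministic
#' given the inputs and configuration.
#'
#' @param responses Wide response tibble (all languages; see
#'   [read_responses()]), or `NULL` to simulate a study from `sim`.
#' @param bank Item-bank tibble; `NULL` with `sim` uses the simulated bank.
#' @param ratings Optional expert ratings tibble (`expert_id`, `item_id`,
#'   `relevance`).
#' @param longitudinal Optional wide response tibble with `arm`/`timepoint`
#'   metadata for the sensitivity analysis.
#' @param sim Optional [sim_config()]; used when `responses` is `NULL`.
#' @param reference Reference language driving equating, DIF and selection
#'   (default `"en"`).
#' @param form_lengths Strictly decreasing form lengths for nested selection
#'   (default `c(40, 20)`).
#' @param p_range Percent-correct bounds for selection (default `c(5, 95)`).
#' @param dif_alpha,dif_adjustment DIF flagging level and multiplicity
#'   adjustment.
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV (and the equating transforms as JSON).
#' @return Named list of results: `cvi`, `item_stats`, `reliability`,
#'   `fits`, `item_params`, `equating`, `dif`, `separation`, `curve`,
#'   `selections`, `review`, `validity`, `sensitivity` (entries `NULL` when
#'   their inputs are absent).
#' @export
run_pipeline <- function(responses = NULL, bank = NULL, ratings = NULL,
                         longitudinal = NULL, sim = NULL, reference = "en",
                         form_lengths = c(40, 20), p_range = c(5, 95),
                         dif_alpha = 0.05, dif_adjustment = "BH",
                         out_dir = NULL) {
  if (any(diff(form_lengths) >= 0)) {
    abort("form_lengths must be strictly decreasing")
  }
  if (is.null(responses)) {
    if (is.null(sim)) abort("supply responses or a sim config")
    study <- generate_study(sim)
    responses <- study$responses
    bank <- study$bank
  }
  if (is.null(bank)) abort("an item bank is required")
  bank <- validate_item_bank(bank)
  responses <- validate_responses(responses, bank = bank)
  languages <- unique(responses$language)
  if (!reference %in% languages) {
    abort(paste0("reference language '", reference, "' absent from the data"))
  }

  cvi <- if (!is.null(ratings)) compute_cvi(ratings) else NULL

  item_stats <- item_statistics(responses, bank = bank)
  reliability <- purrr::map(languages, function(lang) {
    d <- responses[responses$language == lang, , drop = FALSE]
    s <- item_stats[item_stats$language == lang, , drop = FALSE]
    summarize_scale(s, alpha = suppressWarnings(cronbach_alpha(d)))
  }) |> purrr::list_rbind()

  fits <- purrr::map(setNames(languages, languages), function(lang) {
    suppressWarnings(fit_2pl(responses[responses$language == lang, , drop = FALSE]))
  })
  item_params <- purrr::imap(fits, function(f, lang) {
    dplyr::mutate(f$params, language = lang, .after = "item_id")
  }) |> purrr::list_rbind()

  focal_langs <- setdiff(languages, reference)
  equating <- purrr::map(setNames(focal_langs, focal_langs), function(lang) {
    mean_sigma_equate(fits[[lang]]$params, fits[[reference]]$params)
  })
  dif <- purrr::map(setNames(focal_langs, focal_langs), function(lang) {
    suppressWarnings(dif_test(
      responses[responses$language %in% c(lang, reference), , drop = FALSE],
      focal = lang, reference = reference,
      alpha = dif_alpha, adjustment = dif_adjustment
    ))
  })
  separation <- purrr::map(fits, function(f) difficulty_separation(f$params, bank))

  ref_stats <- item_stats[item_stats$language == reference, , drop = FALSE]
  curve <- fit_mean_curve(ref_stats)
  selections <- list()
  parent <- NULL
  for (L in form_lengths) {
    sizes <- if (is.null(parent)) {
      stratum_sizes(bank)
    } else {
      s <- table(factor(parent$stratum, levels = .strata))
      setNames(as.integer(s), .strata)
    }
    quotas <- allocate_quotas(sizes, L)
    sel <- select_items(ref_stats, curve, quotas, bank, p_range = p_range,
                        parent = parent, language = reference)
    selections[[paste0("form_", L)]] <- sel
    parent <- sel
  }
  review <- if (length(focal_langs) > 0) {
    multi_language_review(selections[[1]], item_stats)
  } else {
    NULL
  }

  # per-form reliability on the selected subsets
  form_reliability <- purrr::imap(selections, function(sel, nm) {
    purrr::map(languages, function(lang) {
      d <- responses[responses$language == lang, , drop = FALSE]
      s <- item_statistics(d, bank = bank, items = sel$item_id)
      out <- summarize_scale(s, alpha = suppressWarnings(cronbach_alpha(d, items = sel$item_id)))
      out$form <- nm
      out$language <- lang
      out
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  cov_cols <- grep("^cov_", names(responses), value = TRUE)
  validity <- if (length(cov_cols) > 0) {
    scores <- form_scores(responses, form = "full")
    score_tbl <- dplyr::select(scores, "person_id", "language",
                               dplyr::all_of(cov_cols), score_full = "percent")
    for (nm in names(selections)) {
      fs <- form_scores(responses, items = selections[[nm]]$item_id, form = nm)
      score_tbl[[paste0("score_", nm)]] <- fs$percent
    }
    convergent_validity(
      score_tbl,
      vars = c("score_full", paste0("score_", names(selections)), cov_cols)
    )
  } else {
    NULL
  }

  sensitivity <- if (!is.null(longitudinal)) {
    forms <- c(list(full = bank$item_id),
               purrr::map(selections, ~ .x$item_id))
    purrr::imap(forms, function(items, nm) {
      sc <- form_scores(longitudinal, items = items, form = nm)
      sensitivity_analysis(sc, form = nm)
    }) |> purrr::list_rbind()
  } else {
    NULL
  }

  results <- list(
    cvi = cvi, item_stats = item_stats, reliability = reliability,
    form_reliability = form_reliability, fits = fits,
    item_params = item_params, equating = equating, dif = dif,
    separation = separation, curve = curve, selections = selections,
    review = review, validity = validity, sensitivity = sensitivity
  )
  if (!is.null(out_dir)) write_pipeline_outputs(results, out_dir)
  results
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x)) readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")), na = "NA")
  }
  wr(results$cvi, "cvi_report")
  wr(results$item_stats, "item_stats")
  wr(results$reliability, "reliability")
  wr(results$form_reliability, "form_reliability")
  wr(results$item_params, "item_params")
  wr(purrr::list_rbind(purrr::map(results$dif, tibble::as_tibble), names_to = "focal"),
     "dif_report")
  wr(results$validity, "validity_matrix")
  wr(results$sensitivity, "sensitivity_table")
  for (nm in names(results$selections)) {
    wr(tibble::as_tibble(results$selections[[nm]]), paste0("selection_", nm))
  }
  wr(results$review, "selection_review")
  transforms <- purrr::map(results$equating, ~ as.list(.x$transform))
  jsonlite::write_json(transforms, file.path(out_dir, "equating.json"),
                       auto_unbox = TRUE, digits = NA)
  traces <- purrr::map(results$fits, function(f) {
    list(loglik = f$trace$loglik, converged = f$converged,
         n_quadrature = f$n_quad)
  })
  jsonlite::write_json(traces, file.path(out_dir, "fit_trace.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
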