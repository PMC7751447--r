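#' Mean/sigma linear equating of item parameters
#'
#' Places a focal language form's item parameters on the reference form's
#' difficulty metric by the linear transformation `b' = A b + B`,
#' `a' = a / A`, with `A = sd(b_ref) / sd(b_focal)` and
#' `B = mean(b_ref) - A * mean(b_focal)`. After the transformation the mean
#' and standard deviation of the focal difficulties equal the reference's
#' exactly, and the item response functions are unchanged under the matching
#' ability transformation `theta' = A theta + B`.
#'
#' @param focal,reference Item-parameter tibbles (or `irt2pl` fits) sharing
#'   the same item ids; rows with non-finite `b` are dropped from both before
#'   computing the constants. At least 3 common items are required.
#' @return A list of class `equating`: `transform` (one-row tibble with `A`,
#'   `B`, languages when present) and `params` (the focal parameters with
#'   transformed `a`, `b`, and standard errors scaled accordingly).
#' @export
#' @examples
#' focal <- tibble::tibble(item_id = c("w1", "w2", "w3"), a = 1, b = c(0, 1, 2))
#' ref <- tibble::tibble(item_id = c("w1", "w2", "w3"), a = 1, b = c(-1, 1, 3))
#' mean_sigma_equate(focal, ref)$transform
mean_sigma_equate <- function(focal, reference) {
  if (inherits(focal, "irt2pl")) focal <- focal$params
  if (inherits(reference, "irt2pl")) reference <- reference$params
  focal <- tibble::as_tibble(focal)
  reference <- tibble::as_tibble(reference)
  only_f <- setdiff(focal$item_id, reference$item_id)
  only_r <- setdiff(reference$item_id, focal$item_id)
  if (length(only_f) > 0 || length(only_r) > 0) {
    fmt <- function(v) if (length(v) == 0) "(none)" else paste(v, collapse = ", ")
    abort(paste0("item sets differ between forms; only in focal: ", fmt(only_f),
                 "; only in reference: ", fmt(only_r)))
  }
  common <- focal$item_id
  ref <- reference[match(common, reference$item_id), ]
  usable <- is.finite(focal$b) & is.finite(ref$b)
  if (sum(usable) < 3) abort("mean/sigma equating needs at least 3 common items")
  b_f <- focal$b[usable]
  b_r <- ref$b[usable]
  if (sd(b_f) == 0) abort("focal difficulties have zero standard deviation")
  A <- sd(b_r) / sd(b_f)
  B <- mean(b_r) - A * mean(b_f)
  out <- focal
  out$b <- A * focal$b + B
  out$a <- focal$a / A
  if ("se_b" %in% names(out)) out$se_b <- A * out$se_b
  if ("se_a" %in% names(out)) out$se_a <- out$se_a / A
  transform <- tibble::tibble(
    focal_language = if ("language" %in% names(focal)) focal$language[1] else NA_character_,
    reference_language = if ("language" %in% names(ref)) ref$language[1] else NA_character_,
    A = A, B = B, n_common = sum(usable)
  )
  structure(list(transform = transform, params = out), class = "equating")
}

#' @export
print.equating <- function(x, ...) {
  cat(sprintf("mean/sigma equating: A = %.6f, B = %.6f (%d common items)\n",
              x$transform$A, x$transform$B, x$transform$n_common))
  invisible(x)
}

#' Difficulty separation across strata
#'
#' Summarises estimated (or true) item difficulties by stratum and computes a
#' separation index contrasting the high stratum against the pooled low and
#' medium strata: `(mean b_high - mean b_low+medium) / pooled sd`. In a
#' deep-orthography form the high-stratum words are expected to stand clearly
#' apart (large index); in shallow-orthography forms the separation is
#' compressed.
#'
#' @param params Item-parameter tibble (or `irt2pl` fit) with `item_id`, `b`.
#' @param bank Item bank supplying the `stratum` labels (ignored when
#'   `params` already carries a `stratum` column).
#' @return List of class `separation_report`: `strata` (per-stratum tibble
#'   `stratum`, `n`, `mean_b`, `sd_b` with `sd_b` `NA` when fewer than 2
#'   items) and `separation` (the index; 0 when all difficulties are equal).
#' @export
difficulty_separation <- function(params, bank = NULL) {
  if (inherits(params, "irt2pl")) params <- params$params
  params <- tibble::as_tibble(params)
  if (!"stratum" %in% names(params)) {
    if (is.null(bank)) abort("supply a bank (or a stratum column) for stratum labels")
    params <- dplyr::left_join(params, dplyr::select(bank, "item_id", "stratum"),
                               by = "item_id")
  }
  params <- dplyr::filter(params, is.finite(.data$b), .data$stratum %in% .strata)
  strata <- params |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_b = mean(.data$b),
      sd_b = if (dplyr::n() < 2) NA_real_ else sd(.data$b),
      .by = "stratum"
    ) |>
    dplyr::arrange(factor(.data$stratum, levels = .strata))
  b_high <- params$b[params$stratum == "high"]
  b_lm <- params$b[params$stratum != "high"]
  if (length(b_high) == 0 || length(b_lm) == 0) {
    sep <- NA_real_
  } else {
    diff_means <- mean(b_high) - mean(b_lm)
    s2 <- ((length(b_high) - 1) * ifelse(length(b_high) > 1, var(b_high), 0) +
             (length(b_lm) - 1) * ifelse(length(b_lm) > 1, var(b_lm), 0)) /
      (length(b_high) + length(b_lm) - 2)
    pooled_sd <- sqrt(s2)
    sep <- if (diff_means == 0) 0 else diff_means / pooled_sd
  }
  structure(list(strata = strata, separation = sep), class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  print(x$strata)
  cat(sprintf("separation index (high vs low+medium): %.4f\n", x$separation))
  invisible(x)
}
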