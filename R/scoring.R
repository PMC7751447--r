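#' Score administrator marks
#'
#' The administration protocol scores each presented word with a mark: the
#' examinee reads each word aloud and the administrator records `correct`
#' (`+`), or `-` for a word mispronounced (`incorrect`), skipped after the
#' 5-second limit (`skipped`), or never attempted (`not_attempted`). Only
#' `correct` scores 1; every `-` variant scores 0. The timing rule itself is
#' applied by the administrator, upstream of this function.
#'
#' @param marks Character vector of marks.
#' @return Integer 0/1 vector of the same length.
#' @export
#' @examples
#' score_marks(c("correct", "correct", "incorrect", "skipped", "correct"))
score_marks <- function(marks) {
  marks <- as.character(marks)
  bad <- setdiff(unique(marks), .marks)
  if (length(bad) > 0) {
    abort(paste0("unknown mark(s): ", paste(bad, collapse = ", "),
                 " (expected ", paste(.marks, collapse = "/"), ")"))
  }
  as.integer(marks == "correct")
}

#' Score administrations into sum scores
#'
#' Takes long administration records (one row per person x item with the
#' administrator's mark) and produces the per-person scored summary: the sum
#' score (count of correctly pronounced words) and the percent score.
#'
#' @param data Long data frame with columns `person_id`, `item_id`, `mark`.
#' @param bank Optional item bank; when given, each person's marks must align
#'   with the bank (same item count), and a mismatch is an error.
#' @return Tibble with `person_id`, `n_items`, `sum_score`, `percent`.
#' @export
score_administration <- function(data, bank = NULL) {
  data <- tibble::as_tibble(data)
  needed <- c("person_id", "item_id", "mark")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("administration records lack: ",
                 paste(missing_cols, collapse = ", ")))
  }
  data$score <- score_marks(data$mark)
  out <- data |>
    dplyr::summarise(
      n_items = dplyr::n(),
      sum_score = sum(.data$score),
      .by = "person_id"
    ) |>
    dplyr::mutate(percent = 100 * .data$sum_score / .data$n_items)
  if (!is.null(bank)) {
    off <- out$n_items != nrow(bank)
    if (any(off)) {
      abort(sprintf(
        "administration length mismatch for person '%s': %d marks for a %d-item bank",
        out$person_id[which(off)[1]], out$n_items[which(off)[1]], nrow(bank)
      ))
    }
  }
  out
}

#' Sum and percent scores for a form
#'
#' Computes per-person scores on a form (a subset of items), keeping the
#' person metadata columns so the result feeds directly into the validity and
#' sensitivity analyses. Scores use the items each person was actually
#' administered (non-missing cells).
#'
#' @param data Wide response tibble.
#' @param items Character vector of item ids defining the form; default all
#'   item columns.
#' @param form Label stored in the `form` column (default the item count).
#' @return Tibble: metadata columns, `form`, `n_answered`, `sum_score`,
#'   `percent`.
#' @export
form_scores <- function(data, items = NULL, form = NULL) {
  x <- response_values(data, item_ids = items)
  n_answered <- rowSums(!is.na(x))
  sum_score <- rowSums(x, na.rm = TRUE)
  meta <- tibble::as_tibble(data)[, .meta_cols(data), drop = FALSE]
  dplyr::bind_cols(
    meta,
    tibble::tibble(
      form = form %||% paste0(ncol(x), "-item"),
      n_answered = as.integer(n_answered),
      sum_score = as.integer(sum_score),
      percent = ifelse(n_answered > 0, 100 * sum_score / n_answered, NA_real_)
    )
  )
}
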