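#' Read a response table
#'
#' The canonical layout is wide: one row per administered form, with metadata
#' columns `person_id`, `language`, `arm`, `timepoint`, any covariate columns
#' prefixed `cov_`, and then one 0/1/NA column per item. `NA` marks an item
#' that was never presented; a scored administration has no `NA` cells (every
#' presented word is scored correct or incorrect).
#'
#' @param path CSV path.
#' @param bank Optional item bank; when supplied, item columns and language
#'   codes are validated against it.
#' @return A validated response tibble. Rows with no non-missing response are
#'   flagged in the `empty_rows` attribute (row indices).
#' @export
read_responses <- function(path, bank = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          na = "NA")
  validate_responses(data, bank = bank)
}

#' Write a response table
#'
#' Missing responses are written with the `NA` sentinel; the file round-trips
#' through [read_responses()] unchanged.
#'
#' @param data A response tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path) {
  readr::write_csv(data, path, na = "NA")
  invisible(path)
}

#' Validate a response table
#'
#' @param data Wide response data frame (see [read_responses()]).
#' @param bank Optional item bank to cross-check item columns and languages.
#' @return The data as a tibble with attribute `empty_rows`.
#' @export
validate_responses <- function(data, bank = NULL) {
  data <- tibble::as_tibble(data)
  if (!"person_id" %in% names(data)) abort("response data lacks person_id")
  if (!"language" %in% names(data)) abort("response data lacks language")
  missing_lang <- which(is.na(data$language) | !nzchar(as.character(data$language)))
  if (length(missing_lang) > 0) {
    abort(sprintf("person '%s' (row %d) has no language code",
                  as.character(data$person_id[missing_lang[1]]), missing_lang[1]))
  }
  if ("arm" %in% names(data)) {
    bad <- which(!(data$arm %in% .arms))
    if (length(bad) > 0) {
      abort(sprintf("unknown arm '%s' in row %d", as.character(data$arm[bad[1]]), bad[1]))
    }
  }
  if ("timepoint" %in% names(data)) {
    bad <- which(!(data$timepoint %in% .timepoints))
    if (length(bad) > 0) {
      abort(sprintf("unknown timepoint '%s' in row %d",
                    as.character(data$timepoint[bad[1]]), bad[1]))
    }
  }
  item_cols <- setdiff(names(data), .meta_cols(data))
  if (length(item_cols) == 0) abort("response data has no item columns")
  if (!is.null(bank)) {
    unknown <- setdiff(item_cols, bank$item_id)
    if (length(unknown) > 0) {
      abort(paste0("response columns not in item bank: ",
                   paste(unknown, collapse = ", ")))
    }
    langs <- item_bank_languages(bank)
    bad <- setdiff(unique(data$language), langs)
    if (length(bad) > 0) {
      abort(paste0("language code(s) not declared by the item bank: ",
                   paste(bad, collapse = ", ")))
    }
  }
  x <- response_values(data) # errors with coordinates on non-0/1/NA cells
  empty <- unname(which(rowSums(!is.na(x)) == 0))
  if (length(empty) > 0) {
    warn(sprintf("%d row(s) have no non-missing responses (see attr 'empty_rows')",
                 length(empty)))
  }
  attr(data, "empty_rows") <- empty
  data
}

#' Convert long (person, item, response) records to the wide canonical layout
#'
#' @param data Long data frame with columns `person_id`, `item_id`, `response`
#'   plus any person-level metadata columns (repeated within person).
#' @param bank Optional item bank giving the item order (and validation).
#' @return Wide response tibble, one row per person (per timepoint if present).
#' @export
responses_long_to_wide <- function(data, bank = NULL) {
  data <- tibble::as_tibble(data)
  needed <- c("person_id", "item_id", "response")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("long response data lacks: ", paste(missing_cols, collapse = ", ")))
  }
  keys <- intersect(c("person_id", "language", "arm", "timepoint"), names(data))
  keys <- union(keys, grep("^cov_", names(data), value = TRUE))
  wide <- tidyr::pivot_wider(data, id_cols = dplyr::all_of(keys),
                             names_from = "item_id", values_from = "response")
  if (!is.null(bank)) {
    wide <- dplyr::relocate(wide, dplyr::all_of(intersect(bank$item_id, names(wide))),
                            .after = dplyr::last_col())
    validate_responses(wide, bank = bank)
  } else {
    validate_responses(wide)
  }
}
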