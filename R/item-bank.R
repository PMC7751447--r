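#' Read an item bank
#'
#' An item bank describes the instrument: one row per word, with the word form
#' in each language and the expert-assigned difficulty stratum. The canonical
#' CSV layout has columns `item_id`, `stratum` (one of `low`, `medium`,
#' `high`) and one `word_<code>` column per language (e.g. `word_en`,
#' `word_es`, `word_ko`), so that translated forms travel with the instrument.
#'
#' @param path Path to a CSV or JSON file.
#' @param format `"csv"` (default) or `"json"`. JSON files hold an array of
#'   objects with the same fields as the CSV columns.
#' @return A validated item-bank tibble, in input order, with attribute
#'   `languages` (character vector of language codes).
#' @export
#' @examples
#' bank_file <- system.file("extdata", "demo_word_bank_en.csv", package = "wordlit")
#' bank <- read_item_bank(bank_file)
#' dplyr::count(bank, stratum)
read_item_bank <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  bank <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
  validate_item_bank(bank)
}

#' Write an item bank
#'
#' @param bank An item-bank tibble (see [read_item_bank()]).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path, format = c("csv", "json")) {
  format <- match.arg(format)
  bank <- validate_item_bank(bank)
  if (format == "csv") {
    readr::write_csv(bank, path, na = "NA")
  } else {
    jsonlite::write_json(bank, path, dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Validate an item bank
#'
#' Checks the invariants every downstream stage relies on: unique item ids, a
#' recognised stratum label on every row, at least one `word_<code>` column,
#' and a non-empty word form for every item in every declared language.
#'
#' @param bank A data frame with columns `item_id`, `stratum` and one or more
#'   `word_<code>` columns.
#' @return The bank as a tibble with a `languages` attribute.
#' @export
validate_item_bank <- function(bank) {
  bank <- tibble::as_tibble(bank)
  if (nrow(bank) == 0) abort("no items: the item bank is empty")
  required <- c("item_id", "stratum")
  missing_cols <- setdiff(required, names(bank))
  if (length(missing_cols) > 0) {
    abort(paste0("item bank lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bank$item_id <- as.character(bank$item_id)
  dup <- unique(bank$item_id[duplicated(bank$item_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate item_id: ", paste(dup, collapse = ", ")))
  }
  bad <- which(!(bank$stratum %in% .strata))
  if (length(bad) > 0) {
    abort(sprintf("unknown stratum label '%s' in row %d (expected low/medium/high)",
                  as.character(bank$stratum[bad[1]]), bad[1]))
  }
  word_cols <- grep("^word_", names(bank), value = TRUE)
  if (length(word_cols) == 0) abort("item bank has no word_<language> column")
  for (wc in word_cols) {
    empty <- which(is.na(bank[[wc]]) | !nzchar(as.character(bank[[wc]])))
    if (length(empty) > 0) {
      abort(sprintf("empty word form in column '%s', row %d (item '%s')",
                    wc, empty[1], bank$item_id[empty[1]]))
    }
  }
  attr(bank, "languages") <- sub("^word_", "", word_cols)
  bank
}

#' Languages declared by an item bank
#'
#' @param bank An item-bank tibble.
#' @return Character vector of language codes.
#' @export
item_bank_languages <- function(bank) {
  sub("^word_", "", grep("^word_", names(bank), value = TRUE))
}

#' Per-stratum item counts
#'
#' @param bank An item-bank tibble.
#' @return Named integer vector over `low`, `medium`, `high`.
#' @export
stratum_sizes <- function(bank) {
  counts <- table(factor(bank$stratum, levels = .strata))
  setNames(as.integer(counts), .strata)
}
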