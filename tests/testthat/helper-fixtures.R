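# Shared fixtures and independent oracles used across the test files.

# small two-language study configuration used by most integration tests
small_config <- function(seed = 1, n_en = 250, n_es = 200, lambda = 0.5,
                         dif_spec = NULL) {
  sim_config(
    seed = seed,
    strata = c(low = 7, medium = 7, high = 6),
    languages = list(
      en = list(n = n_en, mode = "separated"),
      es = list(n = n_es, mode = "compressed")
    ),
    lambda = lambda,
    dif_spec = dif_spec
  )
}

# random dichotomous persons x items matrix (no missing values)
random_binary_matrix <- function(n, j, seed, p = NULL) {
  set.seed(seed)
  p <- p %||% runif(j, 0.2, 0.8)
  x <- sapply(p, function(pp) rbinom(n, 1, pp))
  storage.mode(x) <- "double"
  colnames(x) <- paste0("it", seq_len(j))
  x
}

# brute-force Cronbach's alpha: direct variance of the row sums
alpha_oracle <- function(x) {
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / var(rowSums(x)))
}

# brute-force corrected item-total correlations
item_total_oracle <- function(x) {
  sapply(seq_len(ncol(x)), function(j) {
    cor(x[, j], rowSums(x[, -j, drop = FALSE]))
  })
}

# item-bank tibble with arbitrary strata counts
toy_bank <- function(sizes = c(low = 3, medium = 3, high = 2),
                     languages = "en") {
  strat <- rep(names(sizes), times = sizes)
  ids <- sprintf("%s_%d", strat, unlist(lapply(sizes, seq_len)))
  bank <- tibble::tibble(item_id = ids, stratum = strat)
  for (lang in languages) bank[[paste0("word_", lang)]] <- paste0(ids, "_w")
  bank
}

# wide response tibble around a plain matrix
as_response_tibble <- function(x, language = "en", prefix = "p") {
  dplyr::bind_cols(
    tibble::tibble(
      person_id = paste0(prefix, seq_len(nrow(x))),
      language = language, arm = "none", timepoint = "none"
    ),
    tibble::as_tibble(x)
  )
}

`%||%` <- rlang::`%||%`
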