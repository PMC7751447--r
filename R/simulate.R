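#' Simulation configuration
#'
#' Bundles the generative specification of a synthetic multi-language
#' word-recognition study. The defaults emulate the design the analyses in
#' this package assume: an 82-item bank in three difficulty strata
#' (29/28/25), three language groups (n = 261/128/245), a 2PL response
#' process in which the English form shows a
#' distinct difficulty separation between the high stratum and the rest
#' while the Spanish and Korean forms are compressed toward the grand mean
#' (shallow-orthography behaviour), optional DIF on selected items, a
#' two-arm four-timepoint longitudinal design, and ability-linked covariates.
#' All effect sizes are generator configuration, not estimates.
#'
#' @param seed Integer seed; every generated artifact is a deterministic
#'   function of the seed and the configuration.
#' @param strata Items per stratum (low/medium/high).
#' @param languages Named list; each entry has `n` (persons), `mode`
#'   (`"separated"` or `"compressed"`), and optionally `ability` =
#'   `c(mean, sd)`.
#' @param b_low_medium,b_high Mean and sd (length-2 vectors) of true
#'   difficulties for the low/medium strata and the high stratum in the
#'   separated (deep-orthography) mode.
#' @param lambda Compression factor in `(0, 1]` for compressed-mode forms:
#'   each stratum's centre is pulled toward the grand mean
#'   (`b' = b + (lambda - 1) (m_stratum - m_grand)`) while within-stratum
#'   spread is kept; `lambda = 1` means no compression.
#' @param a_range Uniform range of true discriminations.
#' @param dif_spec Optional tibble `item_id`, `language`, `delta_a`,
#'   `delta_b` of parameter shifts defining DIF.
#' @param arms,timepoints Longitudinal design labels.
#' @param delta Named list per arm of ability drifts (logits), one value per
#'   timepoint. Defaults mirror a roughly 10-percentage-point intervention
#'   gain by month 12 against a flat control.
#' @param tau Within-person ability noise sd per timepoint (logits).
#' @param covariates Tibble `name`, `rho`, `levels` (NA = continuous) of
#'   ability-linked covariates generated as `rho * theta +
#'   sqrt(1 - rho^2) * noise`, optionally discretised into `levels` bins.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    strata = c(low = 29L, medium = 28L, high = 25L),
    languages = list(
      en = list(n = 261L, mode = "separated"),
      es = list(n = 128L, mode = "compressed"),
      ko = list(n = 245L, mode = "compressed")
    ),
    b_low_medium = c(mean = -0.7, sd = 0.5),
    b_high = c(mean = 1.3, sd = 0.4),
    lambda = 0.5,
    a_range = c(0.8, 2.0),
    dif_spec = NULL,
    arms = c("intervention", "control"),
    timepoints = c("baseline", "m3", "m6", "m12"),
    delta = list(
      intervention = c(baseline = 0, m3 = 0.45, m6 = 0.35, m12 = 0.5),
      control = c(baseline = 0, m3 = 0, m6 = 0, m12 = 0)
    ),
    tau = 0.3,
    covariates = tibble::tibble(
      name = c("nvs", "education", "dm_knowledge"),
      rho = c(0.5, 0.5, 0.3),
      levels = c(NA, 4, NA)
    )) {
  if (lambda <= 0 || lambda > 1) abort("lambda must be in (0, 1]")
  structure(
    list(
      seed = as.integer(seed), strata = strata, languages = languages,
      b_low_medium = b_low_medium, b_high = b_high, lambda = lambda,
      a_range = a_range, dif_spec = dif_spec, arms = arms,
      timepoints = timepoints, delta = delta, tau = tau,
      covariates = covariates
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic item bank with true parameters
#'
#' Builds the bank (placeholder word tokens per language) and the true 2PL
#' parameters per language form. In separated mode the low/medium strata draw
#' difficulties from the easy component and the high stratum from a clearly
#' harder one; compressed-mode languages shrink every item's difficulty
#' toward the grand mean by `lambda`, so with `lambda = 1` the compressed
#' form's true difficulties equal the separated form's. Discriminations are
#' uniform on `a_range` and shared across languages; `dif_spec` shifts are
#' applied last.
#'
#' @param config A [sim_config()].
#' @return List with `bank` (item-bank tibble) and `truth` (tibble
#'   `item_id`, `language`, `stratum`, `a`, `b`).
#' @export
generate_item_bank <- function(config = sim_config()) {
  if (config$lambda <= 0 || config$lambda > 1) abort("lambda must be in (0, 1]")
  set.seed(config$seed)
  sizes <- config$strata
  strat <- rep(.strata, times = sizes)
  n_items <- sum(sizes)
  ids <- sprintf("w_%s_%02d", strat, unlist(lapply(sizes, seq_len)))
  bank <- tibble::tibble(item_id = ids, stratum = strat)
  for (lang in names(config$languages)) {
    bank[[paste0("word_", lang)]] <- paste0(ids, "_", lang)
  }

  a <- runif(n_items, config$a_range[1], config$a_range[2])
  b_sep <- ifelse(
    strat == "high",
    rnorm(n_items, config$b_high["mean"], config$b_high["sd"]),
    rnorm(n_items, config$b_low_medium["mean"], config$b_low_medium["sd"])
  )
  grand <- mean(b_sep)
  stratum_means <- tapply(b_sep, strat, mean)[strat]
  truth <- purrr::imap(config$languages, function(spec, lang) {
    # compression moves each stratum's centre toward the grand mean while
    # leaving within-stratum spread intact, so the standardized separation
    # between strata genuinely shrinks
    b <- if (identical(spec$mode, "separated")) {
      b_sep
    } else {
      unname(b_sep + (config$lambda - 1) * (stratum_means - grand))
    }
    tibble::tibble(item_id = ids, language = lang, stratum = strat, a = a, b = b)
  }) |> purrr::list_rbind()

  if (!is.null(config$dif_spec)) {
    ds <- tibble::as_tibble(config$dif_spec)
    for (i in seq_len(nrow(ds))) {
      sel <- truth$item_id == ds$item_id[i] & truth$language == ds$language[i]
      if (!any(sel)) abort(paste0("dif_spec refers to unknown item/language: ",
                                  ds$item_id[i], "/", ds$language[i]))
      truth$a[sel] <- truth$a[sel] + (ds$delta_a[i] %||% 0)
      truth$b[sel] <- truth$b[sel] + (ds$delta_b[i] %||% 0)
    }
    if (any(truth$a <= 0)) abort("dif_spec drove a discrimination below zero")
  }
  list(bank = validate_item_bank(bank), truth = truth)
}

#' Generate 2PL responses for one language form
#'
#' Draws abilities from a normal distribution and responses from Bernoulli
#' trials with probabilities from the true item response functions.
#'
#' @param truth Truth tibble from [generate_item_bank()] (may hold several
#'   languages).
#' @param language Language form to generate.
#' @param n Number of persons (at least 1).
#' @param ability_mean,ability_sd Latent ability distribution.
#' @param seed Integer seed.
#' @param person_prefix Prefix for generated person ids.
#' @return Wide response tibble (`person_id`, `language`, `arm`, `timepoint`,
#'   item columns), with the true abilities in attribute `theta`.
#' @export
generate_responses <- function(truth, language, n, ability_mean = 0,
                               ability_sd = 1, seed = 1L,
                               person_prefix = language) {
  if (n < 1) abort("n must be at least 1")
  tr <- dplyr::filter(tibble::as_tibble(truth), .data$language == !!language)
  if (nrow(tr) == 0) abort(paste0("no truth rows for language '", language, "'"))
  set.seed(seed)
  theta <- rnorm(n, ability_mean, ability_sd)
  x <- draw_responses(theta, tr$a, tr$b)
  colnames(x) <- tr$item_id
  out <- dplyr::bind_cols(
    tibble::tibble(
      person_id = sprintf("%s_%04d", person_prefix, seq_len(n)),
      language = language, arm = "none", timepoint = "none"
    ),
    tibble::as_tibble(x)
  )
  attr(out, "theta") <- theta
  out
}

# Bernoulli draws from the 2PL, persons x items
draw_responses <- function(theta, a, b) {
  p <- plogis(outer(theta, b, `-`) * rep(a, each = length(theta)))
  matrix(as.double(rbinom(length(p), 1, p)), nrow = length(theta))
}

#' Generate a two-arm longitudinal administration
#'
#' Each person keeps a baseline ability; at every timepoint the administered
#' ability is `theta_i + delta_arm(t) + eps`, with `eps ~ N(0, tau^2)`
#' within-person noise, and responses are regenerated from the 2PL at that
#' ability. The arm-specific drifts `delta` are the injected intervention
#' effect.
#'
#' @param truth Truth tibble from [generate_item_bank()].
#' @param language Language form administered.
#' @param n_per_arm Persons per arm.
#' @param config A [sim_config()] supplying `arms`, `timepoints`, `delta`,
#'   `tau`.
#' @param seed Integer seed.
#' @return Wide response tibble with one row per person x timepoint and
#'   `arm`/`timepoint` metadata.
#' @export
generate_longitudinal <- function(truth, language, n_per_arm,
                                  config = sim_config(), seed = 1L) {
  tps <- config$timepoints
  if (length(tps) < 2) abort("need at least 2 timepoints")
  if (tps[1] != "baseline" || !"baseline" %in% tps) {
    abort("the first timepoint must be 'baseline'")
  }
  tr <- dplyr::filter(tibble::as_tibble(truth), .data$language == !!language)
  if (nrow(tr) == 0) abort(paste0("no truth rows for language '", language, "'"))
  set.seed(seed)
  arms <- rep(config$arms, each = n_per_arm)
  n <- length(arms)
  theta0 <- rnorm(n, 0, 1)
  ids <- sprintf("%s_L%04d", language, seq_len(n))
  rows <- purrr::map(tps, function(tp) {
    drift <- purrr::map_dbl(arms, function(arm) {
      d <- config$delta[[arm]]
      if (is.null(d) || !tp %in% names(d)) 0 else unname(d[tp])
    })
    theta_t <- theta0 + drift + rnorm(n, 0, config$tau)
    x <- draw_responses(theta_t, tr$a, tr$b)
    colnames(x) <- tr$item_id
    dplyr::bind_cols(
      tibble::tibble(person_id = ids, language = language, arm = arms,
                     timepoint = tp),
      tibble::as_tibble(x)
    )
  })
  purrr::list_rbind(rows)
}

#' Generate ability-linked covariates
#'
#' Each covariate is `rho * theta + sqrt(1 - rho^2) * noise` with standard
#' normal noise, optionally discretised into equal-probability ordinal levels
#' (e.g. education categories).
#'
#' @param theta Numeric vector of true abilities.
#' @param spec Tibble `name`, `rho` (in `[-1, 1]`), `levels` (`NA` keeps the
#'   covariate continuous).
#' @param seed Integer seed.
#' @return Tibble of covariate columns named `cov_<name>`.
#' @export
generate_covariates <- function(theta, spec = sim_config()$covariates,
                                seed = 1L) {
  spec <- tibble::as_tibble(spec)
  if (any(abs(spec$rho) > 1)) abort("covariate loadings rho must be in [-1, 1]")
  set.seed(seed)
  out <- purrr::pmap(spec, function(name, rho, levels, ...) {
    v <- rho * theta + sqrt(1 - rho^2) * rnorm(length(theta))
    if (!is.na(levels)) {
      br <- quantile(v, probs = seq(0, 1, length.out = levels + 1))
      br[1] <- -Inf
      br[length(br)] <- Inf
      v <- as.integer(cut(v, breaks = br, labels = FALSE, include.lowest = TRUE))
    }
    tibble::tibble("cov_{name}" := v)
  })
  dplyr::bind_cols(out)
}

#' Generate a complete cross-sectional multi-language study
#'
#' Convenience wrapper: builds the bank and truth, generates each language
#' group's responses at its configured sample size and ability distribution,
#' and attaches covariates.
#'
#' @param config A [sim_config()].
#' @return List: `bank`, `truth`, `responses` (all languages stacked, with
#'   covariate columns), `theta` (per-person true abilities tibble).
#' @export
generate_study <- function(config = sim_config()) {
  gen <- generate_item_bank(config)
  parts <- purrr::imap(config$languages, function(spec, lang) {
    ab <- spec$ability %||% c(0, 1)
    resp <- generate_responses(gen$truth, lang, spec$n,
                               ability_mean = ab[1], ability_sd = ab[2],
                               seed = config$seed + match(lang, names(config$languages)))
    covs <- generate_covariates(
      attr(resp, "theta"), config$covariates,
      seed = config$seed + 100L + match(lang, names(config$languages))
    )
    theta <- tibble::tibble(person_id = resp$person_id, language = lang,
                            theta = attr(resp, "theta"))
    list(resp = dplyr::bind_cols(resp[, 1:4], covs, resp[, -(1:4)]), theta = theta)
  })
  responses <- purrr::list_rbind(purrr::map(parts, "resp"))
  theta <- purrr::list_rbind(purrr::map(parts, "theta"))
  list(bank = gen$bank, truth = gen$truth, responses = responses, theta = theta)
}
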