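#' Item-level content validity index (Lynn's method)
#'
#' Experts rate each candidate item's relevance on a 4-point scale (1 = not
#' relevant, 4 = very relevant). The item CVI (I-CVI) is the proportion of
#' experts rating the item 3 or 4; items are retained when I-CVI exceeds the
#' threshold (default .80). The scale-level S-CVI (mean of item I-CVIs) is
#' attached as an attribute and returned by [glance()] on the result.
#'
#' An alternative reading screens on the mean rating instead of the
#' proportion; `method = "mean"` retains items whose mean rating is at least
#' 3.
#'
#' @param ratings Long data frame with columns `expert_id`, `item_id`,
#'   `relevance` (integers 1-4).
#' @param threshold Retention threshold on I-CVI (strict: retained when
#'   I-CVI > threshold). Default 0.80.
#' @param method `"proportion"` (Lynn's I-CVI, default) or `"mean"`.
#' @return Tibble `item_id`, `n_experts`, `i_cvi`, `retained`, with attributes
#'   `s_cvi` and `threshold`. Class `"cvi_result"`.
#' @export
#' @examples
#' ratings <- tidyr::expand_grid(expert_id = paste0("e", 1:6), item_id = "w1")
#' ratings$relevance <- c(4, 3, 4, 3, 4, 2)
#' compute_cvi(ratings)
compute_cvi <- function(ratings, threshold = 0.80,
                        method = c("proportion", "mean")) {
  method <- match.arg(method)
  ratings <- tibble::as_tibble(ratings)
  needed <- c("expert_id", "item_id", "relevance")
  missing_cols <- setdiff(needed, names(ratings))
  if (length(missing_cols) > 0) {
    abort(paste0("ratings lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(ratings$relevance %in% 1:4)) {
    bad <- ratings$relevance[!(ratings$relevance %in% 1:4)][1]
    abort(sprintf("relevance ratings must be integers 1-4; found %s", format(bad)))
  }
  n_experts <- length(unique(ratings$expert_id))
  if (n_experts < 3) abort("content validity screening needs at least 3 experts")
  out <- ratings |>
    dplyr::summarise(
      n_experts = dplyr::n(),
      i_cvi = mean(.data$relevance >= 3),
      mean_rating = mean(.data$relevance),
      .by = "item_id"
    )
  out$retained <- if (method == "proportion") {
    out$i_cvi > threshold
  } else {
    out$mean_rating >= 3
  }
  out <- dplyr::select(out, "item_id", "n_experts", "i_cvi", "retained")
  attr(out, "s_cvi") <- mean(out$i_cvi)
  attr(out, "threshold") <- threshold
  class(out) <- c("cvi_result", class(out))
  out
}

#' @exportS3Method generics::glance
glance.cvi_result <- function(x, ...) {
  tibble::tibble(
    n_items = nrow(x),
    n_retained = sum(x$retained),
    s_cvi = attr(x, "s_cvi"),
    threshold = attr(x, "threshold")
  )
}

#' Assign difficulty strata from expert votes
#'
#' Experts categorise each word's difficulty as 1 (low), 2 (medium) or 3
#' (high). The modal rule takes the most frequent category; any tie resolves
#' to the medium stratum (the least selection-distorting default). The
#' mean-binned rule maps the mean vote onto thirds of `[1, 3]`.
#'
#' Optionally, items whose mean difficulty vote falls outside given
#' percentile bounds of the pool (words too easy or too difficult relative to
#' the overall distribution) can be flagged for removal via `trim`; by
#' default no trimming is applied.
#'
#' @param votes Long data frame with columns `expert_id`, `item_id`,
#'   `difficulty` (integers 1-3).
#' @param rule `"modal"` (default) or `"mean_binned"`.
#' @param trim Optional length-2 numeric of percentile bounds in `[0, 1]`
#'   (e.g. `c(0.05, 0.95)`); items with mean vote outside these quantiles of
#'   the item pool get `trimmed = TRUE`.
#' @return Tibble `item_id`, `mean_vote`, `stratum`, `trimmed`.
#' @export
assign_difficulty <- function(votes, rule = c("modal", "mean_binned"),
                              trim = NULL) {
  rule <- match.arg(rule)
  votes <- tibble::as_tibble(votes)
  needed <- c("expert_id", "item_id", "difficulty")
  missing_cols <- setdiff(needed, names(votes))
  if (length(missing_cols) > 0) {
    abort(paste0("votes lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(votes) == 0) abort("empty difficulty votes")
  if (!all(votes$difficulty %in% 1:3)) {
    abort("difficulty votes must be integers 1-3")
  }
  per_item <- votes |>
    dplyr::summarise(
      mean_vote = mean(.data$difficulty),
      stratum = {
        counts <- tabulate(.data$difficulty, nbins = 3)
        top <- which(counts == max(counts))
        if (length(top) > 1) "medium" else .strata[top]
      },
      .by = "item_id"
    )
  if (rule == "mean_binned") {
    per_item$stratum <- .strata[
      findInterval(per_item$mean_vote, c(1 + 2 / 3, 1 + 4 / 3)) + 1
    ]
  }
  per_item$trimmed <- FALSE
  if (!is.null(trim)) {
    if (length(trim) != 2 || any(trim < 0) || any(trim > 1)) {
      abort("trim must be two percentiles in [0, 1]")
    }
    bounds <- quantile(per_item$mean_vote, sort(trim), names = FALSE)
    per_item$trimmed <- per_item$mean_vote < bounds[1] | per_item$mean_vote > bounds[2]
  }
  per_item
}
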