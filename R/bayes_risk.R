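#' Correlation-level anchors for Likert ratings
#'
#' Ratings are grouped into three correlation levels for all counting:
#' low (rating <= `low_max`), medium (= `medium_value`), high
#' (>= `high_min`). Defaults follow the standard anchoring on the 5-point
#' scale: low <= 2, medium = 3, high >= 4.
#'
#' @param low_max,medium_value,high_min integer anchors within 1..5 with
#'   `low_max < medium_value < high_min`.
#' @return list of class `correlation_anchors`.
#' @export
correlation_anchors <- function(low_max = 2L, medium_value = 3L,
                                high_min = 4L) {
  stopifnot(low_max < medium_value, medium_value < high_min,
            low_max >= 1, high_min <= 5)
  structure(list(low_max = as.integer(low_max),
                 medium_value = as.integer(medium_value),
                 high_min = as.integer(high_min)),
            class = "correlation_anchors")
}

risk_levels <- c("low", "medium", "high")

#' Map a Likert rating to its correlation level
#'
#' @param rating integer vector of ratings in 1..5.
#' @param anchors a [correlation_anchors()].
#' @return character vector in `c("low", "medium", "high")`.
#' @export
map_correlation_level <- function(rating, anchors = correlation_anchors()) {
  stopifnot(all(rating %in% 1:5))
  ifelse(rating <= anchors$low_max, "low",
         ifelse(rating >= anchors$high_min, "high", "medium"))
}

#' Count ratings per factor and correlation level
#'
#' Tallies, for every factor, how many experts rated it at each correlation
#' level, plus the pooled tallies used as counting denominators: the two
#' stage groups (a primary factor with its three children, 4 columns), the
#' pooled six secondary columns, and the pooled all-8 set.
#'
#' @param panel an `expert_panel`.
#' @param hierarchy a [pl_hierarchy()].
#' @param anchors a [correlation_anchors()].
#' @return list of class `level_counts`: `counts` (factor x level matrix),
#'   `stage_counts` (stage x level), `secondary_counts`, `all_counts`
#'   (level vectors), `n_experts`, cell totals `stage_cells`,
#'   `secondary_cells`, `all_cells`.
#' @export
count_levels <- function(panel, hierarchy = pl_hierarchy(),
                         anchors = correlation_anchors()) {
  x <- panel_matrix(panel)
  n <- nrow(x)
  lev <- matrix(map_correlation_level(x, anchors), n, ncol(x),
                dimnames = dimnames(x))
  counts <- t(sapply(hierarchy$factors, function(f) {
    tabulate(factor(lev[, f], levels = risk_levels), nbins = 3L)
  }))
  colnames(counts) <- risk_levels
  stages <- unique(hierarchy$stage_of)
  stage_counts <- t(sapply(stages, function(s) {
    cols <- hierarchy$factors[hierarchy$stage_of == s]
    colSums(counts[cols, , drop = FALSE])
  }))
  colnames(stage_counts) <- risk_levels
  sec <- hierarchy$secondary_factors
  list(
    counts = counts,
    stage_counts = stage_counts,
    secondary_counts = colSums(counts[sec, , drop = FALSE]),
    all_counts = colSums(counts),
    n_experts = n,
    stage_cells = stats::setNames(
      sapply(stages, function(s) n * sum(hierarchy$stage_of == s)), stages),
    secondary_cells = n * length(sec),
    all_cells = n * length(hierarchy$factors)
  )
}

#' The counting-based posterior update
#'
#' The scheme used throughout the risk stage, applied per factor and
#' correlation level:
#' \deqn{inverse = 1 - likelihood}
#' \deqn{marginal = prior \cdot likelihood + (1 - prior) \cdot inverse}
#' \deqn{posterior = \frac{prior \cdot likelihood}{marginal}}
#' Note the marginal mixes the likelihood with its own complement rather
#' than marginalizing over all levels; that is the scheme as designed (the
#' `canonical` method of [assess_risk()] offers the textbook mixture).
#' `marginal = 0` yields an `undefined` flag, never NaN.
#'
#' @param prior,likelihood probabilities in `[0, 1]` (vectorized).
#' @return data frame with columns `prior`, `likelihood`, `inverse`,
#'   `marginal`, `posterior`, `undefined`.
#' @export
posterior_probability <- function(prior, likelihood) {
  if (any(prior < 0 | prior > 1 | likelihood < 0 | likelihood > 1)) {
    stop("prior and likelihood must lie in [0, 1]")
  }
  inverse <- 1 - likelihood
  marginal <- prior * likelihood + (1 - prior) * inverse
  undefined <- marginal == 0
  posterior <- ifelse(undefined, NA_real_, prior * likelihood / marginal)
  data.frame(prior = prior, likelihood = likelihood, inverse = inverse,
             marginal = marginal, posterior = posterior,
             undefined = undefined)
}

#' ISO-31000-style probability banding scheme
#'
#' Equidistant 0.2 bands collapsed to three labels for the all-cause
#' structure: low (p <= 0.4), medium (0.4 < p < 0.8), high (p >= 0.8).
#' The half-open sliver left by quoting the high band as starting at 0.81
#' is closed downward to 0.8 so the labels partition `[0, 1]`. Factor-level
#' binary calls: risky iff p > `risky_cut` (default 0.4).
#'
#' @param low_max upper edge of the low band.
#' @param high_min lower edge of the high band.
#' @param risky_cut binary risky/non-risky cut.
#' @return list of class `risk_band_scheme`.
#' @export
risk_band_scheme <- function(low_max = 0.4, high_min = 0.8,
                             risky_cut = 0.4) {
  stopifnot(0 < low_max, low_max < high_min, high_min <= 1)
  structure(list(low_max = low_max, high_min = high_min,
                 risky_cut = risky_cut, step = 0.2),
            class = "risk_band_scheme")
}

#' Classify a posterior probability into a risk band
#'
#' @param p probability vector in `[0, 1]`.
#' @param scheme a [risk_band_scheme()].
#' @return character vector in `c("low", "medium", "high")`.
#' @export
#' @examples
#' classify_band(c(0.9838, 0.4803, 0.0545)) # high, medium, low
classify_band <- function(p, scheme = risk_band_scheme()) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(p <= scheme$low_max, "low",
         ifelse(p >= scheme$high_min, "high", "medium"))
}

#' Risky / non-risky binary call for factor-level posteriors
#'
#' @inheritParams classify_band
#' @return logical vector, `TRUE` iff `p > scheme$risky_cut`.
#' @export
is_risky <- function(p, scheme = risk_band_scheme()) {
  p > scheme$risky_cut
}

#' Counting-based Bayesian risk assessment
#'
#' For each factor `f` and correlation level `l`:
#' * `prior` — share of level-`l` cells in `f`'s stage group (the primary
#'   factor plus its three children, 4 columns);
#' * `likelihood` — level-`l` count in `f`'s own column divided by the
#'   cell count of the pooled six secondary columns;
#' * posterior via [posterior_probability()].
#'
#' The all-cause rows (`factor = "all"`) pool all 8 columns and use the
#' pooled level share as both prior and likelihood. Every posterior is
#' banded by `scheme` and given the binary risky call.
#'
#' Denominators are configurable through `prior_group` ("stage" or "all")
#' and `likelihood_cells` ("secondary" or "all") because the counting
#' bases cannot be pinned down further without the original raw panel;
#' defaults are the faithful reading.
#'
#' @param panel an `expert_panel`.
#' @param hierarchy a [pl_hierarchy()].
#' @param anchors a [correlation_anchors()].
#' @param scheme a [risk_band_scheme()].
#' @param method `"paper"` (complement-mixture marginal, the default) or
#'   `"canonical"` (marginal as the full mixture over levels).
#' @param prior_group,likelihood_cells denominator configuration, see
#'   Details.
#' @return data frame of class `risk_assessment`: one row per
#'   (factor-or-all, level) with the posterior-computation columns, `band`
#'   and `risky`.
#' @export
assess_risk <- function(panel, hierarchy = pl_hierarchy(),
                        anchors = correlation_anchors(),
                        scheme = risk_band_scheme(),
                        method = c("paper", "canonical"),
                        prior_group = c("stage", "all"),
                        likelihood_cells = c("secondary", "all")) {
  method <- match.arg(method)
  prior_group <- match.arg(prior_group)
  likelihood_cells <- match.arg(likelihood_cells)
  lc <- count_levels(panel, hierarchy, anchors)
  lik_cells <- if (likelihood_cells == "secondary") {
    lc$secondary_cells
  } else {
    lc$all_cells
  }
  rows <- list()
  for (f in hierarchy$factors) {
    stage <- hierarchy$stage_of[[f]]
    prior <- if (prior_group == "stage") {
      lc$stage_counts[stage, ] / lc$stage_cells[[stage]]
    } else {
      lc$all_counts / lc$all_cells
    }
    likelihood <- lc$counts[f, ] / lik_cells
    rows[[f]] <- data.frame(factor = f, level = risk_levels,
                            compute_posteriors(prior, likelihood, method))
  }
  all_share <- lc$all_counts / lc$all_cells
  rows[["all"]] <- data.frame(factor = "all", level = risk_levels,
                              compute_posteriors(all_share, all_share,
                                                 method))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$band <- ifelse(is.na(out$posterior), NA_character_,
                     classify_band(out$posterior, scheme))
  out$risky <- is_risky(out$posterior, scheme)
  class(out) <- c("risk_assessment", "data.frame")
  out
}

compute_posteriors <- function(prior, likelihood, method) {
  pc <- posterior_probability(prior, likelihood)
  if (method == "canonical") {
    mix <- sum(prior * likelihood)
    pc$marginal <- mix
    pc$undefined <- mix == 0
    pc$posterior <- ifelse(pc$undefined, NA_real_,
                           prior * likelihood / mix)
  }
  pc
}
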