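#' Discretize a ratings column for mutual-information estimation
#'
#' @param column integer ratings.
#' @param method `"raw"` (default) keeps the five Likert categories as-is;
#'   `"equal_frequency"` splits ranks into `n_bins` near-equal groups,
#'   keeping tied values in one bin.
#' @param n_bins number of bins for the equal-frequency method; default
#'   `ceiling(sqrt(n))`.
#' @return integer category labels, same length as `column`.
#' @export
discretize_ratings <- function(column, method = c("raw", "equal_frequency"),
                               n_bins = NULL) {
  method <- match.arg(method)
  if (method == "raw") return(as.integer(column))
  n <- length(column)
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(n))
  # min-rank keeps all copies of a tied value in the same bin
  r <- rank(column, ties.method = "min")
  as.integer(ceiling(r * n_bins / n))
}

#' Mutual information of two categorical vectors
#'
#' Plug-in estimator from the empirical joint table:
#' \deqn{I(X;Y) = \sum_{x,y} p(x,y)\,\ln\frac{p(x,y)}{p(x)\,p(y)}}
#' with \eqn{0 \ln 0 = 0}. Nats by default (natural log).
#'
#' @param x,y equal-length category vectors.
#' @param unit `"nats"` or `"bits"`.
#' @return mutual information (non-negative scalar).
#' @export
#' @examples
#' mutual_information(c(1, 2, 1, 2), c(1, 2, 1, 2)) # ln 2
mutual_information <- function(x, y, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  ratio <- joint / outer(px, py)
  mi <- sum(joint * ifelse(joint == 0, 0, log(ratio)))
  mi <- max(mi, 0)  # clip float residue below zero
  if (unit == "bits") mi <- mi / log(2)
  mi
}

# Shannon entropy of a category vector, in nats (MI upper bound / the
# self-information a duplicated column attains)
shannon_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(ifelse(p == 0, 0, p * log(p)))
}

#' Pairwise mutual-information matrix over the panel factors
#'
#' All 28 unordered pairs computed once and mirrored; the diagonal is
#' `NA` (self-information is not a synergy and is excluded from the
#' sensitivity aggregation, where it counts as 0).
#'
#' @param panel an `expert_panel` or ratings matrix.
#' @param method,n_bins discretization, see [discretize_ratings()].
#' @param unit `"nats"` or `"bits"`.
#' @return symmetric numeric matrix with `NA` diagonal, dimnames = factor
#'   codes.
#' @export
mi_matrix <- function(panel, method = c("raw", "equal_frequency"),
                      n_bins = NULL, unit = c("nats", "bits")) {
  method <- match.arg(method)
  unit <- match.arg(unit)
  x <- panel_matrix(panel)
  k <- ncol(x)
  d <- sapply(seq_len(k), function(j) {
    discretize_ratings(x[, j], method, n_bins)
  })
  m <- matrix(NA_real_, k, k, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- mutual_information(d[, i], d[, j], unit)
    }
  }
  m
}

#' Stage-anchored sensitivity values
#'
#' The sensitivity value of a factor is its mean mutual information with
#' the two primary (stage-level) factors X1 and X5, a factor's entry
#' against itself counting as 0:
#' \deqn{SV(f) = \tfrac{1}{2}\left(I(f; X_1) + I(f; X_5)\right)}
#' Higher SV marks a more "active" factor in the all-cause structure.
#' Activity ranks are assigned by SV descending, ties broken by factor
#' code order.
#'
#' This aggregation rule — average against the primary factors with
#' self-MI zero — is the interpretation adopted for the model's loosely
#' worded "included in the average value" instruction; it is the unique
#' simple rule consistent with the study's published sensitivity row.
#'
#' @param mi a mutual-information matrix as from [mi_matrix()] (NA
#'   diagonal allowed).
#' @param hierarchy a [pl_hierarchy()] identifying the primary factors.
#' @return list of class `sensitivity_values` with `sv` (named numeric)
#'   and `activity_rank`.
#' @export
sensitivity_values <- function(mi, hierarchy = pl_hierarchy()) {
  mi <- as.matrix(mi)
  f <- hierarchy$factors
  if (!all(f %in% rownames(mi)) || !all(f %in% colnames(mi))) {
    stop("MI matrix must be labelled with all factor codes")
  }
  mi <- mi[f, f]
  primaries <- hierarchy$primary_factors
  sv <- vapply(f, function(fac) {
    vals <- vapply(primaries, function(p) {
      if (identical(p, fac)) 0 else mi[fac, p]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  if (anyNA(sv)) stop("MI matrix has NA off-diagonal entries for primaries")
  structure(list(sv = sv, activity_rank = stats::setNames(rank_desc(sv), f)),
            class = "sensitivity_values")
}

#' @export
print.sensitivity_values <- function(x, ...) {
  df <- data.frame(factor = names(x$sv), sv = round_half_away(x$sv, 4),
                   activity_rank = x$activity_rank)
  cat("Stage-anchored sensitivity values (nats)\n")
  print(df, row.names = FALSE)
  invisible(x)
}
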