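#' Normalize a ratings matrix for the entropy-weight method
#'
#' Two normalization routes to the column-stochastic share matrix
#' \eqn{p_{ij}} that the Shannon entropy is computed on:
#' * `mode = "paper"` (default): each cell is first divided by its
#'   column's range (max - min) — the spreadsheet-style "binning
#'   intercept" — and the column is then rescaled to sum 1. Without the
#'   rescale the entropy is not bounded by `ln(n)` and difference
#'   coefficients can go negative.
#' * `mode = "column_share"`: each cell divided by its column sum (the
#'   textbook entropy-weight normalization).
#'
#' A constant column has zero range and zero information; it is flagged
#' degenerate and handled downstream (entropy 1, weight 0), never an
#' error.
#'
#' @param panel an `expert_panel` or numeric matrix.
#' @param mode `"paper"` or `"column_share"`.
#' @return list with `p` (column-stochastic matrix; degenerate columns
#'   `NA`) and `degenerate` (logical per column).
#' @export
normalize_ratings <- function(panel, mode = c("paper", "column_share")) {
  mode <- match.arg(mode)
  x <- panel_matrix(panel)
  if (nrow(x) < 2L) stop("need at least 2 experts")
  degenerate <- apply(x, 2, function(v) max(v) == min(v))
  p <- x * NA_real_
  for (j in seq_len(ncol(x))) {
    if (degenerate[j]) next
    v <- as.numeric(x[, j])
    if (mode == "paper") v <- v / (max(v) - min(v))
    p[, j] <- v / sum(v)
  }
  list(p = p, degenerate = degenerate)
}

#' Entropy-reduction risk weights
#'
#' Classical entropy-weight method over the factor columns: with
#' column-stochastic shares \eqn{p_{ij}} over the \eqn{n} experts and
#' moderating coefficient \eqn{k = 1/\ln n},
#' \deqn{E_j = -k \sum_i p_{ij} \ln p_{ij}, \quad g_j = 1 - E_j, \quad
#'   w_j = g_j / \sum_j g_j}
#' with the convention \eqn{0 \ln 0 = 0}. Factors whose ratings disperse
#' more carry lower entropy, a larger difference coefficient \eqn{g_j},
#' and hence more weight. A constant (degenerate) column gets \eqn{E_j=1},
#' \eqn{g_j = 0}, weight 0. If every column is degenerate the weights fall
#' back to uniform with a warning.
#'
#' @param panel an `expert_panel` or numeric matrix.
#' @param mode normalization route, see [normalize_ratings()].
#' @return object of class `entropy_weights`: list with `normalized`,
#'   `k`, `E`, `g`, `w`, `weight_pct`, `rank` (1 = largest weight, ties by
#'   column order) and `degenerate`.
#' @export
entropy_weights <- function(panel, mode = c("paper", "column_share")) {
  mode <- match.arg(mode)
  x <- panel_matrix(panel)
  nm <- normalize_ratings(x, mode)
  n <- nrow(x)
  k <- 1 / log(n)
  E <- vapply(seq_len(ncol(x)), function(j) {
    if (nm$degenerate[j]) return(1)
    p <- nm$p[, j]
    -k * sum(ifelse(p == 0, 0, p * log(p)))
  }, numeric(1))
  names(E) <- colnames(x)
  g <- 1 - E
  g <- pmax(g, 0)  # guard tiny negative float residue
  if (sum(g) == 0) {
    warning("all columns degenerate: falling back to uniform weights")
    w <- rep(1 / ncol(x), ncol(x))
    names(w) <- colnames(x)
  } else {
    w <- g / sum(g)
  }
  structure(
    list(normalized = nm$p, k = k, E = E, g = g, w = w,
         weight_pct = 100 * w, rank = rank_desc(w),
         degenerate = nm$degenerate),
    class = "entropy_weights"
  )
}

#' @export
print.entropy_weights <- function(x, ...) {
  df <- data.frame(factor = names(x$w), E = round(x$E, 4),
                   g = signif(x$g, 4), weight_pct = round(x$weight_pct, 2),
                   rank = x$rank)
  cat("Entropy-reduction risk weights (k = 1/ln n =", round(x$k, 4), ")\n")
  print(df, row.names = FALSE)
  invisible(x)
}
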