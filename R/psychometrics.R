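#' Cronbach's alpha internal-consistency coefficient
#'
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right)}
#' where \eqn{s_j^2} are the sample item variances (denominator n-1) and
#' \eqn{s_T^2} the variance of the per-expert total score. Values above 0.7
#' are conventionally acceptable.
#'
#' @param panel an `expert_panel` or numeric matrix (rows = respondents,
#'   columns = items).
#' @return the alpha coefficient (length-1 numeric).
#' @export
cronbach_alpha <- function(panel) {
  x <- panel_matrix(panel)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("cronbach_alpha needs at least 2 rows and 2 columns")
  }
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) stop("total-score variance is zero: alpha undefined")
  item_var <- sum(apply(x, 2, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Content validity indices (I-CVI and S-CVI)
#'
#' The item-level index I-CVI is the proportion of experts rating the item
#' at or above `relevant_min`; the scale-level index S-CVI is the mean of
#' the I-CVIs (averaging convention — see the methods vignette for why the
#' universal-agreement variant is not used). Conventional floors: I-CVI
#' >= 0.8, S-CVI >= 0.9.
#'
#' @param relevance_ratings matrix of integer ratings 1..5 (rows = experts,
#'   columns = items).
#' @param relevant_min rating floor counted as "relevant"; default 4 on the
#'   5-point scale.
#' @return list with `i_cvi` (named per item) and `s_cvi`.
#' @export
content_validity <- function(relevance_ratings, relevant_min = 4) {
  x <- panel_matrix(relevance_ratings)
  if (length(x) == 0L) stop("empty relevance matrix")
  i_cvi <- colMeans(x >= relevant_min)
  list(i_cvi = i_cvi, s_cvi = mean(i_cvi))
}

#' Test-retest reliability: ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement — the
#' standard intraclass correlation for a test-retest design with two
#' administrations. Computed from the two-way ANOVA mean squares
#' (rows = subjects, columns = occasions):
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' A 95% confidence interval follows McGraw & Wong's F-based
#' approximation. Values >= 0.5 are conventionally acceptable.
#'
#' @param test,retest numeric vectors (one score per subject and occasion)
#'   or matrices of identical shape (subjects x items; items are stacked as
#'   additional subjects, a common pooling for instrument-level ICC).
#' @param conf_level confidence level for the interval.
#' @return list with `icc`, `lower`, `upper`, `ms` (the ANOVA mean
#'   squares).
#' @export
icc_test_retest <- function(test, retest, conf_level = 0.95) {
  if (!all(dim(as.matrix(test)) == dim(as.matrix(retest)))) {
    stop("test and retest must have identical shapes")
  }
  y <- cbind(as.vector(as.matrix(test)), as.vector(as.matrix(retest)))
  n <- nrow(y)
  k <- ncol(y)
  if (n < 2L) stop("need at least 2 subjects")
  grand <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- if (denom == 0) NA_real_ else (msr - mse) / denom
  # McGraw & Wong (1996) approximate CI for ICC(A,1)
  lower <- upper <- NA_real_
  if (is.finite(icc) && mse > 0) {
    alpha <- 1 - conf_level
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  }
  list(icc = icc, lower = lower, upper = upper,
       ms = c(MSR = msr, MSC = msc, MSE = mse))
}

#' Per-factor descriptive moments
#'
#' Sample mean, sample SD (denominator n-1), adjusted Fisher-Pearson
#' skewness \eqn{G_1 = g_1\sqrt{n(n-1)}/(n-2)} and plain (non-excess)
#' kurtosis \eqn{b_2 = m_4/m_2^2}. Screening flags follow the usual survey
#' conventions |skewness| < 3 and |kurtosis| < 10. A constant column has
#' undefined shape moments; these are reported as 0 with `degenerate =
#' TRUE`.
#'
#' @param panel an `expert_panel` or numeric matrix.
#' @return data frame with one row per column: `factor`, `mean`, `sd`,
#'   `skewness`, `kurtosis`, `degenerate`, `skew_ok`, `kurt_ok`.
#' @export
panel_descriptives <- function(panel) {
  x <- panel_matrix(panel)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows")
  out <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    m <- mean(v)
    s <- stats::sd(v)
    m2 <- mean((v - m)^2)
    if (m2 == 0) {
      data.frame(factor = colnames(x)[j], mean = m, sd = 0,
                 skewness = 0, kurtosis = 0, degenerate = TRUE)
    } else {
      g1 <- mean((v - m)^3) / m2^1.5
      skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
      kurt <- mean((v - m)^4) / m2^2
      data.frame(factor = colnames(x)[j], mean = m, sd = s,
                 skewness = skew, kurtosis = kurt, degenerate = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out$skew_ok <- abs(out$skewness) < 3
  out$kurt_ok <- abs(out$kurtosis) < 10
  out
}

#' Quality-control report for an expert panel
#'
#' Bundles the data-cleansing stage: internal consistency, content
#' validity, optional test-retest reliability and descriptive moments.
#' Threshold violations (alpha <= 0.7, I-CVI < 0.8, S-CVI < 0.9,
#' ICC < 0.5) are warnings, never errors: the pipeline always proceeds.
#'
#' @param panel an `expert_panel`.
#' @param relevance_ratings optional expert x item relevance matrix for
#'   [content_validity()]; defaults to the panel's own ratings.
#' @param retest optional second-occasion panel (matrix or `expert_panel`)
#'   for [icc_test_retest()].
#' @return list of class `qc_report` with elements `cronbach_alpha`,
#'   `i_cvi`, `s_cvi`, `icc`, `per_factor`, `flags`.
#' @export
qc_report <- function(panel, relevance_ratings = NULL, retest = NULL) {
  x <- panel_matrix(panel)
  alpha <- cronbach_alpha(x)
  cv <- content_validity(relevance_ratings %||% x)
  icc <- if (is.null(retest)) NULL else icc_test_retest(x, panel_matrix(retest))
  desc <- panel_descriptives(x)
  flags <- character(0)
  if (alpha <= 0.7) flags <- c(flags, sprintf("alpha %.3f <= 0.7", alpha))
  if (any(cv$i_cvi < 0.8)) {
    flags <- c(flags, sprintf("I-CVI < 0.8 for: %s",
                              paste(names(cv$i_cvi)[cv$i_cvi < 0.8],
                                    collapse = ", ")))
  }
  if (cv$s_cvi < 0.9) flags <- c(flags, sprintf("S-CVI %.3f < 0.9", cv$s_cvi))
  if (!is.null(icc) && is.finite(icc$icc) && icc$icc < 0.5) {
    flags <- c(flags, sprintf("ICC %.3f < 0.5", icc$icc))
  }
  for (f in flags) warning("QC threshold: ", f, call. = FALSE)
  structure(
    list(cronbach_alpha = alpha, i_cvi = cv$i_cvi, s_cvi = cv$s_cvi,
         icc = icc, per_factor = desc, flags = flags),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: alpha = %.3f, S-CVI = %.3f", x$cronbach_alpha,
              x$s_cvi))
  if (!is.null(x$icc)) cat(sprintf(", ICC = %.3f", x$icc$icc))
  cat("\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
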