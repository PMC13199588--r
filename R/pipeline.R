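#' Pipeline configuration
#'
#' Every option defaults to the model-faithful choice; overriding them is
#' an explicit analytical decision.
#'
#' @param anchors a [correlation_anchors()].
#' @param scheme a [risk_band_scheme()].
#' @param bayes_method `"paper"` or `"canonical"`, see [assess_risk()].
#' @param prior_group,likelihood_cells counting denominators, see
#'   [assess_risk()].
#' @param entropy_mode normalization route, see [entropy_weights()].
#' @param mi_method,mi_bins discretization, see [mi_matrix()].
#' @param mi_unit `"nats"` or `"bits"`.
#' @param seed integer seed for any simulation subcommand.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(anchors = correlation_anchors(),
                            scheme = risk_band_scheme(),
                            bayes_method = "paper",
                            prior_group = "stage",
                            likelihood_cells = "secondary",
                            entropy_mode = "paper",
                            mi_method = "raw",
                            mi_bins = NULL,
                            mi_unit = "nats",
                            seed = 1L) {
  structure(
    list(anchors = anchors, scheme = scheme, bayes_method = bayes_method,
         prior_group = prior_group, likelihood_cells = likelihood_cells,
         entropy_mode = entropy_mode, mi_method = mi_method,
         mi_bins = mi_bins, mi_unit = mi_unit, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the five-stage risk-assessment pipeline
#'
#' QC -> Bayesian risk levels -> entropy weights -> mutual-information
#' sensitivity -> ETTO optimization, in order, on one expert panel.
#' QC threshold violations are warnings and never abort the run; the run
#' is deterministic given the panel and config.
#'
#' @param panel an `expert_panel`, or a path to a panel CSV readable by
#'   [read_panel()].
#' @param config a [pipeline_config()].
#' @param hierarchy a [pl_hierarchy()].
#' @param retest optional second-occasion panel for the QC ICC.
#' @return list of class `hfrpam_report` with elements `qc`, `risk`,
#'   `weights`, `mi`, `sv`, `optimization`, `provenance`.
#' @export
run_pipeline <- function(panel, config = pipeline_config(),
                         hierarchy = pl_hierarchy(), retest = NULL) {
  input_path <- NULL
  if (is.character(panel)) {
    input_path <- panel
    panel <- read_panel(panel, hierarchy)
  }
  stage <- "qc"
  report <- tryCatch({
    qc <- qc_report(panel, retest = retest)
    stage <- "bayes_risk"
    risk <- assess_risk(panel, hierarchy, config$anchors, config$scheme,
                        method = config$bayes_method,
                        prior_group = config$prior_group,
                        likelihood_cells = config$likelihood_cells)
    stage <- "entropy_weights"
    w <- entropy_weights(panel, mode = config$entropy_mode)
    if (any(w$degenerate)) {
      warning("degenerate (constant) factor column(s): ",
              paste(names(w$w)[w$degenerate], collapse = ", "),
              " -> entropy weight 0", call. = FALSE)
    }
    stage <- "mi_sensitivity"
    mi <- mi_matrix(panel, method = config$mi_method,
                    n_bins = config$mi_bins, unit = config$mi_unit)
    sv <- sensitivity_values(mi, hierarchy)
    stage <- "optimization"
    opt <- optimization_table(sv, w, hierarchy)
    list(qc = qc, risk = risk, weights = w, mi = mi, sv = sv,
         optimization = opt)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("hfrpam")),
    config = config_snapshot(config),
    input_digest = panel_digest(panel),
    input_path = input_path
  )
  class(report) <- "hfrpam_report"
  report
}

config_snapshot <- function(config) {
  list(anchors = unclass(config$anchors),
       scheme = unclass(config$scheme),
       bayes_method = config$bayes_method,
       prior_group = config$prior_group,
       likelihood_cells = config$likelihood_cells,
       entropy_mode = config$entropy_mode,
       mi_method = config$mi_method,
       mi_bins = config$mi_bins,
       mi_unit = config$mi_unit,
       seed = config$seed)
}

# md5 over the canonical CSV serialization: changes iff panel bytes change
panel_digest <- function(panel) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_panel(panel, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a pipeline report to disk
#'
#' JSON is the canonical artifact (`report.json`); the table-shaped CSVs
#' (`risk.csv`, `weights.csv`, `mi_matrix.csv`, `sensitivity.csv`,
#' `optimization.csv`) mirror the human-readable report layouts and are
#' re-parseable by the package's own readers.
#'
#' @param report an `hfrpam_report`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "hfrpam_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- report$weights
  weights_df <- data.frame(factor = names(w$w), E = w$E, g = w$g,
                           weight = w$w, weight_pct = w$weight_pct,
                           rank = w$rank)
  utils::write.csv(as.data.frame(report$risk),
                   file.path(dir, "risk.csv"), row.names = FALSE)
  utils::write.csv(weights_df, file.path(dir, "weights.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(code = rownames(report$mi), report$mi,
                              check.names = FALSE),
                   file.path(dir, "mi_matrix.csv"), row.names = FALSE)
  utils::write.csv(data.frame(factor = names(report$sv$sv),
                              sv = report$sv$sv,
                              activity_rank = report$sv$activity_rank),
                   file.path(dir, "sensitivity.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$optimization),
                   file.path(dir, "optimization.csv"), row.names = FALSE)
  json <- list(
    qc = list(cronbach_alpha = report$qc$cronbach_alpha,
              i_cvi = as.list(report$qc$i_cvi),
              s_cvi = report$qc$s_cvi,
              icc = if (is.null(report$qc$icc)) NULL else
                report$qc$icc[c("icc", "lower", "upper")],
              per_factor = report$qc$per_factor,
              flags = report$qc$flags),
    risk = as.data.frame(report$risk),
    weights = weights_df,
    mi = as.data.frame(report$mi),
    sensitivity = as.list(report$sv$sv),
    optimization = as.data.frame(report$optimization),
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read a mutual-information matrix from CSV
#'
#' Expects the layout written by [write_report()] / shipped in
#' `extdata`: a `code` column followed by one column per factor, `NA` on
#' the diagonal.
#'
#' @param path CSV path.
#' @return numeric matrix with dimnames.
#' @export
read_mi_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a risk-weight vector from CSV
#'
#' Expects columns `factor` and one of `weight_pct` or `weight`.
#'
#' @param path CSV path.
#' @return named numeric vector of weight *proportions* (percentages are
#'   divided by 100).
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path)
  w <- if ("weight_pct" %in% names(df)) df$weight_pct / 100 else df$weight
  stats::setNames(as.numeric(w), df$factor)
}

#' Replay the optimization stage from published intermediates
#'
#' Recomputes sensitivity values, optimization indices, the activity
#' sequence and path labels from a supplied weight vector and
#' mutual-information matrix — the entry point for auditing the
#' optimization stage against printed intermediates when the raw panel is
#' unavailable.
#'
#' @param weights named numeric weights (proportions or percentages; a
#'   vector summing above 2 is treated as percentages) or a CSV path for
#'   [read_weights()].
#' @param mi an MI matrix or a CSV path for [read_mi_matrix()].
#' @param hierarchy a [pl_hierarchy()].
#' @return an `optimization_record` data frame (see
#'   [optimization_table()]).
#' @export
#' @examples
#' tab <- replay_intermediates(reference_risk_weights(),
#'                             reference_mi_matrix())
#' tab[tab$factor == "X8", c("oi", "activity_rank")]
replay_intermediates <- function(weights, mi, hierarchy = pl_hierarchy()) {
  if (is.character(weights)) weights <- read_weights(weights)
  if (is.character(mi)) mi <- read_mi_matrix(mi)
  if (sum(weights) > 2) weights <- weights / 100
  weights <- weights[hierarchy$factors]
  sv <- sensitivity_values(mi, hierarchy)
  optimization_table(sv, weights, hierarchy)
}

#' Reference intermediates from the original expert study
#'
#' The mutual-information matrix and entropy risk weights published by the
#' expert-elicitation study this model derives from, shipped as plain-text
#' package data. They are the standard audit inputs for
#' [replay_intermediates()]; the raw 62-expert panel behind them was never
#' released, so downstream values (sensitivity, optimization index,
#' activity sequence) are reproducible from these while the intermediates
#' themselves are not.
#'
#' @return `reference_mi_matrix()`: an 8x8 numeric matrix (nats, `NA`
#'   diagonal); `reference_risk_weights()`: a named vector of weight
#'   percentages.
#' @export
reference_mi_matrix <- function() {
  read_mi_matrix(system.file("extdata", "reference_mi_matrix.csv",
                             package = "hfrpam", mustWork = TRUE))
}

#' @rdname reference_mi_matrix
#' @export
reference_risk_weights <- function() {
  df <- utils::read.csv(system.file("extdata", "reference_risk_weights.csv",
                                    package = "hfrpam", mustWork = TRUE))
  stats::setNames(df$weight_pct, df$factor)
}

#' @export
print.hfrpam_report <- function(x, ...) {
  cat("HFRPAM pipeline report\n")
  print(x$qc)
  all_high <- x$risk[x$risk$factor == "all" & x$risk$level == "high", ]
  cat(sprintf("all-cause high-correlation posterior: %.4f (%s risk)\n",
              all_high$posterior, all_high$band))
  top <- x$optimization[x$optimization$activity_rank == 1, ]
  cat(sprintf("top optimization target: %s (OI = %.4f)\n",
              top$factor, top$oi))
  invisible(x)
}
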