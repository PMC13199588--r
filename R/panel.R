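#' Expert panels of Likert ratings
#'
#' An expert panel is an `n_experts x 8` matrix of integer ratings on the
#' standard 5-point Likert scale (1 = strongly disagree, 5 = strongly
#' agree), one column per human factor in hierarchy order. `as_panel()`
#' validates a matrix or data frame; [read_panel()] reads the CSV interface
#' format (`expert_id,X1,...,X8`, the id column optional).
#'
#' @param x matrix or data frame of ratings with columns named by factor
#'   code.
#' @param hierarchy a [pl_hierarchy()]; fixes the canonical column order.
#' @param expert_ids optional identifiers, defaulting to `1:n`; used only
#'   in messages and written output.
#' @return an object of class `expert_panel`: a list with `ratings`
#'   (integer matrix, dimnames = expert ids x factor codes), `expert_ids`
#'   and `factor_codes`.
#' @export
as_panel <- function(x, hierarchy = pl_hierarchy(), expert_ids = NULL) {
  if (is.data.frame(x)) {
    if ("expert_id" %in% names(x)) {
      if (is.null(expert_ids)) expert_ids <- as.character(x$expert_id)
      x <- x[setdiff(names(x), "expert_id")]
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) stop("ratings must be a matrix or data frame")
  want <- hierarchy$factors
  if (is.null(colnames(x))) {
    if (ncol(x) != length(want)) {
      stop("unnamed ratings must have ", length(want), " columns")
    }
    colnames(x) <- want
  }
  missing <- setdiff(want, colnames(x))
  if (length(missing)) {
    stop("panel lacks factor column(s): ", paste(missing, collapse = ", "))
  }
  x <- x[, want, drop = FALSE]  # canonicalize column order
  if (nrow(x) < 1L) stop("panel needs at least one expert (row)")
  validate_ratings(x)
  ratings <- matrix(as.integer(round(as.numeric(x))), nrow(x), ncol(x),
                    dimnames = list(NULL, want))
  ids <- expert_ids %||% as.character(seq_len(nrow(x)))
  if (length(ids) != nrow(x)) stop("expert_ids length != number of rows")
  rownames(ratings) <- ids
  structure(
    list(ratings = ratings, expert_ids = ids, factor_codes = want),
    class = "expert_panel"
  )
}

# reject missing / non-integer / out-of-range cells with exact coordinates
validate_ratings <- function(x) {
  num <- suppressWarnings(matrix(as.numeric(x), nrow(x), ncol(x)))
  bad <- is.na(num) | num != round(num) | num < 1 | num > 5
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid rating %s at row %d, column %s: ratings must be integers in 1..5",
      deparse(as.vector(x[idx[1], idx[2]])), idx[1], colnames(x)[idx[2]]
    ))
  }
  invisible(TRUE)
}

#' Read an expert panel from CSV
#'
#' Expects a header row naming the 8 factor codes (any order; columns are
#' re-aligned to hierarchy order) and optionally an `expert_id` column.
#'
#' @param path path to a comma-separated file.
#' @inheritParams as_panel
#' @return an `expert_panel`.
#' @export
read_panel <- function(path, hierarchy = pl_hierarchy()) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- NULL
  if ("expert_id" %in% names(df)) {
    ids <- df$expert_id
    df <- df[setdiff(names(df), "expert_id")]
  }
  m <- as.matrix(df)
  as_panel(m, hierarchy = hierarchy, expert_ids = ids)
}

#' Write an expert panel to CSV
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(p, f))` reproduces
#' `p` exactly (ratings are integers, so the round trip is lossless).
#'
#' @param panel an `expert_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "expert_panel"))
  df <- data.frame(expert_id = panel$expert_ids, panel$ratings,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.expert_panel <- function(x, ...) {
  cat("Expert panel:", nrow(x$ratings), "experts x",
      ncol(x$ratings), "factors (Likert 1-5)\n")
  print(utils::head(x$ratings, 6))
  if (nrow(x$ratings) > 6) cat("...\n")
  invisible(x)
}

#' @export
dim.expert_panel <- function(x) dim(x$ratings)

#' @export
as.matrix.expert_panel <- function(x, ...) x$ratings

# accept either an expert_panel or a bare ratings matrix in the numeric
# stages; returns the ratings matrix
panel_matrix <- function(x) {
  if (inherits(x, "expert_panel")) x$ratings else as.matrix(x)
}
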