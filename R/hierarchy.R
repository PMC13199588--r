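#' The two-stage / six-attribute physical-literacy factor hierarchy
#'
#' Physical literacy (PL), in Whitehead's holistic formulation, comprises a
#' *core* stage (motivation; confidence and physical competence; interaction
#' with the environment) and an *external* stage (sense of self; self-
#' expression and communication with others; knowledge and understanding).
#' For risk assessment each stage is a primary human factor and each
#' attribute a secondary human factor, coded `X1`-`X8`:
#'
#' | code | stage    | role      | attribute                                   |
#' |------|----------|-----------|---------------------------------------------|
#' | X1   | core     | primary   | core stage (CS)                              |
#' | X2   | core     | secondary | motivation (CS01)                            |
#' | X3   | core     | secondary | confidence and physical competence (CS02)    |
#' | X4   | core     | secondary | interaction with the environment (CS03)      |
#' | X5   | external | primary   | external stage (ES)                          |
#' | X6   | external | secondary | sense of self and self-confidence (ES01)     |
#' | X7   | external | secondary | self-expression / communication (ES02)       |
#' | X8   | external | secondary | knowledge and understanding (ES03)           |
#'
#' Each secondary factor maps to three items of the 18-item Perceived
#' Physical Literacy Instrument (PPLI); the item codes are metadata only and
#' play no role in the numerical pipeline.
#'
#' @param config optional hierarchy description: a named list with elements
#'   `factors` (character vector of codes), `stage_of` (named character,
#'   `"core"`/`"external"`), `parent_of` (named character mapping secondary
#'   codes to their primary factor) and optionally `items_of` (named list of
#'   item codes). `NULL` (the default) returns the built-in PPLI structure.
#' @return an object of class `pl_hierarchy` with fields `factors`,
#'   `stage_of`, `parent_of`, `items_of`, `primary_factors`,
#'   `secondary_factors`.
#' @export
#' @examples
#' h <- pl_hierarchy()
#' h$parent_of[["X8"]]  # "X5"
#' h$items_of[["X8"]]   # PL04, PL05, PL17
pl_hierarchy <- function(config = NULL) {
  if (is.null(config)) config <- default_hierarchy_config()
  required <- c("factors", "stage_of", "parent_of")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("hierarchy config lacks field(s): ", paste(missing, collapse = ", "))
  }
  factors <- as.character(config$factors)
  if (anyDuplicated(factors)) {
    stop("duplicate factor code(s): ",
         paste(unique(factors[duplicated(factors)]), collapse = ", "))
  }
  stage_of <- unlist(config$stage_of)[factors]
  if (anyNA(stage_of) || !all(stage_of %in% c("core", "external"))) {
    stop("stage_of must assign 'core' or 'external' to every factor")
  }
  parent_of <- unlist(config$parent_of)
  primary <- setdiff(factors, names(parent_of))
  secondary <- intersect(factors, names(parent_of))
  if (length(primary) != 2L || length(secondary) != 6L) {
    stop("hierarchy must have exactly 2 primary and 6 secondary factors; got ",
         length(primary), " primary")
  }
  for (f in secondary) {
    p <- parent_of[[f]]
    if (!p %in% primary) {
      stop("secondary factor ", f, " has missing/invalid parent: ", p)
    }
    if (stage_of[[f]] != stage_of[[p]]) {
      stop("secondary factor ", f, " (", stage_of[[f]],
           ") cannot be parented to ", p, " (", stage_of[[p]], ")")
    }
  }
  items_of <- config$items_of
  if (is.null(items_of)) {
    items_of <- stats::setNames(rep(list(character(0)), length(factors)),
                                factors)
  } else {
    items_of <- lapply(items_of, as.character)
    all_items <- unlist(items_of, use.names = FALSE)
    if (anyDuplicated(all_items)) {
      stop("item assigned to more than one factor: ",
           paste(unique(all_items[duplicated(all_items)]), collapse = ", "))
    }
    for (f in setdiff(factors, names(items_of))) {
      items_of[[f]] <- character(0)
    }
    items_of <- items_of[factors]
  }
  structure(
    list(
      factors = factors,
      stage_of = stage_of,
      parent_of = parent_of[secondary],
      items_of = items_of,
      primary_factors = primary[order(match(primary, factors))],
      secondary_factors = secondary[order(match(secondary, factors))]
    ),
    class = "pl_hierarchy"
  )
}

# Built-in PPLI 2-stage / 6-attribute structure with the 18 item codes.
default_hierarchy_config <- function() {
  list(
    factors = paste0("X", 1:8),
    stage_of = list(
      X1 = "core", X2 = "core", X3 = "core", X4 = "core",
      X5 = "external", X6 = "external", X7 = "external", X8 = "external"
    ),
    parent_of = list(
      X2 = "X1", X3 = "X1", X4 = "X1",
      X6 = "X5", X7 = "X5", X8 = "X5"
    ),
    items_of = list(
      X2 = c("PL09", "PL15", "PL18"),
      X3 = c("PL01", "PL06", "PL14"),
      X4 = c("PL03", "PL10", "PL16"),
      X6 = c("PL02", "PL07", "PL08"),
      X7 = c("PL11", "PL12", "PL13"),
      X8 = c("PL04", "PL05", "PL17")
    )
  )
}

#' Load a factor hierarchy from a JSON configuration
#'
#' @param path path to a JSON file with fields `factors`, `stage_of`,
#'   `parent_of` and optionally `items_of` (see [pl_hierarchy()]).
#' @return a `pl_hierarchy` object.
#' @export
load_hierarchy <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$items_of)) cfg$items_of <- as.list(cfg$items_of)
  pl_hierarchy(cfg)
}

#' @export
print.pl_hierarchy <- function(x, ...) {
  cat("Physical-literacy factor hierarchy:",
      length(x$primary_factors), "primary /",
      length(x$secondary_factors), "secondary factors\n")
  for (p in x$primary_factors) {
    kids <- names(x$parent_of)[x$parent_of == p]
    cat(sprintf("  %s [%s] -> %s\n", p, x$stage_of[[p]],
                paste(kids, collapse = ", ")))
  }
  invisible(x)
}

# columns of the panel belonging to a factor's stage group:
# the primary factor plus its three children (4 columns)
stage_group <- function(hierarchy, factor) {
  stage <- hierarchy$stage_of[[factor]]
  hierarchy$factors[hierarchy$stage_of == stage]
}
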