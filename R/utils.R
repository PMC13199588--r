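#' Round half away from zero
#'
#' Display rounding used throughout the reporting layer. Base [round()] uses
#' banker's rounding (round-half-to-even), which disagrees with the usual
#' spreadsheet convention at exact halves (e.g. 0.05105 at 4 decimals).
#' A 1e-9 guard absorbs binary floating-point representation error so that
#' values that are halves in decimal arithmetic round up in magnitude.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(0.05105, 4) # 0.0511
round_half_away <- function(x, digits = 4) {
  s <- 10^digits
  out <- sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
  out[!is.finite(x)] <- x[!is.finite(x)]
  out
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards. Keeps all randomness explicit and local.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# rank 1 = largest value; ties broken by position (factor code order)
rank_desc <- function(x) {
  ord <- order(-x, seq_along(x))
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
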