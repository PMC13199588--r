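#' Efficiency-thoroughness trade-off (ETTO) optimization index
#'
#' The composite index balancing how *active* a factor is (sensitivity
#' value, thoroughness of its synergy with the stage anchors) against how
#' much *risk mass* it carries (entropy weight, efficiency of attention):
#' \deqn{OI(f) = SV(f) + w(f)}
#' with the weight expressed as a proportion (12.25\% enters as 0.1225).
#'
#' @param sv a [sensitivity_values()] object or named numeric vector of
#'   sensitivity values.
#' @param w an [entropy_weights()] object or named numeric vector of
#'   weight proportions (summing to about 1).
#' @return named numeric vector of optimization indices.
#' @export
optimization_index <- function(sv, w) {
  svv <- if (inherits(sv, "sensitivity_values")) sv$sv else sv
  wv <- if (inherits(w, "entropy_weights")) w$w else w
  if (!setequal(names(svv), names(wv))) {
    stop("sv and w must cover the same factors")
  }
  wv <- wv[names(svv)]
  if (sum(wv) > 2) {
    stop("weights look like percentages (sum ", round(sum(wv), 2),
         "); divide by 100 first")
  }
  svv + wv
}

#' Activity sequence: rank factors by optimization index
#'
#' @param oi named numeric vector of optimization indices.
#' @return named integer ranks; 1 = largest index, ties broken by factor
#'   code order.
#' @export
activity_sequence <- function(oi) {
  stats::setNames(rank_desc(oi), names(oi))
}

#' Label the four optimization paths
#'
#' Factors are paired by consecutive activity ranks — (1,2), (3,4), (5,6),
#' (7,8) — each path running from the better-ranked factor (source) to the
#' worse (target). Paths are labelled by stage membership, reading the
#' core stage as the *subjective* pole and the external stage as the
#' *objective* pole:
#' * external source, core target: `"objective->subjective"`
#' * core source, external target: `"subjective->objective"`
#' * both core: `"subjective stage"`
#' * both external: `"objective stage"`
#'
#' @param ranks complete named ranking (a permutation of 1..8), e.g. from
#'   [activity_sequence()].
#' @param hierarchy a [pl_hierarchy()].
#' @return data frame with one row per path: `path_id`, `source`,
#'   `target`, `label`.
#' @export
classify_paths <- function(ranks, hierarchy = pl_hierarchy()) {
  k <- length(hierarchy$factors)
  if (!setequal(names(ranks), hierarchy$factors) ||
      !setequal(ranks, seq_len(k))) {
    stop("ranks must be a complete permutation of 1..", k,
         " over the factor codes")
  }
  by_rank <- names(sort(ranks))
  pole <- function(f) {
    if (hierarchy$stage_of[[f]] == "core") "subjective" else "objective"
  }
  paths <- lapply(seq_len(k / 2), function(i) {
    src <- by_rank[2 * i - 1]
    tgt <- by_rank[2 * i]
    sp <- pole(src)
    tp <- pole(tgt)
    label <- if (sp == tp) paste(sp, "stage") else paste0(sp, "->", tp)
    data.frame(path_id = i, source = src, target = tgt, label = label)
  })
  do.call(rbind, paths)
}

#' Full optimization record per factor
#'
#' Assembles the table-shaped report of the optimization stage: per-factor
#' sensitivity value, weight, optimization index, activity rank, and path
#' membership/role/label.
#'
#' @inheritParams optimization_index
#' @param hierarchy a [pl_hierarchy()].
#' @return data frame of class `optimization_record` with columns
#'   `factor`, `sv`, `weight`, `oi`, `activity_rank`, `path_id`,
#'   `path_role`, `path_label`.
#' @export
optimization_table <- function(sv, w, hierarchy = pl_hierarchy()) {
  svv <- if (inherits(sv, "sensitivity_values")) sv$sv else sv
  wv <- if (inherits(w, "entropy_weights")) w$w else w
  wv <- wv[names(svv)]
  oi <- optimization_index(svv, wv)
  ranks <- activity_sequence(oi)
  paths <- classify_paths(ranks, hierarchy)
  out <- data.frame(factor = names(oi), sv = unname(svv),
                    weight = unname(wv), oi = unname(oi),
                    activity_rank = unname(ranks))
  out$path_id <- NA_integer_
  out$path_role <- NA_character_
  out$path_label <- NA_character_
  for (i in seq_len(nrow(paths))) {
    s <- match(paths$source[i], out$factor)
    t <- match(paths$target[i], out$factor)
    out$path_id[c(s, t)] <- paths$path_id[i]
    out$path_role[s] <- "source"
    out$path_role[t] <- "target"
    out$path_label[c(s, t)] <- paths$label[i]
  }
  class(out) <- c("optimization_record", "data.frame")
  out
}
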