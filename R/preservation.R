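# Cross-condition module preservation and specificity: shared-gene Fisher
# exact tests between every module pair of two conditions; a module is
# condition-specific when no module of any other condition overlaps it
# significantly (p < 0.01).

#' Module overlap between two partitions
#'
#' For every non-grey module pair across two conditions, the number of
#' shared genes and a Fisher exact p-value on the 2x2 table (overlap,
#' A-only, B-only, neither) in the shared universe. One-sided
#' (over-representation) p is the decision value, matching degree-of-
#' overlap semantics; the two-sided p is reported alongside.
#'
#' @param partA,partB [module_assignment()]s from two conditions.
#' @param universe Gene universe; default is the intersection of the two
#'   partitions' gene sets (the conservative choice when the two networks
#'   were built on different gene lists).
#' @param alpha Significance threshold (default 0.01).
#' @return An `OverlapMatrix` data frame: moduleA, moduleB, sizes, shared
#'   count, p (one-sided), p_two_sided, significant.
#' @export
module_overlap <- function(partA, partB, universe = NULL, alpha = 0.01) {
  if (is.null(universe))
    universe <- intersect(names(partA), names(partB))
  if (!length(universe)) stop("partitions share no genes (disjoint universes)")
  partA <- partA[intersect(names(partA), universe)]
  partB <- partB[intersect(names(partB), universe)]
  labsA <- setdiff(unique(partA), GREY)
  labsB <- setdiff(unique(partB), GREY)
  rows <- list()
  for (a in labsA) {
    ga <- names(partA)[partA == a]
    for (b in labsB) {
      gb <- names(partB)[partB == b]
      e <- enrichment_fisher(ga, gb, universe, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        moduleA = a, moduleB = b,
        sizeA = length(ga), sizeB = length(gb),
        shared = e$table[1, 1],
        p = e$p_greater, p_two_sided = e$p_two_sided,
        significant = e$p_greater < alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(moduleA = character(), moduleB = character(),
               sizeA = integer(), sizeB = integer(), shared = integer(),
               p = numeric(), p_two_sided = numeric(), significant = logical())
  rownames(out) <- NULL
  class(out) <- c("OverlapMatrix", "data.frame")
  out
}

#' Call condition-specific modules
#'
#' A module is specific to its condition when it has no significant
#' counterpart (overlap p < threshold) in any module of every comparison
#' condition.
#'
#' @param overlaps Named list of `OverlapMatrix` objects, one per
#'   comparison condition, each comparing this condition's partition
#'   (moduleA side) against another condition's.
#' @param alpha Significance threshold (default 0.01).
#' @return Data frame: module, specific flag, number of significant
#'   counterparts per comparison.
#' @export
call_specific_modules <- function(overlaps, alpha = 0.01) {
  if (!length(overlaps)) return(data.frame(module = character(),
                                           specific = logical()))
  modules <- unique(unlist(lapply(overlaps, function(o) o$moduleA)))
  if (!length(modules)) return(data.frame(module = character(),
                                          specific = logical()))
  rows <- lapply(modules, function(m) {
    hits <- vapply(overlaps, function(o)
      sum(o$p[o$moduleA == m] < alpha), integer(1))
    data.frame(module = m, specific = all(hits == 0),
               t(hits), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count preserved modules between two conditions
#'
#' Reports both conventions for "n modules preserved": counting a module
#' once if it overlaps any module of the other condition significantly
#' (`any_match`), and the number of significant pairs (`pair_matches`).
#'
#' @param overlap An `OverlapMatrix`.
#' @param alpha Significance threshold.
#' @return List with `any_match`, `pair_matches`.
#' @export
count_preserved <- function(overlap, alpha = 0.01) {
  sig <- overlap[overlap$p < alpha, , drop = FALSE]
  list(any_match = length(unique(sig$moduleA)),
       pair_matches = nrow(sig))
}
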