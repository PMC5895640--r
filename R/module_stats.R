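# Module-level condition statistics: strain x condition module-average
# expression tables, one-way treatment ANOVA (E_ij = mu + T_i + eps_ij),
# classification into the four condition-response patterns, module
# eigengene-trait correlations, and 2x2 Fisher over-representation against
# gene-set collections.

#' Strain x condition module-average expression
#'
#' For each module, `E[i, j]` is the mean over the module's genes of strain
#' i's expression under condition j — the dependent variable of the
#' condition-pattern ANOVA.
#'
#' @param exprs Named list of [expression_matrix()] per condition.
#' @param assignment A [module_assignment()].
#' @return Named list of strain x condition matrices, one per non-grey
#'   module.
#' @export
module_condition_profile <- function(exprs, assignment) {
  labels <- setdiff(unique(assignment), GREY)
  strains <- Reduce(union, lapply(exprs, colnames))
  out <- list()
  for (l in labels) {
    genes <- names(assignment)[assignment == l]
    E <- matrix(NA_real_, length(strains), length(exprs),
                dimnames = list(strains, names(exprs)))
    for (cond in names(exprs)) {
      m <- unclass(exprs[[cond]])
      present <- intersect(genes, rownames(m))
      if (!length(present)) {
        warning("module ", l, " has no genes in condition ", cond)
        next
      }
      E[colnames(m), cond] <- colMeans(m[present, , drop = FALSE], na.rm = TRUE)
    }
    out[[l]] <- E
  }
  out
}

#' One-way condition ANOVA on a module's E table
#'
#' Fixed-effects one-way ANOVA of module-average expression on treatment
#' condition: `E_ij = mu + T_i + eps_ij`, F = MS_between / MS_within with
#' df (c - 1, N - c), p from the F distribution.
#'
#' @param E Strain x condition matrix from [module_condition_profile()].
#' @return List with `F`, `p`, `df`, and the per-condition means.
#' @export
anova_pattern <- function(E) {
  long <- data.frame(
    value = as.vector(E),
    condition = factor(rep(colnames(E), each = nrow(E)))
  )
  long <- long[!is.na(long$value), ]
  counts <- table(long$condition)
  if (sum(counts >= 2) < 2)
    stop("need at least 2 conditions with at least 2 strains each")
  ssw <- sum(tapply(long$value, long$condition,
                    function(v) sum((v - mean(v))^2)))
  ssb <- sum(tapply(long$value, long$condition,
                    function(v) length(v) * (mean(v) - mean(long$value))^2))
  if (ssw <= 1e-300 && ssb > 0) {
    warning("zero within-group variance: p at the 0 boundary")
    return(list(F = Inf, p = 0,
                df = c(nlevels(long$condition) - 1,
                       nrow(long) - nlevels(long$condition)),
                means = colMeans(E, na.rm = TRUE)))
  }
  fit <- stats::aov(value ~ condition, data = long)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  list(F = Fv, p = p, df = unname(tab[["Df"]]),
       means = colMeans(E, na.rm = TRUE))
}

#' Classify a module's condition-response pattern
#'
#' Deltas are taken against the NOS control mean; a condition counts as
#' up/down when its delta magnitude reaches `delta_min` with that sign.
#' Pattern 1: NOE up, RSE restored to control; pattern 2: NOE down, RSE
#' rescued to control; pattern 3: RSS and NOE up with RSE amplified beyond
#' both; pattern 4: RSS up with NOE and RSE flat-or-reduced. Anything else
#' is `"unclassified"` — ambiguous profiles are not force-assigned.
#'
#' @param means Named numeric vector with entries NOS, RSS, NOE, RSE.
#' @param delta_min Minimum log2 shift to call a condition up or down
#'   (default 0.1).
#' @return `"1"`, `"2"`, `"3"`, `"4"` or `"unclassified"`.
#' @export
classify_pattern <- function(means, delta_min = 0.1) {
  if (!all(CONDITIONS %in% names(means)) || any(is.na(means[CONDITIONS])))
    stop("need all four condition means (NOS, RSS, NOE, RSE)")
  d <- means[CONDITIONS] - means[["NOS"]]
  up <- function(x) d[[x]] >= delta_min
  down <- function(x) d[[x]] <= -delta_min
  flat <- function(x) abs(d[[x]]) < delta_min
  if (up("NOE") && flat("RSE") && flat("RSS")) return("1")
  if (down("NOE") && flat("RSE") && flat("RSS")) return("2")
  if (up("RSS") && up("NOE") && up("RSE") &&
      means[["RSE"]] > max(means[["RSS"]], means[["NOE"]])) return("3")
  if (up("RSS") && !up("NOE") && !up("RSE")) return("4")
  "unclassified"
}

#' Pattern summary for every module
#'
#' Combines [module_condition_profile()], [anova_pattern()] and
#' [classify_pattern()].
#'
#' @param exprs Named list of condition [expression_matrix()].
#' @param assignment A [module_assignment()].
#' @param delta_min Passed to [classify_pattern()].
#' @return Data frame with module, per-condition means, pattern label,
#'   ANOVA F and p.
#' @export
pattern_summary <- function(exprs, assignment, delta_min = 0.1) {
  Es <- module_condition_profile(exprs, assignment)
  rows <- lapply(names(Es), function(l) {
    an <- anova_pattern(Es[[l]])
    lab <- tryCatch(classify_pattern(an$means, delta_min),
                    error = function(e) NA_character_)
    data.frame(module = l, t(an$means), pattern = lab,
               F = an$F, p = an$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Module eigengene-trait correlation
#'
#' Pearson correlation of each module eigengene with each trait over the
#' shared strains; two-sided p from the t distribution with n - 2 degrees
#' of freedom. Cells with p below `display_p` form the display mask
#' conventionally shown in module-trait heat maps.
#'
#' @param mes Strain x module eigengene matrix.
#' @param phen A [phenotype_table()].
#' @param display_p Display threshold on the p-value (default 0.1).
#' @return List of module x trait matrices `r`, `p`, `n`, `display`
#'   (logical mask).
#' @export
module_trait_correlation <- function(mes, phen, display_p = 0.1) {
  shared <- intersect(rownames(mes), rownames(phen))
  modules <- colnames(mes)
  traits <- colnames(phen)
  r <- p <- nmat <- matrix(NA_real_, length(modules), length(traits),
                           dimnames = list(modules, traits))
  for (m in modules) for (tr in traits) {
    x <- mes[shared, m]
    y <- phen[shared, tr]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    nmat[m, tr] <- n
    if (n < 4) {
      warning("fewer than 4 shared strains for ", m, " x ", tr)
      next
    }
    rv <- stats::cor(x[ok], y[ok])
    r[m, tr] <- rv
    tstat <- rv * sqrt((n - 2) / (1 - rv^2))
    p[m, tr] <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = nmat, display = !is.na(p) & p < display_p)
}

#' 2x2 Fisher over-representation of a gene set in a module
#'
#' The contingency table counts genes (1) in both the module and the set,
#' (2) in the module only, (3) in the set only, (4) in neither, within the
#' supplied universe. Two-sided Fisher exact p by default with a one-sided
#' (over-representation) alternative available; significance at p < 0.05.
#'
#' @param module_genes,set_genes Character vectors (subset of `universe`).
#' @param universe Character vector of all eligible genes.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param alpha Significance level (default 0.05).
#' @return List with `table` (2x2), `odds_ratio`, `p`, `p_greater`,
#'   `significant`.
#' @export
enrichment_fisher <- function(module_genes, set_genes, universe,
                              alternative = c("two.sided", "greater"),
                              alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (!length(universe)) stop("empty universe")
  module_genes <- intersect(unique(module_genes), universe)
  set_genes <- intersect(unique(set_genes), universe)
  both <- length(intersect(module_genes, set_genes))
  mod_only <- length(module_genes) - both
  set_only <- length(set_genes) - both
  neither <- length(universe) - both - mod_only - set_only
  tab <- matrix(c(both, mod_only, set_only, neither), 2, 2,
                dimnames = list(c("in_set", "not_set"),
                                c("in_module", "not_module")))
  ft2 <- stats::fisher.test(tab, alternative = "two.sided")
  ftg <- stats::fisher.test(tab, alternative = "greater")
  p <- if (alternative == "two.sided") ft2$p.value else ftg$p.value
  list(table = tab, odds_ratio = unname(ft2$estimate),
       p = p, p_two_sided = ft2$p.value, p_greater = ftg$p.value,
       significant = p < alpha)
}

#' Enrichment of every module against every gene set
#'
#' @param assignment A [module_assignment()].
#' @param gsc A [gene_set_collection()].
#' @param universe Universe of genes (default: all genes of the
#'   assignment, i.e. the genes entering the network).
#' @param alpha Significance level.
#' @param adjust Add a Benjamini-Hochberg adjusted column.
#' @return Long data frame: module, set, counts, odds ratio, p-values,
#'   significance flag.
#' @export
module_enrichment <- function(assignment, gsc, universe = names(assignment),
                              alpha = 0.05, adjust = TRUE) {
  labels <- setdiff(unique(assignment), GREY)
  rows <- list()
  for (l in labels) {
    mg <- names(assignment)[assignment == l]
    for (s in names(gsc)) {
      e <- enrichment_fisher(mg, gsc[[s]], universe, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        module = l, set = s,
        overlap = e$table[1, 1], module_only = e$table[2, 1],
        set_only = e$table[1, 2], neither = e$table[2, 2],
        odds_ratio = e$odds_ratio, p = e$p_two_sided,
        p_greater = e$p_greater, significant = e$significant,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust && !is.null(out)) out$p_bh <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
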