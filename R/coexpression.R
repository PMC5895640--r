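# Weighted co-expression network construction and module detection:
# soft-threshold power scan against the scale-free topology criterion,
# unsigned adjacency |cor|^beta, topological overlap, average-linkage
# clustering with static branch cutting, module eigengenes, kME and
# intramodular connectivity.

pairwise_cor <- function(m, min_shared = 3) {
  # genes in rows; pairwise-complete Pearson across strains
  r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  zero_var <- apply(m, 1, function(x) stats::sd(x, na.rm = TRUE)) == 0
  if (any(zero_var, na.rm = TRUE)) {
    warning(sum(zero_var, na.rm = TRUE),
            " zero-variance gene(s): correlations set to 0")
    r[zero_var, ] <- 0
    r[, zero_var] <- 0
  }
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` with pairwise-complete Pearson
#' correlation; diagonal fixed at 1. `signed` mode uses
#' `((1 + cor)/2)^beta` instead.
#'
#' @param expr An [expression_matrix()] (genes x strains).
#' @param beta Soft-threshold power (>= 1).
#' @param signed Use the signed transformation.
#' @return Symmetric adjacency matrix in \[0, 1\] with unit diagonal,
#'   class `AdjacencyMatrix`.
#' @export
adjacency <- function(expr, beta, signed = FALSE) {
  if (beta < 1) stop("beta must be >= 1")
  r <- pairwise_cor(unclass(expr))
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  diag(a) <- 1
  structure(a, class = c("AdjacencyMatrix", "matrix", "array"))
}

#' Scan soft-threshold powers for scale-free topology fit
#'
#' For each candidate power the adjacency is built, per-gene connectivity
#' `k_i = sum_j a_ij` (excluding self) computed, log10 k binned, and
#' log10 of the frequency regressed on log10 of the bin-mean k. The fit
#' index is R-squared signed by the negated slope sign, so a positive value
#' requires the degree distribution to fall off with k as a scale-free
#' topology does. Mean connectivity is reported per power.
#'
#' @param expr An [expression_matrix()].
#' @param powers Candidate powers (default 1:20).
#' @param n_bins Number of connectivity bins (default 10).
#' @param signed Passed to [adjacency()].
#' @return A data frame (`PowerScan`) with columns `power`, `sft_r2`,
#'   `slope`, `mean_k`.
#' @export
scan_powers <- function(expr, powers = 1:20, n_bins = 10, signed = FALSE) {
  m <- unclass(expr)
  if (nrow(m) < 30)
    warning("fewer than 30 genes: scale-free fit will be unstable")
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  if (all(sds == 0, na.rm = TRUE)) stop("all genes constant")
  r <- pairwise_cor(m)
  res <- lapply(powers, function(b) {
    a <- if (signed) ((1 + r) / 2)^b else abs(r)^b
    k <- colSums(a) - 1
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = b, sft_r2 = fit$r2, slope = fit$slope, mean_k = mean(k))
  })
  do.call(rbind, res)
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  # equal-width bins over the observed connectivity range: the frequency
  # per bin estimates p(k), regressed on the bin-mean k on log-log scale
  brk <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  k_mean <- tapply(k, bin, mean)
  p_k <- tabulate(bin, nbins = nlevels(bin)) / length(k)
  keep <- p_k > 0 & !is.na(k_mean) & k_mean > 0
  if (sum(keep) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(p_k[keep]) ~ log10(k_mean[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(r2 = -sign(slope) * r2, slope = unname(slope))
}

#' Pick the soft-threshold power
#'
#' The smallest candidate whose signed scale-free R-squared reaches the
#' target. If none does, the power with maximal R-squared is returned with
#' a warning, restricted to powers keeping mean connectivity at or above
#' `min_mean_k` — soft thresholds that shred the network into isolated
#' nodes can score a spuriously good log-log fit.
#'
#' @param scan Output of [scan_powers()].
#' @param r2_target Scale-free fit target (default 0.8).
#' @param min_mean_k Mean-connectivity floor for the fallback (default 1).
#' @return The chosen power (integer).
#' @export
pick_power <- function(scan, r2_target = 0.8, min_mean_k = 1) {
  ok <- which(!is.na(scan$sft_r2) & scan$sft_r2 >= r2_target)
  if (length(ok)) return(scan$power[ok[1]])
  warning("no power reaches scale-free R^2 target ", r2_target,
          "; returning best-fitting power with mean connectivity >= ",
          min_mean_k)
  eligible <- which(scan$mean_k >= min_mean_k & !is.na(scan$sft_r2))
  if (!length(eligible)) eligible <- which(!is.na(scan$sft_r2))
  scan$power[eligible[which.max(scan$sft_r2[eligible])]]
}

#' Topological overlap matrix
#'
#' The standard unsigned TOM:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' diagonal fixed at 1.
#'
#' @param adj An adjacency matrix from [adjacency()].
#' @return Symmetric `TOMMatrix` in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  a <- unclass(adj)
  diag(a) <- 0
  l <- a %*% a                      # l_ij includes u = i, j terms: a_ii = 0 so ok
  k <- colSums(a)
  kmin <- outer(k, k, pmin)
  tomm <- (l + a) / (kmin + 1 - a)
  diag(tomm) <- 1
  structure(tomm, class = c("TOMMatrix", "matrix", "array"))
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix,
#' returned as a per-strain vector scaled to unit variance. The sign is
#' fixed so the eigengene correlates non-negatively with the module's
#' average standardized expression.
#'
#' @param expr An [expression_matrix()].
#' @param genes Gene identifiers of the module.
#' @return Named numeric vector (one value per strain) with attribute
#'   `var_explained`.
#' @export
module_eigengene <- function(expr, genes) {
  m <- unclass(expr)[genes, , drop = FALSE]
  if (ncol(m) < 3) stop("need at least 3 strains")
  z <- t(scale(t(m)))
  if (any(!is.finite(z)))
    stop("module contains constant or missing-riddled genes; cannot standardize")
  sv <- svd(z)
  me <- sv$v[, 1]
  avg <- colMeans(z)
  if (stats::cor(me, avg) < 0) me <- -me
  me <- me / stats::sd(me)
  names(me) <- colnames(m)
  attr(me, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  me
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`;
#' branches are cut at a static height (default `cut_height_frac` of the
#' maximum merge height) and clusters smaller than `min_size` genes are
#' assigned to the reserved `"grey"` bucket. Modules are labeled M1, M2,
#' ... in decreasing size order. Eigengenes, kME (gene-eigengene
#' correlation) and intramodular connectivity (sum of adjacency to
#' same-module genes) are computed for every non-grey module.
#'
#' @param tom A `TOMMatrix` from [tom_similarity()].
#' @param expr The [expression_matrix()] the TOM came from.
#' @param adj The matching adjacency (for intramodular connectivity).
#' @param min_size Minimum module size (default 30).
#' @param cut_height_frac Static cut height as a fraction of the maximum
#'   merge height (default 0.99).
#' @param cut_height Absolute cut height overriding `cut_height_frac`.
#' @return A `ModuleSet` list: `assignment` (gene -> label),
#'   `dendrogram` (hclust), `eigengenes` (strain x module matrix), `kme`
#'   (gene x module matrix), `k_in` (named vector), `sizes`.
#' @export
detect_modules <- function(tom, expr, adj, min_size = 30,
                           cut_height_frac = 0.99, cut_height = NULL) {
  genes <- rownames(tom)
  n <- length(genes)
  if (n < min_size) {
    warning("fewer genes than min_size: everything goes grey")
    assignment <- stats::setNames(rep(GREY, n), genes)
    return(structure(list(assignment = assignment, dendrogram = NULL,
                          eigengenes = NULL, kme = NULL,
                          k_in = stats::setNames(rep(0, n), genes),
                          sizes = integer(0)),
                     class = "ModuleSet"))
  }
  diss <- stats::as.dist(1 - tom)
  dend <- stats::hclust(diss, method = "average")
  h <- if (is.null(cut_height)) cut_height_frac * max(dend$height) else cut_height
  cl <- stats::cutree(dend, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  assignment <- stats::setNames(rep(GREY, n), genes)
  # label modules M1.. in decreasing size order
  keep <- keep[order(-sizes[keep])]
  for (i in seq_along(keep))
    assignment[cl == as.integer(keep[i])] <- sprintf("M%d", i)
  module_set(assignment, dend, expr, adj)
}

# assemble eigengenes / kME / k_in for a given assignment
module_set <- function(assignment, dend, expr, adj) {
  labels <- setdiff(unique(assignment), GREY)
  labels <- labels[order(as.integer(sub("^M", "", labels)))]
  genes <- names(assignment)
  mes <- NULL; kme <- NULL
  if (length(labels)) {
    mes <- sapply(labels, function(l)
      module_eigengene(expr, genes[assignment == l]))
    z <- unclass(expr)[genes, , drop = FALSE]
    kme <- suppressWarnings(stats::cor(t(z), mes, use = "pairwise.complete.obs"))
    colnames(kme) <- labels
  }
  a <- unclass(adj)
  diag(a) <- 0
  k_in <- vapply(genes, function(g) {
    same <- genes[assignment == assignment[g]]
    same <- setdiff(same, g)
    if (assignment[g] == GREY || !length(same)) 0 else sum(a[g, same])
  }, numeric(1))
  sizes <- vapply(labels, function(l) sum(assignment == l), integer(1))
  structure(list(assignment = assignment, dendrogram = dend,
                 eigengenes = mes, kme = kme, k_in = k_in, sizes = sizes),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat(sprintf("ModuleSet: %d modules over %d genes (%d grey)\n",
              length(x$sizes), length(x$assignment),
              sum(x$assignment == GREY)))
  if (length(x$sizes)) print(x$sizes)
  invisible(x)
}

#' Concatenate condition matrices into a combined expression matrix
#'
#' Condition matrices are joined column-wise over the supplied gene set,
#' with condition-tagged strain column names, producing the combined
#' dataset a cross-condition network is built from.
#'
#' @param exprs Named list of [expression_matrix()], one per condition.
#' @param genes Genes to retain (default: intersection across conditions).
#' @return An [expression_matrix()] with condition `"combined"`.
#' @export
combine_conditions <- function(exprs, genes = NULL) {
  if (is.null(genes))
    genes <- Reduce(intersect, lapply(exprs, rownames))
  mats <- lapply(names(exprs), function(cond) {
    m <- unclass(exprs[[cond]])[genes, , drop = FALSE]
    colnames(m) <- paste(cond, colnames(m), sep = ".")
    m
  })
  expression_matrix(do.call(cbind, mats), "combined")
}

#' Build the full co-expression network for one expression matrix
#'
#' Convenience wrapper: power scan, power selection, adjacency, TOM and
#' module detection in one call.
#'
#' @param expr An [expression_matrix()].
#' @param powers Candidate soft-threshold powers.
#' @param r2_target Scale-free fit target for [pick_power()].
#' @param beta Fixed power overriding the scan (optional).
#' @param min_size,cut_height_frac Passed to [detect_modules()].
#' @param signed Passed to [adjacency()].
#' @return List with `scan`, `beta`, `adjacency`, `tom`, `modules`.
#' @export
build_network <- function(expr, powers = 1:20, r2_target = 0.8, beta = NULL,
                          min_size = 30, cut_height_frac = 0.99,
                          signed = FALSE) {
  scan <- scan_powers(expr, powers = powers, signed = signed)
  if (is.null(beta)) beta <- pick_power(scan, r2_target)
  adj <- adjacency(expr, beta, signed = signed)
  tomm <- tom_similarity(adj)
  mods <- detect_modules(tomm, expr, adj, min_size = min_size,
                         cut_height_frac = cut_height_frac)
  list(scan = scan, beta = beta, adjacency = adj, tom = tomm, modules = mods)
}
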