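# Single-marker QTL/eQTL scanning (LRS/LOD) and SEM-based causal edge
# orienting: five single-anchor trivariate models relating one genotype,
# one gene (or eigengene) and one phenotype, chi-square model fit with one
# degree of freedom, and the LEO score log10(p_causal / p_best_alternative).

LRS_CAP <- 1e6

#' Single-marker regression
#'
#' Ordinary least squares of a trait on a biallelic marker code, reported
#' as a likelihood ratio statistic `LRS = n * ln(RSS0 / RSS1)` against the
#' intercept-only null, with `LOD = LRS / (2 ln 10)`. Strain means of an
#' RI panel are homozygous, so the 0/1 code enters as numeric with no
#' dominance term. A perfect fit (RSS1 = 0) is capped at a large finite
#' LRS and flagged so rankings stay total.
#'
#' @param trait Numeric trait vector.
#' @param marker Numeric 0/1 marker codes, same length.
#' @param min_n Minimum complete observations (default 8).
#' @return A `QTLResult` list: `LRS`, `LOD`, `effect` (additive effect of
#'   the 1 allele), `n`, `capped`, `skipped`.
#' @export
marker_regression <- function(trait, marker, min_n = 8) {
  ok <- !is.na(trait) & !is.na(marker)
  y <- trait[ok]; g <- marker[ok]
  n <- length(y)
  if (n < min_n || length(unique(g)) < 2) {
    return(structure(list(LRS = NA_real_, LOD = NA_real_, effect = NA_real_,
                          n = n, capped = FALSE, skipped = TRUE),
                     class = "QTLResult"))
  }
  rss0 <- sum((y - mean(y))^2)
  b <- stats::cov(y, g) / stats::var(g)
  a <- mean(y) - b * mean(g)
  rss1 <- sum((y - a - b * g)^2)
  capped <- FALSE
  if (rss1 <= 0 || rss0 <= 0) {
    lrs <- LRS_CAP
    capped <- TRUE
  } else {
    lrs <- n * log(rss0 / rss1)
    if (lrs > LRS_CAP) { lrs <- LRS_CAP; capped <- TRUE }
  }
  structure(list(LRS = lrs, LOD = lrs / (2 * log(10)), effect = b, n = n,
                 capped = capped, skipped = FALSE),
            class = "QTLResult")
}

#' QTL scan of one trait over all markers
#'
#' @param trait Named numeric vector (strain names) or a column of a
#'   [phenotype_table()].
#' @param geno A [genotype_matrix()].
#' @param min_n Passed to [marker_regression()].
#' @return Data frame: marker, chr, pos, LRS, LOD, effect, n.
#' @export
qtl_scan <- function(trait, geno, min_n = 8) {
  strains <- intersect(names(trait), colnames(geno$codes))
  rows <- lapply(seq_len(nrow(geno$codes)), function(i) {
    r <- marker_regression(trait[strains], geno$codes[i, strains], min_n)
    data.frame(marker = geno$map$marker[i], chr = geno$map$chr[i],
               pos = geno$map$pos[i], LRS = r$LRS, LOD = r$LOD,
               effect = r$effect, n = r$n, skipped = r$skipped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expression QTL scan
#'
#' Runs [marker_regression()] for every (gene, marker) pair and flags cis
#' pairs: marker on the same chromosome within `cis_window` of the gene
#' position. Genes without a supplied position are scanned trans-only and
#' flagged.
#'
#' @param expr An [expression_matrix()].
#' @param geno A [genotype_matrix()].
#' @param gene_positions Data frame (gene, chr, pos) in the same position
#'   unit as the genotype map; may omit genes.
#' @param cis_window Cis window half-width (default 10, in map units).
#' @param lrs_min Report only pairs with LRS at least this value
#'   (default 0: everything).
#' @return Data frame: gene, marker, LRS, LOD, cis, positioned.
#' @export
eqtl_scan <- function(expr, geno, gene_positions = NULL, cis_window = 10,
                      lrs_min = 0) {
  m <- unclass(expr)
  strains <- intersect(colnames(m), colnames(geno$codes))
  codes <- geno$codes[, strains, drop = FALSE]
  pos_lut <- NULL
  if (!is.null(gene_positions))
    pos_lut <- gene_positions[match(rownames(m), gene_positions$gene), ]
  rows <- list()
  for (gi in seq_len(nrow(m))) {
    y <- m[gi, strains]
    has_pos <- !is.null(pos_lut) && !is.na(pos_lut$chr[gi])
    for (mi in seq_len(nrow(codes))) {
      r <- marker_regression(y, codes[mi, ])
      if (r$skipped || is.na(r$LRS) || r$LRS < lrs_min) next
      cis <- has_pos &&
        geno$map$chr[mi] == pos_lut$chr[gi] &&
        abs(geno$map$pos[mi] - pos_lut$pos[gi]) <= cis_window
      rows[[length(rows) + 1L]] <- data.frame(
        gene = rownames(m)[gi], marker = geno$map$marker[mi],
        LRS = r$LRS, LOD = r$LOD, cis = cis, positioned = has_pos,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), marker = character(), LRS = numeric(),
               LOD = numeric(), cis = logical(), positioned = logical())
  rownames(out) <- NULL
  out
}

# model-implied correlation structure of the five single-anchor trivariate
# models, after standardizing (G, X, Y). Each model leaves one testable
# constraint on the correlation matrix; a and b are the free correlations.
#   1 G->X->Y : r_GX = a, r_XY = b, r_GY = a*b
#   2 G->Y->X : r_GY = a, r_XY = b, r_GX = a*b
#   3 X<-G->Y : r_GX = a, r_GY = b, r_XY = a*b
#   4 G->X<-Y : r_GX = a, r_XY = b, r_GY = 0
#   5 G->Y<-X : r_GY = a, r_XY = b, r_GX = 0
implied_cor <- function(model_id, a, b) {
  r <- diag(3)
  set <- function(i, j, v) { r[i, j] <<- v; r[j, i] <<- v }
  switch(model_id,
         { set(1, 2, a); set(2, 3, b); set(1, 3, a * b) },
         { set(1, 3, a); set(2, 3, b); set(1, 2, a * b) },
         { set(1, 2, a); set(1, 3, b); set(2, 3, a * b) },
         { set(1, 2, a); set(2, 3, b); set(1, 3, 0) },
         { set(1, 3, a); set(2, 3, b); set(1, 2, 0) },
         stop("model_id must be 1..5"))
  r
}

fml <- function(S, Sigma) {
  # maximum-likelihood discrepancy for covariance structure models
  det_s <- det(Sigma)
  if (!is.finite(det_s) || det_s <= 1e-12) return(Inf)
  as.numeric(log(det_s) - log(det(S)) + sum(diag(S %*% solve(Sigma))) - 3)
}

#' Fit one single-anchor SEM
#'
#' Variables are standardized; the model's free correlations are estimated
#' by minimizing the ML discrepancy `F_ML = ln|Sigma| - ln|S| +
#' tr(S Sigma^-1) - 3` over the model-implied correlation matrix. The fit
#' statistic is `chi2 = (n - 1) F_ML` with 1 degree of freedom (six
#' distinct moments against five free parameters once variances are
#' carried), p from chi-square(1).
#'
#' @param g,x,y Numeric vectors: marker codes, gene (or eigengene)
#'   expression, phenotype.
#' @param model_id Model 1-5 (see Details in [leo_score()]).
#' @return A `SEMModelFit` list: `model`, `par` (free correlations),
#'   `chisq`, `df`, `p`, `implied` (fitted correlation matrix), `n`.
#' @export
fit_sem_model <- function(g, x, y, model_id) {
  ok <- !is.na(g) & !is.na(x) & !is.na(y)
  if (sum(ok) < 10) stop("need at least 10 complete (g, x, y) triples")
  d <- scale(cbind(g = g[ok], x = x[ok], y = y[ok]))
  if (any(!is.finite(d))) stop("a variable has zero variance")
  n <- nrow(d)
  S <- stats::cor(d)
  if (!is.finite(det(S)) || det(S) <= 1e-12)
    stop("singular sample correlation matrix")
  start <- switch(model_id,
                  c(S[1, 2], S[2, 3]), c(S[1, 3], S[2, 3]),
                  c(S[1, 2], S[1, 3]), c(S[1, 2], S[2, 3]),
                  c(S[1, 3], S[2, 3]))
  obj <- function(par) {
    if (any(abs(par) >= 0.999)) return(1e10)
    fml(S, implied_cor(model_id, par[1], par[2]))
  }
  opt <- stats::optim(pmin(pmax(start, -0.99), 0.99), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  if (!is.finite(opt$value))
    stop("SEM fit did not converge for model ", model_id)
  chisq <- max((n - 1) * opt$value, 0)
  structure(list(model = model_id, par = opt$par, chisq = chisq, df = 1L,
                 p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 implied = implied_cor(model_id, opt$par[1], opt$par[2]),
                 n = n),
            class = "SEMModelFit")
}

#' LEO score over the five single-anchor model fits
#'
#' The Local Edge Orienting score for the forward orientation:
#' `LEO = log10(p1 / max(p2, ..., p5))`, where p1 is the model p-value of
#' the causal chain genotype -> gene -> phenotype and the denominator is
#' the best-fitting alternative (genotype -> phenotype -> gene; gene <-
#' genotype -> phenotype; genotype -> gene <- phenotype; genotype ->
#' phenotype <- gene). A score of 1 means the causal chain fits ten times
#' better than any competitor; the conventional evidence threshold is 0.5
#' (a 10^0.5 ~ 3.2-fold p-ratio).
#'
#' @param fits List of five `SEMModelFit` objects, models 1-5 in order.
#' @param threshold Pass threshold on the score (default 0.5).
#' @return A `LEOResult` list: `p` (five p-values), `leo`, `passes`,
#'   `floored` (TRUE when a zero p-value was floored at the smallest
#'   representable double).
#' @export
leo_score <- function(fits, threshold = 0.5) {
  stopifnot(length(fits) == 5)
  p <- vapply(fits, `[[`, numeric(1), "p")
  floored <- any(p == 0)
  p_use <- pmax(p, .Machine$double.xmin)
  leo <- log10(p_use[1] / max(p_use[2:5]))
  structure(list(p = p, leo = leo, passes = leo >= threshold,
                 floored = floored, threshold = threshold),
            class = "LEOResult")
}

#' Orient one (marker, gene, phenotype) triplet
#'
#' Fits all five single-anchor models and returns the LEO result with the
#' fits attached.
#'
#' @param g,x,y Marker codes, gene expression, phenotype (same strains).
#' @param threshold LEO pass threshold.
#' @return A `LEOResult` with a `fits` element.
#' @export
orient_edge <- function(g, x, y, threshold = 0.5) {
  fits <- lapply(1:5, function(mid) fit_sem_model(g, x, y, mid))
  out <- leo_score(fits, threshold)
  out$fits <- fits
  out
}

#' Screen module genes for causal links to phenotypes
#'
#' For a fixed anchor marker (typically the phenotype's peak-LRS marker),
#' every (gene, phenotype) pair is oriented with [orient_edge()]; each
#' gene's score is its maximum LEO over the phenotypes, and genes are
#' ranked by that score with a flag at the pass threshold.
#'
#' @param marker Numeric 0/1 codes of the anchor marker (named by strain).
#' @param expr Expression submatrix of the module's genes (genes x
#'   strains).
#' @param phen A [phenotype_table()] (may have one or more traits).
#' @param threshold LEO pass threshold (default 0.5).
#' @param kme_floor Optional kME floor: genes below it are not screened
#'   (requires `kme`, a named vector).
#' @param kme Named vector of kME values for the module's genes.
#' @return Data frame ranked by descending max LEO: gene, best phenotype,
#'   leo, p1..p5 of the best pair, passes.
#' @export
screen_causal_genes <- function(marker, expr, phen, threshold = 0.5,
                                kme_floor = NULL, kme = NULL) {
  m <- unclass(expr)
  if (!is.null(kme_floor) && !is.null(kme))
    m <- m[rownames(m) %in% names(kme)[abs(kme) >= kme_floor], , drop = FALSE]
  traits <- colnames(phen)
  if (!length(traits) || !nrow(m))
    return(data.frame(gene = character(), phenotype = character(),
                      leo = numeric(), passes = logical()))
  strains <- Reduce(intersect, list(names(marker), colnames(m), rownames(phen)))
  rows <- lapply(rownames(m), function(gene) {
    best <- NULL
    for (tr in traits) {
      res <- tryCatch(
        orient_edge(marker[strains], m[gene, strains], phen[strains, tr],
                    threshold),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.null(best) || res$leo > best$leo) {
        best <- res; best$phenotype <- tr
      }
    }
    if (is.null(best)) return(NULL)
    data.frame(gene = gene, phenotype = best$phenotype, leo = best$leo,
               p1 = best$p[1], p2 = best$p[2], p3 = best$p[3],
               p4 = best$p[4], p5 = best$p[5], passes = best$passes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(), phenotype = character(),
                      leo = numeric(), passes = logical()))
  out <- out[order(-out$leo), , drop = FALSE]
  rownames(out) <- NULL
  out
}
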