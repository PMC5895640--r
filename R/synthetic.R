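# Synthetic BXD-like study generator. Emulates: ~41 strains measured as
# strain means under four conditions (NOS control, RSS stress, NOE ethanol,
# RSE stress+ethanol), planted co-expression modules realizing the four
# condition-response patterns, a two-population (variable/invariable) CV
# structure, RI-style genotypes with recombination, phenotypes causally wired
# through genotype -> module -> trait chains, and a PPI layer partially
# overlapping the planted modules. Full ground truth is returned for
# recovery testing.

#' Describe a synthetic study design
#'
#' Default values emulate the scale of a BXD strain-mean microarray study:
#' 41 strains, four conditions, a few thousand genes of which a minority are
#' genuinely variable across strains, and a sparse RI genotype map.
#'
#' @param n_strains Number of RI strains (default 41).
#' @param n_genes Total genes (default 3000).
#' @param n_markers Genotype markers, spread evenly over `n_chr`
#'   chromosomes (default 200 over 5).
#' @param n_chr Number of chromosomes.
#' @param chr_length_cM Chromosome length in centimorgans.
#' @param modules Data frame with columns `size`, `pattern` (1-4) and `rho`
#'   (within-module correlation); defaults to eight modules, two per
#'   pattern.
#' @param delta Condition-shift magnitude in log2 units (default 0.5).
#' @param cv_means,cv_sds,cv_weights Parameters of the two-component CV
#'   mixture (invariable component first). Background genes draw their CV
#'   from the full mixture; planted module genes are always variable.
#' @param grand_mean Grand mean expression on the log2 scale (default 9.0,
#'   so the conventional "mean >= 8" floor separates the designated
#'   low-expression genes from the rest).
#' @param low_mean_frac Fraction of invariable background genes assigned a
#'   grand mean below 8 to exercise the mean filter.
#' @param triplets Data frame of causal triplets with columns `marker`
#'   (index), `module` (index), `phenotype` (trait name), `model` (true
#'   single-anchor model id 1-5), `b1` (marker -> eigengene effect), `b2`
#'   (eigengene -> phenotype effect), `sd_y` (phenotype noise sd). The
#'   default plants two forward-causal (model 1) chains.
#' @param n_noise_traits Pure-noise traits added as negative controls.
#' @param seed Integer seed; the whole study is a deterministic function of
#'   the design including this seed.
#' @return A `SyntheticDesign` list.
#' @export
synthetic_design <- function(n_strains = 41,
                             n_genes = 3000,
                             n_markers = 200,
                             n_chr = 5,
                             chr_length_cM = 100,
                             modules = NULL,
                             delta = 0.5,
                             cv_means = c(0.05, 0.15),
                             cv_sds = c(0.01, 0.03),
                             cv_weights = c(0.7, 0.3),
                             grand_mean = 9.0,
                             low_mean_frac = 0.15,
                             triplets = NULL,
                             n_noise_traits = 2,
                             seed = 1L) {
  if (is.null(modules)) {
    modules <- data.frame(
      size = c(150L, 120L, 100L, 90L, 80L, 70L, 60L, 50L),
      pattern = c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L),
      rho = rep(0.7, 8)
    )
  }
  if (sum(modules$size) > n_genes)
    stop("module sizes exceed n_genes")
  if (any(modules$rho <= 0 | modules$rho >= 1))
    stop("within-module correlation rho must lie in (0, 1)")
  if (abs(sum(cv_weights) - 1) > 1e-8 || any(cv_weights <= 0))
    stop("cv_weights must be positive and sum to 1")
  if (is.null(triplets)) {
    # two forward-causal chains anchored at well-separated markers; fall
    # back gracefully for designs with few modules or markers
    mk_idx <- unique(pmax(1L, as.integer(round(c(0.1, 0.5) * n_markers))))
    mod_idx <- unique(c(1L, min(3L, nrow(modules))))
    k <- min(length(mk_idx), length(mod_idx))
    triplets <- data.frame(
      marker = mk_idx[seq_len(k)],
      module = mod_idx[seq_len(k)],
      phenotype = c("ACTCNT_total_RSS", "OPEN_0_5_RSE")[seq_len(k)],
      model = 1L,
      b1 = 0.8, b2 = 0.8, sd_y = 1,
      stringsAsFactors = FALSE
    )
  }
  if (nrow(triplets)) {
    if (any(triplets$module < 1 | triplets$module > nrow(modules)))
      stop("triplet references unknown module")
    if (any(triplets$marker < 1 | triplets$marker > n_markers))
      stop("triplet references unknown marker")
    if (any(!triplets$model %in% 1:5))
      stop("triplet model id must be in 1..5")
    if (any(!is.finite(triplets$b1)) || any(!is.finite(triplets$b2)))
      stop("triplet effects must be finite")
  }
  structure(list(
    n_strains = n_strains, n_genes = n_genes, n_markers = n_markers,
    n_chr = n_chr, chr_length_cM = chr_length_cM, modules = modules,
    delta = delta, cv_means = cv_means, cv_sds = cv_sds,
    cv_weights = cv_weights, grand_mean = grand_mean,
    low_mean_frac = low_mean_frac, triplets = triplets,
    n_noise_traits = n_noise_traits, seed = as.integer(seed)
  ), class = "SyntheticDesign")
}

# condition shifts (log2 units, relative to NOS) realizing the four
# response patterns: 1 NOE up / RSE restore; 2 NOE down / RSE rescue;
# 3 RSS+NOE up / RSE amplify; 4 RSS up / NOE+RSE reduce
pattern_shifts <- function(pattern, delta) {
  switch(pattern,
         `1` = c(NOS = 0, RSS = 0, NOE = delta, RSE = 0),
         `2` = c(NOS = 0, RSS = 0, NOE = -delta, RSE = 0),
         `3` = c(NOS = 0, RSS = delta, NOE = delta, RSE = 2 * delta),
         `4` = c(NOS = 0, RSS = delta, NOE = -delta, RSE = -delta),
         stop("unknown pattern id: ", pattern))
}

strain_ids <- function(n) sprintf("BXD%03d", seq_len(n))
gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate RI-strain genotypes
#'
#' Each strain is an independent Markov chain along each chromosome: the
#' first marker is Bernoulli(0.5), and adjacent markers recombine with the
#' Haldane probability r = (1 - exp(-2d/100)) / 2 for map distance d cM.
#'
#' @param design A [synthetic_design()].
#' @return A [genotype_matrix()] with markers evenly spaced over the
#'   design's chromosomes.
#' @export
generate_genotypes <- function(design) {
  set.seed(design$seed + 101L)
  per_chr <- ceiling(design$n_markers / design$n_chr)
  chr <- rep(seq_len(design$n_chr), each = per_chr)[seq_len(design$n_markers)]
  pos <- unlist(lapply(split(chr, chr), function(ch) {
    k <- length(ch)
    seq(0, design$chr_length_cM, length.out = max(k, 2))[seq_len(k)]
  }), use.names = FALSE)
  map <- data.frame(marker = sprintf("rs_c%d_%03d", chr,
                                     stats::ave(chr, chr, FUN = seq_along)),
                    chr = as.character(chr), pos = pos,
                    stringsAsFactors = FALSE)
  codes <- matrix(NA_integer_, design$n_markers, design$n_strains,
                  dimnames = list(map$marker, strain_ids(design$n_strains)))
  for (s in seq_len(design$n_strains)) {
    for (ch in unique(chr)) {
      idx <- which(chr == ch)
      g <- integer(length(idx))
      g[1] <- stats::rbinom(1, 1, 0.5)
      if (length(idx) > 1) {
        d <- diff(pos[idx])
        r <- (1 - exp(-2 * d / 100)) / 2
        flips <- stats::rbinom(length(d), 1, r)
        for (k in seq_along(d)) g[k + 1] <- if (flips[k]) 1L - g[k] else g[k]
      }
      codes[idx, s] <- g
    }
  }
  genotype_matrix(codes, map, pos_unit = "cM")
}

# Build the latent strain factor of every module plus, for causal modules,
# the phenotype vector implied by the triplet's true model. Returns
# factors (module x strain), phenotype vectors, and exogenous pieces.
build_causal_system <- function(design, geno) {
  n <- design$n_strains
  n_mod <- nrow(design$modules)
  factors <- matrix(stats::rnorm(n_mod * n), n_mod, n,
                    dimnames = list(sprintf("mod%d", seq_len(n_mod)),
                                    colnames(geno$codes)))
  phen <- list()
  tr <- design$triplets
  if (nrow(tr)) for (k in seq_len(nrow(tr))) {
    G <- geno$codes[tr$marker[k], ]
    m <- tr$module[k]
    b1 <- tr$b1[k]; b2 <- tr$b2[k]; sdy <- tr$sd_y[k]
    z <- factors[m, ]               # exogenous module noise
    y <- switch(tr$model[k],
      { f <- z + b1 * G; factors[m, ] <- f;  b2 * f + stats::rnorm(n, sd = sdy) },
      { y <- b1 * G + stats::rnorm(n, sd = sdy); factors[m, ] <- z + b2 * y; y },
      { f <- z + b1 * G; factors[m, ] <- f;  b2 * G + stats::rnorm(n, sd = sdy) },
      { y <- stats::rnorm(n, sd = sdy); factors[m, ] <- z + b1 * G + b2 * y; y },
      { y <- b1 * G + b2 * z + stats::rnorm(n, sd = sdy); factors[m, ] <- z; y })
    phen[[tr$phenotype[k]]] <- y
  }
  list(factors = factors, phenotypes = phen)
}

#' Simulate four-condition expression with planted modules
#'
#' Each planted module carries a latent strain factor shared across the
#' four conditions (a strain/genetic effect); member genes load on it with
#' within-module correlation `rho`, and the module's per-condition means
#' follow its response pattern. Background genes are independent noise.
#' Per-gene total variability follows the two-component CV mixture, and a
#' designated fraction of invariable background genes is given a grand mean
#' below 8 so the conventional mean filter has something to remove.
#'
#' @param design A [synthetic_design()].
#' @param geno Genotypes from [generate_genotypes()] (causal modules add
#'   `b1 * code` of their marker to the latent factor).
#' @return List with one [expression_matrix()] per condition plus a
#'   `truth` record (gene module labels, per-module patterns, per-gene
#'   variable and low-mean flags, latent factors, phenotype vectors for the
#'   causal triplets).
#' @export
generate_expression <- function(design, geno) {
  set.seed(design$seed + 202L)
  n <- design$n_strains
  p <- design$n_genes
  mods <- design$modules
  genes <- gene_ids(p)
  strains <- colnames(geno$codes)

  module_of <- rep("bg", p)
  idx <- 0L
  for (m in seq_len(nrow(mods))) {
    module_of[idx + seq_len(mods$size[m])] <- sprintf("mod%d", m)
    idx <- idx + mods$size[m]
  }
  names(module_of) <- genes

  # per-gene CV: module genes from the variable component, background from
  # the full mixture
  is_module <- module_of != "bg"
  comp <- integer(p)
  comp[is_module] <- 2L
  comp[!is_module] <- 1L + stats::rbinom(sum(!is_module), 1, design$cv_weights[2])
  cv <- stats::rnorm(p, design$cv_means[comp], design$cv_sds[comp])
  cv <- pmax(cv, 0.01)
  variable_flag <- comp == 2L

  # grand means: low-expression fraction drawn from the invariable
  # background so the mean filter and the CV decision stay orthogonal
  mu <- stats::runif(p, design$grand_mean - 0.5, design$grand_mean + 1.5)
  invariable_bg <- which(!is_module & !variable_flag)
  n_low <- round(design$low_mean_frac * length(invariable_bg))
  low_idx <- sample(invariable_bg, n_low)
  mu[low_idx] <- stats::runif(n_low, 6.5, 7.8)
  low_flag <- logical(p); low_flag[low_idx] <- TRUE

  sys <- build_causal_system(design, geno)
  factors <- sys$factors
  # factors for causal modules are not exactly unit sd; rescale the loading
  # so member genes keep their target total sd
  f_sd <- apply(factors, 1, stats::sd)

  sd_g <- cv * mu
  out <- list()
  for (cond in CONDITIONS) {
    vals <- matrix(NA_real_, p, n, dimnames = list(genes, strains))
    for (g in seq_len(p)) {
      m <- module_of[g]
      if (m == "bg") {
        vals[g, ] <- mu[g] + stats::rnorm(n, sd = sd_g[g])
      } else {
        mi <- as.integer(sub("mod", "", m))
        rho <- mods$rho[mi]
        shift <- pattern_shifts(mods$pattern[mi], design$delta)[cond]
        f <- factors[mi, ] / f_sd[mi]
        vals[g, ] <- mu[g] + shift + sd_g[g] *
          (sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n))
      }
    }
    out[[cond]] <- expression_matrix(vals, cond)
  }
  truth <- list(module = module_of,
                pattern = stats::setNames(mods$pattern,
                                          sprintf("mod%d", seq_len(nrow(mods)))),
                variable = stats::setNames(variable_flag, genes),
                low_mean = stats::setNames(low_flag, genes),
                factors = factors,
                phenotype_vectors = sys$phenotypes,
                triplets = design$triplets,
                balanced_panels = TRUE)
  list(expression = out, truth = truth)
}

#' Assemble phenotypes from the causal system
#'
#' Causal traits were generated jointly with the module factors according
#' to each triplet's true single-anchor model (1: genotype -> gene ->
#' phenotype; 2: genotype -> phenotype -> gene; 3: gene <- genotype ->
#' phenotype; 4: genotype -> gene <- phenotype; 5: genotype -> phenotype <-
#' gene). Pure-noise traits are appended as negative controls.
#'
#' @param design A [synthetic_design()].
#' @param geno Genotypes (for strain names).
#' @param truth Truth record from [generate_expression()].
#' @return A [phenotype_table()].
#' @export
generate_phenotypes <- function(design, geno, truth) {
  set.seed(design$seed + 303L)
  n <- design$n_strains
  cols <- truth$phenotype_vectors
  if (design$n_noise_traits > 0) {
    for (k in seq_len(design$n_noise_traits))
      cols[[sprintf("NOISE%d", k)]] <- stats::rnorm(n)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- colnames(geno$codes)
  phenotype_table(m)
}

#' Simulate a partially module-overlapping PPI layer
#'
#' A configurable fraction of within-module gene pairs receives a
#' high-confidence score (> 700), planting subnetwork signal; random
#' cross-gene edges with scores uniform on \[150, 1000\] are added as
#' background. The planted edge set is recorded for truth checks.
#'
#' @param design A [synthetic_design()].
#' @param truth Truth record from [generate_expression()].
#' @param planted_frac Fraction of within-module pairs planted (default 0.15).
#' @param n_random Number of random background edges (default `4 * n_genes`).
#' @return List with `ppi` (a [ppi_edgelist()]) and `planted` (data frame
#'   of the planted within-module edges).
#' @export
generate_ppi <- function(design, truth, planted_frac = 0.15,
                         n_random = 4L * design$n_genes) {
  set.seed(design$seed + 404L)
  genes <- names(truth$module)
  planted <- list()
  for (m in setdiff(unique(truth$module), "bg")) {
    g <- genes[truth$module == m]
    pairs <- utils::combn(g, 2)
    keep <- which(stats::runif(ncol(pairs)) < planted_frac)
    if (length(keep))
      planted[[m]] <- data.frame(protein1 = pairs[1, keep],
                                 protein2 = pairs[2, keep],
                                 combined_score = sample(701:1000, length(keep),
                                                         replace = TRUE),
                                 module = m, stringsAsFactors = FALSE)
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(protein1 = character(), protein2 = character(),
               combined_score = integer(), module = character())
  rownames(planted) <- NULL
  p1 <- sample(genes, n_random, replace = TRUE)
  p2 <- sample(genes, n_random, replace = TRUE)
  ok <- p1 != p2
  rand_scores <- sample(150:1000, sum(ok), replace = TRUE)
  ppi <- ppi_edgelist(c(planted$protein1, p1[ok]),
                      c(planted$protein2, p2[ok]),
                      c(planted$combined_score, rand_scores))
  list(ppi = ppi, planted = planted)
}

#' Simulate a full study with ground truth
#'
#' Runs the genotype, expression, phenotype and PPI generators in order and
#' bundles their outputs with the truth record.
#'
#' @param design A [synthetic_design()].
#' @param ppi_planted_frac Passed to [generate_ppi()].
#' @return List with `genotypes`, `expression` (named list of four
#'   [expression_matrix()]), `phenotypes`, `ppi`, `truth`, `design`.
#' @export
simulate_study <- function(design = synthetic_design(), ppi_planted_frac = 0.15) {
  geno <- generate_genotypes(design)
  ge <- generate_expression(design, geno)
  phen <- generate_phenotypes(design, geno, ge$truth)
  ppi <- generate_ppi(design, ge$truth, planted_frac = ppi_planted_frac)
  truth <- ge$truth
  truth$planted_ppi <- ppi$planted
  list(genotypes = geno, expression = ge$expression, phenotypes = phen,
       ppi = ppi$ppi, truth = truth, design = design)
}
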