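# Independent oracles used to check the implementation on small instances.

# triple-loop TOM: literal evaluation of
# TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric
# probabilities no larger than the observed one, at fixed margins
fisher_oracle <- function(both, mod_only, set_only, neither) {
  m <- both + set_only          # set size
  n <- mod_only + neither       # non-set size
  k <- both + mod_only          # module size
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(both, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# one-way ANOVA from explicit sums of squares
anova_oracle <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

# union-find connected components over an edge list
components_oracle <- function(from, to) {
  nodes <- unique(c(from, to))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  split(nodes, roots)
}

# brute-force grid minimizer for the single-anchor SEM discrepancy
sem_grid_oracle <- function(S, model_id, grid = seq(-0.98, 0.98, by = 0.02)) {
  ns <- asNamespace("stressnet")
  implied <- get("implied_cor", ns)
  fml <- get("fml", ns)
  best <- Inf
  for (a in grid) for (b in grid) {
    v <- fml(S, implied(model_id, a, b))
    if (is.finite(v) && v < best) best <- v
  }
  best
}

# simulate one standardized (g, x, y) triple under a true model
simulate_triplet <- function(model_id, n = 200, b1 = 0.8, b2 = 0.8) {
  g <- stats::rbinom(n, 1, 0.5)
  e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
  switch(model_id,
         { x <- b1 * g + e1; y <- b2 * x + e2; list(g = g, x = x, y = y) },
         { y <- b1 * g + e1; x <- b2 * y + e2; list(g = g, x = x, y = y) },
         { x <- b1 * g + e1; y <- b2 * g + e2; list(g = g, x = x, y = y) },
         { y <- stats::rnorm(n); x <- b1 * g + b2 * y + e1; list(g = g, x = x, y = y) },
         { x <- stats::rnorm(n); y <- b1 * g + b2 * x + e1; list(g = g, x = x, y = y) })
}

# adjusted Rand index between two label vectors
ari_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# small expression fixture: two planted blocks plus noise genes
block_expression <- function(n_per_block = 10, n_noise = 10, n_strains = 30,
                             rho = 0.9, seed = 1) {
  set.seed(seed)
  f1 <- rnorm(n_strains); f2 <- rnorm(n_strains)
  make <- function(f, n) t(sapply(seq_len(n), function(i)
    sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_strains)))
  m <- rbind(make(f1, n_per_block), make(f2, n_per_block),
             matrix(rnorm(n_noise * n_strains), n_noise))
  m <- m + 9
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%02d", seq_len(n_strains))
  expression_matrix(m, "NOS")
}

# minimal design for loops that only need one planted module
tiny_design <- function(seed = 1, triplets = NULL, ...) {
  if (is.null(triplets))
    triplets <- data.frame(marker = 3L, module = 1L, phenotype = "T_RSS",
                           model = 1L, b1 = 0.8, b2 = 0.8, sd_y = 1)
  synthetic_design(
    n_strains = 41, n_genes = 120, n_markers = 10, n_chr = 1,
    modules = data.frame(size = 30, pattern = 1, rho = 0.7),
    triplets = triplets, seed = seed, ...)
}

# small fast study design for tests that only need qualitative structure
small_design <- function(seed = 1, triplets = NULL, ...) {
  if (is.null(triplets))
    triplets <- data.frame(marker = c(10L, 35L), module = c(1L, 3L),
                           phenotype = c("ACT_RSS", "OPEN_RSE"),
                           model = c(1L, 1L), b1 = c(0.8, 0.8),
                           b2 = c(0.8, 0.8), sd_y = c(1, 1))
  synthetic_design(
    n_strains = 41, n_genes = 600, n_markers = 50, n_chr = 2,
    modules = data.frame(size = c(60, 50, 50, 40),
                         pattern = c(1, 2, 3, 4), rho = rep(0.7, 4)),
    triplets = triplets, seed = seed, ...)
}
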