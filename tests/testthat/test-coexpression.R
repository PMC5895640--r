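test_that("adjacency is |cor|^beta with unit diagonal", {
  set.seed(1)
  n <- 20
  f <- rnorm(n)
  m <- rbind(g1 = f + rnorm(n, sd = 0.3), g2 = -f + rnorm(n, sd = 0.3),
             g3 = rnorm(n))
  colnames(m) <- paste0("s", 1:n)
  expr <- expression_matrix(m, "NOS")
  r <- cor(m["g1", ], m["g2", ])
  a2 <- adjacency(expr, 2)
  expect_equal(a2["g1", "g2"], abs(r)^2, tolerance = 1e-12)
  expect_equal(unname(diag(a2)), rep(1, 3))
  a1 <- adjacency(expr, 1)
  expect_equal(a1["g1", "g2"], abs(r), tolerance = 1e-12)
  # monotone in beta for |cor| < 1
  a5 <- adjacency(expr, 5)
  expect_lt(a5["g1", "g3"], a1["g1", "g3"])
  # perfectly correlated genes keep adjacency 1 at any beta
  m2 <- rbind(a = f, b = 2 * f + 1, c = rnorm(n))
  colnames(m2) <- paste0("s", 1:n)
  expect_equal(adjacency(expression_matrix(m2, "NOS"), 7)["a", "b"], 1)
})

test_that("zero-variance genes get zeroed correlations with a warning", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(a <- adjacency(expression_matrix(m, "NOS"), 2),
                 "zero-variance")
  expect_equal(a["a", "b"], 0)
  expect_equal(a["b", "b"], 1)
})

test_that("TOM matches the literal formula: hand case and triple-loop oracle", {
  # 2 genes, no shared neighbors: TOM12 = a12 / (min(k) + 1 - a12) = 0.5
  a <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(tom_similarity(a)["x", "y"], 0.5)

  # complete graph with all unit adjacency: all TOM = 1
  ones <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  expect_true(all(abs(tom_similarity(ones) - 1) < 1e-12))

  # random instances vs brute force, n <= 12
  set.seed(42)
  for (n in c(3, 5, 8, 12)) {
    for (rep in 1:5) {
      a <- matrix(runif(n * n), n, n)
      a <- (a + t(a)) / 2
      diag(a) <- 1
      dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
      got <- tom_similarity(a)
      expect_equal(unname(unclass(got)), tom_oracle(a), tolerance = 1e-12)
    }
  }
})

test_that("power scan: decreasing mean connectivity, scale-free fit behavior", {
  st <- simulate_study(small_design(seed = 3))
  sel <- {
    prof <- compute_cv(st$expression$NOS)
    fit <- fit_cv_mixture(prof$cv, seed = 1)
    select_variable_genes(prof, fit, condition = "NOS")
  }
  expr <- st$expression$NOS[intersect(sel$genes, rownames(st$expression$NOS)), ]
  scan <- scan_powers(expr, powers = 1:12)
  expect_true(all(diff(scan$mean_k) < 0))      # strictly decreasing in beta
  expect_gt(max(scan$sft_r2[scan$power >= 3], na.rm = TRUE),
            scan$sft_r2[scan$power == 1])

  cm <- matrix(8, 30, 10, dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  expect_error(suppressWarnings(scan_powers(expression_matrix(cm, "NOS"))),
               "constant")
})

test_that("pick_power takes the first crossing, with a guarded fallback", {
  scan <- data.frame(power = c(3, 6, 9, 12), sft_r2 = c(0.2, 0.5, 0.85, 0.9),
                     mean_k = c(50, 20, 8, 3))
  expect_identical(pick_power(scan, 0.8), 9)
  expect_identical(pick_power(scan, 0.5), 6)
  expect_warning(b <- pick_power(scan, 0.95), "no power")
  expect_identical(b, 12)
  # chosen power weakly decreases as the target decreases
  targets <- c(0.9, 0.85, 0.5, 0.2)
  chosen <- vapply(targets, function(t) pick_power(scan, t), 0)
  expect_true(all(diff(chosen) <= 0))
})

test_that("module eigengene is the first PC with the fixed sign rule", {
  set.seed(5)
  n <- 10
  f <- rnorm(n)
  m <- t(sapply(1:5, function(i) 0.9 * f + rnorm(n, sd = 0.3))) + 9
  rownames(m) <- paste0("g", 1:5)
  colnames(m) <- paste0("s", 1:n)
  expr <- expression_matrix(m, "NOS")
  me <- module_eigengene(expr, rownames(m))
  expect_equal(sd(me), 1)
  z <- t(scale(t(m)))
  expect_gte(cor(me, colMeans(z)), 0)
  # variance explained matches a dense eigendecomposition oracle
  ev <- eigen(crossprod(t(z)) / 1)$values
  expect_equal(attr(me, "var_explained"), ev[1] / sum(ev), tolerance = 1e-10)

  # single-gene module: eigengene is the standardized gene
  me1 <- module_eigengene(expr, "g1")
  expect_equal(abs(cor(me1, m["g1", ])), 1, tolerance = 1e-12)
  # identical genes: correlation 1 with each member
  m_id <- rbind(a = f, b = f, c = f) + 9
  colnames(m_id) <- paste0("s", 1:n)
  me_id <- module_eigengene(expression_matrix(m_id, "NOS"), c("a", "b", "c"))
  expect_equal(cor(me_id, f), 1, tolerance = 1e-10)
})

test_that("module detection recovers planted blocks and buckets the rest grey", {
  expr <- block_expression(n_per_block = 35, n_noise = 40, n_strains = 40,
                           rho = 0.9, seed = 2)
  adj <- adjacency(expr, 6)
  tm <- tom_similarity(adj)
  mods <- detect_modules(tm, expr, adj, min_size = 30)
  expect_length(mods$sizes, 2)
  # detected modules coincide with the planted blocks
  block <- rep(c("b1", "b2", "noise"), c(35, 35, 40))
  names(block) <- rownames(expr)
  planted <- names(block)[block != "noise"]
  expect_equal(ari_index(mods$assignment[planted], block[planted]), 1)
  expect_gte(mean(mods$assignment[block == "noise"] == "grey"), 0.9)
  # labels are size-ordered M1, M2
  expect_identical(names(mods$sizes), c("M1", "M2"))
  expect_true(all(diff(mods$sizes) <= 0))

  # min size above the gene count sends everything grey
  mods_all_grey <- suppressWarnings(
    detect_modules(tm, expr, adj, min_size = nrow(expr) + 1))
  expect_true(all(mods_all_grey$assignment == "grey"))
})

test_that("gene order permutation leaves the partition invariant", {
  expr <- block_expression(n_per_block = 20, n_noise = 20, n_strains = 35,
                           seed = 3)
  build <- function(e) {
    a <- adjacency(e, 6)
    detect_modules(tom_similarity(a), e, a, min_size = 15)$assignment
  }
  m1 <- build(expr)
  perm <- sample(nrow(expr))
  expr_p <- expression_matrix(unclass(expr)[perm, ], "NOS")
  m2 <- build(expr_p)
  expect_equal(ari_index(m1[names(m2)], m2), 1)
})

test_that("kME is highest for a gene's own module on synthetic data", {
  st <- simulate_study(small_design(seed = 8))
  sets <- lapply(names(st$expression), function(cd) {
    p <- compute_cv(st$expression[[cd]])
    f <- fit_cv_mixture(p$cv, seed = 1)
    select_variable_genes(p, f, condition = cd)
  })
  comb <- combine_conditions(st$expression, merge_conditions(sets)$genes)
  nw <- suppressWarnings(build_network(comb, min_size = 20))
  asg <- nw$modules$assignment
  planted <- names(asg)[st$truth$module[names(asg)] != "bg" & asg != "grey"]
  own_best <- vapply(planted, function(g) {
    k <- abs(nw$modules$kme[g, ])
    names(which.max(k)) == asg[[g]]
  }, NA)
  expect_gte(mean(own_best), 0.9)
})

test_that("condition matrices concatenate column-wise with tagged strains", {
  st <- simulate_study(tiny_design(seed = 4))
  comb <- combine_conditions(st$expression, rownames(st$expression$NOS)[1:50])
  expect_identical(nrow(comb), 50L)
  expect_identical(ncol(comb), 4L * 41L)
  expect_true(all(grepl("^(NOS|RSS|NOE|RSE)\\.", colnames(comb))))
  expect_identical(condition_of(comb), "combined")
})
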