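test_that("generated outputs are a deterministic function of design + seed", {
  d <- small_design(seed = 11)
  s1 <- simulate_study(d)
  s2 <- simulate_study(d)
  expect_identical(s1$genotypes$codes, s2$genotypes$codes)
  expect_identical(unclass(s1$expression$RSE), unclass(s2$expression$RSE))
  expect_identical(unclass(s1$phenotypes), unclass(s2$phenotypes))
  expect_identical(s1$ppi, s2$ppi)
})

test_that("genotypes follow a Haldane recombination chain", {
  # single marker: allele frequency ~ Bernoulli(0.5)
  d1 <- synthetic_design(n_strains = 400, n_genes = 10, n_markers = 1,
                         n_chr = 1,
                         modules = data.frame(size = 5, pattern = 1, rho = 0.5),
                         triplets = data.frame(marker = integer(),
                                               module = integer(),
                                               phenotype = character(),
                                               model = integer(), b1 = numeric(),
                                               b2 = numeric(), sd_y = numeric()),
                         seed = 3)
  g <- generate_genotypes(d1)
  freq <- mean(g$codes)
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / 400))

  # zero map distance: adjacent markers identical
  d0 <- synthetic_design(n_strains = 50, n_markers = 4, n_chr = 1,
                         chr_length_cM = 0, seed = 5)
  g0 <- generate_genotypes(d0)
  expect_true(all(g0$codes[1, ] == g0$codes[2, ]))
  expect_true(all(g0$codes[1, ] == g0$codes[4, ]))

  # marker correlation decays as 1 - 2r = exp(-2d/100)
  dd <- synthetic_design(n_strains = 10000, n_markers = 5, n_chr = 1,
                         chr_length_cM = 80, seed = 9)
  gg <- generate_genotypes(dd)
  pos <- gg$map$pos
  for (j in 2:5) {
    d_cm <- pos[j] - pos[1]
    expected <- exp(-2 * d_cm / 100)
    observed <- cor(gg$codes[1, ], gg$codes[j, ])
    expect_lt(abs(observed - expected), 0.03)
  }
})

test_that("planted modules realize their correlation and pattern structure", {
  # rho -> 1 limit: within-module pairs nearly perfectly correlated
  d <- synthetic_design(n_strains = 41, n_genes = 100, n_markers = 10,
                        n_chr = 1,
                        modules = data.frame(size = 10, pattern = 1,
                                             rho = 0.999),
                        triplets = data.frame(marker = integer(),
                                              module = integer(),
                                              phenotype = character(),
                                              model = integer(), b1 = numeric(),
                                              b2 = numeric(), sd_y = numeric()),
                        seed = 2)
  st <- simulate_study(d)
  genes <- names(st$truth$module)[st$truth$module == "mod1"]
  cc <- cor(t(unclass(st$expression$NOS)[genes, ]))
  expect_gt(min(cc), 0.99)

  # pattern-3 module: RSE - NOS condition-mean contrast ~ 2 * delta
  d3 <- synthetic_design(n_strains = 200, n_genes = 200, n_markers = 10,
                         n_chr = 1,
                         modules = data.frame(size = 50, pattern = 3, rho = 0.7),
                         seed = 4,
                         triplets = data.frame(marker = integer(),
                                               module = integer(),
                                               phenotype = character(),
                                               model = integer(), b1 = numeric(),
                                               b2 = numeric(), sd_y = numeric()))
  st3 <- simulate_study(d3)
  genes3 <- names(st3$truth$module)[st3$truth$module == "mod1"]
  contrast <- mean(unclass(st3$expression$RSE)[genes3, ]) -
    mean(unclass(st3$expression$NOS)[genes3, ])
  expect_lt(abs(contrast - 2 * 0.5), 0.1)

  # genes in different modules: near-zero correlation
  st_sm <- simulate_study(small_design(seed = 6))
  g1 <- names(st_sm$truth$module)[st_sm$truth$module == "mod1"][1:10]
  g2 <- names(st_sm$truth$module)[st_sm$truth$module == "mod2"][1:10]
  cross <- cor(t(unclass(st_sm$expression$NOS)[c(g1, g2), ]))[1:10, 11:20]
  expect_lt(mean(abs(cross)), 3 / sqrt(41))
})

test_that("all four planted patterns produce the qualitative mean orderings", {
  st <- simulate_study(synthetic_design(seed = 12))
  tr <- st$truth
  cond_means <- function(mod) {
    genes <- names(tr$module)[tr$module == mod]
    vapply(st$expression, function(e) mean(unclass(e)[genes, ]), 0)
  }
  for (mod in names(tr$pattern)) {
    m <- cond_means(mod)
    d <- m - m[["NOS"]]
    switch(as.character(tr$pattern[[mod]]),
      "1" = { expect_gt(d[["NOE"]], 0.3); expect_lt(abs(d[["RSE"]]), 0.15) },
      "2" = { expect_lt(d[["NOE"]], -0.3); expect_lt(abs(d[["RSE"]]), 0.15) },
      "3" = { expect_gt(d[["RSS"]], 0.3); expect_gt(d[["NOE"]], 0.3)
              expect_gt(m[["RSE"]], max(m[["RSS"]], m[["NOE"]])) },
      "4" = { expect_gt(d[["RSS"]], 0.3); expect_lt(d[["NOE"]], -0.3)
              expect_lt(d[["RSE"]], -0.3) })
  }
})

test_that("causal triplets obey their generating model", {
  set.seed(1)
  # b1 = b2 = 0: trait independent of genotype (null LRS ~ chi2(1))
  tr0 <- data.frame(marker = 5L, module = 1L, phenotype = "T0", model = 1L,
                    b1 = 0, b2 = 0, sd_y = 1)
  lrs <- replicate(150, {
    st <- simulate_study(tiny_design(seed = sample.int(1e6, 1),
                                     triplets = tr0))
    marker_regression(st$phenotypes[, "T0"],
                      st$genotypes$codes[5, rownames(st$phenotypes)])$LRS
  })
  expect_lt(abs(mean(lrs) - 1), 0.4)   # chi2(1) mean is 1

  # model 4 (collider): genotype and phenotype marginally independent
  tr4 <- data.frame(marker = 5L, module = 1L, phenotype = "T4", model = 4L,
                    b1 = 0.8, b2 = 0.8, sd_y = 1)
  cors4 <- replicate(60, {
    st <- simulate_study(tiny_design(seed = sample.int(1e6, 1),
                                     triplets = tr4))
    cor(st$phenotypes[, "T4"], st$genotypes$codes[5, rownames(st$phenotypes)])
  })
  expect_lt(abs(mean(cors4)), 0.06)

  # model 1: path-tracing identity cor(G,Y) ~ cor(G,X) * cor(X,Y)
  tr1 <- data.frame(marker = 3L, module = 1L, phenotype = "T1", model = 1L,
                    b1 = 0.8, b2 = 0.8, sd_y = 1)
  d <- synthetic_design(n_strains = 200, n_genes = 300, n_markers = 20,
                        n_chr = 1,
                        modules = data.frame(size = 40, pattern = 1, rho = 0.7),
                        triplets = tr1, seed = 31)
  st <- simulate_study(d)
  G <- st$genotypes$codes[3, ]
  X <- st$truth$factors["mod1", ]
  Y <- st$phenotypes[, "T1"]
  expect_lt(abs(cor(G, Y) - cor(G, X) * cor(X, Y)), 0.1)

  # unknown module reference is rejected at design time
  expect_error(synthetic_design(
    triplets = data.frame(marker = 1L, module = 99L, phenotype = "x",
                          model = 1L, b1 = 1, b2 = 1, sd_y = 1)),
    "unknown module")
})

test_that("planted PPI layer overlaps modules as designed", {
  st <- simulate_study(small_design(seed = 21))
  planted <- st$truth$planted_ppi
  expect_true(all(planted$combined_score > 700))
  # every planted edge is within one truth module
  expect_true(all(st$truth$module[planted$protein1] ==
                    st$truth$module[planted$protein2]))

  # planted fraction 0: high-score same-module edges only by chance
  d <- small_design(seed = 22)
  st0 <- simulate_study(d, ppi_planted_frac = 0)
  hi <- st0$ppi[st0$ppi$combined_score > 700, ]
  same <- st0$truth$module[hi$protein1] == st0$truth$module[hi$protein2] &
    st0$truth$module[hi$protein1] != "bg"
  # chance expectation: fraction of pairs falling in one module
  sizes <- table(st0$truth$module[st0$truth$module != "bg"])
  p_same <- sum(choose(sizes, 2)) / choose(d$n_genes, 2)
  expect_lt(mean(same), 5 * p_same + 0.01)
})
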