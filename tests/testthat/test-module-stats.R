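test_that("module condition profiles average member genes per strain", {
  m <- rbind(a = c(1, 3), b = c(3, 5), c = c(10, 10))
  colnames(m) <- c("s1", "s2")
  mk <- function(vals, cond) {
    vv <- rbind(vals, f1 = 0, f2 = 0)[, c(1, 2, 2)]
    colnames(vv) <- c("s1", "s2", "s3")
    expression_matrix(vv + 0, cond)
  }
  exprs <- list(NOS = mk(m, "NOS"), RSS = mk(m + 1, "RSS"))
  asg <- c(a = "M1", b = "M1", c = "M2", f1 = "grey", f2 = "grey")
  E <- module_condition_profile(exprs, asg)
  expect_equal(E$M1["s1", "NOS"], 2)   # mean of 1 and 3
  expect_equal(E$M1["s1", "RSS"], 3)
  expect_equal(E$M2["s1", "NOS"], 10)  # one-gene module equals the gene
  expect_false("grey" %in% names(E))
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # groups (1,2,3) and (4,5,6): SSB 13.5, SSW 4, F = 13.5
  E <- cbind(A = c(1, 2, 3), B = c(4, 5, 6))
  rownames(E) <- paste0("s", 1:3)
  res <- anova_pattern(E)
  expect_equal(res$F, 13.5, tolerance = 1e-12)
  oracle <- anova_oracle(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$p, oracle$p, tolerance = 1e-12)

  # identical groups: F = 0, p = 1
  E0 <- cbind(A = c(1, 2), B = c(1, 2))
  rownames(E0) <- paste0("s", 1:2)
  res0 <- anova_pattern(E0)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  # random tables against the sums-of-squares oracle
  set.seed(10)
  for (i in 1:20) {
    k <- sample(2:5, 1); n <- sample(3:8, 1)
    E <- matrix(rnorm(n * k), n, k,
                dimnames = list(paste0("s", 1:n), paste0("c", 1:k)))
    got <- anova_pattern(E)
    orc <- anova_oracle(asplit(E, 2))
    expect_equal(got$F, orc$F, tolerance = 1e-10)
    expect_equal(got$p, orc$p, tolerance = 1e-10)
  }

  # zero within-group variance: boundary flagged
  Ec <- cbind(A = c(1, 1), B = c(2, 2))
  rownames(Ec) <- paste0("s", 1:2)
  expect_warning(resc <- anova_pattern(Ec), "boundary")
  expect_equal(resc$p, 0)
})

test_that("ANOVA type-I error is calibrated under the null", {
  set.seed(77)
  n_rep <- 4000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    E <- matrix(rnorm(40), 10, 4,
                dimnames = list(paste0("s", 1:10), c("NOS", "RSS", "NOE", "RSE")))
    rej[i] <- anova_pattern(E)$p < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.012)
})

test_that("pattern classifier implements the four canonical responses", {
  expect_identical(classify_pattern(
    c(NOS = 0, RSS = 0, NOE = 0.5, RSE = 0.02)), "1")
  expect_identical(classify_pattern(
    c(NOS = 0, RSS = 0.02, NOE = -0.5, RSE = -0.05)), "2")
  expect_identical(classify_pattern(
    c(NOS = 0, RSS = 0.5, NOE = 0.5, RSE = 1.0)), "3")
  expect_identical(classify_pattern(
    c(NOS = 0, RSS = 0.5, NOE = -0.5, RSE = -0.5)), "4")
  expect_identical(classify_pattern(
    c(NOS = 0, RSS = 0.01, NOE = 0.02, RSE = 0.01)), "unclassified")
  # invariance to adding a constant to all means
  base <- c(NOS = 0, RSS = 0.5, NOE = 0.5, RSE = 1.0)
  expect_identical(classify_pattern(base + 9), classify_pattern(base))
  expect_error(classify_pattern(c(NOS = 0, RSS = 1, NOE = 1)), "four")
})

test_that("planted pattern labels are recovered from generated data", {
  st <- simulate_study(synthetic_design(seed = 13))
  truth <- st$truth
  asg <- truth$module[truth$module != "bg"]
  pat <- pattern_summary(st$expression, asg)
  got <- pat$pattern[match(names(truth$pattern), pat$module)]
  expect_gte(mean(got == as.character(truth$pattern)), 0.9)
  # pattern-3 module means obey NOS < RSS ~ NOE < RSE
  m3 <- pat[pat$module == names(truth$pattern)[truth$pattern == 3][1], ]
  expect_lt(m3$NOS, m3$RSS)
  expect_lt(abs(m3$RSS - m3$NOE), 0.2)
  expect_gt(m3$RSE, m3$NOE)
  # the largest planted contrast (pattern 3, RSE at +2 delta) is detected
  mods3 <- names(truth$pattern)[truth$pattern == 3]
  expect_lt(max(pat$p[pat$module %in% mods3]), 0.05)
})

test_that("eigengene-trait correlation gives exact t-based p-values", {
  set.seed(3)
  n <- 10
  mes <- matrix(rnorm(2 * n), n, 2, dimnames = list(paste0("b", 1:n),
                                                    c("M1", "M2")))
  # trait equal to an eigengene: r = 1, p ~ 0
  phen <- phenotype_table(cbind(T1 = mes[, "M1"], T2 = rnorm(n)))
  rownames(phen) <- rownames(mes)
  tc <- module_trait_correlation(mes, phen)
  expect_equal(tc$r["M1", "T1"], 1, tolerance = 1e-12)
  expect_lt(tc$p["M1", "T1"], 1e-12)

  # orthogonalized trait: r ~ 0, p ~ 1
  y <- rnorm(n)
  y_orth <- residuals(lm(y ~ mes[, "M1"]))
  phen2 <- phenotype_table(cbind(T = y_orth))
  rownames(phen2) <- rownames(mes)
  tc2 <- module_trait_correlation(mes, phen2)
  expect_lt(abs(tc2$r["M1", "T"]), 1e-10)
  expect_gt(tc2$p["M1", "T"], 0.999)

  # r = 0.632, n = 10 -> t = 2.306, p ~ 0.05 (t-quantile oracle)
  r <- 0.632
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(t_stat, 2.306, tolerance = 1e-3)
  p_oracle <- 2 * pt(t_stat, df = 8, lower.tail = FALSE)
  x <- scale(rnorm(n))[, 1]
  e <- residuals(lm(rnorm(n) ~ x)); e <- e / sd(e)
  y3 <- r * x + sqrt(1 - r^2) * e     # exact sample correlation r
  phen3 <- phenotype_table(cbind(T = y3))
  rownames(phen3) <- paste0("b", 1:n)
  mes3 <- matrix(x, n, 1, dimnames = list(paste0("b", 1:n), "M1"))
  tc3 <- module_trait_correlation(mes3, phen3)
  expect_equal(tc3$r["M1", "T"], r, tolerance = 1e-6)
  expect_equal(tc3$p["M1", "T"], p_oracle, tolerance = 1e-4)
  expect_equal(p_oracle, 0.05, tolerance = 0.01)
  # display mask keeps |p| < 0.1
  expect_true(tc3$display["M1", "T"])
})

test_that("2x2 Fisher enrichment matches the hypergeometric oracle", {
  universe <- sprintf("g%03d", 1:40)
  mod <- universe[1:20]
  res <- enrichment_fisher(mod, mod, universe)
  expect_lt(res$p, 0.05)            # maximal overlap in a universe of 40
  expect_true(res$significant)

  # zero overlap of two singletons in a large universe: depletion ns
  res0 <- enrichment_fisher("g1", "g2", sprintf("g%d", 1:1000))
  expect_equal(res0$p, 1, tolerance = 1e-9)

  # balanced table: odds ratio 1, p = 1
  resb <- enrichment_fisher(c("a", "b", "c", "d"), c("a", "b", "e", "f"),
                            c("a", "b", "c", "d", "e", "f", "g", "h"))
  expect_equal(resb$table[1, 1], 2)
  expect_equal(resb$p, 1)

  # random tables with N <= 60 against exhaustive hypergeometric sums
  set.seed(11)
  for (i in 1:30) {
    N <- sample(10:60, 1)
    u <- sprintf("u%02d", 1:N)
    a <- sample(u, sample(1:(N - 1), 1))
    b <- sample(u, sample(1:(N - 1), 1))
    got <- enrichment_fisher(a, b, u)
    both <- length(intersect(a, b))
    orc <- fisher_oracle(both, length(a) - both, length(b) - both,
                         N - length(union(a, b)))
    expect_equal(got$p, orc, tolerance = 1e-9)
  }
  expect_error(enrichment_fisher("a", "b", character()), "universe")
})

test_that("module-level enrichment table flags known overlaps", {
  asg <- c(setNames(rep("M1", 30), sprintf("m1_%02d", 1:30)),
           setNames(rep("M2", 30), sprintf("m2_%02d", 1:30)),
           setNames(rep("grey", 40), sprintf("bg_%02d", 1:40)))
  gsc <- gene_set_collection(list(hit = sprintf("m1_%02d", 1:20),
                                  miss = sprintf("bg_%02d", 1:20)))
  enr <- module_enrichment(asg, gsc)
  expect_true(enr$significant[enr$module == "M1" & enr$set == "hit"])
  # M2 shares nothing with the set: not over-represented (the two-sided
  # p can still flag depletion)
  expect_gt(enr$p_greater[enr$module == "M2" & enr$set == "hit"], 0.05)
  expect_true("p_bh" %in% names(enr))
})
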