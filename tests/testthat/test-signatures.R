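test_that("rank-biserial scoring matches direct Mann-Whitney enumeration", {
  # 6 genes, the 2 set genes are the 2 highest: U = n1*n2 = 8, r = 1
  expr <- matrix(c(10, 9, 5, 4, 3, 2), ncol = 1,
                 dimnames = list(paste0("g", 1:6), "S1"))
  sc <- score_gene_set(cbind(expr, expr), c("g1", "g2"))
  expect_equal(unname(sc$r_rb), c(1, 1))
  expect_equal(unname(sc$scaled), c(10, 10))

  # interleaved set: U = n1*n2/2, r = 0
  expr2 <- matrix(c(6, 4, 5, 3, 2, 1), ncol = 1,
                  dimnames = list(paste0("g", 1:6), "S1"))
  sc2 <- score_gene_set(cbind(expr2, expr2), c("g2", "g4"))
  expect_equal(unname(sc2$r_rb), c(0, 0), tolerance = 1e-12)

  # random instances against wilcox.test as an independent oracle
  set.seed(17)
  for (i in 1:10) {
    m <- toy_expression(40, 6, seed = i)
    set_genes <- sample(rownames(m), 8)
    sc <- score_gene_set(m, set_genes)
    for (s in 1:6) {
      U <- unname(stats::wilcox.test(m[set_genes, s],
                                     m[setdiff(rownames(m), set_genes), s],
                                     exact = FALSE)$statistic)
      expect_equal(unname(sc$r_rb[s]), 2 * U / (8 * 32) - 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("scores are bounded, centered and monotone-invariant", {
  m <- toy_expression(60, 15, seed = 2)
  sc <- score_gene_set(m, rownames(m)[1:10])
  expect_true(all(sc$scaled >= -10 & sc$scaled <= 10))
  expect_equal(median(sc$centered), 0)
  # any monotone per-sample transform leaves ranks, hence scores, unchanged
  m2 <- 2^m + 5
  sc2 <- score_gene_set(m2, rownames(m)[1:10])
  expect_equal(sc$r_rb, sc2$r_rb)
  expect_error(score_gene_set(m, c("nope1", "nope2")), "nope1")
})

test_that("signed signatures subtract the negative-set score", {
  m <- toy_expression(60, 15, seed = 3)
  sig_same <- gene_signature(rownames(m)[1:5], character(0))
  pos_only <- score_signed_signature(m, sig_same)
  expect_equal(unname(pos_only),
               unname(score_gene_set(m, rownames(m)[1:5])$centered))
  # identical rank profiles in both arms cancel: duplicate the gene rows
  m_dup <- rbind(m, m[1:5, ] + 0)
  rownames(m_dup) <- c(rownames(m), paste0("dup", 1:5))
  sig <- gene_signature(rownames(m)[1:5], paste0("dup", 1:5))
  expect_equal(unname(score_signed_signature(m_dup, sig)), rep(0, 15),
               tolerance = 1e-12)
  expect_error(gene_signature(c("a", "b"), c("b")), "overlap")
})

test_that("signed scores track a planted enrichment gradient", {
  set.seed(4)
  n <- 20
  grad <- seq(-2, 2, length.out = n)
  m <- matrix(rnorm(200 * n, 5, 1), 200, n,
              dimnames = list(sprintf("g%03d", 1:200),
                              sprintf("S%02d", 1:n)))
  m[1:15, ] <- m[1:15, ] + rep(grad, each = 15)   # positive arm
  m[16:30, ] <- m[16:30, ] - rep(grad, each = 15) # negative arm
  sig <- gene_signature(rownames(m)[1:15], rownames(m)[16:30])
  sc <- score_signed_signature(m, sig)
  expect_gt(cor(sc, grad, method = "spearman"), 0.9)
})

test_that("per-gene Spearman correlation handles exact and edge cases", {
  m <- toy_expression(10, 8, seed = 5)
  par <- m["g001", ]  # gene equal to the parameter: R = 1
  R <- correlate_genes_with_parameter(m, par)
  expect_equal(unname(R["g001"]), 1)
  m2 <- rbind(m, rev_gene = rev(sort(par)))
  m2["rev_gene", order(par)] <- seq(8, 1)
  expect_equal(unname(correlate_genes_with_parameter(m2, par)["rev_gene"]),
               -1)
  expect_error(correlate_genes_with_parameter(m, rep(1, 8)), "constant")
  expect_error(correlate_genes_with_parameter(m, c(par[1:3],
                                                   rep(NA, 5))), "4 samples")
})

test_that("planted correlations are recovered in expectation", {
  set.seed(6)
  Rs <- replicate(50, {
    x <- rnorm(80)
    g <- 0.6 * x + sqrt(1 - 0.36) * rnorm(80)
    cor(g, x, method = "spearman")
  })
  expect_lt(abs(mean(Rs) - 0.6 * 0.96), 0.1)  # rank attenuation ~ 2%
})

test_that("signature derivation thresholds strictly at |R| = cutoff", {
  R <- c(g1 = 0.5, g2 = -0.45, g3 = 0.2, g4 = 0.4, g5 = -0.4)
  sig <- derive_distance_signature(R, 0.4)
  expect_equal(sig$positive, "g1")
  expect_equal(sig$negative, "g2")
  expect_warning(derive_distance_signature(c(a = 0.1), 0.4), "empty")
})

test_that("signatures round-trip through TSV", {
  sig <- gene_signature(c("a", "b"), c("c"), name = "sig1", cutoff = 0.4)
  tf <- tempfile(fileext = ".tsv")
  write_signature(sig, tf)
  back <- read_signature(tf, name = "sig1", cutoff = 0.4)
  expect_equal(back$positive, sig$positive)
  expect_equal(back$negative, sig$negative)
})

test_that("permutation test: self-correlation, determinism, errors", {
  m <- toy_expression(80, 20, seed = 7)
  sig <- gene_signature(rownames(m)[1:8], rownames(m)[9:14])
  res <- permutation_test(m, sig, sig, n_perm = 200, seed = 99)
  expect_equal(res$observed_r, 1)
  expect_equal(res$p_value, 0)

  res1 <- permutation_test(m, sig, "g050", n_perm = 300, seed = 42)
  res2 <- permutation_test(m, sig, "g050", n_perm = 300, seed = 42)
  expect_identical(res1$p_value, res2$p_value)
  expect_identical(res1$observed_r, res2$observed_r)
  res3 <- permutation_test(m, sig, "g050", n_perm = 300, seed = 43)
  expect_false(identical(res3$p_value, res1$p_value) &&
                 identical(unclass(res3), unclass(res1)))

  expect_error(permutation_test(m, sig, "absent_gene", n_perm = 10),
               "absent_gene")
})

test_that("an extreme observed correlation yields p = 0", {
  m <- toy_expression(60, 16, seed = 8)
  sig <- gene_signature(rownames(m)[1:6])
  sgoi_scores <- score_signed_signature(m, sig)
  # SGOI = the signature itself: |r| = 1 beats every random |r| < 1
  res <- permutation_test(m, sig, sig, n_perm = 100, seed = 5)
  expect_equal(res$p_value, 0)
  expect_true(all(abs(sgoi_scores) <= 10))
})
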