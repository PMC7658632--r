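test_that("density is count over effective area, clipped to the region", {
  rs <- rect_regions(1000, 500)  # 0.5 mm^2
  ct <- cell_table("s1", runif(50, 0, 1000), runif(50, 0, 500),
                   rep("CD8_Ki67pos", 50))
  expect_equal(compute_density(ct, rs, "tumor", "CD8"), 100)
  expect_equal(compute_density(ct, rs, "tumor", "ARG1"), 0)

  # cells outside the region do not count
  rs1 <- square_regions(1000)
  ct2 <- cell_table("s1", c(runif(10, 0, 1000), runif(5, 2000, 3000)),
                    c(runif(10, 0, 1000), runif(5, 2000, 3000)),
                    rep("FOXP3", 15))
  expect_equal(compute_density(ct2, rs1, "tumor", "FOXP3"), 10)
})

test_that("GAD is the mean nearest-myeloid distance over CD8 cells", {
  expect_equal(compute_gad(data.frame(x = c(0, 10), y = c(0, 0)),
                           data.frame(x = 0, y = 0)), 5.0)
  p <- data.frame(x = runif(20), y = runif(20))
  expect_equal(compute_gad(p, p), 0)
  expect_true(is.na(compute_gad(p[0, ], p)))
  expect_true(is.na(compute_gad(p, p[0, ])))
})

test_that("GAD matches a brute-force all-pairs oracle", {
  set.seed(11)
  for (i in 1:20) {
    p <- cbind(runif(200, 0, 2000), runif(200, 0, 2000))
    q <- cbind(runif(300, 0, 2000), runif(300, 0, 2000))
    got <- compute_gad(data.frame(x = p[, 1], y = p[, 2]),
                       data.frame(x = q[, 1], y = q[, 2]))
    expect_lt(abs(got - gad_oracle(p, q)), 1e-9)
  }
})

test_that("GAD normalization follows the Clark-Evans expectation", {
  expect_equal(normalize_gad(50, 100, 1), 1.0)
  expect_equal(normalize_gad(25, 100, 1), 0.5)
  expect_true(is.na(normalize_gad(NA_real_, 100, 1)))
  expect_true(is.na(normalize_gad(50, 0, 1)))
})

test_that("GAD_norm is ~1 under complete spatial randomness", {
  gn <- vapply(1:50, function(s) {
    set.seed(s)
    side <- sqrt(5e6)
    my <- data.frame(x = runif(500, 0, side), y = runif(500, 0, side))
    cd8 <- data.frame(x = runif(200, 0, side), y = runif(200, 0, side))
    normalize_gad(compute_gad(cd8, my), 500, 5)
  }, 0)
  expect_gte(mean(gn), 0.98)
  expect_lte(mean(gn), 1.10)
})

test_that("cohort thresholds are sample-level medians skipping missing", {
  thr <- cohort_thresholds(data.frame(CD8 = c(10, 20, 30)))
  expect_equal(unname(thr$D["CD8"]), 20)
  thr <- cohort_thresholds(data.frame(CD8 = c(10, 20)))
  expect_equal(unname(thr$D["CD8"]), 15)
  thr <- cohort_thresholds(data.frame(CD8 = c(10, 20)),
                           mto = data.frame(m = c(0.2, NA, 0.6)))
  expect_equal(unname(thr$mto_median["m"]), 0.4)
  expect_error(cohort_thresholds(data.frame(CD8 = c(NA_real_, NA_real_))),
               "CD8")
  expect_error(cohort_thresholds(data.frame(CD8 = 5)), "2 samples")
})

test_that("hot labelling is strictly above the median", {
  expect_equal(label_hot_tiles(c(12, 10, 8, 0), 10), c(1L, 0L, 0L, 0L))
  expect_equal(label_hot_tiles(rep(0, 3), 5), rep(0L, 3))
})

test_that("MTO is the hot-overlap fraction of CD8-hot tiles", {
  expect_equal(compute_mto(c(1, 1, 1, 0), c(1, 1, 0, 1)), 2 / 3)
  expect_true(is.na(compute_mto(c(0, 0), c(1, 1))))
  expect_error(compute_mto(c(1, 0), c(1, 0, 1)), "tile sets")
})

test_that("MTO matches direct enumeration on random hot flags", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    hj <- rbinom(n, 1, 0.4); hk <- rbinom(n, 1, 0.4)
    expected <- if (sum(hj) == 0) NA_real_ else {
      num <- 0
      for (t in seq_len(n)) if (hj[t] == 1 && hk[t] == 1) num <- num + 1
      num / sum(hj)
    }
    expect_identical(compute_mto(hj, hk), expected)
  }
})

test_that("MTO is invariant to tile relabeling and translation", {
  set.seed(5)
  hj <- rbinom(40, 1, 0.5); hk <- rbinom(40, 1, 0.5)
  perm <- sample(40)
  expect_equal(compute_mto(hj, hk), compute_mto(hj[perm], hk[perm]))

  rs <- rect_regions(2000, 1500)
  ct <- csr_cells(600, 2000, 1500, c("CD8_Ki67neg", "CD11b_CD14"), seed = 9)
  g <- build_hex_grid(rs, 250)
  D <- c(CD8 = 150, CD11b_CD14 = 150)
  ov1 <- sample_overlap(ct, g, D, "CD11b_CD14")
  shift <- c(12345.6, -789.1)
  ct2 <- cell_table("s1", ct$x + shift[1], ct$y + shift[2], ct$phenotype)
  rs2 <- region_set(list(list(
    rings = list(cbind(c(0, 2000, 2000, 0) + shift[1],
                       c(0, 0, 1500, 1500) + shift[2])),
    region_class = "tumor")), "s1")
  ov2 <- sample_overlap(ct2, build_hex_grid(rs2, 250), D, "CD11b_CD14")
  expect_equal(ov1$mto, ov2$mto)
})

test_that("stratification maps (CD8, MTO) levels to categories 1-4", {
  expect_equal(stratify_sample(5, 0.8, 10, 0.5)$category, 2L)  # low/high
  expect_equal(stratify_sample(15, 0.2, 10, 0.5)$category, 4L) # high/low
  expect_equal(stratify_sample(5, 0.2, 10, 0.5)$category, 1L)  # low/low
  expect_equal(stratify_sample(15, 0.8, 10, 0.5)$category, 3L) # high/high
  # values exactly at the median are low
  s <- stratify_sample(10, 0.5, 10, 0.5)
  expect_equal(s$category, 1L)
  expect_equal(s$cd8_level, "low")
  # undefined MTO yields no assignment
  expect_true(is.na(stratify_sample(5, NA, 10, 0.5)$category))
})

test_that("the four categories partition samples, halving each axis", {
  set.seed(21)
  for (n in c(20L, 31L)) {
    cd8 <- runif(n, 10, 300)
    mto <- runif(n)
    thr_cd8 <- median(cd8); thr_mto <- median(mto)
    cat <- vapply(seq_len(n), function(i)
      stratify_sample(cd8[i], mto[i], thr_cd8, thr_mto)$category, 0L)
    expect_false(anyNA(cat))
    expect_equal(sum(table(factor(cat, 1:4))), n)
    n_low <- sum(cat %in% c(1L, 2L))
    expect_true(n_low %in% c(floor(n / 2), ceiling(n / 2)))
  }
})

test_that("cohort statistics: null contrast, identity correlation, power", {
  m <- data.frame(a = c(1, 2, 3, 4, 5, 6), b = c(2, 4, 6, 8, 10, 12))
  st <- cohort_statistics(m, group = rep(c("g1", "g2"), 3)[c(1,3,5,2,4,6)])
  # identical group compositions: two-sided Mann-Whitney p = 1
  st_null <- cohort_statistics(data.frame(a = rep(c(1, 2, 3), 2)),
                               group = rep(c("x", "y"), each = 3))
  expect_equal(st_null$contrasts$p_value, 1.0)
  expect_equal(unname(st$correlations["a", "b"]), 1.0)

  # planted bivariate normal rho = 0.9 recovered
  set.seed(13)
  rs <- replicate(20, {
    x <- rnorm(200); y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(200)
    cohort_statistics(data.frame(x = x, y = y))$correlations["x", "y"]
  })
  expect_true(all(rs > 0.85 & rs < 0.95))

  expect_warning(
    cohort_statistics(data.frame(a = c(1, NA, 3)),
                      group = factor(c("x", "y", "x"), c("x", "y"))),
    "skipped")
})

test_that("analyze_cohort handles a sample with no myeloid cells", {
  set.seed(31)
  cells <- list(
    A = csr_cells(300, 1500, 1500, c("CD8_Ki67neg", "CD11b_CD14",
                                     "CD11b_CD15"), "A"),
    B = csr_cells(300, 1500, 1500, c("CD8_Ki67neg", "CD11b_CD14",
                                     "CD11b_CD15"), "B"),
    C = csr_cells(100, 1500, 1500, "CD8_Ki67neg", "C"))
  regions <- list(A = square_regions(1500, "A"),
                  B = square_regions(1500, "B"),
                  C = square_regions(1500, "C"))
  fit <- analyze_cohort(cells, regions)
  expect_s3_class(fit, "tme_cohort")
  expect_true(any(grepl("C", fit$warnings)))
  dC <- fit$distances[fit$distances$sample_id == "C", ]
  expect_true(all(is.na(dC$gad_norm)))
  # sample C is absent from the defined-GAD medians but densities exist
  expect_equal(nrow(fit$densities), 3L)
})
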