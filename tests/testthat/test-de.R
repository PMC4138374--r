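test_that("two-sample t test matches stats::t.test in both variants", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:6, 1), mean = runif(1, -1, 1))
    for (variant in c("pooled", "welch")) {
      mine <- two_sample_ttest(x, y, variant)
      ref <- t.test(x, y, var.equal = variant == "pooled")
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("t test worked example, degenerate case and scale invariance", {
  ex <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ex$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ex$statistic, -3.674, tolerance = 1e-3)
  expect_identical(ex$df, 4L)
  expect_equal(ex$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(ex$p_value, 0.0213, tolerance = 1e-2)

  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # both groups constant and equal -> p = 1 by convention
  flat <- two_sample_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(flat$p_value, 1)

  a <- two_sample_ttest(c(1, 2, 3), c(4, 5, 7))
  b <- two_sample_ttest(10 * c(1, 2, 3), 10 * c(4, 5, 7))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  expect_error(two_sample_ttest(1, c(1, 2)), "2 replicates")
})

test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(c(0.9, 0.8)), c(0.9, 0.9))
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), hand_bh(p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("responsive calling applies fold and FDR criteria per contrast", {
  # planted suppression: HDSN mean 3 vs LDSN mean 5 (log2) -> fold 0.25
  means <- rbind(g1 = c(5, 5, 3, 5),
                 g2 = c(2, 2, 2, 2),
                 g3 = c(4, 7, 4, 4))
  m <- toy_expr(means, n_rep = 3, noise_sd = 0.01, seed = 2)
  de <- call_responsive(m, 21)
  hd_g1 <- de[de$gene_id == "g1" & de$contrast == "HD", ]
  expect_equal(hd_g1$fold_change, 0.25, tolerance = 0.05)
  expect_true(hd_g1$responsive)
  expect_identical(hd_g1$direction, "suppressed")
  ln_g3 <- de[de$gene_id == "g3" & de$contrast == "LN", ]
  expect_true(ln_g3$responsive)
  expect_identical(ln_g3$direction, "enhanced")
  # a constant gene is responsive nowhere with fold ~ 1
  g2 <- de[de$gene_id == "g2", ]
  expect_equal(g2$fold_change, rep(1, 3), tolerance = 0.05)
  expect_false(any(g2$responsive))
  # fold_change(A,B) * fold_change(B,A) = 1: recompute with swapped control
  expect_equal(de$fold_change * 2^(-de$log2fc), rep(1, nrow(de)))
})

test_that("few genes are called on a global-null matrix", {
  cfg <- sim_config(n_genes = 2000, K_true = 1,
                    profile_means = matrix(8, 1, 4), covariance_params = 0,
                    frac_null = 0, noise_sd = 0.5, seed = 31)
  s <- simulate_expression(cfg)
  de <- call_responsive(s$expr, 21)
  for (cn in c("HD", "LN", "HDLN")) {
    frac <- mean(de$responsive[de$contrast == cn])
    expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
  }
})

test_that("Venn partition performs exact disjoint set algebra", {
  sets <- list(HD = c("a", "b", "c"), LN = c("b", "c", "d"), HDLN = "c")
  v <- venn_partition(sets)
  expect_identical(v$regions$HD_only, "a")
  expect_identical(v$regions$HD_LN, "b")
  expect_identical(v$regions$HD_LN_HDLN, "c")
  expect_identical(v$regions$LN_only, "d")
  expect_identical(unname(v$counts[c("HDLN_only", "HD_HDLN", "LN_HDLN")]),
                   c(0L, 0L, 0L))

  empty <- venn_partition(list(HD = character(0), LN = character(0),
                               HDLN = character(0)))
  expect_identical(sum(empty$counts), 0L)

  same <- venn_partition(list(HD = c("x", "y"), LN = c("x", "y"),
                              HDLN = c("x", "y")))
  expect_identical(sort(same$regions$HD_LN_HDLN), c("x", "y"))
  expect_identical(sum(same$counts), 2L)

  # regions partition the union on random sets
  set.seed(8)
  for (i in 1:15) {
    r <- list(HD = sample(letters, sample(0:15, 1)),
              LN = sample(letters, sample(0:15, 1)),
              HDLN = sample(letters, sample(0:15, 1)))
    vp <- venn_partition(r)
    all_regions <- unlist(vp$regions, use.names = FALSE)
    expect_identical(anyDuplicated(all_regions), 0L)
    expect_setequal(all_regions, unique(unlist(r)))
  }
})

test_that("overlap fraction is |HD intersect LN| / |HD|", {
  expect_equal(overlap_fraction(list(HD = c("a", "b", "c"),
                                     LN = c("b", "c", "d"),
                                     HDLN = character(0))), 2 / 3)
  expect_equal(overlap_fraction(list(HD = "a", LN = "b",
                                     HDLN = character(0))), 0)
  expect_equal(overlap_fraction(list(HD = c("a", "b"),
                                     LN = c("a", "b", "c"),
                                     HDLN = character(0))), 1)
  expect_warning(f <- overlap_fraction(list(HD = character(0), LN = "a",
                                            HDLN = character(0))),
                 "empty")
  expect_true(is.na(f))
})

test_that("density-specific selection recovers planted HD-only genes", {
  # 50 genes responsive to HD only, 50 to both HD and LN, effects >> noise
  means <- rbind(
    matrix(rep(c(8, 8, 11, 11), each = 50), 50, 4),        # HD only
    matrix(rep(c(8, 11, 11, 11), each = 50), 50, 4))        # HD and LN
  rownames(means) <- paste0("g", 1:100)
  m <- toy_expr(means, n_rep = 3, noise_sd = 0.05, seed = 13)
  de3 <- call_responsive(m, 21, fold_cutoff = 3)
  got <- select_density_specific(de3)
  expect_setequal(got, paste0("g", 1:50))
})
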