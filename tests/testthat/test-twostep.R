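test_that("density split rearranges profiles into (SN, LN) pairs", {
  prof <- rbind(g1 = c(5, 4, 3, 1), g2 = c(2, 2, 2, 2))
  colnames(prof) <- condition_levels()
  sp <- split_by_density(prof)
  expect_equal(unname(sp$ld["g1", ]), c(5, 4))
  expect_equal(unname(sp$hd["g1", ]), c(3, 1))
  expect_equal(unname(sp$ld["g2", ]), c(2, 2))
  expect_equal(unname(sp$hd["g2", ]), c(2, 2))
  big <- matrix(rnorm(120), 30, 4,
                dimnames = list(NULL, condition_levels()))
  sp2 <- split_by_density(big)
  expect_identical(dim(sp2$hd), c(30L, 2L))
  expect_identical(dim(sp2$ld), c(30L, 2L))
  expect_error(split_by_density(big[, 1:3]), "columns")
})

test_that("kmeans2 attains the brute-force optimal 2-partition", {
  pts <- rbind(c(0, 0), c(0, 1), c(9, 9), c(9, 10))
  km <- kmeans2(pts, seed = 1)
  oracle <- brute_kmeans2(pts)
  expect_equal(km$wcss, oracle$wcss, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(km$labels, c(1, 1, 2, 2)), 1)
  cent <- km$centers[order(km$centers[, 1]), ]
  expect_equal(unname(cent), rbind(c(0, 0.5), c(9, 9.5)))

  set.seed(30)
  for (i in 1:10) {
    pts <- matrix(rnorm(2 * sample(4:8, 1)), ncol = 2)
    km <- kmeans2(pts, seed = i, n_starts = 10)
    expect_equal(km$wcss, brute_kmeans2(pts)$wcss, tolerance = 1e-9)
  }
  # label permutation leaves WCSS unchanged by construction
  expect_error(kmeans2(matrix(1, 1, 2)), "at least 2")
})

test_that("coincident points collapse to a single cluster by convention", {
  pts <- matrix(2, 5, 2)
  km <- kmeans2(pts, seed = 1)
  expect_identical(km$labels, rep(1L, 5))
  expect_equal(km$centers[1, ], km$centers[2, ])
  expect_equal(km$wcss, 0)
})

test_that("cross-density label matching minimizes disagreement", {
  centers_a <- matrix(c(8, 8, 6, 8), 2, 2,
                      dimnames = list(NULL, c("SN", "LN")))
  centers_b <- matrix(c(8, 8, 8, 6), 2, 2,
                      dimnames = list(NULL, c("SN", "LN")))
  # membership matching against brute force over the two permutations
  set.seed(31)
  for (i in 1:20) {
    la <- sample(1:2, 12, replace = TRUE)
    lb <- sample(1:2, 12, replace = TRUE)
    got <- stressclust:::.match_step2(la, centers_a, lb, centers_b,
                                      match = "membership")
    best <- min(sum(la != lb), sum(la != (3L - lb)))
    expect_identical(sum(la != got), as.integer(best))
  }
  # ties go to identity
  la <- c(1L, 2L); lb <- c(2L, 1L)  # both matchings disagree equally
  tie <- stressclust:::.match_step2(c(1L, 1L), centers_a, c(1L, 2L),
                                    centers_b, match = "membership")
  expect_identical(tie, c(1L, 2L))
  # center matching pairs clusters with the same nitrogen response:
  # a's cluster 1 responds -2 (LN 6 vs SN 8), b's cluster 2 responds -2
  got <- stressclust:::.match_step2(c(1L, 2L), centers_a, c(1L, 2L),
                                    centers_b, match = "centers")
  expect_identical(got, c(2L, 1L))
})

test_that("a single-trend component yields no discordance flags", {
  # every gene suppressed by LN under both densities
  set.seed(32)
  prof <- cbind(LDSN = rnorm(40, 8, 0.1), LDLN = rnorm(40, 6, 0.1),
                HDSN = rnorm(40, 8, 0.1), HDLN = rnorm(40, 6, 0.1))
  ts <- run_two_step(prof, strategy = "gpcm-kmeans",
                     step1 = list(G_range = 1, model_set = "EII",
                                  n_starts = 2), seed = 1)
  expect_false(any(ts$assignments$discordant))
  expect_false(ts$components[[1]]$split)
})

test_that("planted discordant genes are recovered with high sensitivity", {
  cfg <- sim_config(n_genes = 240, K_true = 2,
                    profile_means = rbind(c(8, 6, 8, 6), c(14, 12, 14, 12)),
                    frac_null = 0, frac_discordant = 0.5,
                    covariance_params = 0.15, noise_sd = 0.2, seed = 5)
  s <- simulate_expression(cfg)
  prof <- condition_means(s$expr, 21)
  ts <- run_two_step(prof, strategy = "gpcm-kmeans",
                     step1 = list(G_range = 2, n_starts = 3), seed = 7)
  truth <- s$discordant
  flag <- ts$assignments$discordant
  expect_gte(sum(flag & truth) / sum(truth), 0.9)
  expect_gte(sum(!flag & !truth) / sum(!truth), 0.9)
  expect_equal(adjusted_rand_index(s$labels, ts$assignments$component), 1)
})

test_that("discordance flags are invariant to gene input order", {
  cfg <- sim_config(n_genes = 120, K_true = 2,
                    profile_means = rbind(c(8, 6, 8, 6), c(14, 12, 14, 12)),
                    frac_null = 0, frac_discordant = 0.4,
                    covariance_params = 0.15, noise_sd = 0.2, seed = 6)
  s <- simulate_expression(cfg)
  prof <- condition_means(s$expr, 21)
  ts1 <- run_two_step(prof, step1 = list(G_range = 2, n_starts = 3),
                      seed = 9)
  set.seed(40)
  perm <- sample(nrow(prof))
  ts2 <- run_two_step(prof[perm, ], step1 = list(G_range = 2, n_starts = 3),
                      seed = 9)
  f1 <- setNames(ts1$assignments$discordant, ts1$assignments$gene_id)
  f2 <- setNames(ts2$assignments$discordant, ts2$assignments$gene_id)
  expect_identical(f1[names(f2)], f2)
  expect_equal(adjusted_rand_index(ts1$assignments$component,
                                   ts2$assignments$component[
                                     match(names(f1), names(f2))]), 1)
})

test_that("k-means and G=2 GPCM second steps agree on separated data", {
  cfg <- sim_config(n_genes = 160, K_true = 2,
                    profile_means = rbind(c(8, 6, 8, 6), c(14, 12, 14, 12)),
                    frac_null = 0, frac_discordant = 0.5,
                    covariance_params = 0.05, noise_sd = 0.05, seed = 8)
  s <- simulate_expression(cfg)
  prof <- condition_means(s$expr, 21)
  a <- run_two_step(prof, strategy = "gpcm-kmeans",
                    step1 = list(G_range = 2, n_starts = 3), seed = 11)
  b <- run_two_step(prof, strategy = "gpcm-gpcm",
                    step1 = list(G_range = 2, n_starts = 3), seed = 11)
  expect_identical(a$assignments$discordant, b$assignments$discordant)
})

test_that("components too small for the second step are skipped", {
  set.seed(33)
  prof <- rbind(matrix(rnorm(40 * 4, 8, 0.2), 40, 4),
                matrix(rnorm(3 * 4, 20, 0.2), 3, 4))
  colnames(prof) <- condition_levels()
  ts <- run_two_step(prof, step1 = list(G_range = 2, model_set = "EII",
                                        n_starts = 3), seed = 2)
  sizes <- vapply(ts$components, `[[`, 0L, "size")
  small <- which(sizes < 4)
  expect_length(small, 1)
  expect_false(ts$components[[small]]$split)
  expect_identical(ts$components[[small]]$reason, "too small")
})
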