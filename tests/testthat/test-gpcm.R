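test_that("single-component fits reproduce the closed-form MLEs", {
  set.seed(3)
  x <- matrix(rnorm(200, sd = 2), 50, 4)
  for (model in gpcm_models()) {
    f <- fit_gpcm(x, G = 1, model = model, n_starts = 1, seed = 1)
    expect_equal(unname(f$mu[1, ]), unname(colMeans(x)), tolerance = 1e-10)
  }
  S <- crossprod(sweep(x, 2, colMeans(x)))
  f_eii <- fit_gpcm(x, G = 1, model = "EII", n_starts = 1, seed = 1)
  expect_equal(f_eii$Sigma[[1]][1, 1], sum(diag(S)) / (nrow(x) * 4),
               tolerance = 1e-10)
  f_vvv <- fit_gpcm(x, G = 1, model = "VVV", n_starts = 1, seed = 1)
  expect_equal(f_vvv$Sigma[[1]], S / nrow(x), tolerance = 1e-10)
})

test_that("BIC parameter counts follow the model table", {
  set.seed(4)
  x2 <- matrix(rnorm(80), 40, 2)
  f <- fit_gpcm(x2, G = 2, model = "EII", n_starts = 2, seed = 1)
  expect_equal(f$n_params, 6)              # (G-1) + G*p + 1 = 1 + 4 + 1
  expect_equal(f$bic, 2 * f$loglik - 6 * log(40))
  expect_equal(bic_of(f), f$bic)
  x4 <- matrix(rnorm(160), 40, 4)
  f2 <- fit_gpcm(x4, G = 1, model = "VVV", n_starts = 1)
  expect_equal(f2$n_params, 14)            # 0 + 4 + 10
  # equal log-likelihood, fewer parameters -> larger BIC
  fa <- f2; fa$n_params <- 10
  expect_gt(bic_of(fa), bic_of(f2))
  expect_error(bic_of(f2, n = 0), "positive")
})

test_that("well-separated two-component structure is recovered exactly", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, 0, 0.01), 10, 4),
             matrix(rnorm(40, 10, 0.01), 10, 4))
  truth <- rep(1:2, each = 10)
  for (model in c("EII", "VVI", "VVV")) {
    f <- fit_gpcm(x, G = 2, model = model, n_starts = 5, seed = 2)
    ord <- order(f$mu[, 1])
    expect_lt(max(abs(f$mu[ord[1], ] - 0)), 0.05)
    expect_lt(max(abs(f$mu[ord[2], ] - 10)), 0.05)
    expect_equal(unname(f$pi), c(0.5, 0.5), tolerance = 1e-6)
    expect_equal(adjusted_rand_index(truth, predict_labels(f)), 1)
  }
})

test_that("EM log-likelihood is non-decreasing for every model", {
  set.seed(10)
  for (i in 1:10) {
    x <- matrix(rnorm(60 * 4, sd = runif(1, 0.5, 2)), 60, 4) +
      rep(sample(c(0, 3), 60, replace = TRUE), 4)
    for (model in gpcm_models()) {
      f <- fit_gpcm(x, G = 2, model = model, n_starts = 1, seed = i,
                    max_iter = 200)
      expect_gte(min(diff(f$loglik_trace)), -1e-7)
    }
  }
})

test_that("fit invariants hold: responsibilities, shape determinant, floor", {
  set.seed(12)
  x <- matrix(rnorm(240), 60, 4)
  for (model in c("VEI", "EVI", "EEE", "VVV")) {
    f <- fit_gpcm(x, G = 3, model = model, n_starts = 2, seed = 5)
    expect_lt(max(abs(rowSums(f$z) - 1)), 1e-10)
    for (g in 1:3) {
      expect_equal(prod(f$shape[[g]]), 1, tolerance = 1e-8)
      ev <- eigen(f$Sigma[[g]], symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), 1e-6 * mean(apply(x, 2, var)) * 0.99)
    }
  }
})

test_that("fits are translation-equivariant; spherical fits rotation-invariant", {
  set.seed(14)
  x <- rbind(matrix(rnorm(60, 0, 0.5), 15, 4),
             matrix(rnorm(60, 4, 0.5), 15, 4))
  f0 <- fit_gpcm(x, G = 2, model = "VVV", n_starts = 3, seed = 9)
  shift <- c(10, -5, 2, 0)
  f1 <- fit_gpcm(sweep(x, 2, shift, "+"), G = 2, model = "VVV",
                 n_starts = 3, seed = 9)
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-6)
  expect_equal(sweep(f1$mu, 2, shift, "-"), f0$mu, tolerance = 1e-4)
  expect_equal(f1$Sigma, f0$Sigma, tolerance = 1e-4)

  theta <- 0.7
  R <- diag(4)
  R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)),
                        2, 2)
  for (model in c("EII", "VII")) {
    fa <- fit_gpcm(x, G = 2, model = model, n_starts = 3, seed = 9)
    fb <- fit_gpcm(x %*% R, G = 2, model = model, n_starts = 3, seed = 9)
    expect_equal(fb$loglik, fa$loglik, tolerance = 1e-6)
    expect_equal(sort(fb$lambda), sort(fa$lambda), tolerance = 1e-6)
  }
})

test_that("fitted log-likelihood agrees with mclust on separated data", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  set.seed(16)
  x <- rbind(matrix(rnorm(120, 0, 1), 30, 4),
             matrix(rnorm(120, 5, 0.7), 30, 4))
  for (model in c("EII", "VVI", "EEE", "VVV")) {
    mine <- fit_gpcm(x, G = 2, model = model, n_starts = 5, seed = 3)
    ref <- mclust::Mclust(x, G = 2, modelNames = model, verbose = FALSE)
    expect_equal(mine$loglik, ref$loglik, tolerance = 1e-4)
    expect_equal(adjusted_rand_index(predict_labels(mine),
                                     ref$classification), 1)
  }
})

test_that("adjusted Rand index matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(17)
  for (i in 1:10) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
})

test_that("model selection grid reports feasibility and breaks ties sanely", {
  set.seed(18)
  x <- matrix(rnorm(14 * 4), 14, 4)  # n < G*(p+1) for G = 3
  sel <- select_model(x, G_range = c(1, 3), model_set = c("EII", "VVV"),
                      n_starts = 2, seed = 1)
  g3 <- sel$grid[sel$grid$G == 3, ]
  expect_true(all(g3$status == "unfitted"))
  expect_true(all(is.na(g3$bic)))
  # singleton grid returns that fit as best
  sel1 <- select_model(x, G_range = 1, model_set = "EII", n_starts = 1,
                       seed = 1)
  expect_identical(nrow(sel1$grid), 1L)
  expect_identical(sel1$best$model, "EII")
  expect_equal(sel1$best$G, 1)
})

test_that("hard labels use maximum responsibility with ties to lowest index", {
  fake <- structure(list(z = rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))),
                    class = "gpcm_fit")
  expect_identical(predict_labels(fake), c(1L, 1L, 2L))
})
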