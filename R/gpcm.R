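# Gaussian parsimonious clustering models: finite Gaussian mixtures whose
# component covariances are constrained through the eigen-decomposition
# Sigma_g = lambda_g * D_g * A_g * t(D_g) (lambda volume, D orientation,
# A shape with det(A) = 1). Eight members are implemented (EII, VII, EEI,
# VEI, EVI, VVI, EEE, VVV; the code letters read equal/variable/identity for
# volume, shape, orientation). Fitting is by EM with k-means++ hard-start
# responsibilities and multiple restarts; model and component-count
# selection maximizes BIC = 2*loglik - m*log(n).

#' Supported GPCM covariance model names
#' @return Character vector of the eight model codes.
#' @export
gpcm_models <- function() c("EII", "VII", "EEI", "VEI",
                            "EVI", "VVI", "EEE", "VVV")

# free covariance parameters + mixing + means
.gpcm_nparams <- function(model, G, p) {
  cov_params <- switch(model,
                       EII = 1,
                       VII = G,
                       EEI = p,
                       VEI = G + (p - 1),
                       EVI = 1 + G * (p - 1),
                       VVI = G * p,
                       EEE = p * (p + 1) / 2,
                       VVV = G * p * (p + 1) / 2,
                       stop("unsupported model: ", model))
  (G - 1) + G * p + cov_params
}

# per-component log Gaussian density, n x G
.log_dens <- function(x, mu, Sigma) {
  n <- nrow(x); p <- ncol(x); G <- nrow(mu)
  ld <- matrix(0, n, G)
  for (g in seq_len(G)) {
    ch <- tryCatch(chol(Sigma[[g]]), error = function(e) NULL)
    if (is.null(ch)) stop_degenerate("singular covariance in component ", g)
    xc <- sweep(x, 2L, mu[g, ], "-")
    u <- backsolve(ch, t(xc), transpose = TRUE)
    ld[, g] <- -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))) +
                         colSums(u^2))
  }
  ld
}

stop_degenerate <- function(...) {
  stop(structure(class = c("gpcm_degenerate", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}

# Scatter matrices W_g = sum_i z_ig (x_i - mu_g)(x_i - mu_g)^T
.scatter <- function(x, z, mu) {
  lapply(seq_len(ncol(z)), function(g) {
    xc <- sweep(x, 2L, mu[g, ], "-")
    crossprod(xc, xc * z[, g])
  })
}

# M-step under the covariance constraint. `state` carries warm-start values
# for the iterative VEI inner loop. Returns pi, mu, Sigma (+ state).
.gpcm_mstep <- function(x, z, model, floor_val, state = NULL) {
  n <- nrow(x); p <- ncol(x); G <- ncol(z)
  ns <- colSums(z)
  if (any(ns < 1)) stop_degenerate("vanishing component weight")
  pi_g <- ns / n
  mu <- t(crossprod(x, z)) / ns  # G x p
  W <- .scatter(x, z, mu)
  Sigma <- vector("list", G)
  regularized <- FALSE
  floor_diag <- function(d) {
    if (any(d < floor_val)) { regularized <<- TRUE; d <- pmax(d, floor_val) }
    d
  }
  floor_full <- function(S) {
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < floor_val) {
      regularized <<- TRUE
      e$values <- pmax(e$values, floor_val)
      S <- e$vectors %*% (e$values * t(e$vectors))
    }
    S
  }
  switch(model,
    EII = {
      lam <- sum(vapply(W, function(w) sum(diag(w)), 0)) / (n * p)
      lam <- floor_diag(lam)
      for (g in seq_len(G)) Sigma[[g]] <- diag(lam, p)
    },
    VII = {
      for (g in seq_len(G)) {
        lam <- floor_diag(sum(diag(W[[g]])) / (p * ns[g]))
        Sigma[[g]] <- diag(lam, p)
      }
    },
    EEI = {
      d <- floor_diag(diag(Reduce(`+`, W)) / n)
      for (g in seq_len(G)) Sigma[[g]] <- diag(d, p)
    },
    VEI = {
      # common shape A, component volumes lambda_g: alternate the two
      # closed-form conditional updates, warm-started from the previous
      # M-step for monotone EM
      lam <- state$vei_lambda
      if (is.null(lam) || length(lam) != G)
        lam <- vapply(seq_len(G), function(g) sum(diag(W[[g]])) / (p * ns[g]),
                      0)
      lam <- pmax(lam, floor_val)
      a <- state$vei_a
      if (is.null(a)) a <- rep.int(1, p)
      for (it in seq_len(50L)) {
        cvec <- diag(Reduce(`+`, Map(function(w, l) w / l, W, as.list(lam))))
        a_new <- cvec / prod(cvec)^(1 / p)
        lam_new <- vapply(seq_len(G), function(g)
          sum(diag(W[[g]]) / a_new) / (p * ns[g]), 0)
        lam_new <- pmax(lam_new, floor_val)
        done <- max(abs(a_new - a)) < 1e-10 &&
          max(abs(lam_new - lam) / lam) < 1e-10
        a <- a_new; lam <- lam_new
        if (done) break
      }
      state$vei_lambda <- lam; state$vei_a <- a
      for (g in seq_len(G)) Sigma[[g]] <- diag(floor_diag(lam[g] * a), p)
    },
    EVI = {
      cg <- lapply(W, function(w) pmax(diag(w), floor_val * 1e-3))
      dg <- vapply(cg, function(cv) prod(cv)^(1 / p), 0)
      lam <- sum(dg) / n
      for (g in seq_len(G))
        Sigma[[g]] <- diag(floor_diag(lam * cg[[g]] / dg[g]), p)
    },
    VVI = {
      for (g in seq_len(G))
        Sigma[[g]] <- diag(floor_diag(diag(W[[g]]) / ns[g]), p)
    },
    EEE = {
      S <- floor_full(Reduce(`+`, W) / n)
      for (g in seq_len(G)) Sigma[[g]] <- S
    },
    VVV = {
      for (g in seq_len(G)) Sigma[[g]] <- floor_full(W[[g]] / ns[g])
    },
    stop("unsupported model: ", model))
  list(pi = pi_g, mu = mu, Sigma = Sigma, state = state,
       regularized = regularized)
}

.gpcm_em <- function(x, G, model, z0, tol, max_iter, floor_val) {
  par <- .gpcm_mstep(x, z0, model, floor_val)
  trace <- numeric(0)
  ll_old <- -Inf
  z <- z0
  regularized <- par$regularized
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- .log_dens(x, par$mu, par$Sigma)
    lp <- sweep(ld, 2L, log(par$pi), "+")
    mx <- apply(lp, 1L, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    z <- exp(lp - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    par <- .gpcm_mstep(x, z, model, floor_val, state = par$state)
    regularized <- regularized || par$regularized
  }
  list(par = par, z = z, loglik = trace[length(trace)], trace = trace,
       iter = length(trace), converged = converged,
       regularized = regularized)
}

#' Fit a Gaussian parsimonious clustering model by EM
#'
#' @param x Numeric matrix, observations (genes) in rows; typically the
#'   genes x 4 condition-mean profiles from [condition_means()].
#' @param G Number of mixture components (>= 1, < `nrow(x)`).
#' @param model Covariance constraint code, one of [gpcm_models()].
#' @param n_starts Number of k-means++ restarts (default 10); the best final
#'   log-likelihood is kept.
#' @param seed Integer seed controlling the restarts; `NULL` uses the
#'   current RNG state.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param z_init Optional n x G responsibility matrix used as the single
#'   deterministic start (overrides `n_starts`); useful for oracle
#'   comparisons.
#' @return An object of class `gpcm_fit`: component weights `pi`, means `mu`
#'   (G x p), covariances `Sigma` (list), the eigen-decomposition per
#'   component (`lambda` volumes, `shape` unit-determinant eigenvalue
#'   vectors, `orientation` eigenvector matrices), responsibilities `z`,
#'   `loglik`, the per-iteration `loglik_trace`, `n_params`, `bic`, and
#'   bookkeeping fields (`iter`, `converged`, `regularized`).
#' @export
fit_gpcm <- function(x, G, model = "VVV", n_starts = 10, seed = NULL,
                     tol = 1e-8, max_iter = 500, z_init = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (!model %in% gpcm_models()) stop("unsupported model: ", model)
  if (G < 1) stop("G must be >= 1")
  if (n <= G) stop("need more observations than components")
  floor_val <- 1e-6 * mean(apply(x, 2L, stats::var))
  if (!is.finite(floor_val) || floor_val <= 0) floor_val <- 1e-10

  starts <- if (!is.null(z_init)) {
    stopifnot(nrow(z_init) == n, ncol(z_init) == G)
    list(z_init)
  } else {
    with_seed(seed, lapply(seq_len(n_starts), function(s)
      kmeanspp_responsibilities(x, G)))
  }

  best <- NULL
  errors <- character(0)
  for (z0 in starts) {
    run <- tryCatch(.gpcm_em(x, G, model, z0, tol, max_iter, floor_val),
                    gpcm_degenerate = function(e) e)
    if (inherits(run, "condition")) {
      errors <- c(errors, conditionMessage(run))
      next
    }
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best))
    stop("all ", length(starts), " starts degenerate for G=", G, " ",
         model, ": ", errors[1L])

  m <- .gpcm_nparams(model, G, p)
  decomp <- lapply(best$par$Sigma, function(S) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    lam <- prod(e$values)^(1 / p)
    list(lambda = lam, shape = e$values / lam, orientation = e$vectors)
  })
  structure(list(G = G, model = model, pi = best$par$pi, mu = best$par$mu,
                 Sigma = best$par$Sigma,
                 lambda = vapply(decomp, `[[`, 0, "lambda"),
                 shape = lapply(decomp, `[[`, "shape"),
                 orientation = lapply(decomp, `[[`, "orientation"),
                 z = best$z, loglik = best$loglik,
                 loglik_trace = best$trace, n_params = m,
                 bic = 2 * best$loglik - m * log(n), n = n, p = p,
                 iter = best$iter, converged = best$converged,
                 regularized = best$regularized),
            class = "gpcm_fit")
}

#' @export
print.gpcm_fit <- function(x, ...) {
  cat(sprintf("gpcm_fit: model %s, G = %d, n = %d, p = %d\n",
              x$model, x$G, x$n, x$p))
  cat(sprintf("  loglik = %.4f  params = %d  BIC = %.4f\n",
              x$loglik, x$n_params, x$bic))
  invisible(x)
}

#' BIC of a fitted mixture model
#'
#' Uses the maximized convention `2*loglik - m*log(n)`: larger is better.
#'
#' @param fit A `gpcm_fit` or `pgmm_fit`.
#' @param n Sample size (default: taken from the fit).
#' @return The BIC value.
#' @export
bic_of <- function(fit, n = fit$n) {
  if (is.null(n) || n <= 0) stop("n must be positive")
  2 * fit$loglik - fit$n_params * log(n)
}

#' Fit a grid of GPCMs and select by BIC
#'
#' Fits every (G, model) pair, skipping cells with too few observations
#' (`n < G * (p + 1)` is flagged `unfitted`), and returns the BIC-maximizing
#' fit together with the full grid. Ties are broken toward smaller `G`, then
#' toward the simpler model (order of [gpcm_models()]).
#'
#' @param x Observations x variables matrix.
#' @param G_range Integer vector of component counts (default `1:9`).
#' @param model_set Subset of [gpcm_models()] (default: all eight).
#' @param n_starts,seed,tol,max_iter Passed to [fit_gpcm()]; each grid cell
#'   gets a deterministic seed derived from `seed`.
#' @return List of class `gpcm_selection`: `best` (the winning `gpcm_fit`)
#'   and `grid` (data frame of G, model, loglik, n_params, bic, status).
#' @export
select_model <- function(x, G_range = 1:9, model_set = gpcm_models(),
                         n_starts = 10, seed = NULL, tol = 1e-8,
                         max_iter = 500) {
  x <- as.matrix(x)
  if (length(G_range) == 0L) stop("G_range must be non-empty")
  stopifnot(all(model_set %in% gpcm_models()))
  n <- nrow(x); p <- ncol(x)
  grid <- expand.grid(G = sort(unique(as.integer(G_range))),
                      model = model_set, stringsAsFactors = FALSE)
  grid$loglik <- NA_real_; grid$n_params <- NA_integer_
  grid$bic <- NA_real_; grid$status <- "unfitted"
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    G <- grid$G[i]; model <- grid$model[i]
    if (n < G * (p + 1)) next  # too few observations for this G
    cell_seed <- if (is.null(seed)) NULL else seed + 7907L * i
    f <- tryCatch(fit_gpcm(x, G, model, n_starts = n_starts,
                           seed = cell_seed, tol = tol,
                           max_iter = max_iter),
                  error = function(e) e)
    if (inherits(f, "error")) {
      grid$status[i] <- "degenerate"
      next
    }
    fits[[i]] <- f
    grid$loglik[i] <- f$loglik
    grid$n_params[i] <- f$n_params
    grid$bic[i] <- f$bic
    grid$status[i] <- "fitted"
  }
  ok <- which(grid$status == "fitted")
  if (length(ok) == 0L) {
    err <- simpleError("no (G, model) cell could be fitted")
    err$grid <- grid
    stop(err)
  }
  # argmax BIC; ties toward smaller G then simpler model
  ord <- ok[order(-grid$bic[ok], grid$G[ok],
                  match(grid$model[ok], gpcm_models()))]
  structure(list(best = fits[[ord[1L]]], grid = grid),
            class = "gpcm_selection")
}

#' @export
print.gpcm_selection <- function(x, ...) {
  cat("gpcm_selection; best fit:\n")
  print(x$best)
  invisible(x)
}

#' Hard cluster labels from a fitted mixture
#'
#' Maximum-responsibility assignment; ties go to the lowest component index.
#'
#' @param fit A `gpcm_fit` or `pgmm_fit`.
#' @return Integer vector of labels in `1:G`.
#' @export
predict_labels <- function(fit) {
  max.col(fit$z, ties.method = "first")
}
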