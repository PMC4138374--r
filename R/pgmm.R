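# Parsimonious Gaussian mixture models: mixtures of factor analyzers with
# component covariance Sigma_g = Lambda_g Lambda_g^T + Psi_g (Lambda p x q
# loadings, Psi diagonal noise), fitted by alternating expectation-
# conditional maximization (AECM). Constraint codes follow the
# (loadings common?, noise common?, noise isotropic?) convention; UUU (fully
# unconstrained) and UUC (isotropic per-component noise) are implemented.
# Loadings are identifiable only up to rotation, so results should be
# compared through Lambda Lambda^T + Psi, never element-wise.

.pgmm_constraints <- c("UUU", "UUC")

# Largest admissible latent dimension for p observed variables.
pgmm_q_max <- function(p) p - 2L

# Woodbury inverse and log-determinant of Lambda Lambda^T + diag(psi)
.lowrank_inv <- function(Lambda, psi) {
  p <- nrow(Lambda); q <- ncol(Lambda)
  PiL <- Lambda / psi                      # Psi^{-1} Lambda
  M <- diag(q) + crossprod(Lambda, PiL)    # I_q + Lambda^T Psi^{-1} Lambda
  ch <- chol(M)
  inv <- diag(1 / psi, p) - PiL %*% chol2inv(ch) %*% t(PiL)
  list(inv = inv, logdet = sum(log(psi)) + 2 * sum(log(diag(ch))))
}

.pgmm_logdens <- function(x, mu, Lambda, Psi) {
  n <- nrow(x); p <- ncol(x); G <- nrow(mu)
  ld <- matrix(0, n, G)
  for (g in seq_len(G)) {
    wb <- .lowrank_inv(Lambda[[g]], Psi[[g]])
    xc <- sweep(x, 2L, mu[g, ], "-")
    quad <- rowSums((xc %*% wb$inv) * xc)
    ld[, g] <- -0.5 * (p * log(2 * pi) + wb$logdet + quad)
  }
  ld
}

.pgmm_estep <- function(x, pi_g, mu, Lambda, Psi) {
  lp <- sweep(.pgmm_logdens(x, mu, Lambda, Psi), 2L, log(pi_g), "+")
  mx <- apply(lp, 1L, max)
  lse <- mx + log(rowSums(exp(lp - mx)))
  list(z = exp(lp - lse), loglik = sum(lse))
}

# initial loadings/noise from the component scatter eigen-structure
.pgmm_init_cov <- function(S, q, floor_val, constraint) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  p <- nrow(S)
  resid <- if (q < p) mean(e$values[(q + 1L):p]) else floor_val
  scale <- sqrt(pmax(e$values[seq_len(q)] - resid, floor_val))
  Lambda <- e$vectors[, seq_len(q), drop = FALSE] %*% diag(scale, q)
  psi <- pmax(diag(S - tcrossprod(Lambda)), floor_val)
  if (constraint == "UUC") psi <- rep.int(mean(psi), p)
  list(Lambda = Lambda, psi = psi)
}

.pgmm_aecm <- function(x, G, q, constraint, z0, tol, max_iter, floor_val) {
  n <- nrow(x); p <- ncol(x)
  ns <- colSums(z0)
  if (any(ns < 1)) stop_degenerate("vanishing component weight at init")
  pi_g <- ns / n
  mu <- t(crossprod(x, z0)) / ns
  Lambda <- vector("list", G); Psi <- vector("list", G)
  for (g in seq_len(G)) {
    xc <- sweep(x, 2L, mu[g, ], "-")
    S <- crossprod(xc, xc * z0[, g]) / ns[g]
    ini <- .pgmm_init_cov(S, q, floor_val, constraint)
    Lambda[[g]] <- ini$Lambda; Psi[[g]] <- ini$psi
  }

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  z <- z0
  for (cycle in seq_len(max_iter)) {
    # --- cycle 1: update pi, mu -------------------------------------------
    e1 <- .pgmm_estep(x, pi_g, mu, Lambda, Psi)
    trace <- c(trace, e1$loglik)
    if (is.finite(ll_old) &&
        abs(e1$loglik - ll_old) <= tol * (abs(e1$loglik) + 1e-3)) {
      converged <- TRUE
      z <- e1$z
      break
    }
    ll_old <- e1$loglik
    ns <- colSums(e1$z)
    if (any(ns < 1)) stop_degenerate("vanishing component weight")
    pi_g <- ns / n
    mu <- t(crossprod(x, e1$z)) / ns
    # --- cycle 2: update Lambda, Psi given new pi, mu ---------------------
    e2 <- .pgmm_estep(x, pi_g, mu, Lambda, Psi)
    ns2 <- colSums(e2$z)
    if (any(ns2 < 1)) stop_degenerate("vanishing component weight")
    for (g in seq_len(G)) {
      xc <- sweep(x, 2L, mu[g, ], "-")
      S <- crossprod(xc, xc * e2$z[, g]) / ns2[g]
      wb <- .lowrank_inv(Lambda[[g]], Psi[[g]])
      beta <- crossprod(Lambda[[g]], wb$inv)            # q x p
      Theta <- diag(q) - beta %*% Lambda[[g]] + beta %*% S %*% t(beta)
      Lam_new <- S %*% t(beta) %*% solve(Theta)
      psi <- pmax(diag(S - Lam_new %*% beta %*% S), floor_val)
      if (constraint == "UUC") psi <- rep.int(mean(psi), p)
      Lambda[[g]] <- Lam_new; Psi[[g]] <- psi
    }
    z <- e2$z
  }
  final <- .pgmm_estep(x, pi_g, mu, Lambda, Psi)
  list(pi = pi_g, mu = mu, Lambda = Lambda, Psi = Psi, z = final$z,
       loglik = final$loglik, trace = c(trace, final$loglik),
       iter = length(trace), converged = converged)
}

.pgmm_nparams <- function(constraint, G, q, p) {
  load_params <- G * (p * q - q * (q - 1) / 2)  # up-to-rotation count
  noise_params <- switch(constraint, UUU = G * p, UUC = G,
                         stop("unsupported constraint: ", constraint))
  (G - 1) + G * p + load_params + noise_params
}

#' Fit a parsimonious Gaussian mixture model (mixture of factor analyzers)
#'
#' @param x Observations x variables matrix (p >= 3).
#' @param G Number of components.
#' @param q Latent factor dimension, `1 <= q <= p - 2` (so `q <= 2` for the
#'   4-condition profiles).
#' @param constraint `"UUU"` (unconstrained loadings and diagonal noise, the
#'   default) or `"UUC"` (isotropic per-component noise).
#' @param n_starts,seed,tol,max_iter As in [fit_gpcm()]; `max_iter` counts
#'   AECM cycles.
#' @param z_init Optional deterministic starting responsibilities.
#' @return An object of class `pgmm_fit` with `pi`, `mu`, `Lambda` (list of
#'   p x q loadings), `Psi` (list of diagonal noise vectors), `Sigma`
#'   (implied covariances), responsibilities `z`, `loglik`, `loglik_trace`
#'   (one value per AECM cycle), `n_params`, `bic`.
#' @export
fit_pgmm <- function(x, G, q = 1, constraint = "UUU", n_starts = 10,
                     seed = NULL, tol = 1e-8, max_iter = 500,
                     z_init = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (!constraint %in% .pgmm_constraints)
    stop("unsupported constraint: ", constraint,
         " (implemented: ", paste(.pgmm_constraints, collapse = ", "), ")")
  if (p < 3L) stop("PGMM requires at least 3 variables")
  if (q < 1L || q > pgmm_q_max(p))
    stop("q must lie in 1..", pgmm_q_max(p), " for p = ", p)
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
    run <- tryCatch(.pgmm_aecm(x, G, q, constraint, z0, tol, max_iter,
                               floor_val),
                    gpcm_degenerate = function(e) e)
    if (inherits(run, "condition")) {
      errors <- c(errors, conditionMessage(run))
      next
    }
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best))
    stop("all ", length(starts), " starts degenerate for G=", G, " q=", q,
         ": ", errors[1L])
  m <- .pgmm_nparams(constraint, G, q, p)
  Sigma <- Map(function(L, psi) tcrossprod(L) + diag(psi, p),
               best$Lambda, best$Psi)
  structure(list(G = G, q = q, constraint = constraint, pi = best$pi,
                 mu = best$mu, Lambda = best$Lambda, Psi = best$Psi,
                 Sigma = Sigma, z = best$z, loglik = best$loglik,
                 loglik_trace = best$trace, n_params = m,
                 bic = 2 * best$loglik - m * log(n), n = n, p = p,
                 iter = best$iter, converged = best$converged),
            class = "pgmm_fit")
}

#' @export
print.pgmm_fit <- function(x, ...) {
  cat(sprintf("pgmm_fit: constraint %s, G = %d, q = %d, n = %d, p = %d\n",
              x$constraint, x$G, x$q, x$n, x$p))
  cat(sprintf("  loglik = %.4f  params = %d  BIC = %.4f\n",
              x$loglik, x$n_params, x$bic))
  invisible(x)
}

#' Fit a grid of PGMMs and select by BIC
#'
#' @param x Observations x variables matrix.
#' @param G_range,q_range Integer grids; cells with `q > p - 2` or too few
#'   observations (`n < G * (p + 1)`) are flagged infeasible and not fitted.
#' @param constraints Subset of the implemented constraint codes.
#' @param n_starts,seed,tol,max_iter Passed to [fit_pgmm()].
#' @return List of class `pgmm_selection`: `best` and `grid`.
#' @export
select_pgmm <- function(x, G_range = 1:9, q_range = 1, constraints = "UUU",
                        n_starts = 10, seed = NULL, tol = 1e-8,
                        max_iter = 500) {
  x <- as.matrix(x)
  if (length(G_range) == 0L || length(q_range) == 0L)
    stop("G_range and q_range must be non-empty")
  n <- nrow(x); p <- ncol(x)
  grid <- expand.grid(G = sort(unique(as.integer(G_range))),
                      q = sort(unique(as.integer(q_range))),
                      constraint = constraints, stringsAsFactors = FALSE)
  grid$loglik <- NA_real_; grid$n_params <- NA_integer_
  grid$bic <- NA_real_; grid$status <- "unfitted"
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (grid$q[i] > pgmm_q_max(p)) {
      grid$status[i] <- "infeasible"
      next
    }
    if (n < grid$G[i] * (p + 1)) next
    cell_seed <- if (is.null(seed)) NULL else seed + 104729L * i
    f <- tryCatch(fit_pgmm(x, grid$G[i], grid$q[i], grid$constraint[i],
                           n_starts = n_starts, seed = cell_seed, tol = tol,
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
    err <- simpleError("no (G, q, constraint) cell could be fitted")
    err$grid <- grid
    stop(err)
  }
  ord <- ok[order(-grid$bic[ok], grid$G[ok], grid$q[ok])]
  structure(list(best = fits[[ord[1L]]], grid = grid),
            class = "pgmm_selection")
}
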