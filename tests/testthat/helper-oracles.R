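# Independent oracles, coded naively and kept free of the package's own
# fitting paths.

# Naive full-covariance (VVV) mixture EM: plain loops, direct solve()/det(),
# same update order as the package (M-step from the starting
# responsibilities, then E-step; log-likelihood recorded at each E-step).
naive_vvv_em <- function(x, z0, max_iter = 50) {
  n <- nrow(x); p <- ncol(x); G <- ncol(z0)
  z <- z0
  trace <- numeric(0)
  pi_g <- numeric(G); mu <- matrix(0, G, p); Sigma <- vector("list", G)
  for (it in seq_len(max_iter)) {
    ns <- colSums(z)
    pi_g <- ns / n
    for (g in seq_len(G)) {
      mu[g, ] <- colSums(x * z[, g]) / ns[g]
      S <- matrix(0, p, p)
      for (i in seq_len(n)) {
        d <- x[i, ] - mu[g, ]
        S <- S + z[i, g] * tcrossprod(d)
      }
      Sigma[[g]] <- S / ns[g]
    }
    dens <- matrix(0, n, G)
    for (g in seq_len(G)) {
      Sinv <- solve(Sigma[[g]])
      dt <- det(Sigma[[g]])
      for (i in seq_len(n)) {
        d <- x[i, ] - mu[g, ]
        dens[i, g] <- pi_g[g] * exp(-0.5 * drop(t(d) %*% Sinv %*% d)) /
          sqrt((2 * pi)^p * dt)
      }
    }
    tot <- rowSums(dens)
    trace <- c(trace, sum(log(tot)))
    z <- dens / tot
  }
  trace
}

# Brute-force optimal 2-means: enumerate every 2-partition, minimize WCSS.
brute_kmeans2 <- function(points) {
  n <- nrow(points)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {  # fix point 1 in cluster 1
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (length(unique(lab)) < 2L) next
    c1 <- colMeans(points[lab == 1L, , drop = FALSE])
    c2 <- colMeans(points[lab == 2L, , drop = FALSE])
    wcss <- sum((points - rbind(c1, c2)[lab, , drop = FALSE])^2)
    if (is.null(best) || wcss < best$wcss)
      best <- list(labels = lab, centers = rbind(c1, c2), wcss = wcss)
  }
  best
}

# Hand step-up BH adjustment.
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}
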