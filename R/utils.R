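# Shared internals: seeded evaluation that leaves the global RNG untouched,
# k-means++ seeding, and the adjusted Rand index used by the simulation
# studies.

# Evaluate expr under a fixed RNG seed without disturbing .Random.seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# k-means++ seeding: returns k row indices of x. Assumes RNG already seeded.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1L], ], "-")^2)
  if (k > 1L) for (j in 2L:k) {
    if (all(d2 == 0)) {
      idx[j] <- sample.int(n, 1L)
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j], ], "-")^2))
  }
  idx
}

# Hard k-means++ assignment converted to one-hot responsibilities (n x G).
kmeanspp_responsibilities <- function(x, G) {
  n <- nrow(x)
  centers <- x[kmeanspp_centers(x, G), , drop = FALSE]
  d <- vapply(seq_len(G),
              function(g) rowSums(sweep(x, 2L, centers[g, ], "-")^2),
              numeric(n))
  lab <- max.col(-matrix(d, nrow = n), ties.method = "first")
  # guarantee every component is non-empty
  for (g in seq_len(G)) {
    if (!any(lab == g)) lab[which.max(d[, if (g > 1) g - 1 else g])] <- g
  }
  z <- matrix(0, n, G)
  z[cbind(seq_len(n), lab)] <- 1
  z
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), ~0 for independent ones.
#' Used throughout the simulation studies to score cluster recovery against
#' planted labels.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return The adjusted Rand index (scalar).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(NaN)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)  # both partitions trivial
  (nij - expected) / (mx - expected)
}
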