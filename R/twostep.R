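# The two-step clustering strategy: step 1 clusters the 4-condition mean
# profiles with a mixture engine (GPCM or PGMM, BIC-selected); step 2 splits
# each component's profiles by planting density into two 2-dimensional
# (SN, LN) data sets and clusters each with k = 2 (k-means or a G = 2 GPCM).
# A gene whose nitrogen-response sub-cluster differs between the densities
# (after matching the sub-clusters across densities) is flagged discordant.

#' Split component profiles by planting density
#'
#' Rearranges 4-condition profiles into the two 2-dimensional data sets of
#' the second clustering step: per gene, the LD pair `(LDSN, LDLN)` and the
#' HD pair `(HDSN, HDLN)` - expression under sufficient and limiting
#' nitrogen within each density.
#'
#' @param profiles Matrix with columns `condition_levels()` (e.g. a
#'   component's rows of [condition_means()]).
#' @return List with matrices `ld` and `hd`, each n x 2 with columns
#'   `SN`, `LN`.
#' @export
split_by_density <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (!all(condition_levels() %in% colnames(profiles)))
    stop("profiles must have columns ", paste(condition_levels(),
                                              collapse = ", "))
  mk <- function(cols) {
    m <- profiles[, cols, drop = FALSE]
    colnames(m) <- c("SN", "LN")
    m
  }
  list(ld = mk(c("LDSN", "LDLN")), hd = mk(c("HDSN", "HDLN")))
}

#' Two-means clustering (Lloyd's algorithm from k-means++ starts)
#'
#' Best of `n_starts` runs by within-cluster sum of squares. When all points
#' coincide the convention is a single effective cluster: all labels 1 and
#' both centers equal.
#'
#' @param points n x d numeric matrix, n >= 2.
#' @param seed Integer seed for the starts.
#' @param n_starts Number of restarts (default 10).
#' @return List with `labels` (1/2), `centers` (2 x d) and `wcss`.
#' @export
kmeans2 <- function(points, seed = NULL, n_starts = 10) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("kmeans2 needs at least 2 points")
  if (all(apply(points, 2L, function(v) diff(range(v)) == 0))) {
    return(list(labels = rep.int(1L, n),
                centers = rbind(points[1L, ], points[1L, ]), wcss = 0))
  }
  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      centers0 <- points[kmeanspp_centers(points, 2L), , drop = FALSE]
      km <- tryCatch(suppressWarnings(
        stats::kmeans(points, centers = centers0, iter.max = 100L,
                      algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) {  # every start collapsed to one cluster
      list(labels = rep.int(1L, n),
           centers = rbind(colMeans(points), colMeans(points)),
           wcss = sum(scale(points, scale = FALSE)^2))
    } else {
      list(labels = as.integer(best$cluster), centers = best$centers,
           wcss = best$tot.withinss)
    }
  })
}

# Accept a 2-cluster split only when the centers are separated relative to
# the within-cluster spread; otherwise the data carry a single trend and a
# forced split would only partition noise.
.split_supported <- function(points, labels, centers, min_sep = 3) {
  if (length(unique(labels)) < 2L) return(FALSE)
  wcss <- sum((points - centers[labels, , drop = FALSE])^2)
  within_rms <- sqrt(wcss / (length(labels) * ncol(points)))
  sep <- sqrt(sum((centers[1L, ] - centers[2L, ])^2))
  if (within_rms == 0) return(sep > 0)
  sep / within_rms > min_sep
}

# Match density-B 2-cluster labels onto density-A labels. "centers" matches
# the clusters whose centers show the same nitrogen response (LN - SN);
# "membership" minimizes Hamming disagreement (ties to identity).
.match_step2 <- function(labels_a, centers_a, labels_b, centers_b,
                         match = c("centers", "membership")) {
  match <- match.arg(match)
  if (match == "centers") {
    resp_a <- centers_a[, "LN"] - centers_a[, "SN"]
    resp_b <- centers_b[, "LN"] - centers_b[, "SN"]
    cost_id <- abs(resp_a[1L] - resp_b[1L]) + abs(resp_a[2L] - resp_b[2L])
    cost_sw <- abs(resp_a[1L] - resp_b[2L]) + abs(resp_a[2L] - resp_b[1L])
    swap <- cost_sw < cost_id
  } else {
    dis_id <- sum(labels_a != labels_b)
    dis_sw <- sum(labels_a != (3L - labels_b))
    swap <- dis_sw < dis_id
  }
  if (swap) 3L - labels_b else labels_b
}

#' Run the two-step clustering strategy
#'
#' Step 1 clusters the 4-condition profiles with the chosen engine under BIC
#' selection. Step 2, per component: the profiles are split by density
#' ([split_by_density()]), each density's (SN, LN) pairs are clustered into
#' two groups (k-means or a G = 2 GPCM, per strategy), the sub-clusters are
#' matched across densities by their nitrogen response, and each gene whose
#' matched sub-cluster differs between densities is flagged discordant.
#' Components with fewer than 4 genes, or whose 2-group split is not
#' supported under either density (center separation below `min_sep` times
#' the within-cluster spread), are reported unsplit with all flags `FALSE`.
#'
#' @param profiles Genes x 4 matrix with columns `condition_levels()`
#'   (typically [condition_means()] on the density-specific gene set).
#' @param strategy One of `"gpcm-kmeans"` (default), `"pgmm-kmeans"`,
#'   `"gpcm-gpcm"`, `"pgmm-gpcm"`: the step-1 engine and the step-2 method.
#' @param step1 List of arguments for the step-1 selection
#'   ([select_model()] or [select_pgmm()]): `G_range`, `model_set` /
#'   `constraints`, `q_range`, `n_starts`, `tol`, `max_iter`.
#' @param seed Integer seed for both steps.
#' @param match Sub-cluster matching rule: `"centers"` (default; match by
#'   nitrogen response of the cluster centers) or `"membership"` (minimal
#'   Hamming disagreement, ties to identity).
#' @param min_sep Split-acceptance threshold (default 3; see Details).
#' @return Object of class `two_step_result`: `strategy`, `step1` (the
#'   selection object), `assignments` (data frame: `gene_id`, `component`,
#'   `hd_sublabel`, `ld_sublabel`, `discordant`), and `components` (per
#'   component: size, whether step 2 ran, the step-2 centers).
#' @export
run_two_step <- function(profiles,
                         strategy = c("gpcm-kmeans", "pgmm-kmeans",
                                      "gpcm-gpcm", "pgmm-gpcm"),
                         step1 = list(), seed = NULL,
                         match = c("centers", "membership"), min_sep = 3) {
  strategy <- match.arg(strategy)
  match <- match.arg(match)
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("g", seq_len(nrow(profiles)))
  engine1 <- if (startsWith(strategy, "gpcm")) "gpcm" else "pgmm"
  engine2 <- if (endsWith(strategy, "kmeans")) "kmeans" else "gpcm"

  s1_args <- utils::modifyList(
    list(x = profiles, seed = seed),
    step1)
  sel <- if (engine1 == "gpcm") do.call(select_model, s1_args)
         else do.call(select_pgmm, s1_args)
  labels1 <- predict_labels(sel$best)
  G1 <- sel$best$G

  cluster2 <- function(points, sub_seed) {
    if (engine2 == "kmeans") {
      km <- kmeans2(points, seed = sub_seed)
      list(labels = km$labels, centers = km$centers)
    } else {
      f <- tryCatch({
        models <- c("EII", "VII", "EEI", "VVI", "EEE", "VVV")
        fits <- lapply(models, function(mod)
          tryCatch(fit_gpcm(points, G = 2L, model = mod, n_starts = 5,
                            seed = sub_seed),
                   error = function(e) NULL))
        fits <- Filter(Negate(is.null), fits)
        if (length(fits) == 0L) NULL
        else fits[[which.max(vapply(fits, `[[`, 0, "bic"))]]
      }, error = function(e) NULL)
      if (is.null(f)) return(NULL)
      lab <- predict_labels(f)
      list(labels = lab, centers = f$mu)
    }
  }

  gene_ids <- rownames(profiles)
  assignments <- data.frame(gene_id = gene_ids, component = labels1,
                            hd_sublabel = NA_integer_,
                            ld_sublabel = NA_integer_,
                            discordant = FALSE, stringsAsFactors = FALSE)
  comp_info <- vector("list", G1)
  for (g in seq_len(G1)) {
    idx <- which(labels1 == g)
    info <- list(component = g, size = length(idx), split = FALSE,
                 reason = NULL)
    if (length(idx) < 4L) {      # fewer than 2*k genes: skip step 2
      info$reason <- "too small"
      comp_info[[g]] <- info
      next
    }
    pairs <- split_by_density(profiles[idx, , drop = FALSE])
    sub_seed <- if (is.null(seed)) NULL else seed + 1009L * g
    hd <- cluster2(pairs$hd, sub_seed)
    ld <- cluster2(pairs$ld,
                   if (is.null(sub_seed)) NULL else sub_seed + 1L)
    if (is.null(hd) || is.null(ld)) {
      info$reason <- "unsplittable"
      comp_info[[g]] <- info
      next
    }
    colnames(hd$centers) <- colnames(ld$centers) <- c("SN", "LN")
    ok_hd <- .split_supported(pairs$hd, hd$labels, hd$centers, min_sep)
    ok_ld <- .split_supported(pairs$ld, ld$labels, ld$centers, min_sep)
    if (!ok_hd || !ok_ld) {
      info$reason <- "single trend"
      comp_info[[g]] <- info
      next
    }
    ld_matched <- .match_step2(hd$labels, hd$centers, ld$labels, ld$centers,
                               match = match)
    assignments$hd_sublabel[idx] <- hd$labels
    assignments$ld_sublabel[idx] <- ld_matched
    assignments$discordant[idx] <- hd$labels != ld_matched
    info$split <- TRUE
    info$hd_centers <- hd$centers
    info$ld_centers <- ld$centers
    comp_info[[g]] <- info
  }
  structure(list(strategy = strategy, step1 = sel,
                 assignments = assignments, components = comp_info,
                 match = match, min_sep = min_sep),
            class = "two_step_result")
}

#' @export
print.two_step_result <- function(x, ...) {
  cat(sprintf("two_step_result (%s): %d genes, %d step-1 components\n",
              x$strategy, nrow(x$assignments), x$step1$best$G))
  split <- vapply(x$components, `[[`, FALSE, "split")
  cat(sprintf("  components split in step 2: %d of %d; discordant genes: %d\n",
              sum(split), length(split), sum(x$assignments$discordant)))
  invisible(x)
}
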