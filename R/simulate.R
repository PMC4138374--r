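# Seeded generators for every input type the pipeline consumes. The
# expression generator inverts the mixture model the clustering assumes:
# per-gene latent 4-condition profiles drawn from a Gaussian mixture, flat
# "null" profiles for the unresponsive bulk of the transcriptome, optional
# density-discordant genes whose low-nitrogen offset is applied under only
# one planting density, and i.i.d. Gaussian replicate noise on the log2
# scale. All generators are pure in their seed: the global RNG state is
# saved and restored.

#' Canonical cluster mean profiles
#'
#' Builds `K` condition-mean profiles (log2 scale, order
#' `LDSN, LDLN, HDSN, HDLN`) as a baseline plus additive high-density and
#' low-nitrogen effects, cycling through the eight sign patterns of
#' (enhanced/suppressed by density) x (none/enhanced/suppressed by nitrogen)
#' that the cluster analysis is designed to separate.
#'
#' @param K Number of profiles (default 8, the number of clusters selected at
#'   the 21-day timepoint in the motivating experiment).
#' @param baseline Baseline log2 expression (default 8).
#' @param effect Absolute log2 effect size for each applied stress
#'   (default 2).
#' @return A `K x 4` matrix with column names `condition_levels()`.
#' @export
default_profile_means <- function(K = 8, baseline = 8, effect = 2) {
  hd_pattern <- c(0, 0, 1, 1)  # applies to HDSN, HDLN
  ln_pattern <- c(0, 1, 0, 1)  # applies to LDLN, HDLN
  signs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  signs <- signs[rep_len(seq_len(nrow(signs)), K), , drop = FALSE]
  out <- t(vapply(seq_len(K), function(k) {
    baseline + effect * (signs[k, 1L] * hd_pattern + signs[k, 2L] * ln_pattern)
  }, numeric(4L)))
  colnames(out) <- condition_levels()
  out
}

#' Configuration for the expression generator
#'
#' Defaults mirror the structure of the motivating four-condition rice
#' experiment: ~21,179 genes, 4 conditions, 3 replicates per condition at a
#' timepoint, most of the transcriptome unresponsive, and a handful of
#' responsive expression-profile clusters.
#'
#' @param n_genes Number of genes (default 21179).
#' @param n_replicates Replicates per condition (default 3).
#' @param K_true Number of planted cluster profiles (default 8).
#' @param profile_means `K_true x 4` matrix of log2 condition means in the
#'   order `condition_levels()`; default [default_profile_means()].
#' @param covariance_model Name of the planted component covariance model
#'   (one of the GPCM codes, see [fit_gpcm()]); only used to describe the
#'   scatter when `covariance_params` is a list of matrices.
#' @param covariance_params Gene-level scatter around the component mean:
#'   either a single number (the standard deviation of spherical scatter,
#'   default 0.5) or a list of `K_true` 4x4 covariance matrices.
#' @param frac_null Fraction of genes with flat (condition-independent)
#'   profiles (default 0.9: most of the transcriptome does not respond).
#' @param frac_discordant Fraction of the clustered genes whose low-nitrogen
#'   offset is applied under only one (randomly chosen) density
#'   (default 0).
#' @param noise_sd Replicate-level log2 standard deviation (default 0.5).
#' @param timepoint Timepoint label for the generated samples (default 21).
#' @param seed Integer seed; mandatory.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 21179, n_replicates = 3, K_true = 8,
                       profile_means = default_profile_means(K_true),
                       covariance_model = "EII", covariance_params = 0.5,
                       frac_null = 0.9, frac_discordant = 0,
                       noise_sd = 0.5, timepoint = 21, seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  profile_means <- as.matrix(profile_means)
  if (K_true < 1) stop("K_true must be >= 1")
  if (nrow(profile_means) != K_true || ncol(profile_means) != 4L)
    stop("profile_means must be a K_true x 4 matrix")
  if (frac_null < 0 || frac_null > 1 || frac_discordant < 0 ||
      frac_discordant > 1)
    stop("frac_null and frac_discordant must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.list(covariance_params)) {
    if (length(covariance_params) != K_true)
      stop("covariance_params list must have one matrix per component")
  } else if (!(is.numeric(covariance_params) &&
               length(covariance_params) == 1L && covariance_params >= 0)) {
    stop("covariance_params must be a single sd >= 0 or a list of matrices")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 K_true = as.integer(K_true), profile_means = profile_means,
                 covariance_model = covariance_model,
                 covariance_params = covariance_params,
                 frac_null = frac_null, frac_discordant = frac_discordant,
                 noise_sd = noise_sd, timepoint = as.integer(timepoint),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a four-condition expression matrix with planted structure
#'
#' Each clustered gene receives a latent 4-condition profile equal to its
#' component mean plus component-covariance scatter; discordant genes first
#' have the low-nitrogen offset of their component removed under one density
#' (so their nitrogen response exists under the other density only). Null
#' genes get flat profiles at a gene-specific baseline. Observed replicate
#' values are the latent condition value plus independent
#' `N(0, noise_sd^2)` noise.
#'
#' @param cfg A [sim_config()].
#' @return A list: `expr` (an [expression_matrix()]), `labels` (integer
#'   component per gene, 0 for null genes), `discordant` (logical),
#'   `discordant_side` (`"HD"`/`"LD"`/`NA`: the density under which the
#'   nitrogen offset was kept), and `latent` (the genes x 4 latent profile
#'   matrix).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  conds <- condition_levels()
  sample_meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                             condition = conds, stringsAsFactors = FALSE)
  sample_meta <- data.frame(
    sample_id = paste0(sample_meta$condition, "_", cfg$timepoint, "_r",
                       sample_meta$replicate),
    density = substr(sample_meta$condition, 1L, 2L),
    nitrogen = substr(sample_meta$condition, 3L, 4L),
    timepoint = cfg$timepoint,
    replicate = sample_meta$replicate,
    stringsAsFactors = FALSE)

  if (n == 0L) {
    values <- matrix(numeric(0), 0L, nrow(sample_meta),
                     dimnames = list(character(0), sample_meta$sample_id))
    return(list(expr = expression_matrix(values, sample_meta),
                labels = integer(0), discordant = logical(0),
                discordant_side = character(0),
                latent = matrix(numeric(0), 0L, 4L,
                                dimnames = list(NULL, conds))))
  }

  n_null <- round(cfg$frac_null * n)
  n_clustered <- n - n_null
  if (n_clustered < cfg$K_true)
    stop("K_true (", cfg$K_true, ") exceeds the ", n_clustered,
         " genes left after null allocation")

  with_seed(cfg$seed, {
    gene_ids <- sprintf("g%05d", seq_len(n))
    labels <- c(rep.int(0L, n_null),
                sample.int(cfg$K_true, n_clustered, replace = TRUE))
    latent <- matrix(0, n, 4L, dimnames = list(gene_ids, conds))
    baseline <- mean(cfg$profile_means)

    discordant <- rep.int(FALSE, n)
    side <- rep.int(NA_character_, n)
    clustered_idx <- which(labels > 0L)
    n_disc <- round(cfg$frac_discordant * length(clustered_idx))
    if (n_disc > 0L) {
      pick <- sample(clustered_idx, n_disc)
      discordant[pick] <- TRUE
      side[pick] <- sample(c("HD", "LD"), n_disc, replace = TRUE)
    }

    # component scatter generators (chol factors, zero matrix allowed)
    chols <- lapply(seq_len(cfg$K_true), function(k) {
      if (is.list(cfg$covariance_params)) {
        chol(as.matrix(cfg$covariance_params[[k]]))
      } else if (cfg$covariance_params > 0) {
        diag(cfg$covariance_params, 4L)
      } else {
        NULL
      }
    })

    for (i in seq_len(n)) {
      if (labels[i] == 0L) {
        latent[i, ] <- rep.int(stats::rnorm(1L, baseline, 1), 4L)
        next
      }
      mu <- cfg$profile_means[labels[i], ]
      if (discordant[i]) {
        # keep the LN offset under `side` only; flatten it under the other
        if (side[i] == "HD") mu[2L] <- mu[1L]  # remove LD nitrogen offset
        else mu[4L] <- mu[3L]                  # remove HD nitrogen offset
      }
      if (!is.null(chols[[labels[i]]]))
        mu <- mu + drop(stats::rnorm(4L) %*% chols[[labels[i]]])
      latent[i, ] <- mu
    }

    sample_conds <- paste0(sample_meta$density, sample_meta$nitrogen)
    values <- latent[, sample_conds, drop = FALSE] +
      matrix(stats::rnorm(n * nrow(sample_meta), 0, cfg$noise_sd),
             n, nrow(sample_meta))
    colnames(values) <- sample_meta$sample_id

    list(expr = expression_matrix(values, sample_meta), labels = labels,
         discordant = discordant, discordant_side = side, latent = latent)
  })
}

#' Simulate a qPCR Ct table from known fold changes
#'
#' Inverts the 2^-ddCt formula under perfect amplification efficiency
#' (doubling per cycle): the target Ct is `base_ct - log2(fold) + noise` and
#' the reference-gene Ct is constant across conditions up to noise, so the
#' planted folds are exactly recoverable by [ddct_folds()] at zero noise.
#'
#' @param fold_changes Numeric matrix of planted linear fold changes relative
#'   to the calibrator condition: rownames = target genes, colnames =
#'   conditions (must include `calibrator`, typically with fold 1).
#' @param base_ct Target-gene Ct at the calibrator (default 24 cycles);
#'   recycled across genes.
#' @param ref_ct Reference-gene Ct (default 18 cycles).
#' @param n_replicates Replicates per condition (default 3).
#' @param noise_sd Ct measurement noise SD in cycles (default 0.2).
#' @param calibrator Calibrator condition (default `"LDSN"`).
#' @param reference_gene Reference gene name (default `"actin2"`).
#' @param seed Integer seed.
#' @return A [ct_table()].
#' @export
simulate_ct <- function(fold_changes, base_ct = 24, ref_ct = 18,
                        n_replicates = 3, noise_sd = 0.2,
                        calibrator = "LDSN", reference_gene = "actin2",
                        seed) {
  fold_changes <- as.matrix(fold_changes)
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0))
    stop("fold changes must be finite and > 0")
  if (!calibrator %in% colnames(fold_changes))
    stop("fold_changes must include the calibrator condition '",
         calibrator, "'")
  genes <- rownames(fold_changes)
  if (is.null(genes)) genes <- paste0("target", seq_len(nrow(fold_changes)))
  conds <- colnames(fold_changes)
  base_ct <- rep_len(base_ct, length(genes))
  with_seed(seed, {
    rows <- list()
    for (cond in conds) for (r in seq_len(n_replicates)) {
      ct_t <- base_ct - log2(fold_changes[, cond]) +
        stats::rnorm(length(genes), 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = c(genes, reference_gene), condition = cond, replicate = r,
        ct = c(ct_t, ref_ct + stats::rnorm(1L, 0, noise_sd)),
        stringsAsFactors = FALSE)
    }
    ct_table(do.call(rbind, rows), reference_gene = reference_gene)
  })
}

#' Simulate a GC-MS component-area table
#'
#' Component areas are the planted relative concentration times the
#' internal-standard area times multiplicative log-normal noise, so that
#' [ribitol_normalize()] recovers the concentrations exactly at zero noise.
#' Signal-to-noise values are drawn uniformly from `snr_range`; the internal
#' standard always carries a high S/N.
#'
#' @param true_concentrations Matrix of relative concentrations: rownames =
#'   component ids, colnames = conditions. Must be positive.
#' @param ribitol_area Internal-standard detector area per sample
#'   (default 500); must be > 0.
#' @param snr_range Length-2 range for the uniform S/N draw
#'   (default `c(10, 100)`).
#' @param n_replicates Replicates per condition (default 3).
#' @param noise_sd SD of the log-normal multiplicative noise on the log scale
#'   (default 0).
#' @param internal_standard Component id of the standard (default
#'   `"ribitol"`).
#' @param seed Integer seed.
#' @return A [metabolite_table()].
#' @export
simulate_metabolites <- function(true_concentrations, ribitol_area = 500,
                                 snr_range = c(10, 100), n_replicates = 3,
                                 noise_sd = 0, internal_standard = "ribitol",
                                 seed) {
  conc <- as.matrix(true_concentrations)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("true concentrations must be finite and > 0")
  if (!is.finite(ribitol_area) || ribitol_area <= 0)
    stop("internal-standard area must be > 0")
  if (length(snr_range) != 2L || any(snr_range <= 0))
    stop("snr_range must be two positive numbers")
  comps <- rownames(conc)
  if (is.null(comps)) comps <- paste0("component", seq_len(nrow(conc)))
  conds <- colnames(conc)
  if (is.null(conds)) stop("true_concentrations needs condition colnames")
  with_seed(seed, {
    rows <- list()
    for (cond in conds) for (r in seq_len(n_replicates)) {
      area <- conc[, cond] * ribitol_area *
        exp(stats::rnorm(length(comps), 0, noise_sd))
      snr <- stats::runif(length(comps), snr_range[1L], snr_range[2L])
      rows[[length(rows) + 1L]] <- data.frame(
        component_id = c(comps, internal_standard), condition = cond,
        replicate = r, area = c(area, ribitol_area), snr = c(snr, 999),
        stringsAsFactors = FALSE)
    }
    metabolite_table(do.call(rbind, rows),
                     internal_standard = internal_standard)
  })
}
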