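# In-code fixtures shared across the suite.

# Minimal valid sample sheet: n replicates per condition at one timepoint.
toy_samples <- function(n_rep = 3, timepoint = 21) {
  conds <- condition_levels()
  data.frame(
    sample_id = paste0(rep(conds, each = n_rep), "_r", seq_len(n_rep)),
    density = rep(substr(conds, 1, 2), each = n_rep),
    nitrogen = rep(substr(conds, 3, 4), each = n_rep),
    timepoint = timepoint,
    replicate = rep(seq_len(n_rep), times = length(conds)),
    stringsAsFactors = FALSE)
}

# Expression matrix with explicit per-condition gene means plus optional
# i.i.d. noise; `means` is genes x 4 (LDSN, LDLN, HDSN, HDLN).
toy_expr <- function(means, n_rep = 3, noise_sd = 0, seed = 1,
                     timepoint = 21) {
  means <- as.matrix(means)
  if (is.null(rownames(means)))
    rownames(means) <- paste0("g", seq_len(nrow(means)))
  colnames(means) <- condition_levels()
  sam <- toy_samples(n_rep, timepoint)
  vals <- means[, paste0(sam$density, sam$nitrogen), drop = FALSE]
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + matrix(rnorm(length(vals), 0, noise_sd), nrow(vals))
  }
  colnames(vals) <- sam$sample_id
  expression_matrix(vals, sam)
}

# Small hand-made Ct table: per-gene named vector of ddCt-scale folds
# relative to the calibrator, exact Ct values, no noise.
toy_ct <- function(folds, conditions = c("LDSN", "HDSN"), n_rep = 3,
                   base_ct = 24, ref_ct = 18) {
  rows <- list()
  for (cond in conditions) for (r in seq_len(n_rep)) {
    for (g in names(folds)) {
      fold <- if (cond == "LDSN") 1 else folds[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond, replicate = r,
        ct = base_ct - log2(fold), stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = "actin2", condition = cond, replicate = r, ct = ref_ct,
      stringsAsFactors = FALSE)
  }
  ct_table(do.call(rbind, rows))
}
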