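# qPCR relative quantification by the 2^-ddCt method against a reference
# gene, GC-MS component filtering and internal-standard normalization, and
# the univariate statistics used for both: pairwise t tests, one-way ANOVA
# with Fisher's least significant difference (plus delegated Tukey and
# Shapiro-Wilk checks).

#' 2^-ddCt relative quantification
#'
#' Per replicate, dCt = Ct(target) - Ct(reference) in the same (condition,
#' replicate); ddCt = dCt - mean dCt of the calibrator condition; the fold
#' difference is `2^-ddCt` (amplification efficiency assumed to be a perfect
#' doubling per cycle). Condition-level folds use the mean ddCt; replicate
#' dCt values feed a pairwise t test of each condition against the
#' calibrator.
#'
#' @param ct A [ct_table()].
#' @param calibrator Calibrator condition (default `"LDSN"`, the optimal
#'   growth condition).
#' @param variant t-test variant passed to [two_sample_ttest()].
#' @return Data frame of class `ddct_result`, one row per gene x condition:
#'   `gene`, `condition`, `dct_mean`, `ddct`, `fold` (= `2^-ddct`),
#'   `fold_replicates` (comma-joined per-replicate folds), `p_value`
#'   (`NA` for the calibrator itself).
#' @export
ddct_folds <- function(ct, calibrator = "LDSN",
                       variant = c("pooled", "welch")) {
  stopifnot(inherits(ct, "ct_table"))
  variant <- match.arg(variant)
  ref_gene <- attr(ct, "reference_gene")
  df <- as.data.frame(ct)
  if (!calibrator %in% df$condition)
    stop("calibrator condition '", calibrator, "' not present")
  ref <- df[df$gene == ref_gene, c("condition", "replicate", "ct")]
  names(ref)[3L] <- "ct_ref"
  targ <- df[df$gene != ref_gene, , drop = FALSE]
  merged <- merge(targ, ref, by = c("condition", "replicate"))
  if (nrow(merged) < nrow(targ)) {
    miss <- !paste(targ$condition, targ$replicate) %in%
      paste(ref$condition, ref$replicate)
    stop("reference gene '", ref_gene, "' missing for: ",
         paste(unique(paste0(targ$condition[miss], " replicate ",
                             targ$replicate[miss])), collapse = "; "))
  }
  merged$dct <- merged$ct - merged$ct_ref
  out <- list()
  for (gene in unique(merged$gene)) {
    sub <- merged[merged$gene == gene, , drop = FALSE]
    cal_dct <- sub$dct[sub$condition == calibrator]
    if (length(cal_dct) == 0L)
      stop("gene '", gene, "' has no measurement at calibrator '",
           calibrator, "'")
    cal_mean <- mean(cal_dct)
    for (cond in unique(sub$condition)) {
      dct <- sub$dct[sub$condition == cond]
      ddct_rep <- dct - cal_mean
      ddct <- mean(ddct_rep)
      p <- if (cond == calibrator || length(dct) < 2L ||
               length(cal_dct) < 2L) NA_real_
           else two_sample_ttest(dct, cal_dct, variant)$p_value
      out[[length(out) + 1L]] <- data.frame(
        gene = gene, condition = cond, dct_mean = mean(dct), ddct = ddct,
        fold = 2^(-ddct),
        fold_replicates = paste(signif(2^(-ddct_rep), 6L), collapse = ","),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, calibrator = calibrator, reference_gene = ref_gene,
            class = c("ddct_result", "data.frame"))
}

#' Signal-to-noise filter for GC-MS components
#'
#' Retains components with `snr >= threshold` (boundary inclusive).
#'
#' @param tbl A [metabolite_table()].
#' @param threshold S/N cutoff (default 5).
#' @return The filtered `metabolite_table`.
#' @export
sn_filter <- function(tbl, threshold = 5) {
  stopifnot(inherits(tbl, "metabolite_table"))
  is_id <- attr(tbl, "internal_standard")
  keep <- as.data.frame(tbl)[tbl$snr >= threshold, , drop = FALSE]
  rownames(keep) <- NULL
  if (!is_id %in% keep$component_id)
    return(structure(keep, internal_standard = is_id,
                     class = c("metabolite_table", "data.frame")))
  metabolite_table(keep, internal_standard = is_id)
}

#' Normalize component areas to the internal standard
#'
#' Divides every component area by the internal-standard (ribitol) area of
#' the same sample; the standard itself normalizes to 1. Areas recorded as
#' `NA` ("ND": detectable but below quantifiable amount) stay `NA` and are
#' flagged non-quantifiable, never imputed as zero.
#'
#' @param tbl A [metabolite_table()].
#' @return Data frame of class `normalized_components`: `component_id`,
#'   `condition`, `replicate`, `normalized_area`, `snr`, `quantifiable`.
#' @export
ribitol_normalize <- function(tbl) {
  stopifnot(inherits(tbl, "metabolite_table"))
  is_id <- attr(tbl, "internal_standard")
  df <- as.data.frame(tbl)
  is_rows <- df[df$component_id == is_id, , drop = FALSE]
  key <- paste(df$condition, df$replicate, sep = "::")
  is_key <- paste(is_rows$condition, is_rows$replicate, sep = "::")
  pos <- match(key, is_key)
  if (anyNA(pos))
    stop("internal standard '", is_id, "' missing for sample(s): ",
         paste(unique(key[is.na(pos)]), collapse = "; "))
  is_area <- is_rows$area[pos]
  if (any(is.na(is_area) | is_area <= 0))
    stop("internal standard area must be > 0 in every sample; offending: ",
         paste(unique(key[is.na(is_area) | is_area <= 0]), collapse = "; "))
  out <- data.frame(component_id = df$component_id,
                    condition = df$condition, replicate = df$replicate,
                    normalized_area = df$area / is_area, snr = df$snr,
                    quantifiable = !is.na(df$area),
                    stringsAsFactors = FALSE)
  structure(out, internal_standard = is_id,
            class = c("normalized_components", "data.frame"))
}

#' One-way ANOVA with Fisher's least significant difference
#'
#' One-way ANOVA across the groups (delegated to [stats::aov()]), the LSD
#' threshold `t(1 - alpha/2, df_error) * sqrt(MSE * (1/n_i + 1/n_j))`
#' (reducing to `t * sqrt(2 MSE / n)` for balanced groups), and the pairwise
#' significance matrix of mean differences exceeding it. Tukey's HSD and a
#' Shapiro-Wilk normality check of the residuals are reported alongside. An
#' optional square-root transform is applied first (values must then be
#' non-negative); pairwise flags are only meaningful when the omnibus F is
#' significant, but are reported either way.
#'
#' @param groups Named (or unnamed) list of >= 2 numeric replicate vectors,
#'   each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @param sqrt_transform Square-root transform the data first
#'   (default FALSE).
#' @return List of class `anova_lsd`: `F`, `p`, `df`, `mse`, `lsd` (balanced
#'   value, or the pairwise matrix average for unbalanced groups),
#'   `means`, `significant` (logical pairwise matrix), `tukey`
#'   (from [stats::TukeyHSD()]), `shapiro_p`.
#' @export
anova_lsd <- function(groups, alpha = 0.05, sqrt_transform = FALSE) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("each group needs at least 2 replicates")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (sqrt_transform) {
    if (any(unlist(groups) < 0))
      stop("square-root transform requires non-negative values")
    groups <- lapply(groups, sqrt)
  }
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, 0L)),
                                  levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  # anova() warns on an exactly perfect fit; the degenerate case is handled
  # explicitly below
  tab <- suppressWarnings(stats::anova(fit))
  Fval <- tab[["F value"]][1L]
  pval <- tab[["Pr(>F)"]][1L]
  mse <- tab[["Mean Sq"]][2L]
  dfe <- tab[["Df"]][2L]
  # all values identical: zero between- and within-variance -> F = 0, p = 1
  if (stats::var(df$value) == 0) { Fval <- 0; pval <- 1; mse <- 0 }
  if (!is.finite(Fval)) { Fval <- 0; pval <- 1 }
  k <- length(groups)
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  tcrit <- stats::qt(1 - alpha / 2, dfe)
  sig <- matrix(FALSE, k, k, dimnames = list(names(groups), names(groups)))
  lsd_pair <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    lsd_ij <- tcrit * sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    lsd_pair[i, j] <- lsd_pair[j, i] <- lsd_ij
    flag <- abs(means[i] - means[j]) > lsd_ij
    sig[i, j] <- sig[j, i] <- flag
  }
  balanced <- length(unique(ns)) == 1L
  lsd <- if (balanced) tcrit * sqrt(2 * mse / ns[1L])
         else mean(lsd_pair[upper.tri(lsd_pair)])
  shapiro_p <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                        error = function(e) NA_real_)
  tukey <- tryCatch(stats::TukeyHSD(fit, conf.level = 1 - alpha),
                    error = function(e) NULL)
  structure(list(F = Fval, p = pval, df = c(between = k - 1L, error = dfe),
                 mse = mse, lsd = unname(lsd), means = means,
                 significant = sig, tukey = tukey, shapiro_p = shapiro_p,
                 alpha = alpha, sqrt_transform = sqrt_transform),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g; LSD = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$p, x$lsd))
  invisible(x)
}
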