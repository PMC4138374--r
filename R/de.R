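# Responsive-gene calling against the LDSN control: per-gene two-sample t
# tests on replicate log2 values, fold-change cutoff on condition means,
# Benjamini-Hochberg adjustment per contrast, three-way Venn partitioning of
# the responsive sets, and selection of the density-specific clustering
# input set.

.contrasts <- c(HD = "HDSN", LN = "LDLN", HDLN = "HDLN")
.control_condition <- "LDSN"

#' Two-sample t test with pooled or Welch variance
#'
#' Pooled-variance Student t by default (the appropriate choice at n = 3
#' replicates per condition); Welch selectable. When both groups have zero
#' variance and equal means the statistic is defined as 0 with p = 1.
#'
#' @param x,y Numeric replicate vectors, each of length >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `statistic`, `df` and `p_value` (two-sided).
#' @export
two_sample_ttest <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 replicates")
  res <- .ttest_rows(matrix(x, nrow = 1L), matrix(y, nrow = 1L),
                     pooled = variant == "pooled")
  list(statistic = res$t[1L], df = res$df[1L], p_value = res$p[1L])
}

# Vectorized row-wise two-sample t: X, Y are genes x replicates matrices.
.ttest_rows <- function(X, Y, pooled = TRUE) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1L)
  vy <- rowSums((Y - my)^2) / (ny - 1L)
  d <- mx - my
  if (pooled) {
    sp2 <- ((nx - 1L) * vx + (ny - 1L) * vy) / (nx + ny - 2L)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep.int(nx + ny - 2L, length(d))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      (vx^2 / (nx^2 * (nx - 1L)) + vy^2 / (ny^2 * (ny - 1L)))
  }
  t <- d / se
  # zero variance in both groups: equal means -> t = 0, p = 1 by convention;
  # unequal means -> infinite statistic, p = 0
  degen <- se == 0
  if (any(degen)) {
    t[degen] <- ifelse(d[degen] == 0, 0, sign(d[degen]) * Inf)
    df[degen] <- nx + ny - 2L
  }
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate: sort
#' ascending, multiply `p_(i)` by `m/i`, enforce monotonicity from the
#' largest down, cap at 1, and return in the input order (the
#' `stats::p.adjust` "BH" method, with input validation).
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Call stress-responsive genes against the LDSN control
#'
#' For each gene and each contrast (HD: HDSN vs LDSN; LN: LDLN vs LDSN;
#' HDLN: HDLN vs LDSN) at one timepoint, computes the linear fold change
#' `2^(difference of condition-mean log2 values)`, a two-sample t test on the
#' replicate log2 values, and a Benjamini-Hochberg adjusted q-value per
#' contrast across all genes. A gene is responsive in a contrast when
#' `|log2 fold| >= log2(fold_cutoff)` and `q < alpha` (raw p when
#' `adjust = FALSE`); its direction is `enhanced` or `suppressed` by the sign
#' of the log2 difference.
#'
#' @param m An [expression_matrix()].
#' @param timepoint 21 or 31.
#' @param fold_cutoff Minimum linear fold change (default 2).
#' @param alpha FDR level (default 0.05).
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @param adjust Apply BH adjustment (default TRUE); when FALSE the raw p is
#'   compared with `alpha`.
#' @return A long data frame of class `de_result` with one row per gene x
#'   contrast: `gene_id`, `contrast`, `fold_change`, `log2fc`, `p_raw`,
#'   `q_bh`, `responsive`, `direction`; attributes `fold_cutoff`, `alpha`,
#'   `timepoint`.
#' @export
call_responsive <- function(m, timepoint, fold_cutoff = 2, alpha = 0.05,
                            variant = c("pooled", "welch"), adjust = TRUE) {
  stopifnot(inherits(m, "expr_matrix"))
  variant <- match.arg(variant)
  if (fold_cutoff <= 1) stop("fold_cutoff must be > 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  timepoint <- as.integer(timepoint)
  sam <- m$samples[m$samples$timepoint == timepoint, , drop = FALSE]
  cond_cols <- function(cond) {
    cols <- sam$sample_id[sam$condition == cond]
    if (length(cols) < 2L)
      stop("condition ", cond, " needs >= 2 replicates at timepoint ",
           timepoint)
    m$values[, cols, drop = FALSE]
  }
  ctrl <- cond_cols(.control_condition)
  out <- lapply(names(.contrasts), function(cn) {
    treat <- cond_cols(.contrasts[[cn]])
    log2fc <- rowMeans(treat) - rowMeans(ctrl)
    tt <- .ttest_rows(treat, ctrl, pooled = variant == "pooled")
    q <- bh_adjust(tt$p)
    crit_p <- if (adjust) q else tt$p
    responsive <- abs(log2fc) >= log2(fold_cutoff) & crit_p < alpha
    data.frame(gene_id = rownames(m$values), contrast = cn,
               fold_change = 2^log2fc, log2fc = log2fc, p_raw = tt$p,
               q_bh = q, responsive = responsive,
               direction = ifelse(!responsive, "none",
                                  ifelse(log2fc > 0, "enhanced",
                                         "suppressed")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, fold_cutoff = fold_cutoff, alpha = alpha,
            timepoint = timepoint, class = c("de_result", "data.frame"))
}

#' Responsive gene sets per contrast
#'
#' @param de A `de_result` from [call_responsive()].
#' @return Named list of character vectors: `HD`, `LN`, `HDLN`.
#' @export
responsive_sets <- function(de) {
  stopifnot(inherits(de, "de_result"))
  lapply(stats::setNames(nm = names(.contrasts)), function(cn)
    de$gene_id[de$contrast == cn & de$responsive])
}

#' Three-way Venn partition of responsive gene sets
#'
#' Splits the HD, LN and HDLN responsive sets into the 7 disjoint Venn
#' regions.
#'
#' @param de A `de_result`, or a named list of three character vectors
#'   `HD`, `LN`, `HDLN`.
#' @return An object of class `venn_partition`: list with `regions` (named
#'   list of 7 disjoint gene-id vectors) and `counts`.
#' @export
venn_partition <- function(de) {
  sets <- if (inherits(de, "de_result")) responsive_sets(de) else de
  stopifnot(all(c("HD", "LN", "HDLN") %in% names(sets)))
  hd <- unique(sets$HD); ln <- unique(sets$LN); hl <- unique(sets$HDLN)
  in_hd <- function(x) x %in% hd
  in_ln <- function(x) x %in% ln
  in_hl <- function(x) x %in% hl
  u <- unique(c(hd, ln, hl))
  regions <- list(
    HD_only = u[in_hd(u) & !in_ln(u) & !in_hl(u)],
    LN_only = u[!in_hd(u) & in_ln(u) & !in_hl(u)],
    HDLN_only = u[!in_hd(u) & !in_ln(u) & in_hl(u)],
    HD_LN = u[in_hd(u) & in_ln(u) & !in_hl(u)],
    HD_HDLN = u[in_hd(u) & !in_ln(u) & in_hl(u)],
    LN_HDLN = u[!in_hd(u) & in_ln(u) & in_hl(u)],
    HD_LN_HDLN = u[in_hd(u) & in_ln(u) & in_hl(u)])
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1L))),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition of responsive sets (HD, LN, HDLN):\n")
  print(x$counts)
  invisible(x)
}

#' Fraction of density-responsive genes that are also nitrogen-responsive
#'
#' `|HD intersect LN| / |HD|`, the headline overlap statistic of the
#' responsive-set comparison (41% at 21 days and 16% at 31 days in the
#' motivating experiment).
#'
#' @param de A `de_result` or a named list of sets as in [venn_partition()].
#' @return The overlap fraction, or `NA` (with a warning) when no gene is
#'   HD-responsive.
#' @export
overlap_fraction <- function(de) {
  sets <- if (inherits(de, "de_result")) responsive_sets(de) else de
  hd <- unique(sets$HD)
  if (length(hd) == 0L) {
    warning("HD-responsive set is empty; overlap fraction undefined")
    return(NA_real_)
  }
  length(intersect(hd, unique(sets$LN))) / length(hd)
}

#' Select density-specific genes for clustering
#'
#' Genes responsive to high density and not to nitrogen limitation; the
#' clustering stages operate on this set, called at a stricter fold cutoff
#' (3-fold in the motivating analysis).
#'
#' @param de A `de_result` computed at the stricter cutoff (see
#'   [call_responsive()] with `fold_cutoff = 3`).
#' @return Character vector of gene ids.
#' @export
select_density_specific <- function(de) {
  sets <- responsive_sets(de)
  setdiff(sets$HD, sets$LN)
}
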