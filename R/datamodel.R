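# Core data types: expression matrices with condition metadata, qPCR Ct
# tables, and GC-MS metabolite tables, plus their tab-separated readers and
# writers. Expression values are assumed to be already-normalized log2
# intensities; missing values are rejected, never imputed.

#' Fixed condition order used throughout the package
#'
#' Conditions are the density x nitrogen pairs. LDSN (low density, sufficient
#' nitrogen) is the optimal control against which all contrasts are formed,
#' and the order `LDSN, LDLN, HDSN, HDLN` is fixed everywhere: condition-mean
#' profiles, clustering input, and file headers all use it.
#'
#' @return Character vector `c("LDSN", "LDLN", "HDSN", "HDLN")`.
#' @export
condition_levels <- function() c("LDSN", "LDLN", "HDSN", "HDLN")

.densities <- c("LD", "HD")
.nitrogens <- c("SN", "LN")
.timepoints <- c(21L, 31L)

#' Construct an expression matrix with sample metadata
#'
#' @param values Numeric matrix of log2 expression, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param samples Data frame with columns `sample_id`, `density` (`"HD"` or
#'   `"LD"`), `nitrogen` (`"SN"` or `"LN"`), `timepoint` (21 or 31) and
#'   `replicate` (positive integer), one row per column of `values`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix, columns ordered as in `samples`) and `samples` (the
#'   metadata, with a derived `condition` column).
#' @export
expression_matrix <- function(values, samples) {
  values <- as.matrix(values)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "density", "nitrogen", "timepoint", "replicate")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols))
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$timepoint <- as.integer(samples$timepoint)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  bad_dens <- setdiff(unique(samples$density), .densities)
  if (length(bad_dens))
    stop("unknown density label(s): ", paste(bad_dens, collapse = ", "))
  bad_nit <- setdiff(unique(samples$nitrogen), .nitrogens)
  if (length(bad_nit))
    stop("unknown nitrogen label(s): ", paste(bad_nit, collapse = ", "))
  bad_tp <- setdiff(unique(samples$timepoint), .timepoints)
  if (length(bad_tp))
    stop("unknown timepoint(s): ", paste(bad_tp, collapse = ", "),
         " (expected 21 or 31)")
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1L))
    stop("replicate must be a positive integer")
  samples$condition <- paste0(samples$density, samples$nitrogen)

  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("expression values must carry gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (is.null(colnames(values)))
    stop("expression values must carry sample ids as colnames")
  absent <- setdiff(samples$sample_id, colnames(values))
  if (length(absent))
    stop("sample(s) in metadata but not in values: ",
         paste(absent, collapse = ", "))
  extra <- setdiff(colnames(values), samples$sample_id)
  if (length(extra))
    stop("sample(s) in values but not in metadata: ",
         paste(extra, collapse = ", "))
  values <- values[, samples$sample_id, drop = FALSE]  # order from metadata
  if (nrow(values) > 0 && !all(is.finite(values))) {
    bad <- rownames(values)[!apply(is.finite(values), 1L, all)]
    stop("non-finite expression value(s) for gene(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$condition, x$samples$timepoint)
  cat("replicates per condition x timepoint:\n")
  print(tab)
  invisible(x)
}

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The values file is tab-separated with a header row: first column `gene_id`,
#' then one column per sample. The metadata file has columns `sample_id`,
#' `density`, `nitrogen`, `timepoint`, `replicate`. Sample order is taken from
#' the metadata file.
#'
#' @param path_values Path to the gene x sample TSV of log2 values.
#' @param path_meta Path to the sample metadata TSV.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path_values, path_meta) {
  raw <- utils::read.delim(path_values, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("values file must have gene_id plus sample columns")
  ids <- as.character(raw[[1L]])
  num <- raw[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        bad <- which(is.na(vn) & !is.na(v))[1L]
        stop(sprintf("non-numeric cell in column '%s', row %d (gene '%s'): '%s'",
                     names(num)[j], bad, ids[bad], v[bad]))
      }
      num[[j]] <- vn
    }
  }
  values <- as.matrix(num)
  rownames(values) <- ids
  meta <- utils::read.delim(path_meta, stringsAsFactors = FALSE)
  expression_matrix(values, meta)
}

#' Write an expression matrix and its metadata to TSV files
#'
#' Inverse of [read_expression()]; a read-write-read cycle reproduces the
#' object exactly.
#'
#' @param m An `expr_matrix`.
#' @param path_values,path_meta Output paths.
#' @return Invisibly, `m`.
#' @export
write_expression <- function(m, path_values, path_meta) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path_values, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- m$samples[, c("sample_id", "density", "nitrogen", "timepoint",
                        "replicate")]
  utils::write.table(meta, path_meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}

#' Per-condition mean profiles at one timepoint
#'
#' Averages replicate log2 values within each of the four conditions,
#' returning one 4-vector per gene in the fixed order
#' `LDSN, LDLN, HDSN, HDLN`. These condition profiles are the input to the
#' clustering stages.
#'
#' @param m An `expr_matrix`.
#' @param timepoint 21 or 31 (days).
#' @return A genes x 4 numeric matrix of class `condition_profiles` with
#'   column names `condition_levels()` and attribute `timepoint`.
#' @export
condition_means <- function(m, timepoint) {
  stopifnot(inherits(m, "expr_matrix"))
  timepoint <- as.integer(timepoint)
  sel <- m$samples$timepoint == timepoint
  if (!any(sel)) stop("no samples at timepoint ", timepoint)
  sam <- m$samples[sel, , drop = FALSE]
  missing_cond <- setdiff(condition_levels(), unique(sam$condition))
  if (length(missing_cond))
    stop("condition(s) absent at timepoint ", timepoint, ": ",
         paste(missing_cond, collapse = ", "))
  vals <- m$values[, sam$sample_id, drop = FALSE]
  out <- vapply(condition_levels(), function(cond) {
    cols <- sam$sample_id[sam$condition == cond]
    rowMeans(vals[, cols, drop = FALSE])
  }, numeric(nrow(vals)))
  out <- matrix(out, nrow = nrow(vals), ncol = 4L,
                dimnames = list(rownames(vals), condition_levels()))
  structure(out, timepoint = timepoint, class = c("condition_profiles",
                                                  class(out)))
}

# ---- qPCR Ct tables --------------------------------------------------------

#' Construct a qPCR Ct table
#'
#' @param df Data frame with columns `gene`, `condition`, `replicate`, `ct`
#'   (threshold cycles). The reference gene must have a row for every
#'   (condition, replicate) in which any target gene was measured.
#' @param reference_gene Name of the reference gene (default `"actin2"`).
#' @return `df` with class `ct_table` and attribute `reference_gene`.
#' @export
ct_table <- function(df, reference_gene = "actin2") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("gene", "condition", "replicate", "ct")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("Ct table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop("Ct values must be finite and positive")
  if (!reference_gene %in% df$gene)
    stop("reference gene '", reference_gene, "' not present in table")
  targ <- df[df$gene != reference_gene, , drop = FALSE]
  ref <- df[df$gene == reference_gene, , drop = FALSE]
  want <- unique(paste(targ$condition, targ$replicate, sep = "::"))
  have <- paste(ref$condition, ref$replicate, sep = "::")
  lost <- setdiff(want, have)
  if (length(lost))
    stop("reference gene '", reference_gene,
         "' missing for (condition, replicate): ",
         paste(lost, collapse = "; "))
  structure(df, reference_gene = reference_gene,
            class = c("ct_table", "data.frame"))
}

#' Read / write a Ct table as TSV
#'
#' @param path File path.
#' @param reference_gene Reference gene name (default `"actin2"`).
#' @return [read_ct()] returns a `ct_table`; [write_ct()] returns its input
#'   invisibly.
#' @export
read_ct <- function(path, reference_gene = "actin2") {
  ct_table(utils::read.delim(path, stringsAsFactors = FALSE), reference_gene)
}

#' @rdname read_ct
#' @param tbl A `ct_table`.
#' @export
write_ct <- function(tbl, path) {
  stopifnot(inherits(tbl, "ct_table"))
  utils::write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tbl)
}

# ---- GC-MS metabolite tables ----------------------------------------------

#' Construct a GC-MS component-area table
#'
#' @param df Data frame with columns `component_id`, `condition`, `replicate`,
#'   `area` (detector units, `NA` marks a component detectable but below
#'   quantifiable amount, "ND") and `snr` (signal-to-noise ratio).
#' @param internal_standard Component id of the spiked internal standard
#'   (default `"ribitol"`); its area must be positive in every sample.
#' @return `df` with class `metabolite_table` and attribute
#'   `internal_standard`.
#' @export
metabolite_table <- function(df, internal_standard = "ribitol") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("component_id", "condition", "replicate", "area", "snr")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metabolite table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$area < 0, na.rm = TRUE)) stop("component areas must be >= 0")
  is_rows <- df[df$component_id == internal_standard, , drop = FALSE]
  if (nrow(is_rows) == 0L)
    stop("internal standard '", internal_standard, "' not present in table")
  samples <- unique(df[, c("condition", "replicate")])
  key <- function(d) paste(d$condition, d$replicate, sep = "::")
  lost <- setdiff(key(samples), key(is_rows))
  if (length(lost))
    stop("internal standard '", internal_standard,
         "' missing for sample(s): ", paste(lost, collapse = "; "))
  if (any(is.na(is_rows$area)) || any(is_rows$area <= 0)) {
    bad <- key(is_rows)[is.na(is_rows$area) | is_rows$area <= 0]
    stop("internal standard area must be > 0; offending sample(s): ",
         paste(bad, collapse = "; "))
  }
  structure(df, internal_standard = internal_standard,
            class = c("metabolite_table", "data.frame"))
}

#' Read / write a metabolite table as TSV
#'
#' @param path File path.
#' @param internal_standard Internal-standard component id.
#' @return [read_metabolites()] returns a `metabolite_table`;
#'   [write_metabolites()] returns its input invisibly.
#' @export
read_metabolites <- function(path, internal_standard = "ribitol") {
  metabolite_table(utils::read.delim(path, stringsAsFactors = FALSE),
                   internal_standard)
}

#' @rdname read_metabolites
#' @param tbl A `metabolite_table`.
#' @export
write_metabolites <- function(tbl, path) {
  stopifnot(inherits(tbl, "metabolite_table"))
  utils::write.table(as.data.frame(tbl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tbl)
}
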