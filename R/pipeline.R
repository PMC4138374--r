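# Pipeline orchestration: a validated configuration object and a seeded
# run-all driver that orders the stages the way the analysis does -
# responsive-gene screening, Venn partitioning, density-specific selection
# at the stricter cutoff, condition-mean profiles, two-step clustering -
# writing every stage's TSV/JSON plus a machine-readable manifest. Outputs
# are deterministic given the seed (the manifest carries no timestamps;
# stage timing goes to stderr).

#' Pipeline configuration
#'
#' @param values_path,meta_path Input expression TSVs (see
#'   [read_expression()]); leave `NULL` when passing an in-memory matrix to
#'   [run_all()].
#' @param timepoint Timepoint to analyze (default 21).
#' @param screen_fold Fold cutoff of the responsive-gene screen (default 2).
#' @param cluster_fold Stricter cutoff for the density-specific clustering
#'   input set (default 3).
#' @param alpha FDR level (default 0.05).
#' @param strategy Two-step strategy, see [run_two_step()].
#' @param G_range Step-1 component-count grid (default `1:9`).
#' @param model_set Step-1 GPCM model set (default all eight).
#' @param n_starts EM restarts per grid cell (default 5).
#' @param seed Integer seed; mandatory.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(values_path = NULL, meta_path = NULL,
                            timepoint = 21, screen_fold = 2,
                            cluster_fold = 3, alpha = 0.05,
                            strategy = "gpcm-kmeans", G_range = 1:9,
                            model_set = gpcm_models(), n_starts = 5, seed) {
  if (missing(seed) || is.null(seed)) stop("pipeline_config requires a seed")
  if (screen_fold <= 1 || cluster_fold <= 1)
    stop("fold cutoffs must be > 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!strategy %in% c("gpcm-kmeans", "pgmm-kmeans", "gpcm-gpcm",
                       "pgmm-gpcm"))
    stop("unknown strategy: ", strategy)
  structure(list(values_path = values_path, meta_path = meta_path,
                 timepoint = as.integer(timepoint),
                 screen_fold = screen_fold, cluster_fold = cluster_fold,
                 alpha = alpha, strategy = strategy,
                 G_range = as.integer(G_range), model_set = model_set,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_msg <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full analysis pipeline
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param expr Optional in-memory [expression_matrix()]; when `NULL` the
#'   matrix is read from the paths in `cfg`.
#' @return Invisibly, a list with the stage results (`de_screen`, `venn`,
#'   `overlap`, `de_cluster`, `density_specific`, `profiles`, `twostep`,
#'   `manifest_path`).
#' @export
run_all <- function(cfg, out_dir, expr = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load"
  res <- tryCatch({
    if (is.null(expr)) {
      if (is.null(cfg$values_path) || is.null(cfg$meta_path))
        stop("no expression input: set values_path/meta_path or pass expr")
      .stage_msg("loading expression from ", cfg$values_path)
      expr <- read_expression(cfg$values_path, cfg$meta_path)
    }

    stage <- "de-screen"
    .stage_msg("responsive-gene screen at ", cfg$screen_fold, "-fold, FDR ",
               cfg$alpha)
    de2 <- call_responsive(expr, cfg$timepoint,
                           fold_cutoff = cfg$screen_fold,
                           alpha = cfg$alpha)
    utils::write.table(as.data.frame(de2),
                       file.path(out_dir, "de_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "venn"
    venn <- venn_partition(de2)
    ov <- suppressWarnings(overlap_fraction(de2))
    jsonlite::write_json(list(counts = as.list(venn$counts),
                              hd_ln_overlap_fraction = ov),
                         file.path(out_dir, "venn.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "de-cluster-input"
    .stage_msg("density-specific selection at ", cfg$cluster_fold, "-fold")
    de3 <- call_responsive(expr, cfg$timepoint,
                           fold_cutoff = cfg$cluster_fold,
                           alpha = cfg$alpha)
    utils::write.table(as.data.frame(de3),
                       file.path(out_dir, "de_cluster.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dens_genes <- select_density_specific(de3)
    writeLines(dens_genes, file.path(out_dir, "density_specific_genes.txt"))
    if (length(dens_genes) < 8L)
      stop("only ", length(dens_genes),
           " density-specific genes; too few to cluster")

    stage <- "profiles"
    prof <- condition_means(expr, cfg$timepoint)
    prof <- prof[dens_genes, , drop = FALSE]
    utils::write.table(data.frame(gene_id = rownames(prof), prof,
                                  check.names = FALSE),
                       file.path(out_dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "two-step"
    .stage_msg("two-step clustering (", cfg$strategy, ") of ",
               length(dens_genes), " genes")
    ts <- run_two_step(prof, strategy = cfg$strategy,
                       step1 = list(G_range = cfg$G_range,
                                    model_set = cfg$model_set,
                                    n_starts = cfg$n_starts),
                       seed = cfg$seed)
    utils::write.table(ts$assignments, file.path(out_dir, "twostep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comp_summary <- lapply(ts$components, function(ci)
      list(component = ci$component, size = ci$size, split = ci$split,
           reason = if (is.null(ci$reason)) "ok" else ci$reason))
    jsonlite::write_json(
      list(strategy = cfg$strategy, G = ts$step1$best$G,
           model = if (!is.null(ts$step1$best$model)) ts$step1$best$model
                   else ts$step1$best$constraint,
           bic = ts$step1$best$bic,
           n_discordant = sum(ts$assignments$discordant),
           components = comp_summary),
      file.path(out_dir, "twostep_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "manifest"
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    manifest <- list(
      package = "stressclust",
      version = as.character(utils::packageVersion("stressclust")),
      seed = cfg$seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      n_genes = nrow(expr$values), n_samples = ncol(expr$values),
      timepoint = cfg$timepoint,
      n_density_specific = length(dens_genes),
      outputs = c("de_screen.tsv", "venn.json", "de_cluster.tsv",
                  "density_specific_genes.txt", "profiles.tsv",
                  "twostep.tsv", "twostep_summary.json", "config.json"))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    .stage_msg("done; outputs in ", out_dir)
    list(de_screen = de2, venn = venn, overlap = ov, de_cluster = de3,
         density_specific = dens_genes, profiles = prof, twostep = ts,
         manifest_path = manifest_path)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
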