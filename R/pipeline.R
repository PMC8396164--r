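#' Validate a pipeline configuration
#'
#' A pipeline config is a named list (typically read from YAML) with the
#' stage blocks below; unknown keys anywhere are rejected before any
#' compute, so typos fail fast.
#'
#' \describe{
#'   \item{seed}{global integer seed; per-stage child seeds derive from it
#'     by a fixed stride (`seed + 7919 * stage_index`, documented in
#'     `child_seed`), so each stage is independently reproducible.}
#'   \item{cohort}{arguments for [cohort_config()] (synthetic input), or
#'     omitted when `inputs` point at files on disk.}
#'   \item{inputs}{paths: `fragments`, `controls`, `panel` (optional).}
#'   \item{preprocess}{`correlation_threshold`,
#'     `anticorrelation_exclusion_threshold`, `nonneg_shift_mode`.}
#'   \item{nsnmf}{`theta`, `ranks`, `n_runs`, `max_iter`, `tol`.}
#'   \item{characterize}{`alpha`, `outlier_threshold`, `detection`,
#'     `dominance`.}
#'   \item{longitudinal}{`markers`.}
#'   \item{out}{output directory.}
#' }
#'
#' @param config named list.
#' @return the config with defaults filled in; errors on unknown keys.
#' @export
pipeline_config <- function(config) {
  defaults <- list(
    seed = 1L,
    out = NULL,
    cohort = NULL,
    inputs = NULL,
    preprocess = list(correlation_threshold = 0.5,
                      anticorrelation_exclusion_threshold = -0.5,
                      nonneg_shift_mode = "global_min_shift"),
    nsnmf = list(theta = 0.5, ranks = 2:5, n_runs = 50,
                 max_iter = 2000, tol = 1e-6),
    characterize = list(alpha = 0.05, outlier_threshold = 3.5,
                        detection = 0.2, dominance = 0.5),
    longitudinal = list(markers = NULL),
    log_level = "info",
    resume = FALSE)
  check_keys <- function(given, allowed, where) {
    unknown <- setdiff(names(given), allowed)
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ", paste(unknown, collapse = ", "))
  }
  check_keys(config, names(defaults), "pipeline config")
  for (blk in c("preprocess", "nsnmf", "characterize", "longitudinal")) {
    if (!is.null(config[[blk]])) check_keys(config[[blk]], names(defaults[[blk]]), blk)
  }
  if (!is.null(config$inputs))
    check_keys(config$inputs, c("fragments", "controls", "panel"), "inputs")
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$out)) stop("config must name an output directory (out)")
  if (is.null(cfg$cohort) && is.null(cfg$inputs))
    stop("config needs either a synthetic 'cohort' block or file 'inputs'")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Read a YAML pipeline configuration
#' @param path YAML file.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) pipeline_config(yaml::read_yaml(path))

.log_line <- function(con, stage, msg, ...) {
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage,
              message = msg, ...)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the end-to-end subtype-discovery pipeline
#'
#' Stages, in order: preprocess -> rank selection -> consensus clustering at
#' the selected rank -> loading-outlier recheck (flagged subjects removed
#' and the clustering repeated) -> subtype characterization -> longitudinal
#' slopes. Every stage writes its outputs under `config$out` together with
#' the config hash and the stage seed; a failure aborts with the stage name,
#' keeping partial outputs. With `resume = TRUE`, stages whose outputs exist
#' are skipped.
#'
#' @param config validated list from [pipeline_config()] (or a raw list /
#'   YAML path, validated on entry).
#' @return a run report (list, also written as `report.json` and
#'   `report.md`): subject counts per subtype, rank-selection criteria,
#'   specific-protein counts, cell-type composition, slope estimates.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$resume)) config <- pipeline_config(config)
  cfg <- config
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  cfg_hash <- substr(unname(tools::md5sum(tf)), 1, 12)
  unlink(tf)
  log_con <- file(file.path(cfg$out, "pipeline.log.jsonl"), open = "a")
  on.exit(close(log_con), add = TRUE)
  stage_seed <- function(i) child_seed(cfg$seed, i)
  report <- list(config_hash = unname(cfg_hash), seed = cfg$seed)

  run_stage <- function(name, index, outfile, fun) {
    path <- file.path(cfg$out, outfile)
    if (isTRUE(cfg$resume) && file.exists(path)) {
      .log_line(log_con, name, "resumed from existing output")
      return(readRDS(path))
    }
    .log_line(log_con, name, "start", seed = stage_seed(index))
    res <- tryCatch(fun(stage_seed(index)),
                    error = function(e) stop("pipeline stage '", name, "' failed: ",
                                             conditionMessage(e), call. = FALSE))
    saveRDS(res, path)
    .log_line(log_con, name, "done")
    res
  }

  # -- stage 1: inputs + preprocessing ------------------------------------
  pre <- run_stage("preprocess", 1L, "stage_preprocess.rds", function(seed) {
    if (!is.null(cfg$cohort)) {
      cohort <- generate_cohort(do.call(cohort_config,
                                        modifyList(cfg$cohort, list(seed = seed))))
      fragments <- cohort$fragment_table
      controls <- cohort$control_ids
      panel <- NULL
      truth <- cohort$true_labels
      longit <- cohort$longitudinal_table
      celltypes <- cohort$celltype_reference
    } else {
      fragments <- read.table(cfg$inputs$fragments, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
      controls <- readLines(cfg$inputs$controls)
      panel <- if (!is.null(cfg$inputs$panel)) readLines(cfg$inputs$panel) else NULL
      truth <- NULL; longit <- NULL; celltypes <- NULL
    }
    pp <- preprocess_fragments(fragments, controls, panel,
                               cfg$preprocess$correlation_threshold,
                               cfg$preprocess$anticorrelation_exclusion_threshold)
    vmat <- nonneg_shift(t(pp$matrix), mode = cfg$preprocess$nonneg_shift_mode)
    list(matrix = pp$matrix, V = vmat, provenance = pp$provenance,
         platform_log = pp$platform_log, truth = truth,
         longitudinal = longit, celltypes = celltypes)
  })

  # -- stage 2: rank selection -------------------------------------------
  sel <- run_stage("rank_selection", 2L, "stage_rank.rds", function(seed) {
    select_rank(pre$V, ranks = cfg$nsnmf$ranks, theta = cfg$nsnmf$theta,
                n_runs = cfg$nsnmf$n_runs, seed = seed,
                max_iter = cfg$nsnmf$max_iter, tol = cfg$nsnmf$tol)
  })
  if (is.na(sel$selected_rank))
    stop("pipeline stage 'rank_selection' failed: no rank satisfies the selection criteria")
  k <- sel$selected_rank
  report$rank_selection <- sel$table
  report$selected_rank <- k

  # -- stage 3: consensus clustering at the selected rank -----------------
  cons <- run_stage("clustering", 3L, "stage_cluster.rds", function(seed) {
    run_consensus(pre$V, k, theta = cfg$nsnmf$theta, n_runs = cfg$nsnmf$n_runs,
                  seed = seed, max_iter = cfg$nsnmf$max_iter, tol = cfg$nsnmf$tol)
  })

  # -- stage 4: outlier recheck ------------------------------------------
  final <- run_stage("outlier_recheck", 4L, "stage_outliers.rds", function(seed) {
    pred <- predict_subtypes(cons$best_model)
    out_idx <- detect_loading_outliers(t(cons$best_model$H),
                                       threshold = cfg$characterize$outlier_threshold)
    if (length(out_idx) == 0)
      return(list(consensus = cons, pred = pred, outliers = character(0)))
    keep <- setdiff(seq_len(ncol(pre$V)), out_idx)
    cons2 <- run_consensus(pre$V[, keep, drop = FALSE], k, theta = cfg$nsnmf$theta,
                           n_runs = cfg$nsnmf$n_runs, seed = seed,
                           max_iter = cfg$nsnmf$max_iter, tol = cfg$nsnmf$tol)
    list(consensus = cons2, pred = predict_subtypes(cons2$best_model),
         outliers = colnames(pre$V)[out_idx])
  })
  labels <- final$pred$labels
  report$outliers_excluded <- final$outliers
  report$subtype_counts <- as.list(table(labels))
  report$cophenetic <- final$consensus$cophenetic
  report$silhouette <- final$consensus$silhouette

  # -- stage 5: characterization -----------------------------------------
  char <- run_stage("characterize", 5L, "stage_characterize.rds", function(seed) {
    mat <- pre$matrix[names(labels), , drop = FALSE]
    spec <- subtype_specific_proteins(mat, labels, alpha = cfg$characterize$alpha)
    prot_labels <- label_proteins(mat, labels)
    ct <- if (!is.null(pre$celltypes)) {
      lab <- celltype_specificity(pre$celltypes, cfg$characterize$detection,
                                  cfg$characterize$dominance)
      split(pre$celltypes$protein, lab)
    } else NULL
    list(specific = spec, protein_labels = prot_labels, celltype_sets = ct)
  })
  report$specific_protein_counts <- lapply(char$specific, function(s)
    list(increased = length(s$increased), decreased = length(s$decreased)))

  # -- stage 6: longitudinal ---------------------------------------------
  if (!is.null(pre$longitudinal)) {
    slopes <- run_stage("longitudinal", 6L, "stage_longitudinal.rds", function(seed) {
      slope_table(pre$longitudinal, markers = cfg$longitudinal$markers)
    })
    report$slopes <- slopes
    write.table(slopes, file.path(cfg$out, "slopes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if (!is.null(pre$truth)) {
    common <- intersect(names(labels), names(pre$truth))
    report$ari_vs_truth <- adjusted_rand_index(labels[common], pre$truth[common])
  }

  jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(format_report(report), file.path(cfg$out, "report.md"))
  invisible(report)
}

# human-readable Markdown run report
format_report <- function(report) {
  lines <- c("# Subtype discovery run report", "",
             paste0("- config hash: ", report$config_hash),
             paste0("- seed: ", report$seed),
             paste0("- selected rank: ", report$selected_rank),
             paste0("- cophenetic coefficient: ",
                    format(report$cophenetic, digits = 4)),
             paste0("- mean silhouette: ", format(report$silhouette, digits = 4)),
             "", "## Subjects per subtype", "")
  for (nm in names(report$subtype_counts))
    lines <- c(lines, paste0("- subtype ", nm, ": ", report$subtype_counts[[nm]]))
  if (length(report$outliers_excluded))
    lines <- c(lines, "", paste0("Outliers excluded: ",
                                 paste(report$outliers_excluded, collapse = ", ")))
  lines <- c(lines, "", "## Specific proteins", "")
  for (nm in names(report$specific_protein_counts)) {
    s <- report$specific_protein_counts[[nm]]
    lines <- c(lines, paste0("- ", nm, ": ", s$increased, " increased, ",
                             s$decreased, " decreased"))
  }
  if (!is.null(report$slopes)) {
    lines <- c(lines, "", "## Longitudinal slopes (units/year)", "")
    sl <- report$slopes
    lines <- c(lines, apply(sl, 1, function(r)
      sprintf("- %s subtype %s: beta = %s +/- %s (p = %s)",
              r[["marker"]], r[["subtype"]],
              format(as.numeric(r[["beta"]]), digits = 3),
              format(as.numeric(r[["se"]]), digits = 3),
              format(as.numeric(r[["p"]]), digits = 3))))
  }
  if (!is.null(report$ari_vs_truth))
    lines <- c(lines, "", paste0("Adjusted Rand index vs generator truth: ",
                                 format(report$ari_vs_truth, digits = 4)))
  lines
}
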