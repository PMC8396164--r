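#' Longitudinal generator settings
#'
#' Describes the repeated CSF biomarker measurements the cohort generator
#' emulates: per-subtype linear time trends in amyloid-beta 1-42 (`abeta42`,
#' pg/mL), p181-tau (`ptau`, pg/mL) and ADAS-Cog delayed word recall
#' (`memory`, score points; higher = worse), observed at 3.2 +/- 1.2 visits
#' over a follow-up span of 3 +/- 1.9 years, with subject-level random
#' intercepts.
#'
#' Default slopes are the per-subtype, per-year trends the pipeline is meant
#' to recover: abeta42 -4.4 / -3.7 / -5.6 pg/mL/yr, ptau 2.6 / 3.1 / 1.29
#' pg/mL/yr, memory 0.06 / 0.15 / 0.20 points/yr for subtypes 1-3.
#' Baseline means sit in the biomarker-normal range (230 pg/mL abeta42,
#' 18 pg/mL p-tau, 3 recall points); intercept and residual SDs are sized so
#' simulated slope standard errors are of the order observed in cohorts of
#' 12-17 subjects per subtype.
#'
#' @param slopes numeric matrix, markers x subtypes (rownames = marker names).
#' @param baseline_mean,intercept_sd,residual_sd named numeric vectors per
#'   marker: population baseline mean, subject random-intercept SD, and
#'   within-subject residual SD, in marker units.
#' @param visits_mean,visits_sd mean and SD of the per-subject visit count
#'   (drawn from a rounded normal, floored at 2 for slope identifiability).
#' @param span_mean,span_sd mean and SD of each subject's follow-up span in
#'   years (floored at 0.5). The first visit is at time 0; later visits are
#'   uniform over the span.
#' @return a `longitudinal_config` list.
#' @export
longitudinal_config <- function(slopes = NULL,
                                baseline_mean = c(abeta42 = 230, ptau = 18, memory = 3),
                                intercept_sd = c(abeta42 = 35, ptau = 6, memory = 1.5),
                                residual_sd = c(abeta42 = 12, ptau = 5, memory = 0.5),
                                visits_mean = 3.2, visits_sd = 1.2,
                                span_mean = 3, span_sd = 1.9) {
  if (is.null(slopes)) {
    slopes <- rbind(abeta42 = c(-4.4, -3.7, -5.6),
                    ptau    = c(2.6, 3.1, 1.29),
                    memory  = c(0.06, 0.15, 0.20))
  }
  slopes <- as.matrix(slopes)
  markers <- rownames(slopes)
  if (is.null(markers)) stop("slopes must have marker rownames")
  for (v in list(baseline_mean, intercept_sd, residual_sd)) {
    if (!all(markers %in% names(v))) stop("per-marker parameter missing a marker named in slopes")
  }
  stopifnot(visits_mean > 0, visits_sd >= 0, span_mean > 0, span_sd >= 0,
            all(intercept_sd[markers] >= 0), all(residual_sd[markers] >= 0))
  structure(list(slopes = slopes, baseline_mean = baseline_mean,
                 intercept_sd = intercept_sd, residual_sd = residual_sd,
                 visits_mean = visits_mean, visits_sd = visits_sd,
                 span_mean = span_mean, span_sd = span_sd),
            class = "longitudinal_config")
}

#' Synthetic-cohort generator settings
#'
#' The generator emulates the statistical structure the subtype analysis
#' assumes: `k_subtypes` latent nonnegative subtype profiles mixed into
#' protein abundances with Gaussian noise; each subtype owns a disjoint
#' signature set (`frac_signature` of all proteins) whose abundance is raised
#' by `profile_effect` control-SD units in that subtype's subjects; a
#' designated 20% control subsample supplies reference statistics; correlated
#' fragment panels per protein; a fraction of proteins duplicated on a second
#' platform; and per-subtype longitudinal biomarker trends.
#'
#' Subject loadings are drawn from a symmetric Dirichlet with concentration
#' `1 / mixing_concentration`, so larger `mixing_concentration` means sharper
#' (closer to one-hot) memberships; the hard subtype is the argmax loading.
#'
#' @param n_subjects,n_proteins,k_subtypes cohort dimensions (k >= 2).
#' @param mixing_concentration positive; sharpness of subject loadings
#'   (infinity = hard assignment).
#' @param profile_effect abundance shift of signature proteins in their
#'   subtype's subjects, in units of the generating noise SD.
#' @param noise_sd SD of the protein-level Gaussian noise.
#' @param frac_signature fraction of proteins in each subtype's signature;
#'   `frac_signature * k_subtypes` must be <= 1 (signatures are disjoint).
#' @param n_fragments_per_protein MRM fragments simulated per protein.
#' @param fragment_noise_sd extra measurement noise per fragment; two
#'   fragments of one protein correlate at least
#'   `noise_sd^2 / (noise_sd^2 + fragment_noise_sd^2)` by construction.
#' @param platform_duplicate_frac fraction of proteins also measured on a
#'   second (RBM) platform.
#' @param longitudinal a [longitudinal_config()].
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 120, n_proteins = 300, k_subtypes = 3,
                          mixing_concentration = 10, profile_effect = 1.5,
                          noise_sd = 1, frac_signature = 0.1,
                          n_fragments_per_protein = 3, fragment_noise_sd = 0.5,
                          platform_duplicate_frac = 0.05,
                          longitudinal = longitudinal_config(), seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_proteins = as.integer(n_proteins),
              k_subtypes = as.integer(k_subtypes),
              mixing_concentration = mixing_concentration,
              profile_effect = profile_effect, noise_sd = noise_sd,
              frac_signature = frac_signature,
              n_fragments_per_protein = as.integer(n_fragments_per_protein),
              fragment_noise_sd = fragment_noise_sd,
              platform_duplicate_frac = platform_duplicate_frac,
              longitudinal = longitudinal, seed = as.integer(seed))
  with(cfg, {
    if (n_subjects < 1 || n_proteins < 1 || n_fragments_per_protein < 1)
      stop("counts must be >= 1")
    if (k_subtypes < 2) stop("k_subtypes must be >= 2")
    if (k_subtypes > n_subjects) stop("k_subtypes cannot exceed n_subjects")
    if (frac_signature < 0 || frac_signature > 1 ||
        platform_duplicate_frac < 0 || platform_duplicate_frac > 1)
      stop("fractions must lie in [0, 1]")
    if (frac_signature * k_subtypes > 1)
      stop("frac_signature * k_subtypes exceeds 1: signatures must be disjoint")
    if (mixing_concentration <= 0 || profile_effect <= 0 || noise_sd < 0 ||
        fragment_noise_sd < 0)
      stop("scale parameters must be positive")
  })
  structure(cfg, class = "cohort_config")
}

#' Simulate longitudinal biomarker trajectories
#'
#' One row per (subject, visit, marker): value = baseline mean + subject
#' random intercept + subtype slope * time + residual noise. Visit counts and
#' follow-up spans are drawn per subject; the first visit is at time 0.
#'
#' @param labels integer subtype label per subject (1-based). Subtypes beyond
#'   the columns of `config$slopes` recycle.
#' @param config a [longitudinal_config()].
#' @param seed optional seed; omit to use the current RNG stream.
#' @return data.frame (subject, subtype, time, marker, value).
#' @export
simulate_longitudinal <- function(labels, config = longitudinal_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  subjects <- sprintf("S%03d", seq_len(n))
  markers <- rownames(config$slopes)
  k_avail <- ncol(config$slopes)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    n_visits <- max(2L, as.integer(round(rnorm(1, config$visits_mean, config$visits_sd))))
    span <- max(0.5, rnorm(1, config$span_mean, config$span_sd))
    times <- c(0, sort(runif(n_visits - 1L, 0, span)))
    subtype_col <- (labels[i] - 1L) %% k_avail + 1L
    per_marker <- lapply(markers, function(m) {
      b0 <- rnorm(1, 0, config$intercept_sd[[m]])
      mu <- config$baseline_mean[[m]] + b0 + config$slopes[m, subtype_col] * times
      data.frame(subject = subjects[i], subtype = labels[i], time = times,
                 marker = m,
                 value = mu + rnorm(n_visits, 0, config$residual_sd[[m]]),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, per_marker)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Synthetic brain cell-type expression reference
#'
#' Emulates a per-protein expression table over the five major brain cell
#' types (neuron, astrocyte, oligodendrocyte, microglia, endothelial).
#' Rows are constructed in three known categories so downstream specificity
#' labelling can be scored exactly: a `fraction_dominant` share where one
#' cell type exceeds 50% of the row total, a `fraction_undetected` share
#' where all levels are < 0.2, and a mixed remainder (all levels detected but
#' no type dominant). The construction category is attached as attribute
#' `true_category` (a vector of "non-specific"/"not detected"/cell-type
#' names); it is ground truth for tests, not an input to the labelling rule.
#'
#' @param n_proteins number of rows.
#' @param seed integer seed.
#' @param fraction_dominant,fraction_undetected category fractions (sum <= 1).
#' @return data.frame with a `protein` column and one column per cell type.
#' @export
generate_celltype_reference <- function(n_proteins, seed = 1L,
                                        fraction_dominant = 0.5,
                                        fraction_undetected = 0.2) {
  stopifnot(n_proteins >= 1, fraction_dominant >= 0, fraction_undetected >= 0,
            fraction_dominant + fraction_undetected <= 1)
  set.seed(seed)
  types <- c("neuron", "astrocyte", "oligodendrocyte", "microglia", "endothelial")
  n_dom <- round(fraction_dominant * n_proteins)
  n_und <- round(fraction_undetected * n_proteins)
  if (n_dom + n_und > n_proteins) n_und <- n_proteins - n_dom
  category <- sample(c(rep("dominant", n_dom), rep("undetected", n_und),
                       rep("mixed", n_proteins - n_dom - n_und)))
  expr <- matrix(0, n_proteins, length(types), dimnames = list(NULL, types))
  truth <- character(n_proteins)
  for (i in seq_len(n_proteins)) {
    if (category[i] == "dominant") {
      d <- sample.int(length(types), 1)
      dom_val <- runif(1, 2, 5)
      row <- runif(length(types), 0, dom_val / 8)   # others sum <= dom/2 < dom
      row[d] <- dom_val
      truth[i] <- types[d]
    } else if (category[i] == "undetected") {
      row <- runif(length(types), 0, 0.19)
      truth[i] <- "not detected"
    } else {
      # all detected, max < 1 <= half the row total: guaranteed non-specific
      row <- runif(length(types), 0.5, 1)
      truth[i] <- "non-specific"
    }
    expr[i, ] <- row
  }
  out <- data.frame(protein = sprintf("P%04d", seq_len(n_proteins)), expr,
                    stringsAsFactors = FALSE)
  attr(out, "true_category") <- truth
  out
}

#' Generate a synthetic cohort
#'
#' Builds every input the pipeline consumes, with ground truth recorded:
#' a subjects x proteins raw abundance matrix (log-normal positive baseline
#' per protein + subtype signature effects + Gaussian noise), control-group
#' reference statistics from a designated 20% subsample, an MRM fragment
#' table (plus RBM platform duplicates), a cell-type expression reference,
#' and longitudinal biomarker trajectories.
#'
#' The latent abundance of protein p in subject i is
#' `baseline_p + profile_effect * sum_j sig_jp * h_ij + e`, with `h_i` the
#' Dirichlet loadings, `sig_jp` the signature indicator and
#' `e ~ N(0, noise_sd)`. With hard loadings, a signature protein is therefore
#' elevated by exactly `profile_effect` in its subtype.
#'
#' @param config a [cohort_config()].
#' @return an object of class `csf_cohort`: list with `protein_matrix`
#'   (subjects x proteins), `true_labels`, `loadings`, `signature` (protein
#'   ids per subtype), `control_ids`, `control_stats`, `fragment_table`,
#'   `celltype_reference`, `longitudinal_table`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  n <- config$n_subjects; p <- config$n_proteins; k <- config$k_subtypes
  subjects <- sprintf("S%03d", seq_len(n))
  proteins <- sprintf("P%04d", seq_len(p))

  loadings <- rdirichlet(n, rep(1 / config$mixing_concentration, k))
  labels <- max.col(loadings, ties.method = "first")

  n_sig <- floor(config$frac_signature * p)
  signature <- lapply(seq_len(k), function(j) proteins[seq_len(n_sig) + (j - 1L) * n_sig])
  w0 <- matrix(0, p, k)
  for (j in seq_len(k)) w0[match(signature[[j]], proteins), j] <- 1

  baseline <- rlnorm(p, meanlog = 2, sdlog = 0.3)
  latent <- config$profile_effect * (w0 %*% t(loadings))          # p x n
  noise <- matrix(rnorm(p * n, 0, config$noise_sd), p, n)
  signal <- baseline + latent + noise                             # p x n
  raw <- t(signal)
  dimnames(raw) <- list(subjects, proteins)

  control_ids <- sort(sample.int(n, max(2L, round(0.2 * n))))
  control_stats <- data.frame(
    protein = proteins,
    mean = colMeans(raw[control_ids, , drop = FALSE]),
    sd = apply(raw[control_ids, , drop = FALSE], 2, sd),
    stringsAsFactors = FALSE, row.names = NULL)

  nf <- config$n_fragments_per_protein
  frag <- data.frame(
    fragment = rep(paste0(rep(proteins, each = nf), "_f", seq_len(nf)), times = n),
    protein = rep(rep(proteins, each = nf), times = n),
    platform = "MRM",
    subject = rep(subjects, each = p * nf),
    value = as.vector(signal[rep(seq_len(p), each = nf), , drop = FALSE] +
                        rnorm(p * nf * n, 0, config$fragment_noise_sd)),
    stringsAsFactors = FALSE)
  n_dup <- round(config$platform_duplicate_frac * p)
  if (n_dup > 0) {
    dup_proteins <- sort(sample.int(p, n_dup))
    dup <- data.frame(
      fragment = rep(paste0(proteins[dup_proteins], "_RBM"), times = n),
      protein = rep(proteins[dup_proteins], times = n),
      platform = "RBM",
      subject = rep(subjects, each = n_dup),
      value = as.vector(signal[dup_proteins, , drop = FALSE] +
                          rnorm(n_dup * n, 0, config$fragment_noise_sd)),
      stringsAsFactors = FALSE)
    frag <- rbind(frag, dup)
  }

  celltype <- generate_celltype_reference(p, seed = child_seed(config$seed, 1))
  # generate_celltype_reference reseeds; restore an independent stream for the
  # longitudinal draw so the cohort stays deterministic as a whole
  set.seed(child_seed(config$seed, 2))
  longit <- simulate_longitudinal(labels, config$longitudinal)

  structure(list(protein_matrix = raw,
                 true_labels = setNames(labels, subjects),
                 loadings = loadings,
                 signature = signature,
                 control_ids = subjects[control_ids],
                 control_stats = control_stats,
                 fragment_table = frag,
                 celltype_reference = celltype,
                 longitudinal_table = longit,
                 config = config),
            class = "csf_cohort")
}

#' Write a synthetic cohort to disk
#'
#' TSV tables with header rows plus a JSON sidecar holding the ground-truth
#' labels and the generating configuration (for tests; the analysis stages
#' never read it).
#'
#' @param cohort a `csf_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "csf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    path <- file.path(dir, name)
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  pm <- data.frame(subject = rownames(cohort$protein_matrix),
                   cohort$protein_matrix, check.names = FALSE)
  paths <- c(
    tsv(pm, "protein_matrix.tsv"),
    tsv(cohort$control_stats, "control_stats.tsv"),
    tsv(cohort$fragment_table, "fragment_table.tsv"),
    tsv(cohort$celltype_reference, "celltype_reference.tsv"),
    tsv(cohort$longitudinal_table, "longitudinal_table.tsv"))
  sidecar <- file.path(dir, "truth.json")
  cfg <- cohort$config
  cfg$longitudinal <- lapply(unclass(cfg$longitudinal), function(x)
    if (is.matrix(x)) as.data.frame(x) else x)
  jsonlite::write_json(list(true_labels = as.list(cohort$true_labels),
                            control_ids = cohort$control_ids,
                            signature = cohort$signature,
                            config = unclass(cfg)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}
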