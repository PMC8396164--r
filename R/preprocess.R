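#' Control-group reference statistics
#'
#' Per-protein mean and SD over a designated control subsample, used to
#' standardize every measurement ("z-normalization to controls").
#'
#' @param mat subjects x proteins numeric matrix with subject rownames.
#' @param control_ids subject ids forming the control group.
#' @return data.frame (protein, mean, sd).
#' @export
control_reference <- function(mat, control_ids) {
  missing_ids <- setdiff(control_ids, rownames(mat))
  if (length(missing_ids)) stop("control ids not in matrix: ", paste(missing_ids, collapse = ", "))
  sub <- mat[control_ids, , drop = FALSE]
  data.frame(protein = colnames(mat), mean = colMeans(sub),
             sd = apply(sub, 2, sd), stringsAsFactors = FALSE, row.names = NULL)
}

#' Standardize abundances to the control group
#'
#' Replaces each value v by (v - mean_control) / sd_control, protein-wise.
#' Proteins with zero (or missing) control SD cannot be standardized and are
#' dropped with a warning.
#'
#' @param mat subjects x proteins matrix; every column must appear in
#'   `control_ref$protein`.
#' @param control_ref data.frame (protein, mean, sd), e.g. from
#'   [control_reference()].
#' @return standardized matrix, attribute `dropped` naming removed proteins.
#' @export
znormalize <- function(mat, control_ref) {
  missing_p <- setdiff(colnames(mat), control_ref$protein)
  if (length(missing_p)) stop("proteins without control stats: ", paste(missing_p, collapse = ", "))
  idx <- match(colnames(mat), control_ref$protein)
  mu <- control_ref$mean[idx]
  sdv <- control_ref$sd[idx]
  bad <- !is.finite(sdv) | sdv <= 0
  if (any(bad)) {
    warning(sum(bad), " protein(s) with zero control SD dropped: ",
            paste(colnames(mat)[bad], collapse = ", "))
  }
  out <- sweep(sweep(mat[, !bad, drop = FALSE], 2, mu[!bad], "-"), 2, sdv[!bad], "/")
  attr(out, "dropped") <- colnames(mat)[bad]
  attr(out, "standardized") <- TRUE
  out
}

# subjects x fragments matrix for one protein from the long fragment table
.frag_wide <- function(frag, subjects) {
  ids <- unique(frag$fragment)
  m <- matrix(NA_real_, length(subjects), length(ids),
              dimnames = list(subjects, ids))
  m[cbind(match(frag$subject, subjects), match(frag$fragment, ids))] <- frag$value
  m
}

#' Combine correlated fragments into protein scores
#'
#' For each protein, fragments that correlate (mean pairwise Pearson r
#' strictly above `correlation_threshold`, default 0.5) are averaged into a
#' protein score; fragments that do not correlate are left out. Retention is
#' greedy: while any retained fragment's mean pairwise r with the others
#' falls at or below the threshold, the fragment with the lowest mean
#' pairwise r is removed (ties: the later fragment id goes). A single
#' surviving fragment passes through unchanged; zero-variance fragments are
#' dropped up front, and a protein whose fragments are all dropped is
#' omitted and logged.
#'
#' @param fragments long data.frame (fragment, protein, platform, subject,
#'   value) of standardized (z-score) fragment values. Only rows with
#'   `platform == platform_use` are merged; other platforms are returned
#'   separately for [merge_platforms()].
#' @param correlation_threshold minimum mean pairwise r (strict).
#' @param platform_use platform whose fragments are rolled up (default MRM).
#' @return list: `scores` (subjects x proteins matrix), `other_platforms`
#'   (named list of subjects x proteins matrices, one per remaining
#'   platform), `provenance` (data.frame fragment/protein/status),
#'   `omitted` (proteins with no retained fragment).
#' @export
merge_fragments <- function(fragments, correlation_threshold = 0.5,
                            platform_use = "MRM") {
  stopifnot(all(c("fragment", "protein", "platform", "subject", "value") %in%
                  names(fragments)))
  if (anyDuplicated(fragments[, c("fragment", "subject")]))
    stop("(fragment, subject) pairs must be unique")
  subjects <- unique(fragments$subject)
  main <- fragments[fragments$platform == platform_use, , drop = FALSE]
  rest <- fragments[fragments$platform != platform_use, , drop = FALSE]
  proteins <- unique(main$protein)
  scores <- matrix(NA_real_, length(subjects), length(proteins),
                   dimnames = list(subjects, proteins))
  prov <- list()
  omitted <- character(0)
  for (pr in proteins) {
    wide <- .frag_wide(main[main$protein == pr, , drop = FALSE], subjects)
    sds <- apply(wide, 2, sd, na.rm = TRUE)
    degenerate <- !is.finite(sds) | sds == 0
    status <- setNames(rep("retained", ncol(wide)), colnames(wide))
    status[degenerate] <- "dropped_degenerate"
    keep <- colnames(wide)[!degenerate]
    while (length(keep) > 1) {
      r <- cor(wide[, keep, drop = FALSE], use = "pairwise.complete.obs")
      mean_r <- (rowSums(r) - 1) / (length(keep) - 1)
      if (all(mean_r > correlation_threshold)) break
      worst <- keep[max(which(mean_r == min(mean_r)))]
      status[worst] <- "dropped_uncorrelated"
      keep <- setdiff(keep, worst)
    }
    if (length(keep) == 0) {
      omitted <- c(omitted, pr)
      message("protein ", pr, " omitted: no retained fragment")
    } else {
      scores[, pr] <- rowMeans(wide[, keep, drop = FALSE])
    }
    prov[[pr]] <- data.frame(fragment = names(status), protein = pr,
                             status = unname(status), stringsAsFactors = FALSE)
  }
  scores <- scores[, setdiff(proteins, omitted), drop = FALSE]
  other <- lapply(split(rest, rest$platform), function(d) {
    ids <- unique(d$protein)
    m <- matrix(NA_real_, length(subjects), length(ids),
                dimnames = list(subjects, ids))
    m[cbind(match(d$subject, subjects), match(d$protein, ids))] <- d$value
    m
  })
  list(scores = scores, other_platforms = other,
       provenance = do.call(rbind, c(prov, list(make.row.names = FALSE))),
       omitted = omitted)
}

#' Reconcile proteins measured on multiple platforms
#'
#' For each protein present on the primary (MRM) platform and on another
#' platform: if the two standardized vectors correlate with r > 0.5 they are
#' averaged; if r lies in (-0.5, 0.5] the MRM measurement is kept and the
#' other dropped; a strong anticorrelation (r <= the exclusion threshold,
#' default -0.5) excludes the protein entirely. A protein measured only on a
#' secondary platform (no MRM version to fall back on) is kept only in the
#' averaging branch; otherwise it is excluded and logged.
#'
#' @param mrm subjects x proteins matrix of primary-platform scores.
#' @param other_platforms named list of subjects x proteins matrices.
#' @param correlation_threshold averaging threshold (strict >; default 0.5).
#' @param anticorrelation_exclusion_threshold exclusion bound (default -0.5).
#' @return list: `matrix` (merged subjects x proteins), `log` (data.frame
#'   protein/platform/r/action).
#' @export
merge_platforms <- function(mrm, other_platforms,
                            correlation_threshold = 0.5,
                            anticorrelation_exclusion_threshold = -0.5) {
  out <- mrm
  log <- list()
  excluded <- character(0)
  for (pl in names(other_platforms)) {
    om <- other_platforms[[pl]]
    for (pr in colnames(om)) {
      if (pr %in% colnames(mrm)) {
        r <- cor(mrm[, pr], om[rownames(mrm), pr], use = "pairwise.complete.obs")
        if (is.finite(r) && r > correlation_threshold) {
          out[, pr] <- (mrm[, pr] + om[rownames(mrm), pr]) / 2
          action <- "averaged"
        } else if (is.finite(r) && r <= anticorrelation_exclusion_threshold) {
          excluded <- c(excluded, pr)
          action <- "excluded_anticorrelated"
        } else {
          action <- "kept_MRM"
        }
      } else {
        r <- NA_real_
        excluded <- c(excluded, pr)
        action <- "excluded_no_MRM"
        message("protein ", pr, " on platform ", pl, " has no MRM version; excluded")
      }
      log[[paste(pl, pr)]] <- data.frame(protein = pr, platform = pl, r = r,
                                         action = action, stringsAsFactors = FALSE)
    }
  }
  out <- out[, setdiff(colnames(out), excluded), drop = FALSE]
  list(matrix = out, log = do.call(rbind, c(log, list(make.row.names = FALSE))))
}

#' Completeness filter and panel restriction
#'
#' Keeps only proteins observed in 100% of the sample (no missing value in
#' any subject) and, when a panel is supplied, only proteins on the
#' disease-associated panel.
#'
#' @param mat subjects x proteins matrix, possibly with NAs.
#' @param panel optional character vector of protein ids to retain.
#' @return filtered matrix; attribute `filter_counts` records proteins
#'   dropped per rule. Errors if nothing survives.
#' @export
filter_and_select <- function(mat, panel = NULL) {
  complete <- colSums(is.na(mat)) == 0
  n_incomplete <- sum(!complete)
  out <- mat[, complete, drop = FALSE]
  n_off_panel <- 0L
  if (!is.null(panel)) {
    on_panel <- colnames(out) %in% panel
    n_off_panel <- sum(!on_panel)
    out <- out[, on_panel, drop = FALSE]
  }
  if (ncol(out) == 0) stop("no proteins survive the completeness/panel filter")
  attr(out, "filter_counts") <- c(incomplete = n_incomplete, off_panel = n_off_panel)
  out
}

#' Shift a standardized matrix to be nonnegative
#'
#' NMF requires nonnegative input; standardized (z-score) matrices are not.
#' The default subtracts the single global minimum from every entry, which
#' preserves all between-protein contrasts and is invertible via the
#' recorded shift. `per_protein_min_shift` instead shifts each protein by
#' its own minimum.
#'
#' @param mat numeric matrix.
#' @param mode `"global_min_shift"` (default) or `"per_protein_min_shift"`.
#' @return nonnegative matrix with attribute `shift` (scalar or per-protein
#'   vector; 0 when the input is already nonnegative).
#' @export
nonneg_shift <- function(mat, mode = c("global_min_shift", "per_protein_min_shift")) {
  mode <- match.arg(mode)
  if (mode == "global_min_shift") {
    shift <- min(0, min(mat))
    out <- mat - shift
  } else {
    shift <- pmin(0, apply(mat, 2, min))
    out <- sweep(mat, 2, shift, "-")
  }
  attr(out, "shift") <- shift
  attr(out, "shift_mode") <- mode
  out
}

#' Invert [nonneg_shift()]
#' @param mat a matrix produced by [nonneg_shift()].
#' @return the original matrix.
#' @export
nonneg_unshift <- function(mat) {
  shift <- attr(mat, "shift")
  if (is.null(shift)) stop("matrix carries no shift record")
  mode <- attr(mat, "shift_mode")
  out <- if (identical(mode, "per_protein_min_shift")) sweep(mat, 2, shift, "+") else mat + shift
  attr(out, "shift") <- NULL
  attr(out, "shift_mode") <- NULL
  out
}

#' Full harmonization: fragments and platforms to analysis matrix
#'
#' Convenience wrapper running the full preprocessing chain on a long
#' fragment table: standardize fragments to controls, roll up correlated
#' MRM fragments, reconcile platform duplicates, apply the completeness and
#' panel filters.
#'
#' @param fragments long fragment table (fragment, protein, platform,
#'   subject, value), raw scale.
#' @param control_ids control-group subject ids.
#' @param panel optional protein panel to retain.
#' @param correlation_threshold,anticorrelation_exclusion_threshold see
#'   [merge_fragments()] and [merge_platforms()].
#' @return list: `matrix` (standardized subjects x proteins), `provenance`
#'   (fragment log), `platform_log`.
#' @export
preprocess_fragments <- function(fragments, control_ids, panel = NULL,
                                 correlation_threshold = 0.5,
                                 anticorrelation_exclusion_threshold = -0.5) {
  subjects <- unique(fragments$subject)
  frag_ids <- unique(fragments$fragment)
  wide <- matrix(NA_real_, length(subjects), length(frag_ids),
                 dimnames = list(subjects, frag_ids))
  wide[cbind(match(fragments$subject, subjects),
             match(fragments$fragment, frag_ids))] <- fragments$value
  ref <- control_reference(wide, control_ids)
  z <- znormalize(wide, ref)
  zlong <- fragments[fragments$fragment %in% colnames(z), , drop = FALSE]
  zlong$value <- z[cbind(match(zlong$subject, rownames(z)),
                         match(zlong$fragment, colnames(z)))]
  merged <- merge_fragments(zlong, correlation_threshold)
  plat <- merge_platforms(merged$scores, merged$other_platforms,
                          correlation_threshold,
                          anticorrelation_exclusion_threshold)
  mat <- filter_and_select(plat$matrix, panel)
  list(matrix = mat, provenance = merged$provenance, platform_log = plat$log)
}
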