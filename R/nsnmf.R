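#' Nonsmooth NMF smoothing matrix
#'
#' S = (1 - theta) I + (theta / k) J, with J the all-ones matrix. Inserted
#' between basis and coefficients (V ~ W S H), it smooths one factor and
#' thereby forces sparseness (enhanced separability) on the other. theta = 0
#' recovers plain NMF; theta = 1 replaces every component by the average.
#'
#' @param k factorization rank.
#' @param theta smoothing intensity in \[0, 1\].
#' @return a symmetric doubly stochastic k x k matrix.
#' @export
smoothing_matrix <- function(k, theta) {
  stopifnot(k >= 1, theta >= 0, theta <= 1)
  (1 - theta) * diag(k) + theta / k
}

#' Nonsmooth nonnegative matrix factorization
#'
#' Factorizes a nonnegative proteins x subjects matrix V as W S H
#' (W: protein profiles, H: subject loadings, S: the nonsmooth mixing
#' matrix), minimizing the Frobenius residual with multiplicative updates.
#' The residual sum of squares is non-increasing across iterations; the run
#' stops when its relative change drops below `tol` or at `max_iter`.
#' W and H start i.i.d. uniform(0, 1) scaled to V's mean, so the run is
#' deterministic given `seed`.
#'
#' @param V nonnegative numeric matrix, proteins in rows, subjects in
#'   columns, no missing values. Standardized matrices must first go through
#'   [nonneg_shift()].
#' @param k rank (number of subtypes/profiles), `k < min(dim(V))`.
#' @param theta nonsmoothing intensity, default 0.5.
#' @param max_iter,tol stopping rule (relative rss change).
#' @param seed optional integer seed for the initialization.
#' @return object of class `nsnmf_model`: `W`, `H`, `S`, `theta`, `rank`,
#'   `rss`, `rss_trace`, `iterations`.
#' @export
factorize <- function(V, k, theta = 0.5, max_iter = 2000, tol = 1e-6, seed = NULL) {
  V <- as.matrix(V)
  if (anyNA(V)) stop("V contains missing values")
  if (min(V) < 0)
    stop("V has negative entries; apply nonneg_shift() before factorizing")
  if (k < 1 || k >= min(dim(V)) + 1) stop("k must satisfy 1 <= k <= min(dim(V))")
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(V); n <- ncol(V)
  sc <- sqrt(max(mean(V), .Machine$double.eps) / k)
  W <- matrix(runif(p * k), p, k) * sc
  H <- matrix(runif(k * n), k, n) * sc
  S <- smoothing_matrix(k, theta)
  fit <- nsnmf_update_cpp(V, W, H, S, as.integer(max_iter), tol)
  structure(list(W = fit$W, H = fit$H, S = S, theta = theta, rank = as.integer(k),
                 rss = fit$rss, rss_trace = fit$rss_trace,
                 iterations = fit$iterations,
                 proteins = rownames(V), subjects = colnames(V)),
            class = "nsnmf_model")
}

#' @exportS3Method base::print
print.nsnmf_model <- function(x, ...) {
  cat("nsNMF model: rank", x$rank, "| theta", x$theta,
      "| rss", format(x$rss, digits = 6),
      "|", x$iterations, "iterations\n")
  invisible(x)
}

#' Assign subjects to subtypes from a fitted model
#'
#' Each subject is labelled with the component whose loading is largest
#' (the protein profile that best matches their proteomic expression).
#' For new subjects, their columns are first projected onto the fixed basis
#' W S by nonnegative least squares. Ties go to the lowest component index
#' with a warning. Loadings are reported normalized to sum 1 per subject.
#'
#' @param model an `nsnmf_model`.
#' @param V_new optional nonnegative matrix of new subjects (same proteins,
#'   same order, as the training matrix).
#' @return list: `labels` (integer vector), `loadings` (subjects x k matrix,
#'   rows sum to 1), `ties` (indices of tied subjects, if any).
#' @export
predict_subtypes <- function(model, V_new = NULL) {
  stopifnot(inherits(model, "nsnmf_model"))
  if (is.null(V_new)) {
    H <- model$H
    subjects <- model$subjects
  } else {
    V_new <- as.matrix(V_new)
    if (nrow(V_new) != nrow(model$W))
      stop("V_new must have the same proteins (rows) as the training matrix")
    if (min(V_new) < 0) stop("V_new has negative entries")
    H <- nnls_project_cpp(model$W %*% model$S, V_new, 2000L, 1e-10)
    subjects <- colnames(V_new)
  }
  tot <- colSums(H)
  tot[tot == 0] <- 1
  loadings <- t(sweep(H, 2, tot, "/"))
  labels <- apply(H, 2, which.max)
  ties <- which(apply(H, 2, function(h) sum(h == max(h)) > 1))
  if (length(ties))
    warning("tied loadings for ", length(ties),
            " subject(s); assigned to the lowest component index")
  if (!is.null(subjects)) {
    names(labels) <- subjects
    rownames(loadings) <- subjects
  }
  list(labels = labels, loadings = loadings, ties = ties)
}

# consensus (co-assignment frequency) matrix from an n_runs x n_subjects
# label matrix; shared by run_consensus and the test harness's random-label
# injection
consensus_from_labels <- function(label_matrix) {
  n <- ncol(label_matrix)
  C <- matrix(0, n, n)
  for (r in seq_len(nrow(label_matrix))) {
    lab <- label_matrix[r, ]
    C <- C + outer(lab, lab, "==")
  }
  C / nrow(label_matrix)
}

#' Cophenetic correlation of a consensus matrix
#'
#' Correlation between the consensus dissimilarities (1 - C) and the
#' cophenetic distances of their average-linkage hierarchical clustering.
#' 1 means subjects are always classified the same across restarts; values
#' near 0 mean an unstable solution. If all dissimilarities are identical
#' (degenerate tree), the coefficient is 1 when the cophenetic distances
#' reproduce them exactly and 0 otherwise.
#'
#' @param C consensus matrix (symmetric, diagonal 1, entries in \[0, 1\]).
#' @return scalar in \[-1, 1\] (in practice \[0, 1\]).
#' @export
cophenetic_coefficient <- function(C) {
  d <- as.dist(1 - C)
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (sd(d) == 0 || sd(cd) == 0) {
    return(if (max(abs(cd - d)) < 1e-12) 1 else 0)
  }
  cor(d, cd)
}

#' Multi-restart consensus clustering
#'
#' Runs `n_runs` nsNMF factorizations from distinct seeded initializations,
#' assigns hard labels per run via [predict_subtypes()], and accumulates the
#' subject x subject consensus matrix C (fraction of runs co-clustered).
#' Stability is summarized by the cophenetic coefficient of C and by the
#' mean silhouette width on the consensus dissimilarity 1 - C under the
#' consensus labels (average-linkage tree cut at k). The best-rss restart is
#' kept as the reference model.
#'
#' @inheritParams factorize
#' @param n_runs number of restarts (>= 2 for an informative consensus; a
#'   single run yields a binary C with cophenetic 1, flagged uninformative).
#' @param seed integer; per-run seeds are derived deterministically.
#' @return object of class `nsnmf_consensus`: `consensus`, `cophenetic`,
#'   `silhouette`, `labels` (consensus labels), `per_run_rss`, `best_model`,
#'   `rank`, `n_runs`, `degenerate_runs`.
#' @export
run_consensus <- function(V, k, theta = 0.5, n_runs = 50, seed = 1L,
                          max_iter = 2000, tol = 1e-6) {
  V <- as.matrix(V)
  n <- ncol(V)
  run_seeds <- child_seed(seed, seq_len(n_runs))
  labels_mat <- matrix(NA_integer_, n_runs, n)
  rss <- numeric(n_runs)
  best <- NULL
  degenerate <- integer(0)
  for (r in seq_len(n_runs)) {
    model <- factorize(V, k, theta, max_iter, tol, seed = run_seeds[r])
    lab <- predict_subtypes(model)$labels
    if (length(unique(lab)) < k) degenerate <- c(degenerate, r)
    labels_mat[r, ] <- lab
    rss[r] <- model$rss
    if (is.null(best) || model$rss < best$rss) best <- model
  }
  if (length(degenerate))
    message(length(degenerate), " run(s) with an empty component (kept, logged)")
  C <- consensus_from_labels(labels_mat)
  dimnames(C) <- list(colnames(V), colnames(V))
  hc <- hclust(as.dist(1 - C), method = "average")
  cons_labels <- cutree(hc, k = k)
  structure(list(consensus = C,
                 cophenetic = cophenetic_coefficient(C),
                 silhouette = silhouette_width(1 - C, cons_labels),
                 labels = cons_labels,
                 per_run_rss = rss,
                 best_model = best,
                 rank = as.integer(k), n_runs = n_runs,
                 degenerate_runs = degenerate,
                 uninformative = n_runs < 2),
            class = "nsnmf_consensus")
}

#' @exportS3Method base::print
print.nsnmf_consensus <- function(x, ...) {
  cat("nsNMF consensus: rank", x$rank, "|", x$n_runs, "runs",
      "| cophenetic", format(x$cophenetic, digits = 4),
      "| mean silhouette", format(x$silhouette, digits = 4), "\n")
  if (x$uninformative) cat("  (single run: consensus uninformative)\n")
  invisible(x)
}

# best rss over n_runs seeded restarts (no consensus bookkeeping); used for
# the rank-below-range baseline in select_rank
best_rss <- function(V, k, theta, n_runs, seed, max_iter, tol) {
  min(vapply(seq_len(n_runs), function(r)
    factorize(V, k, theta, max_iter, tol, seed = child_seed(seed, r))$rss,
    numeric(1)))
}

# per-protein (row-wise) permutation of subjects: preserves marginals,
# destroys co-structure; one fresh permutation per restart
permute_rows <- function(V) t(apply(V, 1, sample))

#' Stability-based rank selection
#'
#' Evaluates each candidate rank k by multi-restart consensus on V and on
#' randomly permuted copies of V (each protein's values shuffled across
#' subjects independently, one fresh permutation per restart). A rank is
#' admissible when
#' 1. its cophenetic coefficient is high (within `coph_window` of the best
#'    over the tested range),
#' 2. the fit improvement over the next-lower rank is at least `fit_factor`
#'    times the improvement seen on the random (permuted) data, and
#' 3. the mean silhouette width is at least `silhouette_min`.
#' The selected rank is the largest admissible one; if none qualifies the
#' result carries an explicit failure state (`selected_rank = NA`).
#'
#' @inheritParams run_consensus
#' @param ranks candidate ranks (>= 2 values, each >= 2; the fit criterion
#'   also factorizes at `min(ranks) - 1`).
#' @param coph_window tolerance below the maximum cophenetic coefficient.
#' @param silhouette_min minimum mean silhouette width (default 0.5).
#' @param fit_factor required fold-improvement over the random baseline.
#' @return object of class `rank_selection`: `table` (per-rank criteria),
#'   `selected_rank` (integer or NA), `consensus` (per-rank list).
#' @export
select_rank <- function(V, ranks = 2:5, theta = 0.5, n_runs = 50, seed = 1L,
                        max_iter = 2000, tol = 1e-6, coph_window = 0.02,
                        silhouette_min = 0.5, fit_factor = 2) {
  ranks <- sort(unique(as.integer(ranks)))
  if (length(ranks) < 2) stop("rank selection needs a range of at least 2 ranks")
  if (min(ranks) < 2) stop("candidate ranks must be >= 2")
  V <- as.matrix(V)
  all_k <- c(min(ranks) - 1L, ranks)

  cons <- setNames(vector("list", length(ranks)), ranks)
  rss <- rss_perm <- setNames(numeric(length(all_k)), all_k)
  for (k in all_k) {
    key <- as.character(k)
    if (k %in% ranks) {
      cons[[key]] <- run_consensus(V, k, theta, n_runs, seed = child_seed(seed, 31L * k),
                                   max_iter, tol)
      rss[key] <- min(cons[[key]]$per_run_rss)
    } else {
      rss[key] <- best_rss(V, k, theta, n_runs, seed = child_seed(seed, 31L * k),
                           max_iter, tol)
    }
    perm_rss <- vapply(seq_len(n_runs), function(r) {
      set.seed(child_seed(seed, 97L * k + r))
      Vp <- permute_rows(V)
      factorize(Vp, k, theta, max_iter, tol, seed = child_seed(seed, 57L * k + r))$rss
    }, numeric(1))
    rss_perm[key] <- min(perm_rss)
  }

  coph <- vapply(cons, function(x) x$cophenetic, numeric(1))
  sil <- vapply(cons, function(x) x$silhouette, numeric(1))
  gain <- rss[as.character(ranks - 1L)] - rss[as.character(ranks)]
  gain_perm <- rss_perm[as.character(ranks - 1L)] - rss_perm[as.character(ranks)]
  crit_coph <- coph >= max(coph) - coph_window
  crit_fit <- gain >= fit_factor * gain_perm
  crit_sil <- sil >= silhouette_min
  admissible <- crit_coph & crit_fit & crit_sil
  selected <- if (any(admissible)) max(ranks[admissible]) else NA_integer_

  tab <- data.frame(rank = ranks, cophenetic = unname(coph),
                    silhouette = unname(sil),
                    rss = unname(rss[as.character(ranks)]),
                    rss_perm = unname(rss_perm[as.character(ranks)]),
                    fit_gain = unname(gain), fit_gain_perm = unname(gain_perm),
                    crit_cophenetic = unname(crit_coph),
                    crit_fit = unname(crit_fit),
                    crit_silhouette = unname(crit_sil),
                    admissible = unname(admissible))
  structure(list(table = tab, selected_rank = selected, consensus = cons,
                 baseline_rss = rss[1], failed = is.na(selected)),
            class = "rank_selection")
}

#' @exportS3Method base::print
print.rank_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (is.na(x$selected_rank)) {
    cat("No rank satisfies all selection criteria.\n")
  } else {
    cat("Selected rank:", x$selected_rank, "\n")
  }
  invisible(x)
}

#' Serialize a factor model to a directory of TSV matrices + JSON metadata
#' @param model an `nsnmf_model`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "nsnmf_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("W", "H", "S"))
    write.table(model[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(rank = model$rank, theta = model$theta,
                            rss = model$rss, iterations = model$iterations,
                            proteins = model$proteins, subjects = model$subjects),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a factor model written by [write_model()]
#' @param dir model directory.
#' @return an `nsnmf_model`.
#' @export
read_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  read_mat <- function(nm) as.matrix(read.table(file.path(dir, paste0(nm, ".tsv")),
                                                sep = "\t", header = FALSE))
  W <- unname(read_mat("W")); H <- unname(read_mat("H")); S <- unname(read_mat("S"))
  structure(list(W = W, H = H, S = S, theta = meta$theta,
                 rank = as.integer(meta$rank), rss = meta$rss,
                 rss_trace = NULL, iterations = meta$iterations,
                 proteins = meta$proteins, subjects = meta$subjects),
            class = "nsnmf_model")
}
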