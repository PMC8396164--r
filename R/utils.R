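#' @useDynLib csfsubtypes, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats as.dist cophenetic cor cutree hclust mad median pchisq
#'   pf pnorm pt qnorm rgamma rlnorm rnorm runif sd setNames aggregate
#'   coef lm model.matrix pairwise.t.test chisq.test vcov resid fitted
#' @importFrom utils write.table read.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw from a symmetric Dirichlet distribution
#'
#' @param n number of draws.
#' @param alpha vector of concentration parameters (length = dimension).
#' @return an `n x length(alpha)` matrix whose rows sum to 1.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # guard the alpha -> 0 limit where all gammas can underflow to 0
  zero <- rowSums(x) == 0
  if (any(zero)) {
    x[zero, ] <- 0
    x[cbind(which(zero), sample.int(k, sum(zero), replace = TRUE))] <- 1
  }
  x / rowSums(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors (Hubert & Arabie).
#' Used to score recovery of generator ground truth by the clustering.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Mean silhouette width from a dissimilarity matrix
#'
#' Standard silhouette s(i) = (b - a) / max(a, b), where a is the mean
#' dissimilarity of subject i to its own cluster and b the smallest mean
#' dissimilarity to any other cluster. Subjects in singleton clusters get
#' s(i) = 0 by convention (noted via message).
#'
#' @param d square symmetric dissimilarity matrix.
#' @param labels cluster labels, one per row of `d`.
#' @param per_subject return the per-subject widths instead of the mean?
#' @return mean silhouette width (or the per-subject vector).
#' @export
silhouette_width <- function(d, labels, per_subject = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(ncol(d) == n, length(labels) == n)
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette requires at least 2 clusters")
  sizes <- tabulate(labels, k)
  if (any(sizes == 1)) message("singleton cluster(s): silhouette set to 0 for their members")
  s <- numeric(n)
  # mean dissimilarity of each subject to each cluster
  cl_sums <- vapply(seq_len(k), function(g) rowSums(d[, labels == g, drop = FALSE]), numeric(n))
  for (i in seq_len(n)) {
    g <- labels[i]
    if (sizes[g] == 1) { s[i] <- 0; next }
    a <- cl_sums[i, g] / (sizes[g] - 1)
    b <- min(cl_sums[i, -g] / sizes[-g])
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  if (per_subject) s else mean(s)
}

#' Overlap (Szymkiewicz–Simpson) coefficient of two sets
#'
#' |A intersect B| / min(|A|, |B|): 0 means no overlap, 1 means one set is a
#' complete (sub)set of the other.
#'
#' @param a,b non-empty vectors treated as sets (duplicates ignored).
#' @return a scalar in \[0, 1\].
#' @export
#' @examples
#' overlap_coefficient(c("p1", "p2", "p3"), c("p2", "p3", "p4", "p5"))
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0)
    stop("overlap coefficient is undefined for empty sets")
  length(intersect(a, b)) / min(length(a), length(b))
}

# deterministic child seeds (documented splitting rule: large prime stride,
# kept below 2^31 so set.seed() always accepts them)
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483629L)
}
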