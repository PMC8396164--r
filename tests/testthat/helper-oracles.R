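# Independent oracles and shared fixtures. These deliberately re-derive
# quantities with different code paths than the package (brute force loops,
# textbook formulas) so agreement is evidence, not tautology.

# small cohort used across tests (fast; k = 3 latent subtypes)
small_cohort_config <- function(seed = 1, ...) {
  args <- modifyList(list(n_subjects = 60, n_proteins = 80, k_subtypes = 3,
                          seed = seed), list(...))
  do.call(cohort_config, args)
}

# brute-force silhouette from the definition, one subject at a time
silhouette_oracle <- function(d, labels) {
  d <- as.matrix(d)
  labels <- as.integer(factor(labels))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force overlap coefficient via explicit element loops
overlap_oracle <- function(a, b) {
  a <- unique(a); b <- unique(b)
  hits <- 0
  for (x in a) if (any(b == x)) hits <- hits + 1
  hits / min(length(a), length(b))
}

# brute-force cell-type rule, one row at a time, straight from the wording:
# all < 0.2 -> not detected; any share > 50% -> that type; else non-specific
celltype_oracle <- function(row, types, detection = 0.2, dominance = 0.5) {
  if (all(row < detection)) return("not detected")
  shares <- row / sum(row)
  if (any(shares > dominance)) return(types[which.max(shares)])
  "non-specific"
}

# independent plain (theta = 0) NMF: textbook Lee-Seung updates in R
plain_nmf_rss <- function(V, W, H, iters = 5000) {
  for (i in seq_len(iters)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + 1e-12)
    W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + 1e-12)
  }
  sum((V - W %*% H)^2)
}

# reproduce factorize()'s seeded initialization so oracle and implementation
# start from the same point
factorize_init <- function(V, k, seed) {
  set.seed(seed)
  sc <- sqrt(mean(V) / k)
  list(W = matrix(runif(nrow(V) * k), nrow(V), k) * sc,
       H = matrix(runif(k * ncol(V)), k, ncol(V)) * sc)
}

# hand-rolled two-pass column standardization against control rows
zscore_oracle <- function(mat, control_rows) {
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[control_rows, j]
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    out[, j] <- (mat[, j] - m) / s
  }
  out
}

# preprocessed nonnegative proteins x subjects matrix for a cohort
cohort_V <- function(cohort) {
  pp <- preprocess_fragments(cohort$fragment_table, cohort$control_ids)
  nonneg_shift(t(pp$matrix))
}
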