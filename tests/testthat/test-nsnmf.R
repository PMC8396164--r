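test_that("smoothing_matrix follows (1-theta) I + theta/k J", {
  expect_equal(smoothing_matrix(4, 0), diag(4))
  expect_equal(smoothing_matrix(2, 1), matrix(0.5, 2, 2))
  S <- smoothing_matrix(3, 0.5)
  expect_equal(diag(S), rep(1 - 0.5 + 0.5 / 3, 3))       # 0.6667
  expect_equal(S[1, 2], 0.5 / 3, tolerance = 1e-12)      # 0.1667
  expect_equal(unname(rowSums(S)), rep(1, 3))
  expect_equal(S, t(S))
  expect_error(smoothing_matrix(3, 1.2))
})

test_that("factorize recovers an exact rank-1 matrix and rejects bad input", {
  set.seed(1)
  V <- outer(runif(20, 1, 3), runif(10, 1, 3))
  m <- factorize(V, 1, theta = 0, seed = 2)
  expect_lt(m$rss / sum(V^2), 1e-8)
  expect_error(factorize(V - 10, 2), "nonneg_shift")
  Vna <- V; Vna[1, 1] <- NA
  expect_error(factorize(Vna, 2), "missing")
  expect_error(factorize(V, 50), "k must satisfy")
})

test_that("rss decreases monotonically for every seed (multiplicative-update guarantee)", {
  set.seed(7)
  for (s in 1:5) {
    V <- matrix(runif(30 * 15, 0, 4), 30, 15)
    m <- factorize(V, 3, theta = 0.5, seed = s, max_iter = 500)
    expect_true(all(diff(m$rss_trace) <= 1e-9 * m$rss_trace[-length(m$rss_trace)] + 1e-12))
  }
})

test_that("theta = 0 agrees with an independent plain-NMF oracle", {
  set.seed(42)
  V <- matrix(runif(20 * 10, 0.5, 2), 20, 10)
  init <- factorize_init(V, 3, seed = 99)
  oracle_rss <- plain_nmf_rss(V, init$W, init$H, iters = 5000)
  m <- factorize(V, 3, theta = 0, seed = 99, max_iter = 5000, tol = 1e-12)
  expect_equal(m$rss, oracle_rss, tolerance = 1e-4)
})

test_that("scale consistency: c*V scales rss by c^2 and keeps labels", {
  set.seed(3)
  co <- generate_cohort(small_cohort_config(seed = 3, n_subjects = 40, n_proteins = 30))
  V <- cohort_V(co)
  m1 <- factorize(V, 3, seed = 5)
  m2 <- factorize(V * 2.5, 3, seed = 5)
  expect_equal(m2$rss, m1$rss * 2.5^2, tolerance = 1e-6)
  expect_equal(predict_subtypes(m2)$labels, predict_subtypes(m1)$labels)
})

test_that("predict_subtypes takes the argmax, breaks ties low, projects new subjects", {
  model <- structure(list(
    W = matrix(runif(12), 4, 3), S = smoothing_matrix(3, 0),
    H = cbind(c(0.9, 0.05, 0.05), c(0.5, 0.5, 0), c(0.1, 0.2, 0.7)),
    theta = 0, rank = 3L, rss = 0, proteins = NULL,
    subjects = c("a", "b", "c")), class = "nsnmf_model")
  expect_warning(pred <- predict_subtypes(model), "tied")
  expect_equal(unname(pred$labels), c(1L, 1L, 3L))
  expect_equal(pred$ties, 2L)
  expect_equal(unname(rowSums(pred$loadings)), rep(1, 3))

  # projecting a training column of a noise-free factorization reproduces
  # its training label
  co <- generate_cohort(small_cohort_config(seed = 6, noise_sd = 0.05,
                                            mixing_concentration = 1e9,
                                            n_subjects = 30, n_proteins = 40))
  V <- cohort_V(co)
  m <- factorize(V, 3, seed = 1)
  train <- predict_subtypes(m)
  proj <- predict_subtypes(m, V_new = V)
  expect_equal(unname(proj$labels), unname(train$labels))
})

test_that("consensus of two perfectly separated blocks is binary with rho = 1", {
  set.seed(8)
  # block-diagonal structure: two groups of subjects using disjoint proteins
  V <- rbind(cbind(matrix(5, 10, 8), matrix(0.01, 10, 8)),
             cbind(matrix(0.01, 10, 8), matrix(5, 10, 8))) +
    matrix(runif(20 * 16, 0, 0.05), 20, 16)
  cons <- run_consensus(t(V), 2, n_runs = 10, seed = 1)
  expect_true(all(cons$consensus %in% c(0, 1)))
  expect_equal(cons$cophenetic, 1)
  expect_equal(cons$silhouette, 1)
})

test_that("random labels give off-diagonal consensus near 1/k and low rho", {
  set.seed(10)
  k <- 4
  labels_mat <- matrix(sample.int(k, 200 * 60, replace = TRUE), 200, 60)
  C <- csfsubtypes:::consensus_from_labels(labels_mat)
  off <- C[upper.tri(C)]
  expect_equal(mean(off), 1 / k, tolerance = 0.01)
  expect_equal(diag(C), rep(1, 60))
  expect_lt(cophenetic_coefficient(C), 0.8)
})

test_that("a single run yields a binary consensus flagged uninformative", {
  co <- generate_cohort(small_cohort_config(seed = 9, n_subjects = 20, n_proteins = 30))
  cons <- run_consensus(cohort_V(co), 3, n_runs = 1, seed = 2)
  expect_true(all(cons$consensus %in% c(0, 1)))
  expect_equal(cons$cophenetic, 1)
  expect_true(cons$uninformative)
})

test_that("silhouette_width matches brute force and handles stated edge cases", {
  # fixed 6-subject toy dissimilarity
  set.seed(13)
  d <- as.matrix(dist(c(0, 0.1, 0.2, 5, 5.1, 9)))
  labels <- c(1, 1, 1, 2, 2, 3)
  expect_message(sw <- silhouette_width(d, labels), "singleton")
  expect_equal(sw, silhouette_oracle(d, labels), tolerance = 1e-12)

  # perfect separation: within 0, between 1
  d2 <- 1 - diag(4); d2[1, 2] <- d2[2, 1] <- 0; d2[3, 4] <- d2[4, 3] <- 0
  expect_equal(silhouette_width(d2, c(1, 1, 2, 2)), 1)

  # all dissimilarities equal -> a = b -> 0
  d3 <- matrix(0.7, 4, 4); diag(d3) <- 0
  expect_equal(silhouette_width(d3, c(1, 1, 2, 2)), 0)

  expect_error(silhouette_width(d3, c(1, 1, 1, 1)), "2 clusters")
})

test_that("silhouette_width agrees with cluster::silhouette on random cases", {
  skip_if_not_installed("cluster")
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(rnorm(40), 20, 2)
    d <- as.matrix(dist(x))
    labels <- sample(1:3, 20, replace = TRUE)
    if (length(unique(labels)) < 2) next
    ref <- mean(cluster::silhouette(labels, dmatrix = d)[, "sil_width"])
    expect_equal(silhouette_width(d, labels), ref, tolerance = 1e-10)
  }
})

test_that("select_rank validates its range and reports a failure state on noise", {
  set.seed(30)
  V <- matrix(abs(rnorm(40 * 25)), 40, 25)
  expect_error(select_rank(V, ranks = 3), "at least 2 ranks")
  expect_error(select_rank(V, ranks = 1:2), ">= 2")
  sel <- select_rank(V, ranks = 2:3, n_runs = 6, seed = 5)
  expect_s3_class(sel, "rank_selection")
  expect_true(is.na(sel$selected_rank) || is.integer(sel$selected_rank))
  expect_named(sel$consensus, c("2", "3"))
})

test_that("stability ceiling: rho <= 1 and silhouette in [-1, 1] on random consensus", {
  set.seed(17)
  for (i in 1:10) {
    labels_mat <- matrix(sample.int(3, 20 * 25, replace = TRUE), 20, 25)
    C <- csfsubtypes:::consensus_from_labels(labels_mat)
    rho <- cophenetic_coefficient(C)
    expect_lte(rho, 1)
    s <- silhouette_width(1 - C, cutree(hclust(as.dist(1 - C), "average"), 3))
    expect_gte(s, -1)
    expect_lte(s, 1)
  }
})

test_that("models serialize to TSV + JSON and read back equal", {
  co <- generate_cohort(small_cohort_config(seed = 14, n_subjects = 20, n_proteins = 25))
  m <- factorize(cohort_V(co), 3, seed = 3)
  dir <- withr::local_tempdir()
  write_model(m, dir)
  m2 <- read_model(dir)
  expect_equal(unname(m$W), m2$W, tolerance = 1e-12)
  expect_equal(unname(m$H), m2$H, tolerance = 1e-12)
  expect_equal(m$rss, m2$rss, tolerance = 1e-12)
  expect_equal(predict_subtypes(m)$labels, predict_subtypes(m2)$labels,
               ignore_attr = TRUE)
})
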