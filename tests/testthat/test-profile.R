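test_that("detect_loading_outliers flags extreme loadings only", {
  set.seed(1)
  load <- cbind(runif(30, 0.8, 1), runif(30, 0, 0.1), runif(30, 0, 0.1))
  expect_length(detect_loading_outliers(load), 0)     # homogeneous

  load_out <- load
  load_out[7, 1] <- 10 * median(apply(load, 1, max))  # 10x the median
  expect_equal(unname(detect_loading_outliers(load_out)), 7L)

  expect_length(detect_loading_outliers(load_out, threshold = Inf), 0)

  # mass flagging refused without override
  load_many <- load
  load_many[1:12, 1] <- 50
  expect_warning(res <- detect_loading_outliers(load_many), "20%")
  expect_length(res, 0)
  expect_gt(length(detect_loading_outliers(load_many, override = TRUE)), 0)
})

test_that("label_proteins takes the subtype with the highest mean, ties unlabeled", {
  mat <- cbind(p1 = c(1.2, 1.2, 0.1, 0.1, -0.3, -0.3),
               p2 = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
               p3 = c(0, 0, 2, 2, 0, 0))
  labels <- c(1, 1, 2, 2, 3, 3)
  expect_message(out <- label_proteins(mat, labels), "tied")
  expect_equal(unname(out), c(1L, NA_integer_, 2L))
  expect_error(label_proteins(mat, c(1, 1, 1, 1, 1, 2)), NA)
  # generator signature proteins map to their subtype when noise-free
  co <- generate_cohort(small_cohort_config(seed = 2, noise_sd = 0,
                                            mixing_concentration = 1e9))
  z <- scale(co$protein_matrix)
  lab <- label_proteins(z[, unlist(co$signature)], co$true_labels)
  expect_equal(unname(lab), rep(1:3, each = length(co$signature[[1]])))
})

test_that("subtype_specific_proteins requires significance against every other subtype", {
  set.seed(5)
  n_per <- 30
  labels <- rep(1:3, each = n_per)
  mat <- matrix(rnorm(90 * 3), 90, 3,
                dimnames = list(NULL, c("up_in_1", "up_vs_2_only", "null")))
  mat[labels == 1, "up_in_1"] <- mat[labels == 1, "up_in_1"] + 3
  mat[labels %in% c(1, 3), "up_vs_2_only"] <- mat[labels %in% c(1, 3), "up_vs_2_only"] + 3
  spec <- subtype_specific_proteins(mat, labels)
  expect_true("up_in_1" %in% spec$subtype1$increased)
  expect_false("up_vs_2_only" %in% spec$subtype1$increased)  # not higher than 3
  expect_false("null" %in% spec$subtype1$increased)
  expect_true("up_vs_2_only" %in% spec$subtype2$decreased)
  # increased and decreased sets of a subtype are disjoint
  for (s in spec) expect_length(intersect(s$increased, s$decreased), 0)
})

test_that("an elevated protein is detected consistently with a permutation oracle", {
  set.seed(8)
  n_per <- 30
  labels <- rep(1:2, each = n_per)
  x <- rnorm(60)
  x[labels == 1] <- x[labels == 1] + 3
  mat <- matrix(x, ncol = 1, dimnames = list(NULL, "p"))
  spec <- subtype_specific_proteins(mat, labels)
  expect_equal(spec$subtype1$increased, "p")
  # permutation oracle: observed mean difference never reached under the null
  obs <- mean(x[labels == 1]) - mean(x[labels == 2])
  perm <- replicate(500, {
    sh <- sample(x)
    mean(sh[1:n_per]) - mean(sh[-(1:n_per)])
  })
  expect_lt(mean(abs(perm) >= abs(obs)), 0.05)
})

test_that("subtypes with fewer than 3 subjects are skipped", {
  mat <- matrix(rnorm(14), 7, 2)
  expect_warning(spec <- subtype_specific_proteins(mat, c(1, 1, 1, 2, 2, 2, 3)),
                 "fewer than 3")
  expect_true(spec$subtype3$skipped)
})

test_that("difference_profile returns proteins significantly higher in s1", {
  set.seed(9)
  labels <- rep(1:2, each = 25)
  mat <- cbind(up = c(rnorm(25, 2), rnorm(25)), flat = rnorm(50))
  dp <- difference_profile(mat, labels, 1, 2)
  expect_equal(dp$higher, "up")
  dp_rev <- difference_profile(mat, labels, 2, 1)
  expect_false("up" %in% dp_rev$higher)
  expect_error(difference_profile(mat, labels, 1, 9), "unknown subtype")
})

test_that("overlap_coefficient matches the printed examples and brute force", {
  expect_equal(overlap_coefficient(c("p1", "p2"), c("p1", "p2", "p3", "p4")), 1)  # subset
  expect_equal(overlap_coefficient(c("a", "b"), c("c", "d")), 0)                  # disjoint
  expect_equal(overlap_coefficient(c("p1", "p2", "p3"), c("p2", "p3", "p4", "p5")),
               2 / 3, tolerance = 1e-12)
  expect_error(overlap_coefficient(character(0), "a"), "empty")
})

test_that("overlap_coefficient equals brute force on all subset pairs of a 6-set", {
  universe <- letters[1:6]
  subsets <- unlist(lapply(1:6, function(m)
    combn(universe, m, simplify = FALSE)), recursive = FALSE)
  for (i in seq(1, length(subsets), by = 3)) {
    for (j in seq(2, length(subsets), by = 5)) {
      a <- subsets[[i]]; b <- subsets[[j]]
      expect_equal(overlap_coefficient(a, b), overlap_oracle(a, b))
      # symmetry and containment property
      expect_equal(overlap_coefficient(a, b), overlap_coefficient(b, a))
      if (all(a %in% b)) expect_equal(overlap_coefficient(a, b), 1)
    }
  }
})

test_that("celltype_specificity applies the printed rules in order", {
  types <- c("neuron", "astrocyte", "oligodendrocyte", "microglia", "endothelial")
  ref <- rbind(c(0.6, 0.1, 0.1, 0.1, 0.1),    # neuron: 0.6/1.0 > 0.5
               c(0.1, 0.1, 0.1, 0.1, 0.1),    # all < 0.2 -> not detected
               c(0.4, 0.4, 0.2, 0, 0))        # max share 0.4 -> non-specific
  colnames(ref) <- types
  expect_equal(celltype_specificity(ref),
               c("neuron", "not detected", "non-specific"))
  expect_error(celltype_specificity(-ref), "nonnegative")
})

test_that("celltype_specificity matches brute force on a 100-row randomized reference", {
  ref <- generate_celltype_reference(100, seed = 33, fraction_dominant = 0.4,
                                     fraction_undetected = 0.3)
  m <- as.matrix(ref[, -1])
  oracle <- vapply(seq_len(nrow(m)), function(i)
    celltype_oracle(m[i, ], colnames(m)), character(1))
  expect_identical(celltype_specificity(ref), oracle)
})

test_that("detection threshold applies to raw levels, dominance to shares", {
  types <- c("neuron", "astrocyte", "oligodendrocyte", "microglia", "endothelial")
  row <- matrix(c(0.15, 0.01, 0.01, 0.01, 0.01), 1,
                dimnames = list(NULL, types))
  expect_equal(celltype_specificity(row), "not detected")  # despite 79% share
  # scaling above the threshold flips it to the dominant cell type
  expect_equal(celltype_specificity(row * 10), "neuron")
  # scale invariance holds only once everything is detected
  big <- row * 100
  expect_equal(celltype_specificity(big), celltype_specificity(big * 7))
})

test_that("compare_characteristics: chi-square and marginal means match hand computation", {
  # 2x2 table (20,10 / 10,20): all expected counts 15, X^2 = 4 * 25/15 = 6.667
  labels <- rep(1:2, each = 30)
  sex <- c(rep("F", 20), rep("M", 10), rep("F", 10), rep("M", 20))
  res <- compare_characteristics(labels, data.frame(sex = sex))
  expect_equal(res$sex$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res$sex$p, pchisq(20 / 3, 1, lower.tail = FALSE))

  # identical group means: p ~ 1, effect ~ 0
  x <- rep(c(1, 2, 3), 20)
  res0 <- compare_characteristics(rep(1:2, each = 30), data.frame(v = x))
  expect_gt(res0$v$p, 0.99)
  expect_lt(abs(res0$v$contrasts$estimate[1]), 1e-10)

  # balanced design: marginal means equal raw group means
  set.seed(2)
  y <- rnorm(60)
  resb <- compare_characteristics(labels, data.frame(y = y))
  expect_equal(unname(resb$y$emmeans),
               unname(tapply(y, labels, mean)), tolerance = 1e-12)

  # constant covariate skipped
  resc <- compare_characteristics(labels, data.frame(c = rep(1, 60)))
  expect_equal(resc$c$type, "skipped")
})

test_that("continuous covariates standardize to the control group (age exempt)", {
  set.seed(3)
  covars <- data.frame(tau = rnorm(40, 500, 100), age = rnorm(40, 70, 5))
  rownames(covars) <- sprintf("S%02d", 1:40)
  labels <- setNames(rep(1:2, each = 20), rownames(covars))
  controls <- rownames(covars)[1:10]
  res <- compare_characteristics(labels, covars, control_ids = controls)
  ctl_mean <- mean(covars$tau[1:10]); ctl_sd <- sd(covars$tau[1:10])
  manual <- tapply((covars$tau - ctl_mean) / ctl_sd, labels, mean)
  expect_equal(unname(res$tau$emmeans), unname(manual), tolerance = 1e-12)
  expect_equal(unname(res$age$emmeans), unname(tapply(covars$age, labels, mean)),
               tolerance = 1e-12)
})
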