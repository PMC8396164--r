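#' Flag subjects with outlying cluster loadings
#'
#' A subject is flagged when the robust z-score (median/MAD) of their
#' maximum raw loading exceeds `threshold`. Flagged subjects are meant to be
#' excluded and the clustering repeated, since extreme loadings can limit
#' the generalizability of a solution. If more than 20% of subjects would
#' be flagged, nothing is excluded unless `override = TRUE` (a mass
#' exclusion usually signals a modelling problem, not outliers).
#'
#' @param loadings subjects x k matrix of raw (unnormalized) loadings, or a
#'   [predict_subtypes()] result.
#' @param threshold robust z cut-off (default 3.5).
#' @param override allow exclusion of more than 20% of subjects.
#' @return integer indices (with subject names, if any) of flagged subjects.
#' @export
detect_loading_outliers <- function(loadings, threshold = 3.5, override = FALSE) {
  if (is.list(loadings) && !is.null(loadings$loadings)) loadings <- loadings$loadings
  loadings <- as.matrix(loadings)
  x <- apply(loadings, 1, max)
  med <- median(x)
  s <- mad(x)
  if (s == 0) return(integer(0))
  z <- (x - med) / s
  flagged <- which(z > threshold)
  if (length(flagged) > 0.2 * length(x) && !override) {
    warning("more than 20% of subjects flagged as loading outliers; ",
            "no exclusion performed (set override = TRUE to force)")
    return(integer(0))
  }
  flagged
}

#' Label proteins by the subtype with the highest average level
#'
#' @param mat subjects x proteins standardized matrix.
#' @param labels subtype label per subject (row).
#' @return integer vector (protein -> subtype); ties give NA and a message.
#' @export
label_proteins <- function(mat, labels) {
  stopifnot(nrow(mat) == length(labels))
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (any(tabulate(labels, k) == 0)) stop("every subtype needs at least one subject")
  means <- rowsum(mat, labels) / as.vector(tabulate(labels, k))   # k x p
  top <- apply(means, 2, which.max)
  tied <- apply(means, 2, function(m) sum(m == max(m)) > 1)
  if (any(tied)) {
    message(sum(tied), " protein(s) with tied subtype means left unlabeled")
    top[tied] <- NA_integer_
  }
  setNames(as.integer(top), colnames(mat))
}

# group means, pooled residual variance and per-contrast t statistics for
# every protein at once (each protein's model is a one-way fixed-effects
# linear model in the subtype factor)
.groupwise <- function(mat, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n_g <- tabulate(labels, k)
  means <- rowsum(mat, labels) / n_g                       # k x p
  ss <- rowsum(mat^2, labels) - n_g * means^2              # within-group SS
  df <- nrow(mat) - k
  s2 <- colSums(ss) / df                                   # pooled variance per protein
  list(means = means, n = n_g, s2 = s2, df = df, k = k)
}

#' Subtype-specific protein sets
#'
#' A protein is specifically increased in subtype s when its level is
#' significantly higher in s than in every other subtype (two-sided linear
#' model contrast per pair, positive effect and p < alpha for all of them);
#' specifically decreased sets are the mirror image. Tests are uncorrected
#' by default (set `adjust = "BH"` for Benjamini-Hochberg within each
#' pairwise contrast). Subtypes with fewer than 3 subjects are skipped with
#' a warning.
#'
#' @param mat subjects x proteins standardized matrix.
#' @param labels subtype label per subject.
#' @param alpha significance level per contrast (default 0.05).
#' @param adjust p-value adjustment across proteins ("none" or "BH").
#' @return list with one element per subtype: `increased` / `decreased`
#'   protein id vectors and `effects`, a data.frame of per-protein contrast
#'   effects and p-values against each other subtype.
#' @export
subtype_specific_proteins <- function(mat, labels, alpha = 0.05,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(nrow(mat) == length(labels))
  g <- .groupwise(mat, labels)
  k <- g$k
  if (k < 2) stop("need at least 2 subtypes")
  proteins <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
  out <- vector("list", k)
  for (s in seq_len(k)) {
    if (g$n[s] < 3) {
      warning("subtype ", s, " has fewer than 3 subjects; skipped")
      out[[s]] <- list(increased = character(0), decreased = character(0),
                       effects = NULL, skipped = TRUE)
      next
    }
    others <- setdiff(seq_len(k), s)
    eff <- p <- matrix(NA_real_, length(proteins), length(others),
                       dimnames = list(proteins, paste0("vs", others)))
    for (j in seq_along(others)) {
      o <- others[j]
      d <- g$means[s, ] - g$means[o, ]
      se <- sqrt(g$s2 * (1 / g$n[s] + 1 / g$n[o]))
      tstat <- d / se
      pv <- 2 * pt(-abs(tstat), df = g$df)
      if (adjust == "BH") pv <- stats::p.adjust(pv, "BH")
      eff[, j] <- d
      p[, j] <- pv
    }
    inc <- rowSums(eff > 0 & p < alpha) == length(others)
    dec <- rowSums(eff < 0 & p < alpha) == length(others)
    out[[s]] <- list(increased = proteins[inc], decreased = proteins[dec],
                     effects = data.frame(protein = proteins, effect = eff,
                                          p = p, check.names = FALSE),
                     skipped = FALSE)
  }
  names(out) <- paste0("subtype", seq_len(k))
  out
}

#' Pairwise subtype difference profiles
#'
#' For an ordered subtype pair (s1, s2), the set of proteins significantly
#' higher in s1 than in s2 (two-sided contrast, positive effect, p < alpha),
#' with per-protein effects. These sets are what gets compared against
#' external reference difference profiles via [overlap_coefficient()].
#'
#' @inheritParams subtype_specific_proteins
#' @param s1,s2 subtype labels to contrast.
#' @return list: `higher` (protein ids), `effects` data.frame.
#' @export
difference_profile <- function(mat, labels, s1, s2, alpha = 0.05) {
  g <- .groupwise(mat, labels)
  lv <- levels(factor(labels))
  i1 <- match(as.character(s1), lv); i2 <- match(as.character(s2), lv)
  if (is.na(i1) || is.na(i2)) stop("unknown subtype label")
  proteins <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
  d <- g$means[i1, ] - g$means[i2, ]
  se <- sqrt(g$s2 * (1 / g$n[i1] + 1 / g$n[i2]))
  p <- 2 * pt(-abs(d / se), df = g$df)
  list(higher = proteins[d > 0 & p < alpha],
       effects = data.frame(protein = proteins, effect = unname(d),
                            p = unname(p)))
}

#' Cell-type specificity label for protein expression rows
#'
#' Applies, in order: all five levels < `detection` (raw scale) -> "not
#' detected"; any cell type contributing more than `dominance` of the row
#' total -> that cell type; otherwise "non-specific". The detection
#' threshold applies to raw levels, the dominance threshold to row shares.
#'
#' @param reference data.frame or matrix with one column per cell type
#'   (non-numeric columns such as `protein` are carried through, not used).
#' @param detection detection threshold on raw levels (default 0.2).
#' @param dominance dominance threshold on the row share (default 0.5).
#' @return character vector of labels, one per row.
#' @export
celltype_specificity <- function(reference, detection = 0.2, dominance = 0.5) {
  if (is.data.frame(reference)) {
    num <- vapply(reference, is.numeric, logical(1))
    m <- as.matrix(reference[, num, drop = FALSE])
  } else {
    m <- as.matrix(reference)
  }
  if (any(m < 0)) stop("expression levels must be nonnegative")
  labels <- rep("non-specific", nrow(m))
  undetected <- apply(m, 1, function(r) all(r < detection))
  tot <- rowSums(m)
  share <- m / ifelse(tot == 0, 1, tot)
  top <- apply(share, 1, which.max)
  dominant <- share[cbind(seq_len(nrow(m)), top)] > dominance
  labels[dominant] <- colnames(m)[top[dominant]]
  labels[undetected] <- "not detected"
  labels
}

#' Post-hoc subtype comparisons of subject characteristics
#'
#' Continuous covariates are compared with a general linear model on the
#' subtype factor (overall two-sided F test, estimated marginal means per
#' subtype, pairwise contrasts); discrete covariates with a chi-square test
#' (no continuity correction by default). Continuous covariates other than
#' `age` are standardized to the control group's mean and SD when
#' `control_ids` is given. Constant covariates are skipped with a note.
#'
#' @param labels subtype label per subject (named by subject id when
#'   `control_ids` is used).
#' @param covariates data.frame of subject characteristics, rows aligned
#'   with `labels` (rownames = subject ids).
#' @param control_ids optional control subject ids for standardization.
#' @param correct continuity correction for 2x2 chi-square (default FALSE).
#' @return named list per covariate: for continuous ones `type`, `p`
#'   (overall F), `emmeans` (per-subtype marginal means), `contrasts`
#'   (pairwise estimate/SE/p); for discrete ones the chi-square statistic,
#'   df and p.
#' @export
compare_characteristics <- function(labels, covariates, control_ids = NULL,
                                    correct = FALSE) {
  stopifnot(nrow(covariates) == length(labels))
  grp <- factor(labels)
  out <- list()
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    if (is.numeric(x)) {
      if (sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
        out[[nm]] <- list(type = "skipped", note = "constant covariate")
        next
      }
      if (!identical(tolower(nm), "age") && !is.null(control_ids)) {
        ctl <- x[rownames(covariates) %in% control_ids]
        if (length(ctl) > 1 && sd(ctl, na.rm = TRUE) > 0)
          x <- (x - mean(ctl, na.rm = TRUE)) / sd(ctl, na.rm = TRUE)
      }
      fit <- lm(x ~ grp)
      an <- stats::anova(fit)
      emm <- tapply(fitted(fit), grp, mean)        # one-factor model: cell means
      lv <- levels(grp)
      pairs <- utils::combn(lv, 2)
      g <- .groupwise(matrix(x, ncol = 1), grp)
      contrasts <- apply(pairs, 2, function(pp) {
        i <- match(pp[1], lv); j <- match(pp[2], lv)
        est <- g$means[i, 1] - g$means[j, 1]
        se <- sqrt(g$s2[1] * (1 / g$n[i] + 1 / g$n[j]))
        c(estimate = est, SE = se, p = 2 * pt(-abs(est / se), df = g$df))
      })
      out[[nm]] <- list(type = "continuous",
                        p = an[["Pr(>F)"]][1],
                        emmeans = emm,
                        contrasts = data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " - "),
                                               t(contrasts)))
    } else {
      tab <- table(grp, x)
      if (ncol(tab) < 2) {
        out[[nm]] <- list(type = "skipped", note = "constant covariate")
        next
      }
      ct <- suppressWarnings(chisq.test(tab, correct = correct))
      out[[nm]] <- list(type = "discrete", statistic = unname(ct$statistic),
                        df = unname(ct$parameter), p = ct$p.value, table = tab)
    }
  }
  out
}
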