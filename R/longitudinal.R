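#' @importFrom lme4 lmer lmerControl fixef isSingular
NULL

# cluster-robust (CR1) covariance for an lm fit with clustered observations
.cluster_vcov <- function(fit, cluster) {
  X <- model.matrix(fit)
  u <- resid(fit) * X
  cl <- factor(cluster)
  m <- nlevels(cl)
  meat <- crossprod(rowsum(u, cl))
  bread <- solve(crossprod(X))
  n <- nrow(X); p <- ncol(X)
  adj <- m / (m - 1) * (n - 1) / (n - p)
  adj * bread %*% meat %*% bread
}

.prepare_long <- function(table, marker, subtype = NULL) {
  stopifnot(all(c("subject", "subtype", "time", "marker", "value") %in% names(table)))
  d <- table[table$marker == marker, , drop = FALSE]
  if (!is.null(subtype)) d <- d[d$subtype %in% subtype, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for marker ", marker)
  if (any(d$time < 0)) stop("visit times must be nonnegative")
  d$subject <- factor(d$subject)
  d
}

#' Per-subtype biomarker slope from repeated measures
#'
#' Fits value ~ time with subject-level random intercepts (lme4) within one
#' subtype and returns the per-year slope with its Wald SE and a two-sided
#' p-value on between-within denominator degrees of freedom
#' (n_obs - n_subjects - 1). When the random-intercept variance is not
#' estimable (singular fit or too little replication), the estimator falls
#' back to an ordinary least-squares fit with subject-clustered robust (CR1)
#' standard errors, and says so in the result.
#'
#' @param table long-format data.frame (subject, subtype, time in years,
#'   marker, value).
#' @param marker marker name to model.
#' @param subtype subtype label(s) to subset to; NULL = all rows pooled.
#' @return object of class `slope_estimate`: `beta` (units/year), `se`, `p`,
#'   `df`, `n_subjects`, `n_obs`, `subtype`, `marker`, `method`
#'   ("mixed" or "ols_cluster_robust").
#' @export
fit_subtype_slope <- function(table, marker, subtype = NULL) {
  d <- .prepare_long(table, marker, subtype)
  per_subj <- tapply(d$time, d$subject, function(t) length(unique(t)))
  if (sum(per_subj >= 2, na.rm = TRUE) < 2)
    stop("need at least 2 subjects with at least 2 visits")
  n_subj <- nlevels(droplevels(d$subject))
  df <- max(1L, nrow(d) - n_subj - 1L)

  method <- "mixed"
  fit <- tryCatch(
    suppressMessages(lme4::lmer(value ~ time + (1 | subject), data = d,
                                control = lme4::lmerControl(calc.derivs = FALSE))),
    error = function(e) NULL)
  singular <- !is.null(fit) && lme4::isSingular(fit, tol = 1e-5)
  if (is.null(fit) || singular) {
    method <- "ols_cluster_robust"
    ols <- lm(value ~ time, data = d)
    vc <- tryCatch(.cluster_vcov(ols, d$subject), error = function(e) vcov(ols))
    beta <- unname(coef(ols)["time"])
    se <- sqrt(vc["time", "time"])
  } else {
    beta <- unname(lme4::fixef(fit)["time"])
    se <- sqrt(as.matrix(vcov(fit))["time", "time"])
  }
  p <- if (se > 0) 2 * pt(-abs(beta / se), df = df) else 0
  structure(list(beta = beta, se = se, p = p, df = df,
                 n_subjects = n_subj, n_obs = nrow(d),
                 subtype = subtype, marker = marker, method = method),
            class = "slope_estimate")
}

#' @exportS3Method base::print
print.slope_estimate <- function(x, ...) {
  cat(sprintf("%s%s: beta = %.3f +/- %.3f per year (p = %.3g, %d subjects, %d obs, %s)\n",
              x$marker,
              if (is.null(x$subtype)) "" else paste0(" subtype ", paste(x$subtype, collapse = "/")),
              x$beta, x$se, x$p, x$n_subjects, x$n_obs, x$method))
  invisible(x)
}

#' Test whether biomarker slopes differ between subtypes
#'
#' Adds a subtype x time interaction to the random-intercept model and
#' reports the joint Wald chi-square p-value for the interaction terms,
#' together with the per-subtype slopes implied by the joint model.
#'
#' @inheritParams fit_subtype_slope
#' @return list: `p_interaction`, `chisq`, `df`, `slopes` (per-subtype
#'   slope implied by the joint fit), `method`.
#' @export
compare_slopes <- function(table, marker) {
  d <- .prepare_long(table, marker)
  d$subtype <- factor(d$subtype)
  if (nlevels(d$subtype) < 2) stop("slope comparison needs at least 2 subtypes")

  method <- "mixed"
  fit <- tryCatch(
    suppressMessages(lme4::lmer(value ~ time * subtype + (1 | subject), data = d,
                                control = lme4::lmerControl(calc.derivs = FALSE))),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    method <- "ols_cluster_robust"
    ols <- lm(value ~ time * subtype, data = d)
    b <- coef(ols)
    vc <- tryCatch(.cluster_vcov(ols, d$subject), error = function(e) vcov(ols))
  } else {
    b <- lme4::fixef(fit)
    vc <- as.matrix(vcov(fit))
  }
  ia <- grep("^time:subtype", names(b))
  stat <- drop(t(b[ia]) %*% solve(vc[ia, ia, drop = FALSE]) %*% b[ia])
  dfree <- length(ia)
  lv <- levels(d$subtype)
  slopes <- setNames(b["time"] + c(0, b[ia]), lv)
  list(p_interaction = pchisq(stat, dfree, lower.tail = FALSE),
       chisq = unname(stat), df = dfree, slopes = slopes, method = method)
}

#' Cross-subtype comparison of baseline marker values
#'
#' Takes each subject's earliest visit and compares subtypes with a linear
#' model on the subtype factor (overall F test + marginal means). Subjects
#' without any row for the marker are dropped and counted.
#'
#' @inheritParams fit_subtype_slope
#' @return list: `p` (overall), `means` (per-subtype baseline means),
#'   `n_dropped`.
#' @export
baseline_comparison <- function(table, marker) {
  d <- .prepare_long(table, marker)
  first <- do.call(rbind, lapply(split(d, d$subject, drop = TRUE), function(s)
    s[which.min(s$time), , drop = FALSE]))
  n_dropped <- nlevels(d$subject) - nrow(first)
  if (n_dropped > 0) message(n_dropped, " subject(s) without baseline dropped")
  first$subtype <- factor(first$subtype)
  if (nlevels(first$subtype) < 2) stop("need at least 2 subtypes at baseline")
  fit <- lm(value ~ subtype, data = first)
  an <- stats::anova(fit)
  list(p = an[["Pr(>F)"]][1],
       means = tapply(first$value, first$subtype, mean),
       n_dropped = n_dropped)
}

#' Slope table across markers and subtypes
#'
#' Convenience wrapper: [fit_subtype_slope()] for every (marker, subtype)
#' cell plus the [compare_slopes()] interaction p per marker.
#'
#' @param table long-format table as in [fit_subtype_slope()].
#' @param markers marker names (default: all present).
#' @return data.frame (marker, subtype, beta, se, p, n_subjects, n_obs,
#'   method, p_interaction).
#' @export
slope_table <- function(table, markers = NULL) {
  markers <- markers %||% unique(table$marker)
  rows <- list()
  for (m in markers) {
    subtypes <- sort(unique(table$subtype[table$marker == m]))
    p_int <- if (length(subtypes) > 1) compare_slopes(table, m)$p_interaction else NA_real_
    for (s in subtypes) {
      est <- fit_subtype_slope(table, m, s)
      rows[[paste(m, s)]] <- data.frame(
        marker = m, subtype = s, beta = est$beta, se = est$se, p = est$p,
        n_subjects = est$n_subjects, n_obs = est$n_obs, method = est$method,
        p_interaction = p_int, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
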