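COHERENCE_LEVELS <- c("low", "medium", "high")

#' Three-level ordinal coherence label from sample ratings
#'
#' The per-sample coherence scores of one subject are averaged and
#' thresholded: `low` for a mean of at most 1.8, `medium` above 1.8 up to
#' 2.2, `high` above 2.2. Missing samples are dropped (with a flag) and the
#' label computed from the available ones.
#'
#' @param sample_ratings Numeric vector of per-sample ratings in `[1, 3]`
#'   (typically 3 picture descriptions).
#' @param cuts The two thresholds (default `c(1.8, 2.2)`).
#' @return Ordered factor with levels `low < medium < high`; attribute
#'   `"partial"` is `TRUE` when any sample was missing.
#' @export
ordinal_coherence_label <- function(sample_ratings, cuts = c(1.8, 2.2)) {
  ok <- is.finite(sample_ratings)
  if (!any(ok)) stop("all sample ratings missing", call. = FALSE)
  r <- sample_ratings[ok]
  stopifnot(all(r >= 1 & r <= 3))
  m <- mean(r)
  lab <- if (m <= cuts[1]) "low" else if (m <= cuts[2]) "medium" else "high"
  structure(factor(lab, levels = COHERENCE_LEVELS, ordered = TRUE),
            partial = !all(ok))
}

probit_formula_terms <- function(terms) {
  stats::as.formula(paste("coherence ~", paste(terms, collapse = " + ")))
}

#' Fit an ordered probit model of coherence
#'
#' Maximum-likelihood ordered probit (latent standard-normal variable cut at
#' strictly increasing thresholds), fit with [MASS::polr()] whose internal
#' optimizer is BFGS. The diagnosis group enters with `HC` as the reference
#' category. Per-term `z = coef / SE` and two-sided normal p-values are
#' computed from the Hessian.
#'
#' @param data Data frame with a `coherence` column (ordered factor or a
#'   value coercible to one with levels low/medium/high) plus the model
#'   terms.
#' @param terms Character vector of right-hand-side terms, e.g.
#'   `c("age", "sex", "education", "group")`.
#' @param ref_group Reference level for `group` (default `"HC"`).
#' @return A `semcoh_probit` list: `coefficients` (data frame with estimate,
#'   se, z, p per term), `cutpoints`, `converged`, `formula`, `n`, and the
#'   underlying fit.
#' @export
fit_ordered_probit <- function(data, terms = c("age", "sex", "education", "group"),
                               ref_group = "HC") {
  stopifnot(is.data.frame(data), "coherence" %in% names(data))
  data <- prepare_probit_data(data, ref_group)
  if (nlevels(droplevels(data$coherence)) < 2L)
    stop("response has a single observed level", call. = FALSE)
  f <- probit_formula_terms(terms)
  fit <- tryCatch(
    suppressWarnings(MASS::polr(f, data = data, method = "probit", Hess = TRUE)),
    error = function(e) stop("ordered probit failed (possible separation): ",
                             conditionMessage(e), call. = FALSE))
  summ <- suppressWarnings(summary(fit))
  ct <- summ$coefficients
  k <- length(fit$coefficients)
  se <- ct[, "Std. Error"]
  if (any(!is.finite(se)) || any(se[seq_len(k)] > 1e3))
    stop("ordered probit: unstable standard errors (possible separation)",
         call. = FALSE)
  z <- ct[, "Value"] / se
  coefs <- data.frame(
    term = rownames(ct)[seq_len(k)],
    estimate = unname(ct[seq_len(k), "Value"]),
    se = unname(se[seq_len(k)]),
    z = unname(z[seq_len(k)]),
    p = unname(2 * stats::pnorm(-abs(z[seq_len(k)]))),
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, cutpoints = fit$zeta,
                 converged = fit$convergence == 0,
                 formula = deparse(f), n = nrow(fit$model), fit = fit),
            class = "semcoh_probit")
}

prepare_probit_data <- function(data, ref_group) {
  if (!is.factor(data$coherence))
    data$coherence <- factor(as.character(data$coherence),
                             levels = COHERENCE_LEVELS, ordered = TRUE)
  if (!is.ordered(data$coherence))
    data$coherence <- factor(as.character(data$coherence),
                             levels = levels(data$coherence), ordered = TRUE)
  if ("group" %in% names(data)) {
    data$group <- droplevels(as.factor(data$group))
    if (ref_group %in% levels(data$group))
      data$group <- stats::relevel(data$group, ref = ref_group)
  }
  data
}

#' @export
print.semcoh_probit <- function(x, ...) {
  cat("Ordered probit:", x$formula, "\n")
  cat("n =", x$n, " converged:", x$converged, "\n")
  print(x$coefficients, digits = 3)
  cat("cut-points:", paste(sprintf("%.3f", x$cutpoints), collapse = " < "), "\n")
  invisible(x)
}

#' Ordered probit with a linguistic feature and group interaction
#'
#' The two-step scheme for relating a semantic or probabilistic measure to
#' coherence in the clinical cohort: the feature is z-scored (so main and
#' interaction coefficients are per-SD) and entered either as a main effect
#' alongside the diagnosis group, or additionally interacted with group to
#' test whether the feature moderates incoherence differently per group.
#'
#' @param data Subject table with `coherence`, demographics, `group`, and
#'   the feature column.
#' @param feature_name Name of the feature column.
#' @param interaction Include `feature x group` product terms (default
#'   `TRUE`); `FALSE` fits the main-effect model.
#' @param covariates Demographic covariates (default age, sex, education).
#' @param min_coverage Minimum fraction of subjects with a non-missing
#'   feature (default 0.8).
#' @param ref_group Reference group level.
#' @return A `semcoh_probit` fit.
#' @export
fit_interaction <- function(data, feature_name, interaction = TRUE,
                            covariates = c("age", "sex", "education"),
                            min_coverage = 0.8, ref_group = "HC") {
  stopifnot(feature_name %in% names(data))
  x <- data[[feature_name]]
  if (mean(is.finite(x)) < min_coverage)
    stop("feature '", feature_name, "' missing for more than ",
         round(100 * (1 - min_coverage)), "% of subjects", call. = FALSE)
  if (stats::sd(x, na.rm = TRUE) == 0 || !is.finite(stats::sd(x, na.rm = TRUE)))
    stop("feature '", feature_name, "' is degenerate (constant)", call. = FALSE)
  data$.feat <- as.numeric(scale(x))
  terms <- c(covariates, ".feat", "group", if (interaction) ".feat:group")
  fit <- fit_ordered_probit(data[is.finite(data$.feat), , drop = FALSE],
                            terms = terms, ref_group = ref_group)
  fit$coefficients$term <- sub("^\\.feat", feature_name,
                               fit$coefficients$term)
  fit$formula <- sub("\\.feat", feature_name, fit$formula)
  fit
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables (average ranks), residualizes the ranks of
#' `x` and `y` on the rank-transformed covariates by least squares, and
#' correlates the residuals; the p-value uses a t-approximation on
#' `n - 2 - k` degrees of freedom for `k` covariates. Constant covariates
#' are dropped with a warning.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame (or matrix) of covariates.
#' @return List with `r`, `p`, `n`, and `dropped` (names of any constant
#'   covariates removed).
#' @export
partial_spearman <- function(x, y, covariates) {
  covariates <- as.data.frame(covariates)
  cc <- stats::complete.cases(x, y, covariates)
  x <- x[cc]; y <- y[cc]
  covariates <- covariates[cc, , drop = FALSE]
  n <- length(x)
  if (n < 5L) return(list(r = NA_real_, p = NA_real_, n = n,
                          dropped = character(0)))
  const <- vapply(covariates, function(v) stats::sd(as.numeric(v)) == 0,
                  logical(1))
  dropped <- names(covariates)[const]
  if (length(dropped)) {
    warning("dropping constant covariate(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    covariates <- covariates[, !const, drop = FALSE]
  }
  k <- ncol(covariates)
  rx <- rank(x); ry <- rank(y)
  if (k > 0L) {
    Z <- vapply(covariates, function(v) rank(as.numeric(v)), numeric(n))
    rx <- stats::resid(stats::lm.fit(cbind(1, Z), rx))
    ry <- stats::resid(stats::lm.fit(cbind(1, Z), ry))
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, dropped = dropped))
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(r = r, p = p, n = n, dropped = dropped)
}

#' Inter-rater agreement: ICC(2,k) and mean weighted Cohen's kappa
#'
#' Two-way random-effects, absolute-agreement, average-measures intraclass
#' correlation (ICC(2,k)) from the two-way ANOVA decomposition, and Cohen's
#' weighted kappa (linear weights by default, quadratic available) averaged
#' over all rater pairs.
#'
#' @param ratings Numeric matrix or data frame, subjects x raters.
#' @param kappa_weights `"linear"` (default) or `"quadratic"`.
#' @return List with `icc2k` and `mean_weighted_kappa` (either may be `NA`
#'   for degenerate input, e.g. constant ratings).
#' @export
rater_agreement <- function(ratings, kappa_weights = c("linear", "quadratic")) {
  kappa_weights <- match.arg(kappa_weights)
  R <- as.matrix(ratings)
  stopifnot(ncol(R) >= 2L, nrow(R) >= 5L)
  R <- R[stats::complete.cases(R), , drop = FALSE]
  n <- nrow(R); k <- ncol(R)
  # two-way ANOVA mean squares
  grand <- mean(R)
  row_m <- rowMeans(R); col_m <- colMeans(R)
  msr <- k * sum((row_m - grand)^2) / (n - 1)          # subjects
  msc <- n * sum((col_m - grand)^2) / (k - 1)          # raters
  sse <- sum((R - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc2k <- if (msr + (msc - mse) / n <= 0 || stats::sd(as.vector(R)) == 0)
    NA_real_ else (msr - mse) / (msr + (msc - mse) / n)
  pairs <- utils::combn(k, 2)
  kap <- apply(pairs, 2L, function(ij)
    weighted_kappa(R[, ij[1]], R[, ij[2]], kappa_weights))
  list(icc2k = icc2k, mean_weighted_kappa = mean(kap, na.rm = TRUE))
}

weighted_kappa <- function(a, b, weights = "linear") {
  levs <- sort(unique(c(a, b)))
  m <- length(levs)
  if (m < 2L) return(NA_real_)
  O <- table(factor(a, levels = levs), factor(b, levels = levs))
  O <- O / sum(O)
  E <- outer(rowSums(O), colSums(O))
  d <- abs(outer(seq_len(m), seq_len(m), "-"))
  W <- if (weights == "linear") d / (m - 1) else (d / (m - 1))^2
  denom <- sum(W * E)
  if (denom == 0) return(NA_real_)
  1 - sum(W * O) / denom
}
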