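## Regression outlier diagnostics: leverage, studentized residuals, Cook's
## distance, the Bonferroni outlier test, Tukey's one-degree-of-freedom
## non-additivity test, and a combined, configurable flagging rule. Used to
## identify extreme stimuli whose ratings the feature model cannot explain.

#' Linear-fit context for outlier diagnostics
#'
#' Fits `y` on the given features (plus intercept) by least squares and
#' collects the quantities the diagnostic operations need: hat diagonal,
#' residuals, residual variance, and degrees of freedom.
#'
#' @param x feature matrix or data.frame (typically the model-selected
#'   features).
#' @param y numeric response.
#' @param ids optional sample identifiers (default: rownames or `1..n`).
#' @return A `linear_fit_context` object.
#' @export
linear_fit_context <- function(x, y, ids = NULL) {
  x <- as_feature_matrix(x)
  n <- length(y)
  stopifnot(nrow(x) == n)
  if (is.null(ids)) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(n))
  }
  df <- data.frame(.y = y, x, check.names = TRUE)
  fit <- stats::lm(.y ~ ., data = df)
  npar <- fit$rank
  structure(list(
    fit = fit, x = x, y = y, ids = ids,
    h = unname(stats::hatvalues(fit)),
    residuals = unname(stats::residuals(fit)),
    s2 = sum(stats::residuals(fit)^2) / (n - npar),
    npar = npar, df = n - npar), class = "linear_fit_context")
}

#' @export
print.linear_fit_context <- function(x, ...) {
  cat(sprintf("<linear_fit_context: n = %d, parameters = %d, df = %d>\n",
              length(x$y), x$npar, x$df))
  invisible(x)
}

#' Leverage (hat values)
#'
#' The diagonal of the projection onto the design column space; values in
#' `[0, 1]` summing exactly to the number of model parameters.
#'
#' @param context a [linear_fit_context()].
#' @return Numeric vector of per-sample leverages.
#' @export
hat_values <- function(context) {
  stopifnot(inherits(context, "linear_fit_context"))
  context$h
}

#' Studentized residuals
#'
#' Externally studentized (default): `e_i / (s_(-i) sqrt(1 - h_i))` with
#' the deleted residual-variance estimate, the basis of the outlier test.
#' Internally studentized residuals use the full-sample `s`.
#' Samples with `h_i = 1` have undefined residual scale and are reported as
#' `NA` with a warning.
#'
#' @param context a [linear_fit_context()].
#' @param type `"external"` or `"internal"`.
#' @return Numeric vector of studentized residuals.
#' @export
studentized_residuals <- function(context, type = c("external", "internal")) {
  stopifnot(inherits(context, "linear_fit_context"))
  if (context$df < 2) stop("at least 2 residual degrees of freedom required")
  type <- match.arg(type)
  exact_fit <- context$h >= 1 - 1e-12
  if (any(exact_fit))
    warning(sum(exact_fit), " sample(s) with leverage 1: residual undefined")
  t_i <- if (type == "external") unname(stats::rstudent(context$fit))
         else unname(stats::rstandard(context$fit))
  ## an exact fit everywhere gives 0/0; report zeros for a zero residual
  t_i[context$s2 < .Machine$double.eps^0.9] <- 0
  t_i[exact_fit] <- NA_real_
  t_i
}

#' Cook's distance
#'
#' `D_i = r_i^2 / p * h_i / (1 - h_i)` with internally studentized `r_i`;
#' equivalently the scaled shift of the coefficient vector when sample `i`
#' is deleted.
#'
#' @param context a [linear_fit_context()].
#' @return Numeric vector of non-negative distances.
#' @export
cooks_distance <- function(context) {
  stopifnot(inherits(context, "linear_fit_context"))
  d <- unname(stats::cooks.distance(context$fit))
  d[context$s2 < .Machine$double.eps^0.9] <- 0
  d
}

#' Bonferroni outlier test
#'
#' Tests the single most extreme externally studentized residual:
#' `p = min(1, n * 2 * P(T_df-1 > |t_max|))`, the standard mean-shift
#' outlier test with Bonferroni correction for having searched over all
#' `n` samples.
#'
#' @param context a [linear_fit_context()].
#' @return List with `id` (worst sample), `t` (its studentized residual),
#'   `p_adjusted`, and `p_per_sample` (Bonferroni-adjusted p for every
#'   sample, capped at 1).
#' @export
bonferroni_outlier_test <- function(context) {
  stopifnot(inherits(context, "linear_fit_context"))
  if (context$df < 3) stop("at least 3 residual degrees of freedom required")
  t_i <- suppressWarnings(studentized_residuals(context, "external"))
  n <- length(t_i)
  raw <- 2 * stats::pt(abs(t_i), df = context$df - 1, lower.tail = FALSE)
  adj <- pmin(1, n * raw)
  worst <- which.min(ifelse(is.na(adj), Inf, adj))
  list(id = context$ids[worst], t = t_i[worst], p_adjusted = adj[worst],
       p_per_sample = stats::setNames(adj, context$ids))
}

#' Tukey's one-degree-of-freedom non-additivity test
#'
#' Augments the design with the squared fitted values and t-tests the added
#' coefficient: a small p indicates curvature the additive (linear) model
#' does not capture. Degenerate augmentations (squared fits collinear with
#' the design, e.g. a constant response) return p = 1 with a warning.
#'
#' @param context a [linear_fit_context()].
#' @return The test p-value.
#' @export
tukey_nonadditivity <- function(context) {
  stopifnot(inherits(context, "linear_fit_context"))
  yhat <- stats::fitted(context$fit)
  df2 <- data.frame(.y = context$y, context$x, .yhat2 = yhat^2,
                    check.names = TRUE)
  fit2 <- stats::lm(.y ~ ., data = df2)
  ct <- suppressWarnings(summary(fit2)$coefficients)
  if (!(".yhat2" %in% rownames(ct)) || is.na(fit2$coefficients[".yhat2"])) {
    warning("squared fitted values are collinear with the design; p = 1")
    return(1)
  }
  unname(ct[".yhat2", "Pr(>|t|)"])
}

#' Full outlier diagnostics of a feature model
#'
#' Composes the individual diagnostics into one per-sample report plus the
#' global tests.
#'
#' @inheritParams linear_fit_context
#' @return An `outlier_report`: data.frame `samples` (id, leverage,
#'   internally/externally studentized residuals, Cook's distance,
#'   Bonferroni-adjusted p), `tests` (Bonferroni worst-case and Tukey
#'   non-additivity p-values), and the fit context.
#' @export
regression_diagnostics <- function(x, y, ids = NULL) {
  ctx <- linear_fit_context(x, y, ids)
  t_ext <- suppressWarnings(studentized_residuals(ctx, "external"))
  bonf <- bonferroni_outlier_test(ctx)
  samples <- data.frame(
    id = ctx$ids,
    leverage = ctx$h,
    t_internal = suppressWarnings(studentized_residuals(ctx, "internal")),
    t_external = t_ext,
    cooks_d = cooks_distance(ctx),
    p_bonferroni = unname(bonf$p_per_sample),
    stringsAsFactors = FALSE)
  structure(list(
    samples = samples,
    tests = list(bonferroni = bonf,
                 tukey_p = tukey_nonadditivity(ctx)),
    context = ctx), class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report: %d samples, %d parameters>\n",
              nrow(x$samples), x$context$npar))
  cat(sprintf("  Bonferroni worst sample %s: p = %.4g\n",
              x$tests$bonferroni$id, x$tests$bonferroni$p_adjusted))
  cat(sprintf("  Tukey non-additivity p = %.4g\n", x$tests$tukey_p))
  worst <- utils::head(x$samples[order(-abs(x$samples$t_external)), ], 5)
  print(worst, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Flag outlying samples
#'
#' The combined decision rule: a sample is flagged when its Cook's distance
#' exceeds `d_cut` AND its absolute externally studentized residual exceeds
#' `t_cut`, OR its Bonferroni-adjusted outlier p-value falls below `alpha`.
#' Defaults are the conventional cutoffs `4/n`, 3, and 0.05; the rule is
#' deterministic and monotone in each threshold.
#'
#' @param report an `outlier_report` from [regression_diagnostics()].
#' @param d_cut Cook's distance threshold (default `4/n`).
#' @param t_cut studentized-residual threshold.
#' @param alpha Bonferroni significance level.
#' @return Character vector of flagged sample ids.
#' @export
flag_outliers <- function(report, d_cut = NULL, t_cut = 3, alpha = 0.05) {
  stopifnot(inherits(report, "outlier_report"))
  s <- report$samples
  n <- nrow(s)
  if (is.null(d_cut)) d_cut <- 4 / n
  t_abs <- abs(s$t_external)
  t_abs[is.na(t_abs)] <- Inf                 # leverage-1 points are extreme
  flagged <- (s$cooks_d > d_cut & t_abs > t_cut) | s$p_bonferroni < alpha
  s$id[flagged]
}
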