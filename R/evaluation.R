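## The benchmark harness: repeated k-fold cross-validation with R2/RMSE
## scoring and feature-stability accounting, plus the non-parametric
## model-comparison statistics (paired Wilcoxon, Friedman with the
## Iman-Davenport transform, median-based contrast estimation).

#' Model specification for the benchmark harness
#'
#' @param method one of `"fsmkl"`, `"lm"`, `"glm_stepwise"`, `"lasso"`,
#'   `"enet"`, `"svm_rfe"`, or `"custom"`.
#' @param ... method parameters passed through to the fitting function
#'   (e.g. `rho`, `kernels`, `C` for fsmkl; `fraction`, `alpha`,
#'   `bestsubsetsize`, ... for the baselines). For `"custom"`, supply `fit
#'   = function(x, y)` returning an object with a `predict(object,
#'   newdata)` method, and optionally `selected = function(model)`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(method = c("fsmkl", "lm", "glm_stepwise", "lasso",
                                  "enet", "svm_rfe", "custom"), ...) {
  method <- match.arg(method)
  structure(list(method = method, params = list(...)), class = "model_spec")
}

fit_spec <- function(spec, x, y) {
  p <- spec$params
  model <- switch(spec$method,
    fsmkl = do.call(fsmkl, c(list(x = x, y = y), p[setdiff(names(p), "fit")])),
    lm = fit_lm(x, y),
    glm_stepwise = do.call(fit_glm_stepwise, c(list(x = x, y = y),
                                               p[names(p) %in% "max_steps"])),
    lasso = do.call(fit_lasso, c(list(x = x, y = y),
                                 p[names(p) %in% "fraction"])),
    enet = do.call(fit_enet, c(list(x = x, y = y),
                               p[names(p) %in% c("alpha", "nfolds")])),
    svm_rfe = do.call(svm_rfe, c(list(x = x, y = y),
                                 p[names(p) %in% c("bestsubsetsize", "sigma",
                                                   "C", "epsilon", "kernel")])),
    custom = p$fit(x, y))
  sel <- switch(spec$method,
    fsmkl = model$selected,
    custom = if (is.null(p$selected)) character(0) else p$selected(model),
    model$selected)
  list(model = model, selected = sel)
}

#' Repeated k-fold cross-validation of a model
#'
#' For every run a fresh seeded fold partition is drawn
#' (seed = `base_seed + run`), the model is refit on each training fold --
#' every data-dependent step (standardisation, ranking, grouping,
#' selection, penalty tuning) happens inside the fold -- and the
#' out-of-fold predictions are pooled. R2 is the squared Pearson
#' correlation of pooled predictions with the observed response (per-fold
#' averaging available via `pooled = FALSE`); RMSE is computed on the same
#' pooled predictions. A constant prediction vector has undefined
#' correlation and is reported as R2 = 0 with a flag.
#'
#' @param spec a [model_spec()].
#' @param x feature matrix or data.frame.
#' @param y numeric response.
#' @param runs repetitions (the headline summary is the median over runs).
#' @param folds folds per run (`>= 2`; every training fold needs `>= 3`
#'   samples).
#' @param base_seed integer seed schedule base.
#' @param pooled pool out-of-fold predictions (default) or average
#'   fold-wise R2.
#' @return A `cv_report`: per-run scores and seeds, per-run selected
#'   feature sets, medians, and the modal-set stability table.
#' @export
repeated_cv <- function(spec, x, y, runs = 50, folds = 10, base_seed = 1,
                        pooled = TRUE) {
  x <- as_feature_matrix(x)
  n <- length(y)
  stopifnot(folds >= 2, runs >= 1, nrow(x) == n)
  if (n - ceiling(n / folds) < 3)
    stop("fold configuration leaves a training fold with fewer than 3 samples")

  scores <- data.frame(run = seq_len(runs), seed = base_seed + seq_len(runs),
                       r2 = NA_real_, rmse = NA_real_, constant = FALSE)
  sets <- vector("list", runs)
  for (r in seq_len(runs)) {
    seed_r <- base_seed + r
    assign_f <- with_seed(seed_r, sample(rep(seq_len(folds), length.out = n)))
    pred <- numeric(n)
    fold_r2 <- numeric(0)
    sel_union <- character(0)
    for (f in seq_len(folds)) {
      te <- which(assign_f == f)
      tr <- which(assign_f != f)
      fitted <- with_seed(seed_r * 1000L + f,
                          fit_spec(spec, x[tr, , drop = FALSE], y[tr]))
      pred[te] <- stats::predict(fitted$model, x[te, , drop = FALSE])
      sel_union <- union(sel_union, fitted$selected)
      if (!pooled) {
        ok <- stats::sd(pred[te]) > 0 && stats::sd(y[te]) > 0
        fold_r2 <- c(fold_r2, if (ok) stats::cor(pred[te], y[te])^2 else 0)
      }
    }
    const <- stats::sd(pred) == 0
    scores$constant[r] <- const
    scores$r2[r] <- if (pooled) {
      if (const) 0 else stats::cor(pred, y)^2
    } else mean(fold_r2)
    scores$rmse[r] <- sqrt(mean((pred - y)^2))
    sets[[r]] <- sort(sel_union)
  }
  sig <- vapply(sets, paste, character(1), collapse = "|")
  structure(list(
    scores = scores, feature_sets = sets,
    medians = c(r2 = stats::median(scores$r2),
                rmse = stats::median(scores$rmse)),
    stability = sort(table(sig), decreasing = TRUE),
    config = list(method = spec$method, runs = runs, folds = folds,
                  base_seed = base_seed, pooled = pooled)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report %s: %d x %d-fold CV>\n", x$config$method,
              x$config$runs, x$config$folds))
  cat(sprintf("  median R2 %.4f, median RMSE %.4f\n",
              x$medians["r2"], x$medians["rmse"]))
  st <- stability_report(x)
  cat(sprintf("  modal feature set: %d features in %d/%d runs\n",
              length(st$modal_set), st$modal_count, x$config$runs))
  invisible(x)
}

#' Feature-set stability of a CV report
#'
#' @param report a `cv_report` from [repeated_cv()].
#' @return List with `modal_set` (the most frequent per-run feature set),
#'   `modal_count` (how many runs produced exactly that set), and
#'   `frequency` (per-feature inclusion fraction across runs).
#' @export
stability_report <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  sets <- report$feature_sets
  sig <- vapply(sets, paste, character(1), collapse = "|")
  tab <- sort(table(sig), decreasing = TRUE)
  modal <- sets[[match(names(tab)[1], sig)]]
  all_f <- sort(unique(unlist(sets)))
  freq <- vapply(all_f, function(f)
    mean(vapply(sets, function(s) f %in% s, logical(1))), numeric(1))
  list(modal_set = modal, modal_count = as.integer(tab[1]),
       frequency = stats::setNames(freq, all_f))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired score vectors. For `n <= 25`
#' informative (non-zero) pairs the exact sign-flip distribution of the
#' rank sum is enumerated (midranks for tied magnitudes); above that the
#' normal approximation with continuity correction is used. All-zero
#' differences give p = 1.
#'
#' @param scores_a,scores_b equal-length paired score vectors.
#' @return The two-sided p-value.
#' @export
wilcoxon_paired <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  d <- scores_a - scores_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  if (n <= 25) {
    ## Exact null distribution of W+ over the 2^n equiprobable sign
    ## assignments, by convolution on the doubled-midrank integer grid.
    r2 <- round(2 * rank(abs(d)))            # doubled midranks are integers
    probs <- 1
    for (r in r2) {
      nxt <- c(probs, numeric(r)) / 2
      nxt[(r + 1):length(nxt)] <- nxt[(r + 1):length(nxt)] +
        c(numeric(0), probs) / 2
      probs <- nxt
    }
    w_obs <- sum(r2[d > 0])
    lower <- sum(probs[seq_len(w_obs + 1)])
    upper <- sum(probs[(w_obs + 1):length(probs)])
    return(min(1, 2 * min(lower, upper)))
  }
  suppressWarnings(
    stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
}

#' Friedman test with the Iman-Davenport correction
#'
#' Ranks the methods within every run (midranks for ties), forms the
#' Friedman chi-square statistic, and applies the Iman-Davenport
#' transformation `F = (N - 1) chi^2 / (N (k - 1) - chi^2)`, referred to an
#' `F(k - 1, (k - 1)(N - 1))` distribution, which is less conservative than
#' the raw chi-square reference for comparing algorithms over repeated runs.
#'
#' @param scores numeric matrix, runs x methods (larger = better; the
#'   statistic is rank-based so direction does not matter).
#' @return List with `chisq`, `p_chisq`, `statistic` (the Iman-Davenport
#'   F), `p_value`, and `mean_ranks`.
#' @export
friedman_iman_davenport <- function(scores) {
  scores <- as.matrix(scores)
  N <- nrow(scores); k <- ncol(scores)
  stopifnot(N >= 2, k >= 2)
  R <- t(apply(scores, 1, rank))               # midranks for ties
  rbar <- colMeans(R)
  chisq <- 12 * N / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  p_chisq <- stats::pchisq(chisq, df = k - 1, lower.tail = FALSE)
  denom <- N * (k - 1) - chisq
  if (denom <= .Machine$double.eps) {
    fstat <- Inf
    p_f <- 0
  } else {
    fstat <- (N - 1) * chisq / denom
    p_f <- stats::pf(fstat, k - 1, (k - 1) * (N - 1), lower.tail = FALSE)
  }
  list(chisq = chisq, p_chisq = p_chisq, statistic = fstat, p_value = p_f,
       mean_ranks = stats::setNames(rbar, colnames(scores)))
}

#' Median-based contrast estimation between methods
#'
#' For every method pair (i, j), the estimator is the median over runs of
#' the paired score difference `score_i - score_j`, arranged as an
#' antisymmetric matrix (heatmap-ready); the robust effect-size companion
#' to the rank tests.
#'
#' @param scores numeric matrix, runs x methods.
#' @return A `k x k` antisymmetric matrix of median paired differences.
#' @export
median_contrast <- function(scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  out <- matrix(0, k, k, dimnames = list(colnames(scores), colnames(scores)))
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j) out[i, j] <- stats::median(scores[, i] - scores[, j])
  out
}
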