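## File contracts and the top-level benchmark runner: features CSV (first
## column = image id, header = canonical feature names), ratings CSV
## (id, rating), model JSON and importance CSV exports.

#' Read / write a features table CSV
#'
#' The on-disk contract of the extraction pipeline: a header row of
#' canonical feature names, one row per image, first column `id`.
#'
#' @param path CSV path.
#' @param features a data.frame as returned by [extract_features_batch()].
#' @return `read_features_csv` returns the data.frame;
#'   `write_features_csv` returns `path` invisibly.
#' @export
read_features_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_features_csv
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a ratings CSV (columns `id`, `rating`)
#'
#' @param path CSV path.
#' @return data.frame with `id` and numeric `rating`.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "rating") %in% colnames(df)))
    stop("ratings CSV must have columns `id` and `rating`")
  df
}

#' Export a fitted FSMKL model as JSON
#'
#' Serialises the kernel specifications, subsets, simplex weights, dual
#' coefficients, bias and configuration.
#'
#' @param fit an [fsmkl()] object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fsmkl_json <- function(fit, path) {
  stopifnot(inherits(fit, "fsmkl"))
  sol <- fit$solution
  cands <- lapply(fit$candidates, function(k)
    list(subset = names(fit$center)[k$subset],
         spec = unclass(k$spec), norm = k$norm))
  jsonlite::write_json(list(
    model = "fsmkl", config = fit$config,
    d = sol$d, alpha = sol$alpha, b = sol$b,
    active_kernels = sol$active_kernels,
    kernels = cands, selected = fit$selected),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export the feature-importance table as CSV
#'
#' Columns `Pos`, `Feature`, `Weight`, `Kernels`, sorted by descending
#' accumulated weight; only features used by at least one active kernel.
#'
#' @param fit an [fsmkl()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance_csv <- function(fit, path) {
  stopifnot(inherits(fit, "fsmkl"))
  imp <- fit$importance[fit$importance$kernels >= 1, ]
  out <- data.frame(Pos = seq_len(nrow(imp)), Feature = imp$feature,
                    Weight = imp$weight, Kernels = imp$kernels)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Run the full model-comparison benchmark
#'
#' Repeated cross-validation of several model specifications on one
#' features + ratings pair, followed by the non-parametric comparison
#' statistics: pairwise Wilcoxon signed-rank p-values, the Friedman test
#' with Iman-Davenport correction over the per-run R2 matrix, and the
#' median-based contrast matrix.
#'
#' @param x feature matrix/data.frame, or a features data.frame with an
#'   `id` first column (as from [read_features_csv()]).
#' @param y numeric ratings, or a ratings data.frame (`id`, `rating`)
#'   matched to `x` by id.
#' @param specs named list of [model_spec()]s.
#' @param runs,folds,base_seed see [repeated_cv()].
#' @return A `benchmark` object: per-model `cv_report`s, the runs x models
#'   R2 and RMSE matrices, `friedman`, `wilcoxon` (pairwise p matrix) and
#'   `contrast`.
#' @export
run_benchmark <- function(x, y, specs, runs = 50, folds = 10,
                          base_seed = 1) {
  if (is.data.frame(x) && "id" %in% colnames(x)) {
    ids <- x$id
    x <- as.matrix(x[, setdiff(colnames(x), "id"), drop = FALSE])
    if (is.data.frame(y)) {
      y <- y$rating[match(ids, y$id)]
      if (anyNA(y)) stop("ratings missing for some image ids")
    }
  }
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$method, character(1))
  reports <- lapply(specs, repeated_cv, x = x, y = y, runs = runs,
                    folds = folds, base_seed = base_seed)
  r2 <- vapply(reports, function(r) r$scores$r2, numeric(runs))
  rmse <- vapply(reports, function(r) r$scores$rmse, numeric(runs))
  if (runs == 1) { r2 <- rbind(r2); rmse <- rbind(rmse)
                   colnames(r2) <- colnames(rmse) <- names(specs) }
  k <- length(specs)
  wil <- matrix(NA_real_, k, k, dimnames = list(names(specs), names(specs)))
  for (i in seq_len(k)) for (j in seq_len(k))
    if (i != j) wil[i, j] <- wilcoxon_paired(r2[, i], r2[, j])
  structure(list(
    reports = reports, r2 = r2, rmse = rmse,
    friedman = if (runs >= 2 && k >= 2) friedman_iman_davenport(r2) else NULL,
    wilcoxon = wil, contrast = median_contrast(r2),
    config = list(runs = runs, folds = folds, base_seed = base_seed)),
    class = "benchmark")
}

#' @export
print.benchmark <- function(x, ...) {
  cat(sprintf("<benchmark: %d models, %d x %d-fold CV>\n",
              ncol(x$r2), x$config$runs, x$config$folds))
  meds <- data.frame(
    model = colnames(x$r2),
    median_r2 = apply(x$r2, 2, stats::median),
    median_rmse = apply(x$rmse, 2, stats::median))
  print(meds, row.names = FALSE, digits = 4)
  if (!is.null(x$friedman))
    cat(sprintf("Friedman/Iman-Davenport: F = %.3f, p = %.3g\n",
                x$friedman$statistic, x$friedman$p_value))
  invisible(x)
}
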