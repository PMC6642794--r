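## The FSMKL kernel bank: filter ranking of features, grouping of correlated
## features, enumeration of nested ranked subsets crossed with kernel
## specifications, and Gram-matrix evaluation.

#' Kernel specification
#'
#' @param kind `"gaussian"` or `"polynomial"`.
#' @param sigma gaussian bandwidth: `K(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`.
#' @param degree polynomial degree: `K(x, x') = (x . x' + 1)^degree`.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(kind = c("gaussian", "polynomial"), sigma = NULL,
                        degree = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    stopifnot(is.numeric(sigma), sigma > 0)
    structure(list(kind = kind, sigma = sigma), class = "kernel_spec")
  } else {
    stopifnot(is.numeric(degree), degree >= 1, degree == round(degree))
    structure(list(kind = kind, degree = as.integer(degree)),
              class = "kernel_spec")
  }
}

#' @export
format.kernel_spec <- function(x, ...) {
  if (x$kind == "gaussian") sprintf("gaussian(sigma=%g)", x$sigma)
  else sprintf("polynomial(degree=%d)", x$degree)
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec ", format(x), ">\n", sep = "")
  invisible(x)
}

#' The default kernel bank
#'
#' Gaussian kernels with sigma in \{0.1, 0.2, 0.3, 0.4, 0.5, 1, 2\} and
#' polynomial kernels of degrees 1 to 4: eleven kernel specifications.
#'
#' @param sigmas gaussian bandwidths.
#' @param degrees polynomial degrees.
#' @return List of [kernel_spec()] objects.
#' @export
default_kernel_bank <- function(sigmas = c(0.1, 0.2, 0.3, 0.4, 0.5, 1, 2),
                                degrees = 1:4) {
  c(lapply(sigmas, function(s) kernel_spec("gaussian", sigma = s)),
    lapply(degrees, function(d) kernel_spec("polynomial", degree = d)))
}

#' Rank features by filter relevance
#'
#' Orders features by descending absolute Pearson correlation with the
#' response; ties (and constant features, whose score is 0) keep their
#' original column order.
#'
#' @param x feature matrix or data.frame (samples x features).
#' @param y numeric response.
#' @return Integer vector of column indices, most relevant first.
#' @export
filter_rank <- function(x, y) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 3) stop("filter_rank needs at least 3 samples")
  score <- suppressWarnings(abs(as.vector(stats::cor(x, y))))
  score[!is.finite(score)] <- 0
  order(-score, seq_len(ncol(x)))
}

#' Group correlated features
#'
#' Partitions features by complete-linkage hierarchical clustering on the
#' dissimilarity `1 - |corr|`, cutting the tree at height `1 - rho`: within
#' every group, all pairwise absolute correlations exceed `rho`. Constant
#' features (undefined correlations) are treated as uncorrelated.
#'
#' @param x feature matrix or data.frame.
#' @param rho correlation threshold in (0, 1).
#' @return List of integer vectors (column indices), one per group, in
#'   order of first feature appearance; singletons allowed.
#' @export
group_features <- function(x, rho = 0.8) {
  x <- as_feature_matrix(x)
  stopifnot(rho > 0, rho < 1)
  p <- ncol(x)
  if (p == 1L) return(list(1L))
  ac <- suppressWarnings(abs(stats::cor(x)))
  ac[!is.finite(ac)] <- 0
  diag(ac) <- 1
  hc <- stats::hclust(stats::as.dist(1 - ac), method = "complete")
  memb <- stats::cutree(hc, h = 1 - rho)
  groups <- split(seq_len(p), memb)
  names(groups) <- NULL
  groups[order(vapply(groups, min, integer(1)))]
}

#' Enumerate candidate subset kernels
#'
#' For every feature group of size `n >= 2`, the group is reordered by the
#' global filter ranking and its nested top-`k` subsets for `k = 2..n` are
#' each crossed with every kernel specification, yielding
#' `sum_g max(n_g - 1, 0) * length(specs)` candidates. The same feature can
#' therefore appear in several candidate kernels, which is what lets the
#' fitted kernel weights double as a per-feature importance signal.
#'
#' @param groups list of feature-index groups (from [group_features()]).
#' @param ranking global feature ranking (from [filter_rank()]).
#' @param specs list of [kernel_spec()] objects.
#' @return List of candidate kernels: each a list with `subset` (ordered
#'   feature indices) and `spec`; Gram matrices are attached later by
#'   [compute_gram()].
#' @export
enumerate_subset_kernels <- function(groups, ranking, specs) {
  if (length(specs) == 0) stop("empty kernel specification list")
  pos <- match(seq_len(max(ranking)), ranking)  # rank position per feature
  out <- list()
  for (g in groups) {
    if (length(g) < 2) next
    g_ord <- g[order(pos[g])]
    for (k in 2:length(g_ord))
      for (sp in specs)
        out[[length(out) + 1L]] <- list(subset = g_ord[seq_len(k)], spec = sp)
  }
  out
}

## Raw (unnormalised) kernel evaluation between row sets of two matrices.
kernel_eval <- function(xa, xb, spec) {
  if (spec$kind == "gaussian") {
    sq <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
    exp(-pmax(sq, 0) / (2 * spec$sigma^2))
  } else {
    (tcrossprod(xa, xb) + 1)^spec$degree
  }
}

#' Compute the (trace-normalised) Gram matrix of a candidate kernel
#'
#' Evaluates the kernel on the subset coordinates of `x` and rescales it to
#' unit mean diagonal, the standard MKL scale equalisation so that no base
#' kernel dominates by magnitude alone. Features are expected to be
#' standardised beforehand.
#'
#' @param x standardised feature matrix.
#' @param subset integer feature indices.
#' @param spec a [kernel_spec()].
#' @return List with `gram` (normalised `n x n` matrix) and `norm` (the
#'   diagonal mean that was divided out; reuse it to normalise test-vs-train
#'   cross kernels consistently).
#' @export
compute_gram <- function(x, subset, spec) {
  x <- as_feature_matrix(x)
  xs <- x[, subset, drop = FALSE]
  K <- kernel_eval(xs, xs, spec)
  if (!all(is.finite(K))) {
    bad <- subset[!stats::complete.cases(t(xs))]
    stop("non-finite kernel entries (features: ",
         paste(colnames(x)[subset], collapse = ", "), ")")
  }
  nrm <- mean(diag(K))
  if (nrm <= 0) nrm <- 1
  list(gram = K / nrm, norm = nrm)
}

## Cross-kernel between new points and training points for one candidate,
## using the candidate's stored training normalisation.
compute_cross <- function(xnew, xtrain, candidate) {
  ka <- kernel_eval(xnew[, candidate$subset, drop = FALSE],
                    xtrain[, candidate$subset, drop = FALSE],
                    candidate$spec)
  ka / candidate$norm
}
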