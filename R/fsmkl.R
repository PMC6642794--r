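## Feature-Selection Multiple Kernel Learning for regression.
##
## The model learns a simplex-constrained convex combination
## K(d) = sum_m d_m K_m of candidate kernels, jointly with an
## epsilon-insensitive SVR on K(d). Candidates are built over nested,
## filter-ranked subsets of correlated feature groups, so the fitted kernel
## weights d double as a per-feature selection signal. The weights are
## optimised SimpleMKL-style: the SVR dual value J(d) = W(beta*(d)) is a
## convex, differentiable function of d with gradient
## dJ/dd_m = -1/2 beta*' K_m beta* (Danskin), minimised by projected
## gradient descent on the simplex with a backtracking line search.

#' Fit the MKL kernel weights by projected gradient (SimpleMKL-style)
#'
#' Alternates an SVR solve on the weighted sum kernel with a projected
#' gradient step on the simplex of kernel weights, with a backtracking line
#' search that only accepts objective decreases, so the recorded objective
#' trace is non-increasing by construction.
#'
#' @param kernels list of candidate kernels, each carrying a normalised
#'   `gram` matrix of identical dimension (see [compute_gram()]).
#' @param y numeric response.
#' @param C,epsilon SVR hyperparameters.
#' @param tol convergence tolerance on the relative objective change.
#' @param max_iter maximum outer iterations.
#' @param weight_floor kernels with `d_m > weight_floor` count as active.
#' @return An `mkl_solution`: list with simplex weights `d`, dual
#'   coefficients `alpha`, bias `b`, `hyper`, the objective `trace`,
#'   `active_kernels`, and a `converged` flag (a warning, not an error, is
#'   raised when `max_iter` is exhausted).
#' @export
fit_simplemkl <- function(kernels, y, C = 10, epsilon = 0.01, tol = 1e-4,
                          max_iter = 200, weight_floor = 1e-6) {
  M <- length(kernels)
  if (M == 0) stop("at least one candidate kernel is required")
  n <- length(y)
  stopifnot(all(vapply(kernels, function(k) all(dim(k$gram) == n), logical(1))))
  G <- vapply(kernels, function(k) as.vector(k$gram), numeric(n * n))
  mkl_core(G, y, C, epsilon, tol, max_iter, weight_floor)
}

## The projected-gradient optimiser on a pre-stacked gram matrix
## (columns = vectorised candidate grams): weighted sums and all-kernel
## quadratic forms are single BLAS calls.
mkl_core <- function(G, y, C = 10, epsilon = 0.01, tol = 1e-4,
                     max_iter = 200, weight_floor = 1e-6) {
  n <- length(y)
  M <- ncol(G)
  Ksum <- function(d) {
    act <- which(d > 0)
    ## subsetting G copies it; only worthwhile once d is sparse
    if (length(act) < M / 5)
      matrix(G[, act, drop = FALSE] %*% d[act], n, n)
    else matrix(G %*% d, n, n)
  }
  grad <- function(beta) {
    bb <- as.vector(tcrossprod(beta))
    -0.5 * as.vector(crossprod(G, bb))
  }

  d <- rep(1 / M, M)
  sol <- svr_dual_solve(Ksum(d), y, C, epsilon)
  J <- sol$objective
  trace <- J
  converged <- FALSE
  step <- 1

  for (it in seq_len(max_iter)) {
    g <- grad(sol$alpha)
    gn <- sqrt(sum(g^2))
    if (gn < .Machine$double.eps) { converged <- TRUE; break }
    improved <- FALSE
    t_try <- step / gn
    for (ls in 1:25) {
      d_new <- project_simplex(d - t_try * g)
      if (max(abs(d_new - d)) > 1e-12) {
        sol_new <- svr_dual_solve(Ksum(d_new), y, C, epsilon)
        if (sol_new$objective < J) {
          rel <- (J - sol_new$objective) / max(1, abs(J))
          d <- d_new; sol <- sol_new; J <- sol_new$objective
          trace <- c(trace, J)
          improved <- TRUE
          step <- min(step * 2, 1e3)   # cautiously expand for next iteration
          if (rel < tol) converged <- TRUE
          break
        }
      }
      t_try <- t_try / 2
      step <- max(step / 2, 1e-12)
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  if (!converged)
    warning("SimpleMKL reached max_iter = ", max_iter,
            " before the objective stabilised")
  structure(list(
    d = d, alpha = sol$alpha, b = sol$b,
    hyper = list(C = C, epsilon = epsilon),
    trace = trace, objective = J,
    active_kernels = which(d > weight_floor),
    weight_floor = weight_floor,
    fitted = sol$fitted, converged = converged,
    iterations = length(trace) - 1L), class = "mkl_solution")
}

#' Per-feature accumulated kernel weights
#'
#' For every feature, sums the simplex weights `d_m` of the active kernels
#' whose subset contains it, and counts those kernels. Because a feature
#' can sit in several nested subsets, accumulated weights can exceed 1; the
#' identity `sum_f weight_f = sum_m d_m * |subset_m|` (over active kernels)
#' holds exactly.
#'
#' @param solution an `mkl_solution` from [fit_simplemkl()].
#' @param kernels the candidate-kernel list the solution was fitted on.
#' @param feature_names optional character vector naming the feature columns.
#' @return A data.frame with columns `pos`, `feature`, `weight`, `kernels`,
#'   sorted by descending weight (all features included, zeros allowed).
#' @export
feature_importance <- function(solution, kernels, feature_names = NULL) {
  p <- if (!is.null(feature_names)) length(feature_names)
       else max(vapply(kernels, function(k) max(k$subset), numeric(1)))
  if (is.null(feature_names)) feature_names <- sprintf("V%03d", seq_len(p))
  w <- numeric(p)
  cnt <- integer(p)
  for (m in solution$active_kernels) {
    s <- kernels[[m]]$subset
    w[s] <- w[s] + solution$d[m]
    cnt[s] <- cnt[s] + 1L
  }
  ord <- order(-w, seq_len(p))
  data.frame(pos = seq_len(p), feature = feature_names[ord],
             weight = w[ord], kernels = cnt[ord],
             stringsAsFactors = FALSE)
}

#' Feature-Selection Multiple Kernel Learning regression
#'
#' Fits the full FSMKL pipeline: features are standardised (training
#' statistics only), ranked by absolute correlation with the response,
#' clustered into correlated groups, expanded into a bank of candidate
#' kernels over nested ranked subsets (every subset crossed with every
#' kernel specification), and fused by a simplex-constrained SimpleMKL
#' around epsilon-insensitive SVR. Features used by at least one active
#' kernel form the selected set.
#'
#' @param x feature matrix or data.frame (samples x features).
#' @param y numeric response (e.g. mean complexity ratings in `[1, 5]`).
#' @param rho correlation threshold for grouping (see [group_features()]).
#' @param kernels list of [kernel_spec()]s; default [default_kernel_bank()].
#' @param C,epsilon SVR hyperparameters.
#' @param tol,max_iter,weight_floor SimpleMKL controls (see
#'   [fit_simplemkl()]).
#' @param standardize standardise columns on training statistics (constant
#'   columns get scale 1). Disable only for pre-standardised input.
#' @return An object of class `fsmkl` with components `solution` (the
#'   `mkl_solution`), `candidates` (subsets + kernel specs + normalisations,
#'   grams dropped), `importance` (per-feature table), `selected`
#'   (character vector of selected features), `ranking`, `groups`,
#'   `center`/`scale`, and `fitted.values`.
#' @seealso [predict.fsmkl()], [summary.fsmkl()], [feature_importance()]
#' @examples
#' sim <- make_feature_table(n_samples = 60, n_groups = 4,
#'                           informative_groups = 2, seed = 1)
#' fit <- fsmkl(sim$X, sim$y,
#'              kernels = default_kernel_bank(sigmas = c(0.5, 1), degrees = 1))
#' fit
#' head(coef(fit))
#' @export
fsmkl <- function(x, y, rho = 0.8, kernels = default_kernel_bank(),
                  C = 10, epsilon = 0.01, tol = 1e-4, max_iter = 200,
                  weight_floor = 1e-6, standardize = TRUE) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  cl <- match.call()

  ctr <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (standardize) apply(x, 2, stats::sd) else rep(1, ncol(x))
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  ranking <- filter_rank(xs, y)
  groups <- group_features(xs, rho)
  cands <- enumerate_subset_kernels(groups, ranking, kernels)
  if (length(cands) == 0)
    stop("no candidate kernels: all feature groups are singletons ",
         "(lower `rho` or provide correlated features)")

  ## Stack all candidate grams straight into one n^2 x M matrix (single
  ## copy in memory). Within a group the subsets are nested in ranking
  ## order, so squared distances and dot products accumulate one feature
  ## at a time.
  n <- nrow(xs)
  G <- matrix(0, n * n, length(cands))
  m <- 0L
  for (g in groups) {
    if (length(g) < 2) next
    pos <- match(seq_len(ncol(xs)), ranking)
    g_ord <- g[order(pos[g])]
    sq <- matrix(0, n, n)
    dot <- matrix(0, n, n)
    for (j in seq_along(g_ord)) {
      v <- xs[, g_ord[j]]
      sq <- sq + outer(v, v, "-")^2
      dot <- dot + tcrossprod(v)
      if (j < 2) next
      for (sp in kernels) {
        K <- if (sp$kind == "gaussian") exp(-sq / (2 * sp$sigma^2))
             else (dot + 1)^sp$degree
        m <- m + 1L
        nrm <- mean(diag(K))
        if (nrm <= 0) nrm <- 1
        cands[[m]]$norm <- nrm
        G[, m] <- as.vector(K) / nrm
      }
    }
  }
  stopifnot(m == length(cands))
  sol <- mkl_core(G, y, C, epsilon, tol, max_iter, weight_floor)
  rm(G)
  imp <- feature_importance(sol, cands, colnames(x))
  selected <- imp$feature[imp$kernels >= 1L]

  structure(list(
    call = cl, solution = sol, candidates = cands, importance = imp,
    selected = selected, ranking = ranking, groups = groups,
    center = ctr, scale = scl, x = xs, y = y,
    fitted.values = sol$fitted,
    config = list(rho = rho, C = C, epsilon = epsilon, tol = tol,
                  max_iter = max_iter, weight_floor = weight_floor,
                  n_kernel_specs = length(kernels))),
    class = "fsmkl")
}

#' Predict from a fitted FSMKL model
#'
#' `f(x) = sum_i alpha_i sum_m d_m K_m(x_i, x) + b`, evaluated over the
#' active kernels with the training standardisation and per-kernel
#' normalisation.
#'
#' @param object an [fsmkl()] fit.
#' @param newdata feature matrix/data.frame with the training columns.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.fsmkl <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  xn <- as_feature_matrix(newdata)
  tr_names <- names(object$center)
  if (!is.null(tr_names) && all(tr_names %in% colnames(xn)))
    xn <- xn[, tr_names, drop = FALSE]
  else if (ncol(xn) != length(object$center))
    stop("newdata does not match the training feature registry")
  xn <- sweep(sweep(xn, 2, object$center), 2, object$scale, "/")
  sol <- object$solution
  f <- rep(0, nrow(xn))
  for (m in sol$active_kernels) {
    Kx <- compute_cross(xn, object$x, object$candidates[[m]])
    f <- f + sol$d[m] * drop(Kx %*% sol$alpha)
  }
  f + sol$b
}

#' @export
fitted.fsmkl <- function(object, ...) object$fitted.values

#' @export
residuals.fsmkl <- function(object, ...) object$y - object$fitted.values

#' @export
coef.fsmkl <- function(object, ...) {
  stats::setNames(object$importance$weight, object$importance$feature)
}

#' @export
print.fsmkl <- function(x, ...) {
  sol <- x$solution
  cat("FSMKL regression\n")
  cat(sprintf("  %d samples, %d features in %d groups\n",
              length(x$y), length(x$center), length(x$groups)))
  cat(sprintf("  %d candidate kernels, %d active; %d features selected\n",
              length(x$candidates), length(sol$active_kernels),
              length(x$selected)))
  cat(sprintf("  objective %.6g after %d iterations (%s)\n",
              sol$objective, sol$iterations,
              if (sol$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
summary.fsmkl <- function(object, ...) {
  r <- residuals(object)
  out <- list(
    call = object$call,
    n = length(object$y), p = length(object$center),
    n_groups = length(object$groups),
    n_candidates = length(object$candidates),
    n_active = length(object$solution$active_kernels),
    selected = object$selected,
    importance = object$importance[object$importance$weight > 0, ],
    train_rmse = sqrt(mean(r^2)),
    train_r2 = if (stats::sd(object$fitted.values) > 0)
      stats::cor(object$fitted.values, object$y)^2 else 0,
    converged = object$solution$converged,
    iterations = object$solution$iterations)
  class(out) <- "summary.fsmkl"
  out
}

#' @export
print.summary.fsmkl <- function(x, ...) {
  cat("FSMKL regression summary\n\nCall: ")
  print(x$call)
  cat(sprintf("\n%d samples, %d features, %d groups, %d candidate kernels\n",
              x$n, x$p, x$n_groups, x$n_candidates))
  cat(sprintf("Active kernels: %d; selected features: %d\n",
              x$n_active, length(x$selected)))
  cat(sprintf("Training R2 %.4f, RMSE %.4f (%s, %d iterations)\n\n",
              x$train_r2, x$train_rmse,
              if (x$converged) "converged" else "not converged",
              x$iterations))
  cat("Feature importance (accumulated kernel weight):\n")
  print(utils::head(x$importance, 25), row.names = FALSE)
  invisible(x)
}

#' Plot an FSMKL fit
#'
#' Either the accumulated-weight importance profile of the selected
#' features or the (non-increasing) SimpleMKL objective trace.
#'
#' @param x an [fsmkl()] fit.
#' @param which `"importance"` or `"trace"`.
#' @param max_features importance bars to show.
#' @param ... passed to the underlying plot call.
#' @export
plot.fsmkl <- function(x, which = c("importance", "trace"),
                       max_features = 22L, ...) {
  which <- match.arg(which)
  if (which == "importance") {
    imp <- x$importance[x$importance$weight > 0, ]
    imp <- utils::head(imp, max_features)
    op <- graphics::par(mar = c(5, 12, 2, 1))
    on.exit(graphics::par(op))
    graphics::barplot(rev(imp$weight), names.arg = rev(imp$feature),
                      horiz = TRUE, las = 1, cex.names = 0.7,
                      xlab = "accumulated kernel weight", ...)
  } else {
    graphics::plot(seq_along(x$solution$trace) - 1L, x$solution$trace,
                   type = "b", xlab = "iteration",
                   ylab = "SimpleMKL objective", ...)
  }
  invisible(x)
}

#' One-call FSMKL feature selection
#'
#' Convenience wrapper returning the pieces of the pipeline separately:
#' the fitted solution, the importance table and the selected feature set.
#'
#' @inheritParams fsmkl
#' @param config optional named list overriding any of `rho`, `kernels`,
#'   `C`, `epsilon`, `tol`, `max_iter`, `weight_floor`.
#' @return List with `fit` (the `fsmkl` object), `solution`, `importance`,
#'   and `selected`.
#' @export
fsmkl_select <- function(x, y, config = list()) {
  args <- c(list(x = x, y = y), config)
  fit <- do.call(fsmkl, args)
  list(fit = fit, solution = fit$solution, importance = fit$importance,
       selected = fit$selected)
}
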