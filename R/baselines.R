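## The comparison regressors: multiple linear regression, stepwise-AIC GLM,
## lasso (fraction parameterisation), elastic net, and kernel SVM-RFE with
## the squared-weight ranking criterion. All return a common `baseline_fit`
## class with a shared predict method.

new_baseline <- function(method, ...) {
  structure(c(list(method = method), list(...)), class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit %s: %d/%d features selected>\n", x$method,
              length(x$selected), length(x$feature_names)))
  invisible(x)
}

#' Multiple linear regression (no feature selection)
#'
#' Ordinary least squares on all features. A rank-deficient design falls
#' back to the minimum-norm pseudo-inverse solution with a warning.
#'
#' @param x feature matrix or data.frame.
#' @param y numeric response.
#' @return A `baseline_fit` (method `"LM"`).
#' @export
fit_lm <- function(x, y) {
  x <- as_feature_matrix(x)
  X1 <- cbind(`(Intercept)` = 1, x)
  qx <- qr(X1)
  if (qx$rank < ncol(X1)) {
    warning("rank-deficient design: using the minimum-norm pseudo-inverse")
    sv <- svd(X1)
    pos <- sv$d > max(dim(X1)) * .Machine$double.eps * sv$d[1]
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qx, y)
  }
  names(beta) <- colnames(X1)
  new_baseline("LM", coefficients = beta,
               selected = colnames(x), feature_names = colnames(x))
}

#' Stepwise-AIC generalized linear model
#'
#' Bidirectional stepwise search (gaussian family) from the intercept-only
#' model, adding/dropping single features to minimise AIC.
#'
#' @inheritParams fit_lm
#' @param max_steps cap on stepwise moves.
#' @return A `baseline_fit` (method `"GLM_stepwise"`); an intercept-only
#'   model is allowed.
#' @export
fit_glm_stepwise <- function(x, y, max_steps = 1000) {
  x <- as_feature_matrix(x)
  df <- data.frame(.y = y, x, check.names = TRUE)
  safe <- colnames(df)[-1]                       # syntactic names for formula
  null_fit <- stats::glm(.y ~ 1, data = df, family = stats::gaussian())
  scope <- stats::as.formula(paste("~", paste(safe, collapse = " + ")))
  fit <- stats::step(null_fit, scope = list(lower = ~1, upper = scope),
                     direction = "both", trace = 0, steps = max_steps)
  sel_safe <- attr(stats::terms(fit), "term.labels")
  sel <- colnames(x)[match(sel_safe, safe)]
  new_baseline("GLM_stepwise", fit = fit, safe_names = safe,
               selected = sel, feature_names = colnames(x),
               aic = stats::AIC(fit))
}

## L1 norm of the least-squares (or minimum-norm) coefficient vector,
## the reference for the lasso "fraction" parameterisation.
ls_l1_norm <- function(x, y) {
  fit <- suppressWarnings(fit_lm(x, y))
  sum(abs(fit$coefficients[-1]))
}

#' Lasso regression at an L1-norm fraction
#'
#' The penalty is parameterised as a fraction: the fitted coefficients'
#' L1 norm is constrained to `fraction` times the L1 norm of the
#' least-squares solution. The glmnet path is interpolated at that L1
#' budget (for `p >= n`, the least-penalised end of the path plays the
#' role of the reference solution).
#'
#' @inheritParams fit_lm
#' @param fraction L1 budget in (0, 1].
#' @return A `baseline_fit` (method `"Lasso"`) with zero coefficients
#'   implying deselection.
#' @export
fit_lasso <- function(x, y, fraction = 0.1) {
  x <- as_feature_matrix(x)
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(x)
  if (fraction >= 1 && ncol(x) < n) {
    ls <- fit_lm(x, y)
    return(new_baseline("Lasso", coefficients = ls$coefficients,
                        fraction = 1, selected = colnames(x),
                        feature_names = colnames(x)))
  }
  path <- glmnet::glmnet(x, y, alpha = 1, nlambda = 200,
                         lambda.min.ratio = 1e-6)
  B <- as.matrix(path$beta)                       # p x nlambda
  l1 <- colSums(abs(B))
  ref <- if (ncol(x) < n) ls_l1_norm(x, y) else max(l1)
  target <- fraction * ref
  if (target <= min(l1)) {
    idx <- which.min(l1)
    beta <- B[, idx]
    a0 <- path$a0[idx]
  } else if (target >= max(l1)) {
    idx <- which.max(l1)
    beta <- B[, idx]
    a0 <- path$a0[idx]
  } else {
    hi <- min(which(l1 >= target))
    lo <- hi - 1L
    w <- (target - l1[lo]) / (l1[hi] - l1[lo])
    beta <- (1 - w) * B[, lo] + w * B[, hi]
    a0 <- (1 - w) * path$a0[lo] + w * path$a0[hi]
  }
  coefs <- c(`(Intercept)` = unname(a0), beta)
  new_baseline("Lasso", coefficients = coefs, fraction = fraction,
               selected = colnames(x)[beta != 0],
               feature_names = colnames(x))
}

#' Elastic-net regression
#'
#' Mixed L1/L2 penalty at mixing parameter `alpha`; the penalty magnitude
#' is chosen by internal 10-fold cross-validation on the training data over
#' a 50-value log-spaced grid.
#'
#' @inheritParams fit_lm
#' @param alpha mixing parameter in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param nfolds internal CV folds.
#' @return A `baseline_fit` (method `"ENET"`).
#' @export
fit_enet <- function(x, y, alpha = 0.8, nfolds = 10) {
  x <- as_feature_matrix(x)
  stopifnot(alpha >= 0, alpha <= 1)
  cv <- glmnet::cv.glmnet(x, y, alpha = alpha, nfolds = nfolds, nlambda = 50)
  beta <- as.vector(stats::coef(cv, s = "lambda.min"))
  names(beta) <- c("(Intercept)", colnames(x))
  new_baseline("ENET", coefficients = beta, alpha = alpha,
               lambda = cv$lambda.min,
               selected = colnames(x)[beta[-1] != 0],
               feature_names = colnames(x))
}

## Kernel for SVM-RFE: kernlab's bandwidth convention
## K = exp(-sigma * ||x - x'||^2) (default bandwidth sigma = 2^-6), or
## the linear kernel for the exactly-analysable special case.
rfe_kernel <- function(xa, xb, kernel, sigma) {
  if (kernel == "linear") return(tcrossprod(xa, xb))
  sq <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  exp(-sigma * pmax(sq, 0))
}

## Squared-weight importance of each active feature: the change in the SVR
## quadratic form 1/2 beta' K beta when the feature is removed from the
## kernel. For the linear kernel this is exactly 1/2 w_f^2.
rfe_criterion <- function(xs, beta, kernel, sigma) {
  if (kernel == "linear") {
    w <- drop(crossprod(xs, beta))
    return(0.5 * w^2)
  }
  K <- rfe_kernel(xs, xs, kernel, sigma)
  base_q <- 0.5 * drop(crossprod(beta, K %*% beta))
  vapply(seq_len(ncol(xs)), function(f) {
    Df <- outer(xs[, f], xs[, f], "-")^2
    Kf <- K * exp(sigma * Df)          # kernel with feature f removed
    abs(base_q - 0.5 * drop(crossprod(beta, Kf %*% beta)))
  }, numeric(1))
}

#' SVM-RFE: recursive feature elimination by squared-weight ranking
#'
#' Iteratively fits an SVR (gaussian kernel by default), scores every
#' surviving feature by the squared-weight criterion (the change in the
#' fitted quadratic form when the feature is removed from the kernel; for a
#' linear kernel, literally `w_f^2`), removes the lowest-scoring half, and
#' stops at `bestsubsetsize` survivors, on which the final model is refit.
#' Ties are broken by original column order.
#'
#' @inheritParams fit_lm
#' @param bestsubsetsize target number of surviving features (`<= p`).
#' @param sigma gaussian bandwidth, kernlab convention
#'   `exp(-sigma ||x - x'||^2)`.
#' @param C,epsilon SVR hyperparameters.
#' @param kernel `"gaussian"` or `"linear"`.
#' @return A `baseline_fit` (method `"SVM_RFE"`) carrying the survivor set,
#'   the nested elimination history and the refit dual solution.
#' @export
svm_rfe <- function(x, y, bestsubsetsize = 256, sigma = 2^-6, C = 10,
                    epsilon = 0.01, kernel = c("gaussian", "linear")) {
  x <- as_feature_matrix(x)
  kernel <- match.arg(kernel)
  p <- ncol(x)
  if (bestsubsetsize > p)
    stop("bestsubsetsize (", bestsubsetsize, ") exceeds feature count (", p, ")")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  surviving <- seq_len(p)
  history <- list(surviving)
  while (length(surviving) > bestsubsetsize) {
    xcur <- xs[, surviving, drop = FALSE]
    K <- rfe_kernel(xcur, xcur, kernel, sigma)
    sol <- svr_dual_solve(K, y, C, epsilon)
    crit <- rfe_criterion(xcur, sol$alpha, kernel, sigma)
    keep_n <- max(bestsubsetsize, ceiling(length(surviving) / 2))
    ord <- order(-crit, seq_along(surviving))    # ties: earlier column wins
    surviving <- sort(surviving[ord[seq_len(keep_n)]])
    history[[length(history) + 1L]] <- surviving
  }
  xfin <- xs[, surviving, drop = FALSE]
  Kfin <- rfe_kernel(xfin, xfin, kernel, sigma)
  sol <- svr_dual_solve(Kfin, y, C, epsilon)
  new_baseline("SVM_RFE", alpha = sol$alpha, b = sol$b,
               surviving = surviving, history = history,
               center = ctr, scale = scl, x_train = xfin,
               kernel = kernel, sigma = sigma, C = C, epsilon = epsilon,
               selected = colnames(x)[surviving],
               feature_names = colnames(x))
}

#' Predict from a fitted baseline
#'
#' @param object a `baseline_fit`.
#' @param newdata feature matrix/data.frame with the training columns.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.baseline_fit <- function(object, newdata, ...) {
  xn <- as_feature_matrix(newdata)
  fn <- object$feature_names
  if (!is.null(fn) && all(fn %in% colnames(xn)))
    xn <- xn[, fn, drop = FALSE]
  else if (ncol(xn) != length(fn))
    stop("newdata does not match the training feature registry")
  switch(object$method,
    LM = , Lasso = , ENET =
      drop(cbind(1, xn) %*% object$coefficients),
    GLM_stepwise = {
      df <- as.data.frame(xn)
      colnames(df) <- object$safe_names
      unname(stats::predict(object$fit, newdata = df))
    },
    SVM_RFE = {
      xs <- sweep(sweep(xn, 2, object$center), 2, object$scale, "/")
      Kx <- rfe_kernel(xs[, object$surviving, drop = FALSE],
                       object$x_train, object$kernel, object$sigma)
      drop(Kx %*% object$alpha) + object$b
    },
    stop("unknown baseline method: ", object$method))
}
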