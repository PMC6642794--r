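## Epsilon-insensitive support vector regression on a precomputed kernel.
## The dual solved here, in the signed coefficients beta = alpha+ - alpha-:
##
##   maximize  W(beta) = -1/2 beta' K beta + y' beta - epsilon * sum |beta|
##   subject to sum(beta) = 0, |beta_i| <= C
##
## with predictions f(x) = sum_i beta_i K(x_i, x) + b. The box/equality QP
## is delegated to kernlab's SMO; W is recomputed here from the returned
## coefficients so the MKL layer has an exact objective value.

svr_objective <- function(K, y, beta, epsilon) {
  -0.5 * drop(crossprod(beta, K %*% beta)) + sum(y * beta) -
    epsilon * sum(abs(beta))
}

#' Solve the epsilon-insensitive SVR dual on a precomputed kernel
#'
#' @param K symmetric positive semi-definite `n x n` kernel matrix.
#' @param y numeric response of length `n`.
#' @param C box constraint (`|alpha_i| <= C`), positive.
#' @param epsilon tube half-width, non-negative.
#' @param tol solver tolerance.
#' @return List with `alpha` (signed dual coefficients, length `n`), `b`
#'   (bias, so that fitted = `K %*% alpha + b`), `objective` (the dual value
#'   `W`), and `fitted`.
#' @export
svr_dual_solve <- function(K, y, C = 10, epsilon = 0.01, tol = 1e-6) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K), length(y) == nrow(K),
            C > 0, epsilon >= 0)
  n <- length(y)
  ## Constant response inside the tube: beta = 0, b = that constant, is the
  ## exact optimum (any subgradient step would pay the epsilon penalty).
  if (max(abs(y - mean(y))) <= epsilon) {
    return(list(alpha = numeric(n), b = mean(y), objective = 0,
                fitted = rep(mean(y), n)))
  }
  fit <- tryCatch(
    kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "eps-svr",
                  C = C, epsilon = epsilon, tol = tol),
    error = function(e) stop("SVR solver failed: ", conditionMessage(e)))
  beta <- numeric(n)
  beta[unlist(kernlab::alphaindex(fit))] <- unlist(kernlab::coef(fit))
  b <- -kernlab::b(fit)
  list(alpha = beta, b = b,
       objective = svr_objective(K, y, beta, epsilon),
       fitted = drop(K %*% beta) + b)
}
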