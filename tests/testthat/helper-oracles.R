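## Independent oracles, deliberately implemented along different routes
## than the package code they check.

## Epsilon-SVR dual solved as an explicit box/equality QP with kernlab's
## interior-point solver, in the (alpha+, alpha-) parameterisation.
svr_qp_oracle <- function(K, y, C, epsilon, sigf = 9) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  cvec <- c(epsilon - y, epsilon + y)
  A <- matrix(rep(c(1, -1), each = n), 1)
  sol <- kernlab::ipop(cvec, H, A, b = 0, l = rep(0, 2 * n),
                       u = rep(C, 2 * n), r = 0, sigf = sigf,
                       maxiter = 400)
  z <- kernlab::primal(sol)
  beta <- z[1:n] - z[(n + 1):(2 * n)]
  obj <- -0.5 * drop(crossprod(beta, K %*% beta)) + sum(y * beta) -
    epsilon * sum(abs(beta))
  list(alpha = beta, objective = obj)
}

## Simple linear regression of y on x by stats::lm (checks the closed-form
## log-log fits).
lm_slope_r2 <- function(x, y) {
  fit <- stats::lm(y ~ x)
  c(M = unname(stats::coef(fit)[2]), R2 = summary(fit)$r.squared)
}

## Leave-one-out refit diagnostics: externally studentized residual and
## Cook's distance from first principles (n refits).
loo_diagnostics_oracle <- function(x, y) {
  n <- length(y)
  X1 <- cbind(1, x)
  p <- ncol(X1)
  fit <- stats::lm.fit(X1, y)
  beta <- fit$coefficients
  t_ext <- numeric(n)
  cook <- numeric(n)
  s2 <- sum(fit$residuals^2) / (n - p)
  XtXinv <- solve(crossprod(X1))
  for (i in seq_len(n)) {
    fi <- stats::lm.fit(X1[-i, , drop = FALSE], y[-i])
    s2_i <- sum(fi$residuals^2) / (n - 1 - p)
    pred_i <- drop(X1[i, ] %*% fi$coefficients)
    h_i <- drop(X1[i, ] %*% XtXinv %*% X1[i, ])
    ## deleted-prediction form of the external residual
    t_ext[i] <- (y[i] - pred_i) / sqrt(s2_i * (1 + drop(
      X1[i, ] %*% solve(crossprod(X1[-i, , drop = FALSE])) %*% X1[i, ])))
    ## parameter-shift form of Cook's distance
    db <- beta - fi$coefficients
    cook[i] <- drop(t(db) %*% crossprod(X1) %*% db) / (p * s2)
  }
  list(t_external = t_ext, cooks_d = cook)
}

## Tiny PIFS coder at one fixed block size, written as plain loops:
## exhaustive search over every domain/range pairing, then iterative
## decode. Mirrors the contract, not the implementation.
pifs_oracle_error <- function(m, block, s_max = 0.9, iterations = 12L) {
  nr <- nrow(m); nc <- ncol(m)
  dsz <- 2L * block
  dpos <- expand.grid(r = seq(1L, nr - dsz + 1L, by = block),
                      c = seq(1L, nc - dsz + 1L, by = block))
  shrink <- function(b) {
    out <- matrix(0, block, block)
    for (i in 1:block) for (j in 1:block)
      out[i, j] <- mean(b[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    out
  }
  maps <- list()
  for (r0 in seq(1L, nr, by = block)) for (c0 in seq(1L, nc, by = block)) {
    rng <- m[r0 + 0:(block - 1L), c0 + 0:(block - 1L)]
    best <- NULL
    for (k in seq_len(nrow(dpos))) {
      dom <- shrink(m[dpos$r[k] + 0:(dsz - 1L), dpos$c[k] + 0:(dsz - 1L)])
      dv <- as.vector(dom); rv <- as.vector(rng)
      vd <- sum((dv - mean(dv))^2)
      s <- if (vd > 0) sum((dv - mean(dv)) * (rv - mean(rv))) / vd else 0
      s <- max(min(s, s_max), -s_max)
      o <- mean(rv) - s * mean(dv)
      err <- sum((rv - (s * dv + o))^2)
      if (is.null(best) || err < best$err)
        best <- list(err = err, k = k, s = s, o = o)
    }
    maps[[length(maps) + 1L]] <- c(r0 = r0, c0 = c0, k = best$k,
                                   s = best$s, o = best$o)
  }
  img <- matrix(0.5, nr, nc)
  for (it in seq_len(iterations)) {
    nxt <- img
    for (mp in maps) {
      dom <- shrink(img[dpos$r[mp["k"]] + 0:(dsz - 1L),
                        dpos$c[mp["k"]] + 0:(dsz - 1L)])
      nxt[mp["r0"] + 0:(block - 1L), mp["c0"] + 0:(block - 1L)] <-
        mp["s"] * dom + mp["o"]
    }
    img <- pmin(pmax(nxt, 0), 1)
  }
  sqrt(mean((m - img)^2))
}
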