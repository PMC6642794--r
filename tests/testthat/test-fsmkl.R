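test_that("filter ranking recovers planted correlation order", {
  fx <- viscomplexity:::with_seed(21, {
    n <- 400
    y <- stats::rnorm(n)
    mk <- function(r) r * y + sqrt(1 - r^2) * stats::rnorm(n)
    X <- cbind(a = mk(0.9), b = mk(0.5), c = mk(0.1),
               d = stats::rnorm(n), e = stats::rnorm(n))
    list(X = X, y = y)
  })
  rk <- filter_rank(fx$X, fx$y)
  expect_equal(rk[1:3], 1:3)
  expect_setequal(rk, 1:5)

  ## a column equal to y ranks first; constant columns score zero, keep order
  X2 <- cbind(k1 = rep(1, 50), yy = fx$y[1:50], k2 = rep(2, 50))
  expect_equal(filter_rank(X2, fx$y[1:50]), c(2L, 1L, 3L))
  expect_error(filter_rank(fx$X[1:2, ], fx$y[1:2]), "3 samples")
})

test_that("correlation grouping matches the planted block structure", {
  fx <- viscomplexity:::with_seed(8, {
    n <- 500
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    mk <- function(z) sqrt(0.95) * z + sqrt(0.05) * stats::rnorm(n)
    list(X = cbind(mk(z1), mk(z1), mk(z1), mk(z2), mk(z2), mk(z2)))
  })
  gr <- group_features(fx$X, rho = 0.8)
  expect_length(gr, 2)
  expect_setequal(gr[[1]], 1:3)
  expect_setequal(gr[[2]], 4:6)
  ## oracle: connected components of the thresholded |corr| graph coincide
  ## with complete linkage on this block design
  adj <- abs(stats::cor(fx$X)) > 0.8
  expect_true(all(adj[1:3, 1:3]) && all(adj[4:6, 4:6]) &&
              !any(adj[1:3, 4:6]))

  ## independent features: all singletons; identical features: one group
  Xi <- viscomplexity:::with_seed(9, matrix(stats::rnorm(600), 200, 3))
  expect_length(group_features(Xi, 0.8), 3)
  Xd <- cbind(Xi[, 1], Xi[, 1], Xi[, 1])
  expect_length(group_features(Xd, 0.8), 1)
})

test_that("subset-kernel enumeration follows the nested-count formula", {
  specs <- default_kernel_bank()           # 7 gaussian + 4 polynomial = 11
  expect_length(specs, 11)
  cands <- enumerate_subset_kernels(list(1:4), 1:4, specs)
  expect_length(cands, 3 * 11)

  cands2 <- enumerate_subset_kernels(list(1:5, 6:8, 9:10), 1:10,
                                     default_kernel_bank(sigmas = 1,
                                                         degrees = 1))
  expect_length(cands2, (4 + 2 + 1) * 2)
  ## nested subsets are ordered by the global ranking
  rk <- c(3, 1, 2, 4:10)                   # feature 3 ranked first
  c3 <- enumerate_subset_kernels(list(1:3), rk,
                                 default_kernel_bank(sigmas = 1,
                                                     degrees = NULL))
  expect_equal(c3[[1]]$subset, c(3, 1))
  expect_equal(c3[[2]]$subset, c(3, 1, 2))

  expect_length(enumerate_subset_kernels(list(1L, 2L, 3L), 1:3, specs), 0)
  expect_error(enumerate_subset_kernels(list(1:3), 1:3, list()), "empty")
})

test_that("gram computation matches the kernel formulas", {
  fx <- svr_fixture(31, n = 12, p = 3)
  g <- compute_gram(fx$x, 1:3, kernel_spec("gaussian", sigma = 0.7))
  D2 <- unname(as.matrix(dist(fx$x))^2)
  expect_equal(unname(g$gram * g$norm), exp(-D2 / (2 * 0.7^2)),
               tolerance = 1e-12)
  expect_equal(mean(diag(g$gram)), 1, tolerance = 1e-12)

  p1 <- compute_gram(fx$x, 2L, kernel_spec("polynomial", degree = 1))
  expect_equal(p1$gram * p1$norm, tcrossprod(fx$x[, 2]) + 1,
               tolerance = 1e-12)

  ## duplicate rows give K_ii = K_ij = K_jj for the gaussian
  xd <- rbind(fx$x, fx$x[1, ])
  gd <- compute_gram(xd, 1:3, kernel_spec("gaussian", sigma = 1))
  expect_equal(gd$gram[1, 13], gd$gram[1, 1], tolerance = 1e-12)
})

test_that("the SVR dual solve honours its contracts and the QP oracle", {
  ## constant target inside the tube
  K <- diag(5) + 0.5
  out <- svr_dual_solve(K, rep(2.5, 5), C = 10, epsilon = 0.1)
  expect_equal(out$alpha, numeric(5))
  expect_equal(out$b, 2.5)

  ## linear kernel on noiseless line: predictions match least squares
  x <- c(1, 2, 3, 4)
  y <- 2 * x + 1
  Klin <- outer(x, x) + 1
  sol <- svr_dual_solve(Klin, y, C = 1e5, epsilon = 0, tol = 1e-8)
  expect_equal(sol$fitted, y, tolerance = 1e-6)
  expect_lt(abs(sum(sol$alpha)), 1e-8)

  ## tiny problems against the generic QP oracle
  for (s in 1:4) {
    fx <- svr_fixture(40 + s, n = 6, p = 2)
    K <- exp(-as.matrix(dist(fx$x))^2 / 2)
    mine <- svr_dual_solve(K, fx$y, C = 5, epsilon = 0.05, tol = 1e-8)
    orc <- svr_qp_oracle(K, fx$y, C = 5, epsilon = 0.05)
    expect_equal(mine$objective, orc$objective, tolerance = 1e-6)
    expect_true(all(abs(mine$alpha) <= 5 + 1e-8))
  }
})

test_that("SimpleMKL reduces to plain SVR for degenerate kernel banks", {
  fx <- svr_fixture(50, n = 40, p = 3)
  g <- compute_gram(fx$x, 1:3, kernel_spec("gaussian", sigma = 1))
  cand <- list(list(subset = 1:3, spec = kernel_spec("gaussian", sigma = 1),
                    gram = g$gram, norm = g$norm))
  mkl <- fit_simplemkl(cand, fx$y)
  svr <- svr_dual_solve(g$gram, fx$y)
  expect_equal(mkl$d, 1)
  expect_lt(max(abs(mkl$fitted - svr$fitted)), 1e-8)

  ## two identical kernels: returned predictions equal the single-kernel fit
  mkl2 <- fit_simplemkl(c(cand, cand), fx$y)
  expect_lt(max(abs(mkl2$fitted - svr$fitted)), 1e-6)
  expect_equal(sum(mkl2$d), 1, tolerance = 1e-8)
})

test_that("SimpleMKL conserves the simplex, decreases the objective, and
           concentrates weight on the signal kernel", {
  for (s in 1:20) {
    fx <- viscomplexity:::with_seed(60 + s, {
      n <- 30
      x1 <- stats::rnorm(n)
      x2 <- stats::rnorm(n)
      y <- sin(2 * x1) + 0.1 * stats::rnorm(n)
      list(x = scale(cbind(x1, x2)), y = y)
    })
    g1 <- compute_gram(fx$x, 1L, kernel_spec("gaussian", sigma = 1))
    g2 <- compute_gram(fx$x, 2L, kernel_spec("gaussian", sigma = 1))
    cands <- list(
      list(subset = 1L, spec = kernel_spec("gaussian", sigma = 1),
           gram = g1$gram, norm = g1$norm),
      list(subset = 2L, spec = kernel_spec("gaussian", sigma = 1),
           gram = g2$gram, norm = g2$norm))
    sol <- fit_simplemkl(cands, fx$y, C = 10, epsilon = 0.01)
    expect_equal(sum(sol$d), 1, tolerance = 1e-8)
    expect_true(all(sol$d >= 0))
    expect_true(all(diff(sol$trace) <= 1e-10))
    expect_gt(sol$d[1], 0.7)   # the kernel y was generated through dominates
    if (s <= 5) {
      ## oracle: grid search over the simplex for the same objective,
      ## against a tightly converged fit
      tight <- fit_simplemkl(cands, fx$y, C = 10, epsilon = 0.01,
                             tol = 1e-8, max_iter = 500)
      grid <- seq(0, 1, by = 0.02)
      obj <- vapply(grid, function(d1)
        svr_dual_solve(d1 * g1$gram + (1 - d1) * g2$gram, fx$y,
                       C = 10, epsilon = 0.01)$objective, numeric(1))
      expect_lt(abs(tight$d[1] - grid[which.min(obj)]), 0.05)
      expect_lte(tight$objective, min(obj) + 1e-4)
    }
  }
})

test_that("SimpleMKL matches brute-force simplex grid search with an exact
           inner QP on a tiny two-kernel problem", {
  fx <- svr_fixture(77, n = 6, p = 2)
  g1 <- compute_gram(fx$x, 1L, kernel_spec("gaussian", sigma = 0.8))
  g2 <- compute_gram(fx$x, 2L, kernel_spec("polynomial", degree = 2))
  cands <- list(
    list(subset = 1L, spec = kernel_spec("gaussian", sigma = 0.8),
         gram = g1$gram, norm = g1$norm),
    list(subset = 2L, spec = kernel_spec("polynomial", degree = 2),
         gram = g2$gram, norm = g2$norm))
  sol <- fit_simplemkl(cands, fx$y, C = 5, epsilon = 0.05, tol = 1e-7)
  grid_obj <- vapply(seq(0, 1, by = 0.01), function(d1) {
    K <- d1 * g1$gram + (1 - d1) * g2$gram
    svr_qp_oracle(K, fx$y, C = 5, epsilon = 0.05)$objective
  }, numeric(1))
  expect_lte(sol$objective, min(grid_obj) + 1e-4)
})

test_that("predictions compose the weighted kernels correctly", {
  fx <- viscomplexity:::with_seed(90, {
    n <- 120
    x <- matrix(stats::rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    x <- cbind(x, f5 = x[, 1] * 0.98 + 0.02 * stats::rnorm(n))
    sig <- x[, 1] + 0.5 * x[, 2]
    y <- sig + stats::rnorm(n, sd = 0.1 * stats::sd(sig))
    list(x = x, y = y)
  })
  fit <- fsmkl(fx$x[1:80, ], fx$y[1:80], rho = 0.5,
               kernels = default_kernel_bank(sigmas = c(0.5, 1, 2),
                                             degrees = 1:2))
  ## predicting the training points reproduces the fitted values
  expect_equal(predict(fit, fx$x[1:80, ]), fit$fitted.values,
               tolerance = 1e-9)
  ## held-out accuracy at 10:1 signal-to-noise
  p <- predict(fit, fx$x[81:120, ])
  expect_gt(stats::cor(p, fx$y[81:120])^2, 0.8)
  expect_error(predict(fit, fx$x[, 1:2]), "registry")
})

test_that("feature importance accumulates and conserves kernel weights", {
  sol <- structure(list(d = c(0.6, 0.4), active_kernels = 1:2),
                   class = "mkl_solution")
  kernels <- list(list(subset = c(1L, 2L)), list(subset = c(1L, 3L)))
  imp <- feature_importance(sol, kernels, c("f1", "f2", "f3"))
  w <- stats::setNames(imp$weight, imp$feature)
  k <- stats::setNames(imp$kernels, imp$feature)
  expect_equal(unname(w[c("f1", "f2", "f3")]), c(1.0, 0.6, 0.4))
  expect_equal(unname(k[c("f1", "f2", "f3")]), c(2L, 1L, 1L))

  ## conservation identity on a real fit
  fx <- svr_fixture(91, n = 60, p = 6, noise = 0.3)
  colnames(fx$x) <- paste0("f", 1:6)
  fit <- fsmkl(fx$x, fx$y, rho = 0.05,
               kernels = default_kernel_bank(sigmas = 1, degrees = 1))
  sol <- fit$solution
  lhs <- sum(fit$importance$weight)
  rhs <- sum(vapply(sol$active_kernels, function(m)
    sol$d[m] * length(fit$candidates[[m]]$subset), numeric(1)))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("fsmkl is invariant to feature permutation and symmetric under
           duplicated columns", {
  fx <- viscomplexity:::with_seed(95, {
    n <- 80
    z <- stats::rnorm(n)
    x <- cbind(a = z + 0.1 * stats::rnorm(n), b = z + 0.1 * stats::rnorm(n),
               c = stats::rnorm(n), d = stats::rnorm(n))
    y <- z + stats::rnorm(n, sd = 0.2)
    list(x = x, y = y)
  })
  bank <- default_kernel_bank(sigmas = c(0.5, 1), degrees = 1)
  f1 <- fsmkl(fx$x, fx$y, rho = 0.5, kernels = bank)
  perm <- c(3, 1, 4, 2)
  f2 <- fsmkl(fx$x[, perm], fx$y, rho = 0.5, kernels = bank)
  expect_equal(predict(f2, fx$x[, perm]), predict(f1, fx$x),
               tolerance = 1e-6)

  xd <- cbind(fx$x, a2 = fx$x[, "a"])
  fd <- fsmkl(xd, fx$y, rho = 0.5, kernels = bank)
  w <- stats::setNames(fd$importance$weight, fd$importance$feature)
  expect_equal(unname(w["a"]), unname(w["a2"]), tolerance = 1e-10)
})

test_that("fsmkl_select recovers planted informative structure and stays
           near chance under permuted responses", {
  sim <- make_feature_table(n_samples = 150, n_groups = 8,
                            informative_groups = 3, noise_sd = 0.2,
                            seed = 31)
  bank <- default_kernel_bank(sigmas = c(0.5, 1, 2), degrees = 1:2)
  sel <- fsmkl_select(sim$X, sim$y, config = list(kernels = bank))
  expect_gte(mean(sim$informative %in% sel$selected), 0.8)

  ## permuted response: selection should not single out the planted set
  yperm <- viscomplexity:::with_seed(32, sample(sim$y))
  selp <- fsmkl_select(sim$X, yperm, config = list(kernels = bank))
  hit <- mean(sim$informative %in% selp$selected)
  base <- length(selp$selected) / ncol(sim$X)   # size-matched random rate
  expect_lt(abs(hit - base), 0.35)
})
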