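## Shared fixtures, all generated in code.

noise_plane <- function(seed, n = 32L, m = n) {
  vals <- viscomplexity:::with_seed(seed, matrix(stats::runif(n * m), n, m))
  channel_plane(vals, "V")
}

## A small regression problem with one planted gross outlier.
outlier_fixture <- function(seed, n = 20L, shift = 4) {
  viscomplexity:::with_seed(seed, {
    x <- matrix(stats::rnorm(n * 2), n, 2)
    y <- x[, 1] + stats::rnorm(n, sd = 0.3)
    y[5] <- y[5] + shift
    list(x = x, y = y, outlier = 5L)
  })
}

## Small standardized feature matrix + response for kernel tests.
svr_fixture <- function(seed, n = 30L, p = 3L, noise = 0.2) {
  viscomplexity:::with_seed(seed, {
    x <- scale(matrix(stats::rnorm(n * p), n, p))
    y <- x[, 1] + stats::rnorm(n, sd = noise)
    list(x = x, y = as.numeric(y))
  })
}
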