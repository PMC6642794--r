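## Seeded synthetic fixtures: images with analytically known feature
## behaviour, and feature tables with the correlated-group structure and
## rating-noise level that real complexity-rating data exhibits. All
## generators are pure functions of their recipe (seed included).

#' Generate a synthetic stimulus image
#'
#' Deterministic image generators with analytically known feature
#' behaviour: `flat` (constant value), `linear_gradient` (ramp 0..255
#' along one axis), `checkerboard` (edges confined to cell boundaries),
#' `uniform_noise` (iid uniform intensities), and `blended_texture`
#' (checkerboard/noise mixture).
#'
#' @param kind image kind.
#' @param size `c(H, W)` in pixels.
#' @param value gray level (0..255) for `flat`.
#' @param orientation `"horizontal"` or `"vertical"` ramp direction for
#'   `linear_gradient` (`"horizontal"` ramps across columns).
#' @param cell checkerboard cell size in pixels (must fit in the image).
#' @param blend checkerboard weight in `[0, 1]` for `blended_texture`.
#' @param seed RNG seed for the stochastic kinds.
#' @param id image id; default encodes the recipe.
#' @return A [stimulus_image()].
#' @export
make_image <- function(kind = c("flat", "linear_gradient", "checkerboard",
                                "uniform_noise", "blended_texture"),
                       size = c(64L, 64L), value = 128, orientation = "horizontal",
                       cell = 8L, blend = 0.5, seed = 1L, id = NULL) {
  kind <- match.arg(kind)
  h <- size[1]; w <- size[2]
  if (kind %in% c("checkerboard", "blended_texture") && cell > min(h, w))
    stop("cell size exceeds image size")
  gray <- switch(kind,
    flat = matrix(value, h, w),
    linear_gradient = {
      if (orientation == "horizontal")
        matrix(rep(round(seq(0, 255, length.out = w)), each = h), h, w)
      else
        matrix(rep(round(seq(0, 255, length.out = h)), w), h, w)
    },
    checkerboard = {
      ri <- (seq_len(h) - 1L) %/% cell
      ci <- (seq_len(w) - 1L) %/% cell
      255 * outer(ri, ci, function(a, b) (a + b) %% 2L)
    },
    uniform_noise = with_seed(seed, matrix(sample(0:255, h * w, TRUE), h, w)),
    blended_texture = {
      cb <- (function() {
        ri <- (seq_len(h) - 1L) %/% cell
        ci <- (seq_len(w) - 1L) %/% cell
        255 * outer(ri, ci, function(a, b) (a + b) %% 2L)
      })()
      nz <- with_seed(seed, matrix(sample(0:255, h * w, TRUE), h, w))
      round(blend * cb + (1 - blend) * nz)
    })
  if (is.null(id))
    id <- sprintf("%s_%dx%d_s%d", kind, h, w, seed)
  stimulus_image(array(rep(gray, 3), c(h, w, 3)), id = id)
}

## Group sizes: rounded normal (mean, sd) truncated at 2, matching the
## reported moments of the correlated feature groups.
draw_group_sizes <- function(n_groups, mean, sd) {
  pmax(2L, as.integer(round(stats::rnorm(n_groups, mean, sd))))
}

#' Generate a synthetic feature table with correlated groups
#'
#' Emulates the structure of the complexity feature tables: `n_groups`
#' groups of correlated features (sizes drawn from a rounded normal,
#' truncated at 2), generated from a latent-factor model -- each feature is
#' `sqrt(rho) z_g + sqrt(1 - rho) e`, so the within-group correlation is
#' exactly `within_rho` in population and the implied covariance is PSD for
#' any group size. The response is a linear combination of the informative
#' groups' latents plus gaussian rater noise, affinely mapped to the 1-5
#' rating scale (clipped; optionally discretised by quantile binning).
#'
#' The default `noise_sd` is calibrated so that a split-half rater
#' simulation (two independent noisy raters of the same signal) has squared
#' correlation near 0.85, the agreement level real rating studies report;
#' see [split_half_agreement()].
#'
#' @param n_samples number of samples (stimuli).
#' @param n_groups number of correlated feature groups.
#' @param group_size_mean,group_size_sd moments of the group-size draw.
#' @param within_rho within-group population correlation in `[0, 1]`
#'   (default 0.95: real complexity-feature groups are near-duplicate
#'   metric variants with reported correlations up to ~0.98).
#' @param informative_groups how many groups drive the response.
#' @param effect_sizes per-informative-group weights (normalised so the
#'   signal has unit variance); default equal weights.
#' @param noise_sd rater-noise standard deviation relative to the
#'   unit-variance signal (default 0.2926, the split-half calibration).
#' @param rating_scale,rating_center affine map from the latent score to
#'   the 1-5 scale.
#' @param discretize quantile-bin ratings to integers 1..5.
#' @param seed RNG seed.
#' @return List with `X` (named matrix), `y` (ratings), `groups` (feature
#'   indices per group), `informative` (names of the planted informative
#'   features), `r2_signal` (signal variance fraction of `y`),
#'   `r2_achievable` (population R2 of the best linear predictor from `X`,
#'   the ceiling for recovery tests), and the recipe.
#' @export
make_feature_table <- function(n_samples = 800, n_groups = 48,
                               group_size_mean = 7.8, group_size_sd = 2.5,
                               within_rho = 0.95, informative_groups = 3,
                               effect_sizes = NULL, noise_sd = 0.2926,
                               rating_scale = 0.55, rating_center = 3,
                               discretize = FALSE, seed = 1L) {
  stopifnot(within_rho >= 0, within_rho <= 1, noise_sd >= 0,
            informative_groups <= n_groups)
  if (is.null(effect_sizes)) effect_sizes <- rep(1, informative_groups)
  stopifnot(length(effect_sizes) == informative_groups)
  w <- effect_sizes / sqrt(sum(effect_sizes^2))   # unit-variance signal

  out <- with_seed(seed, {
    sizes <- draw_group_sizes(n_groups, group_size_mean, group_size_sd)
    if (n_samples <= max(sizes))
      stop("n_samples must exceed the largest group size")
    Z <- matrix(stats::rnorm(n_samples * n_groups), n_samples, n_groups)
    X <- matrix(0, n_samples, sum(sizes))
    groups <- vector("list", n_groups)
    col <- 0L
    for (g in seq_len(n_groups)) {
      k <- sizes[g]
      E <- matrix(stats::rnorm(n_samples * k), n_samples, k)
      X[, col + seq_len(k)] <-
        sqrt(within_rho) * Z[, g] + sqrt(1 - within_rho) * E
      groups[[g]] <- col + seq_len(k)
      col <- col + k
    }
    signal <- drop(Z[, seq_len(informative_groups), drop = FALSE] %*% w)
    noise <- stats::rnorm(n_samples, sd = noise_sd)
    list(sizes = sizes, X = X, groups = groups, signal = signal,
         noise = noise)
  })
  sizes <- out$sizes
  colnames(out$X) <- unlist(lapply(seq_len(n_groups), function(g)
    sprintf("G%02d_F%d", g, seq_len(sizes[g]))))

  y_lat <- out$signal + out$noise
  y <- pmin(pmax(rating_center + rating_scale * y_lat, 1), 5)
  if (discretize)
    y <- as.numeric(cut(y, stats::quantile(y, seq(0, 1, 0.2)),
                        labels = FALSE, include.lowest = TRUE))

  ## Population ceilings. r2_signal: variance fraction of the true signal.
  ## r2_achievable: R2 of the best linear predictor of y from X, in closed
  ## form from the block factor covariance -- cov(X_g, y) = sqrt(rho) w_g
  ## per feature, and 1' Sigma_g^{-1} 1 = k / (1 + (k - 1) rho).
  var_y <- 1 + noise_sd^2
  r2_signal <- 1 / var_y
  expl <- sum(vapply(seq_len(informative_groups), function(g) {
    k <- sizes[g]
    within_rho * w[g]^2 * k / (1 + (k - 1) * within_rho)
  }, numeric(1)))
  r2_achievable <- if (within_rho == 0) 0 else expl / var_y

  informative <- unlist(lapply(seq_len(informative_groups),
                               function(g) colnames(out$X)[out$groups[[g]]]))
  list(X = out$X, y = y, groups = out$groups, informative = informative,
       r2_signal = r2_signal, r2_achievable = r2_achievable,
       recipe = list(n_samples = n_samples, n_groups = n_groups,
                     group_size_mean = group_size_mean,
                     group_size_sd = group_size_sd,
                     within_rho = within_rho,
                     informative_groups = informative_groups,
                     effect_sizes = effect_sizes, noise_sd = noise_sd,
                     rating_scale = rating_scale,
                     rating_center = rating_center,
                     discretize = discretize, seed = seed))
}

#' Split-half rater agreement of the synthetic rating model
#'
#' Simulates two independent rater groups scoring the same latent signal
#' with iid gaussian noise of `noise_sd`, and returns the squared Pearson
#' correlation of their mean ratings -- the split-half agreement that
#' calibrates the generator's noise level (population value
#' `(1 / (1 + noise_sd^2))^2`, about 0.85 at the default).
#'
#' @param n_samples stimuli count.
#' @param noise_sd rater-noise sd (see [make_feature_table()]).
#' @param seed RNG seed.
#' @return Squared correlation between the two half-panels.
#' @export
split_half_agreement <- function(n_samples = 800, noise_sd = 0.2926,
                                 seed = 1L) {
  with_seed(seed, {
    s <- stats::rnorm(n_samples)
    y1 <- s + stats::rnorm(n_samples, sd = noise_sd)
    y2 <- s + stats::rnorm(n_samples, sd = noise_sd)
    stats::cor(y1, y2)^2
  })
}

#' Generate an outlier-detection benchmark
#'
#' Draws a synthetic feature table and shifts the response of `k` randomly
#' chosen samples by `magnitude` times the rating-scale residual sd,
#' returning the planted ids for recovery scoring.
#'
#' @param recipe named list of [make_feature_table()] arguments.
#' @param k number of planted outliers (`< n/10`).
#' @param magnitude shift in residual-sd units.
#' @param seed RNG seed for the planting (the table uses the recipe's seed).
#' @return List with `X`, `y`, `planted` (ids), and the underlying `table`.
#' @export
make_outlier_bench <- function(recipe = list(), k = 6, magnitude = 6,
                               seed = 1L) {
  tab <- do.call(make_feature_table, recipe)
  n <- length(tab$y)
  stopifnot(k >= 0, k < n / 10)
  ids <- rownames(tab$X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k == 0)
    return(list(X = tab$X, y = tab$y, planted = character(0), table = tab))
  ## residual sd of the population regression of y on X, on the rating
  ## scale: rater noise plus the latent variance the features cannot reach
  resid_sd <- tab$recipe$rating_scale *
    sqrt((1 + tab$recipe$noise_sd^2) * (1 - tab$r2_achievable))
  planted <- with_seed(seed + 7919L, sort(sample(n, k)))
  y <- tab$y
  shift_sign <- with_seed(seed + 104729L, sample(c(-1, 1), k, TRUE))
  y[planted] <- y[planted] + shift_sign * magnitude * resid_sd
  list(X = tab$X, y = y, planted = ids[planted], table = tab)
}
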