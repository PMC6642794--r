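## Zipf's-law complexity metrics: slope (M) and goodness of fit (R2) of a
## log-log least-squares line through the intensity histogram of a plane,
## either rank-ordered (rank-frequency law) or ordered by intensity value
## (size-frequency law). 256 intensity bins match native 8-bit quantisation;
## fits use natural logarithms.

## Closed-form simple linear regression of y on x; returns slope and R2.
loglog_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx < .Machine$double.eps) return(c(M = 0, R2 = 0))
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  syy <- sum((y - my)^2)
  r2 <- if (syy < .Machine$double.eps) 1 else (sxy^2) / (sxx * syy)
  c(M = slope, R2 = r2)
}

plane_counts <- function(plane, bins) {
  v <- pmin(pmax(plane$values, 0), 1)
  idx <- pmin(floor(v * bins), bins - 1L)
  tabulate(as.integer(idx) + 1L, nbins = bins)
}

zipf_guard <- function(counts, what) {
  nz <- sum(counts > 0)
  if (nz < 3) {
    warning(sprintf("%s undefined: only %d nonzero intensity bins", what, nz))
    return(TRUE)
  }
  FALSE
}

#' Zipf rank-frequency metrics of a channel plane
#'
#' Quantises the plane into `bins` intensity bins, sorts the bin occupancy
#' counts in descending order, and fits `log(count) ~ log(rank)` over the
#' nonzero bins by least squares. `M` is the fitted slope (a pure power law
#' `count ~ rank^-1` gives `M = -1`) and `R2` the coefficient of
#' determination of the fit.
#'
#' @param plane a `channel_plane`.
#' @param bins number of intensity bins (default 256).
#' @return Named numeric vector `c(M, R2)`; `c(0, 0)` with a warning when
#'   fewer than 3 bins are occupied.
#' @export
zipf_rank_metrics <- function(plane, bins = 256L) {
  stopifnot(inherits(plane, "channel_plane"))
  counts <- plane_counts(plane, bins)
  if (zipf_guard(counts, "Zipf rank metrics")) return(c(M = 0, R2 = 0))
  cnt <- sort(counts[counts > 0], decreasing = TRUE)
  loglog_fit(log(seq_along(cnt)), log(cnt))
}

#' Zipf size-frequency metrics of a channel plane
#'
#' The same log-log fit as [zipf_rank_metrics()], but ordered by bin
#' intensity rather than by rank: `log(count) ~ log(bin value)` over nonzero
#' bins (bin value = upper bin edge on the 1..`bins` integer scale, so the
#' regressor is strictly positive).
#'
#' @inheritParams zipf_rank_metrics
#' @return Named numeric vector `c(M, R2)`; `c(0, 0)` with a warning when
#'   fewer than 3 bins are occupied.
#' @export
zipf_size_metrics <- function(plane, bins = 256L) {
  stopifnot(inherits(plane, "channel_plane"))
  counts <- plane_counts(plane, bins)
  if (zipf_guard(counts, "Zipf size metrics")) return(c(M = 0, R2 = 0))
  keep <- counts > 0
  loglog_fit(log(which(keep)), log(counts[keep]))
}

#' Mean and standard deviation of a channel plane
#'
#' The two basic pixel statistics: arithmetic mean and population standard
#' deviation (denominator `n`) of the plane values.
#'
#' @param plane a `channel_plane`.
#' @return Named numeric vector `c(mean, std)`.
#' @export
basic_stats <- function(plane) {
  stopifnot(inherits(plane, "channel_plane"))
  v <- plane$values
  m <- mean(v)
  c(mean = m, std = sqrt(mean((v - m)^2)))
}
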