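## Compression-error complexity metrics: lossy JPEG round-trip error and the
## reconstruction error of a quadtree PIFS (partitioned iterated function
## system) fractal coder. Both operate on [0,1] channel planes and return a
## root-mean-square per-pixel error on the [0,1] scale.

JPEG_QUALITY <- c(Low = 0.25, Medium = 0.50, High = 0.75)

#' JPEG compression error of a channel plane
#'
#' Encodes the plane as a lossy JPEG at the quality mapped from `level`
#' (Low/Medium/High -> quality 25/50/75), decodes it, and returns the
#' root-mean-square per-pixel difference. Higher error means the plane is
#' harder to compress, a classic visual-complexity proxy.
#'
#' @param plane a `channel_plane`.
#' @param level `"Low"`, `"Medium"` or `"High"` codec quality.
#' @param qualities named quality map overriding the default
#'   `c(Low = 0.25, Medium = 0.50, High = 0.75)` (on the codec's 0-1 scale).
#' @return Non-negative RMS error on the `[0, 1]` intensity scale.
#' @export
jpeg_error <- function(plane, level = c("Low", "Medium", "High"),
                       qualities = JPEG_QUALITY) {
  stopifnot(inherits(plane, "channel_plane"))
  level <- match.arg(level)
  m <- plane$values
  if (nrow(m) < 8 || ncol(m) < 8)
    stop("jpeg_error requires a plane of at least 8 x 8 pixels")
  raw <- tryCatch(jpeg::writeJPEG(m, raw(), quality = qualities[[level]]),
                  error = function(e)
                    stop("JPEG encode failed (quality ", qualities[[level]],
                         "): ", conditionMessage(e)))
  dec <- jpeg::readJPEG(raw)
  if (length(dim(dec)) == 3L) dec <- dec[, , 1]
  sqrt(mean((m - dec)^2))
}

## --- quadtree PIFS fractal coder -------------------------------------------

## Split tolerances (RMS, [0,1] scale): High = tight (deep quadtree, faithful
## reconstruction), Low = loose (coarse blocks, large error).
FRACTAL_TOL <- c(Low = 0.10, Medium = 0.05, High = 0.02)

## Pad a matrix to multiples of `block` by edge replication.
pad_to_multiple <- function(m, block) {
  nr <- ceiling(nrow(m) / block) * block
  nc <- ceiling(ncol(m) / block) * block
  m[pmin(seq_len(nr), nrow(m)), pmin(seq_len(nc), ncol(m)), drop = FALSE]
}

## 2x2 block-mean decimation.
decimate2 <- function(m) {
  nr <- nrow(m) %/% 2L
  nc <- ncol(m) %/% 2L
  (m[2 * seq_len(nr) - 1L, 2 * seq_len(nc) - 1L, drop = FALSE] +
   m[2 * seq_len(nr),      2 * seq_len(nc) - 1L, drop = FALSE] +
   m[2 * seq_len(nr) - 1L, 2 * seq_len(nc),      drop = FALSE] +
   m[2 * seq_len(nr),      2 * seq_len(nc),      drop = FALSE]) / 4
}

## Domain pool for range size `rs`: all (2*rs)x(2*rs) blocks on a grid with
## step `rs`, decimated to rs x rs. Returns positions and a (rs^2) x ndom
## matrix of decimated domain pixels.
domain_pool <- function(m, rs) {
  ds <- 2L * rs
  if (nrow(m) < ds || ncol(m) < ds) return(NULL)
  r0 <- seq(1L, nrow(m) - ds + 1L, by = rs)
  c0 <- seq(1L, ncol(m) - ds + 1L, by = rs)
  pos <- expand.grid(r = r0, c = c0)
  cols <- vapply(seq_len(nrow(pos)), function(i) {
    blk <- m[pos$r[i] + 0:(ds - 1L), pos$c[i] + 0:(ds - 1L)]
    as.vector(decimate2(blk))
  }, numeric(rs * rs))
  list(pos = pos, px = matrix(cols, nrow = rs * rs))
}

## Best affine fit s*D + o of each pooled domain to range vector `rv`;
## returns the single best (domain index, s, o, rms). `s` is clamped to
## [-s_max, s_max] so the decoder's intensity map is contractive.
best_domain_fit <- function(rv, pool, s_max = 0.9) {
  n <- length(rv)
  D <- pool$px
  dmean <- colMeans(D)
  Dc <- sweep(D, 2, dmean)
  rmean <- mean(rv)
  rc <- rv - rmean
  ssd <- colSums(Dc^2)
  cross <- as.vector(crossprod(Dc, rc))
  s <- ifelse(ssd > 0, cross / ssd, 0)
  s <- pmin(pmax(s, -s_max), s_max)
  sse <- sum(rc^2) - 2 * s * cross + s^2 * ssd
  sse <- pmax(sse, 0)
  best <- which.min(sse)
  s_b <- s[best]
  list(dom = best, s = s_b, o = rmean - s_b * dmean[best],
       rms = sqrt(sse[best] / n))
}

## Encode `m` as a quadtree PIFS: recursively split ranges (range_max down to
## range_min, halving) while the best collage RMS exceeds `tol`. Returns the
## list of leaf mappings.
fractal_encode <- function(m, tol, range_max = 16L, range_min = 4L,
                           s_max = 0.9) {
  pools <- list()
  rs <- range_max
  while (rs >= range_min) {
    pools[[as.character(rs)]] <- domain_pool(m, rs)
    rs <- rs %/% 2L
  }
  leaves <- list()
  code_block <- function(r0, c0, size) {
    pool <- pools[[as.character(size)]]
    fit <- if (is.null(pool)) NULL else {
      rv <- as.vector(m[r0 + 0:(size - 1L), c0 + 0:(size - 1L)])
      best_domain_fit(rv, pool, s_max)
    }
    must_split <- is.null(fit) || (fit$rms > tol && size > range_min)
    if (must_split && size > range_min) {
      h <- size %/% 2L
      for (dr in c(0L, h)) for (dc in c(0L, h))
        code_block(r0 + dr, c0 + dc, h)
    } else {
      if (is.null(fit)) stop("no domain pool at minimum range size")
      leaves[[length(leaves) + 1L]] <<- list(
        r = r0, c = c0, size = size,
        dom_r = pool$pos$r[fit$dom], dom_c = pool$pos$c[fit$dom],
        s = fit$s, o = fit$o, rms = fit$rms)
    }
  }
  for (r0 in seq(1L, nrow(m), by = range_max))
    for (c0 in seq(1L, ncol(m), by = range_max))
      code_block(r0, c0, range_max)
  leaves
}

## Iterate the coded maps from a flat image to (near) the attractor.
fractal_decode <- function(leaves, nr, nc, iterations = 12L) {
  img <- matrix(0.5, nr, nc)
  for (it in seq_len(iterations)) {
    nxt <- matrix(0, nr, nc)
    for (lf in leaves) {
      ds <- 2L * lf$size
      dom <- img[lf$dom_r + 0:(ds - 1L), lf$dom_c + 0:(ds - 1L)]
      nxt[lf$r + 0:(lf$size - 1L), lf$c + 0:(lf$size - 1L)] <-
        lf$s * decimate2(dom) + lf$o
    }
    img <- pmin(pmax(nxt, 0), 1)
  }
  img
}

#' Fractal compression error of a channel plane
#'
#' Codes the plane with a quadtree PIFS fractal coder (range blocks
#' `range_max` down to `range_min` pixels, domain blocks twice the range
#' size, affine intensity map `s * D + o` with `|s|` clamped below 1) and
#' returns the RMS error between the plane and the decoded attractor. The
#' `level` selects the split-tolerance schedule: `High` splits aggressively
#' (tight tolerance, faithful reconstruction), `Low` tolerates coarse blocks.
#'
#' @param plane a `channel_plane`.
#' @param level `"Low"`, `"Medium"` or `"High"` fidelity schedule.
#' @param tolerances named RMS split-tolerance map overriding
#'   `c(Low = 0.10, Medium = 0.05, High = 0.02)`.
#' @param range_max,range_min largest/smallest range-block size (powers of 2).
#' @param iterations decoder iterations.
#' @return Non-negative RMS reconstruction error on the `[0, 1]` scale.
#' @export
fractal_error <- function(plane, level = c("Low", "Medium", "High"),
                          tolerances = FRACTAL_TOL,
                          range_max = 16L, range_min = 4L, iterations = 12L) {
  stopifnot(inherits(plane, "channel_plane"))
  level <- match.arg(level)
  m <- pad_to_multiple(plane$values, range_max)
  leaves <- fractal_encode(m, tolerances[[level]], range_max, range_min)
  dec <- fractal_decode(leaves, nrow(m), ncol(m), iterations)
  orig <- plane$values
  sqrt(mean((orig - dec[seq_len(nrow(orig)), seq_len(ncol(orig))])^2))
}
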