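## Edge-filter preprocessing: Sobel gradient magnitude and a classic Canny
## detector (gaussian blur, Sobel gradients, non-maximum suppression,
## percentile hysteresis). Directional variants respond to edges of one
## orientation: `*_v` keeps only the horizontal derivative (vertical edges),
## `*_h` only the vertical derivative (horizontal edges).

EDGE_FILTER_KINDS <- c("none", "canny_all", "canny_h", "canny_v",
                       "sobel_all", "sobel_h", "sobel_v")

#' Edge filter specification
#'
#' @param kind one of `"none"`, `"canny_all"`, `"canny_h"`, `"canny_v"`,
#'   `"sobel_all"`, `"sobel_h"`, `"sobel_v"`.
#' @param canny_sigma gaussian smoothing sigma (pixels) used by Canny.
#' @param canny_low,canny_high hysteresis thresholds, expressed as quantiles
#'   in `[0, 1]` of the positive gradient magnitudes.
#' @return An `edge_filter_spec` object.
#' @export
edge_filter_spec <- function(kind, canny_sigma = 1.0,
                             canny_low = 0.70, canny_high = 0.90) {
  kind <- match.arg(kind, EDGE_FILTER_KINDS)
  stopifnot(canny_sigma > 0, canny_low < canny_high,
            canny_low >= 0, canny_high <= 1)
  structure(list(kind = kind, canny_sigma = canny_sigma,
                 canny_low = canny_low, canny_high = canny_high),
            class = "edge_filter_spec")
}

## Replicate-padding 2-D convolution with a small kernel (odd dims).
conv2_replicate <- function(m, k) {
  kr <- (nrow(k) - 1L) / 2L
  kc <- (ncol(k) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr + 2L * kr) - kr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * kc) - kc, 1L), nc)
  mp <- m[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(k)))
    for (j in seq_len(ncol(k)))
      out <- out + k[i, j] * mp[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

## Sobel derivatives: gx = d/dx (across columns), gy = d/dy (across rows).
sobel_gradients <- function(m) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  list(gx = conv2_replicate(m, sx), gy = conv2_replicate(m, t(sx)))
}

#' Apply an edge filter to a channel plane
#'
#' Canny variants return a binary plane (values in \{0, 1\}); Sobel variants
#' return gradient magnitude rescaled to `[0, 1]`. A constant plane yields an
#' all-zero plane without error.
#'
#' @param plane a `channel_plane` (from [rgb_to_hsv_planes()]).
#' @param spec an [edge_filter_spec()] with `kind != "none"`.
#' @return A `channel_plane` of the same dimensions.
#' @export
apply_edge_filter <- function(plane, spec) {
  stopifnot(inherits(plane, "channel_plane"), inherits(spec, "edge_filter_spec"))
  if (spec$kind == "none")
    stop("apply_edge_filter requires spec$kind != 'none'")
  m <- plane$values
  if (startsWith(spec$kind, "sobel")) {
    g <- sobel_gradients(m)
    mag <- switch(spec$kind,
      sobel_all = sqrt(g$gx^2 + g$gy^2),
      sobel_v   = abs(g$gx),   # vertical edges: horizontal derivative
      sobel_h   = abs(g$gy))
    mx <- max(mag)
    out <- if (mx > 0) mag / mx else mag
    return(channel_plane(out, plane$channel))
  }
  channel_plane(canny_binary(m, spec), plane$channel)
}

canny_binary <- function(m, spec) {
  sm <- conv2_replicate(m, gaussian_kernel(spec$canny_sigma))
  g <- sobel_gradients(sm)
  gx <- g$gx; gy <- g$gy
  if (spec$kind == "canny_v") gy <- gy * 0
  if (spec$kind == "canny_h") gx <- gx * 0
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) <= 0) return(matrix(0, nrow(m), ncol(m)))

  ## Non-maximum suppression with 4-way direction quantisation. Ties along
  ## the gradient direction are broken asymmetrically (strict on the
  ## negative side) so a symmetric step edge thins to one pixel.
  nr <- nrow(m); nc <- ncol(m)
  ang <- atan2(gy, gx)                      # (-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)    # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  shift <- function(mm, dr, dc) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    mm[ri, ci, drop = FALSE]
  }
  ## gx is the column-direction derivative, gy the row-direction one, so
  ## sector 0 (gradient along x) compares across columns, sector 2 across rows.
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  keep <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    d <- offs[[as.character(s)]]
    fwd <- shift(mag, d[1], d[2])
    bwd <- shift(mag, -d[1], -d[2])
    keep <- keep | (sector == s & mag >= fwd & mag > bwd)
  }
  nms <- mag * keep

  ## hysteresis thresholds: quantiles of the full gradient-magnitude image
  ## (interior pixels anchor the low end), applied to the thinned ridge
  lo <- stats::quantile(mag, spec$canny_low, names = FALSE)
  hi <- stats::quantile(mag, spec$canny_high, names = FALSE)
  if (hi <= 0) return(matrix(0, nr, nc))
  strong <- nms >= hi & nms > 0
  weak <- nms >= lo & nms > 0
  if (!any(strong)) return(matrix(0, nr, nc))

  ## Hysteresis: grow strong seeds through the weak mask (8-connectivity)
  ## by iterated dilation to a fixed point.
  cur <- strong
  repeat {
    dil <- cur
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) dil <- dil | shift(cur, dr, dc)
    nxt <- dil & weak
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur * 1
}

#' Edge density of a binary edge plane
#'
#' The fraction of pixels marked as edges: the percentage of the image that
#' corresponds to edges, on a `[0, 1]` scale.
#'
#' @param plane a binary `channel_plane` (output of a Canny variant of
#'   [apply_edge_filter()]).
#' @return A real in `[0, 1]`.
#' @export
edge_density <- function(plane) {
  stopifnot(inherits(plane, "channel_plane"))
  v <- plane$values
  if (!all(v %in% c(0, 1)))
    stop("edge_density requires a binary plane (Canny output)")
  sum(v) / length(v)
}
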