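## The feature registry: the canonical grid of (family x filter x channel x
## output) combinations, their rendered names, and the metric parameters.
## Names follow the established terminology of the complexity-metrics
## literature, e.g. "JPEG(Canny(S),High)" or "Rank(NoFilter(S),R2)".

FEATURE_FAMILIES <- c("JPEG", "Fractal", "Size", "Rank",
                      "EdgeDensity", "Mean", "StdDev")

FILTER_LABELS <- c(none = "NoFilter", canny_all = "Canny",
                   canny_h = "Canny_horizontal", canny_v = "Canny_vertical",
                   sobel_all = "Sobel", sobel_h = "Sobel_horizontal",
                   sobel_v = "Sobel_vertical")

family_outputs <- function(family) {
  switch(family,
    JPEG = , Fractal = c("Low", "Medium", "High"),
    Size = , Rank = c("M", "R2"),
    EdgeDensity = , Mean = , StdDev = NA_character_)
}

#' Render a feature key in the canonical naming dialect
#'
#' @param family metric family (`"JPEG"`, `"Fractal"`, `"Size"`, `"Rank"`,
#'   `"EdgeDensity"`, `"Mean"`, `"StdDev"`).
#' @param filter edge-filter kind (see [edge_filter_spec()]).
#' @param channel channel tag (`"H"`, `"S"`, `"V"` or `"H+CS"`).
#' @param output metric output tag (`"Low"`, `"Medium"`, `"High"`, `"M"`,
#'   `"R2"`) or `NA` for single-output families.
#' @return The canonical name string, e.g. `"JPEG(Canny(S),High)"`.
#' @export
feature_key <- function(family, filter, channel, output = NA) {
  family <- match.arg(family, FEATURE_FAMILIES)
  filt <- FILTER_LABELS[[match.arg(filter, names(FILTER_LABELS))]]
  inner <- sprintf("%s(%s)", filt, channel)
  if (is.na(output)) sprintf("%s(%s)", family, inner)
  else sprintf("%s(%s,%s)", family, inner, output)
}

#' Build a feature registry
#'
#' Enumerates every applicable (family, filter, channel, output) combination
#' and fixes the metric parameters, giving extraction a stable, named,
#' ordered feature grid. Edge density is only defined for binary Canny
#' planes, compression families take Low/Medium/High outputs, and the Zipf
#' families take M/R2 outputs. The exact grid is configurable; the default
#' covers every name used by the feature taxonomy, including the documented
#' composite channel `"H+CS"` (mean of hue and contrast-stretched
#' saturation).
#'
#' @param families metric families to include.
#' @param filters edge-filter kinds to include.
#' @param channels channel tags among `"H"`, `"S"`, `"V"`, `"H+CS"`.
#' @param bins Zipf histogram bins.
#' @param jpeg_qualities,fractal_tolerances level maps for the compression
#'   families.
#' @param canny_sigma,canny_low,canny_high Canny parameters (sigma in
#'   pixels; hysteresis thresholds as gradient-magnitude quantiles).
#' @return A `feature_registry` object; its `grid` element has one row per
#'   feature with the canonical `name`.
#' @export
feature_registry <- function(families = FEATURE_FAMILIES,
                             filters = names(FILTER_LABELS),
                             channels = c("H", "S", "V", "H+CS"),
                             bins = 256L,
                             jpeg_qualities = JPEG_QUALITY,
                             fractal_tolerances = FRACTAL_TOL,
                             canny_sigma = 1.0, canny_low = 0.70,
                             canny_high = 0.90) {
  families <- match.arg(families, FEATURE_FAMILIES, several.ok = TRUE)
  filters <- match.arg(filters, names(FILTER_LABELS), several.ok = TRUE)
  stopifnot(all(channels %in% c("H", "S", "V", "H+CS")))
  rows <- list()
  for (fam in families) {
    filts <- if (fam == "EdgeDensity")
      intersect(filters, c("canny_all", "canny_h", "canny_v")) else filters
    for (fl in filts) for (ch in channels) for (out in family_outputs(fam))
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, filter = fl, channel = ch, output = out,
        name = feature_key(fam, fl, ch, out), stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  structure(list(
    grid = grid,
    params = list(bins = bins, jpeg_qualities = jpeg_qualities,
                  fractal_tolerances = fractal_tolerances,
                  canny_sigma = canny_sigma, canny_low = canny_low,
                  canny_high = canny_high),
    version = "registry-1"), class = "feature_registry")
}

#' @export
print.feature_registry <- function(x, ...) {
  cat(sprintf("<feature_registry %s: %d features (%s)>\n", x$version,
              nrow(x$grid),
              paste(unique(x$grid$family), collapse = ", ")))
  invisible(x)
}

#' @export
length.feature_registry <- function(x) nrow(x$grid)

#' Write / read a feature registry as JSON
#'
#' @param registry a [feature_registry()].
#' @param path JSON file path.
#' @return `write_feature_registry` returns `path` invisibly;
#'   `read_feature_registry` returns the registry.
#' @export
write_feature_registry <- function(registry, path) {
  stopifnot(inherits(registry, "feature_registry"))
  jsonlite::write_json(
    list(grid = registry$grid, params = registry$params,
         version = registry$version),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_registry
#' @export
read_feature_registry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- feature_registry()
  reg$grid <- as.data.frame(obj$grid, stringsAsFactors = FALSE)
  reg$grid$output <- as.character(reg$grid$output)
  reg$grid$output[reg$grid$output %in% c("NA", "")] <- NA_character_
  p <- obj$params
  reg$params <- list(
    bins = as.integer(p$bins),
    jpeg_qualities = unlist(p$jpeg_qualities),
    fractal_tolerances = unlist(p$fractal_tolerances),
    canny_sigma = p$canny_sigma, canny_low = p$canny_low,
    canny_high = p$canny_high)
  reg$version <- obj$version
  reg
}

#' Extract the complexity feature vector of an image
#'
#' Computes every feature in the registry grid: the image is decomposed into
#' HSV planes (plus the composite `"H+CS"` plane where requested), each
#' plane is optionally edge-filtered, and the family metric is evaluated on
#' the result. Degenerate planes produce the documented sentinel values
#' (e.g. Zipf metrics `(0, 0)`) rather than missing entries, so the vector
#' is always complete and extraction is a pure function of the pixels and
#' the registry.
#'
#' @param img a [stimulus_image()].
#' @param registry a [feature_registry()]; defaults to the full grid.
#' @return Named numeric vector, one finite entry per registry row, in
#'   registry order, with attribute `registry_version`.
#' @export
extract_features <- function(img, registry = feature_registry()) {
  stopifnot(inherits(img, "stimulus_image"),
            inherits(registry, "feature_registry"))
  p <- registry$params
  planes <- rgb_to_hsv_planes(img)
  planes[["H+CS"]] <- composite_hcs_plane(planes)

  filtered <- new.env(parent = emptyenv())
  get_plane <- function(filter, channel) {
    key <- paste(filter, channel, sep = "|")
    if (!is.null(filtered[[key]])) return(filtered[[key]])
    pl <- if (filter == "none") planes[[channel]]
    else apply_edge_filter(planes[[channel]],
                           edge_filter_spec(filter, p$canny_sigma,
                                            p$canny_low, p$canny_high))
    filtered[[key]] <- pl
    pl
  }

  fractal_cache <- new.env(parent = emptyenv())
  grid <- registry$grid
  vals <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fam <- grid$family[i]
    pl <- get_plane(grid$filter[i], grid$channel[i])
    out <- grid$output[i]
    vals[i] <- switch(fam,
      JPEG = jpeg_error(pl, out, p$jpeg_qualities),
      Fractal = {
        key <- paste(grid$filter[i], grid$channel[i], out, sep = "|")
        if (is.null(fractal_cache[[key]]))
          fractal_cache[[key]] <-
            fractal_error(pl, out, p$fractal_tolerances)
        fractal_cache[[key]]
      },
      Size = suppressWarnings(zipf_size_metrics(pl, p$bins)[[out]]),
      Rank = suppressWarnings(zipf_rank_metrics(pl, p$bins)[[out]]),
      EdgeDensity = edge_density(pl),
      Mean = basic_stats(pl)[["mean"]],
      StdDev = basic_stats(pl)[["std"]])
  }
  structure(stats::setNames(vals, grid$name),
            registry_version = registry$version)
}

#' Extract features for a set of images into a table
#'
#' @param imgs list of [stimulus_image()] objects.
#' @param registry a [feature_registry()].
#' @return A data.frame with first column `id` and one column per registry
#'   feature (canonical names preserved via `check.names = FALSE`).
#' @export
extract_features_batch <- function(imgs, registry = feature_registry()) {
  rows <- lapply(imgs, function(im) extract_features(im, registry))
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  data.frame(id = vapply(imgs, function(im) im$id, character(1)), out,
             check.names = FALSE, stringsAsFactors = FALSE)
}
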