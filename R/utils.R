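## Small shared utilities.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state:
## keeps the synthetic generators pure functions of their recipe.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Euclidean projection of `v` onto the probability simplex
## {d : d >= 0, sum(d) = 1} (sort-and-threshold).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

## Coerce feature input to a plain numeric matrix with column names.
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("feature table must be a numeric matrix or data.frame")
  cn <- colnames(x)
  if (is.null(cn)) cn <- character(ncol(x))
  blank <- is.na(cn) | cn == ""
  cn[blank] <- sprintf("V%03d", which(blank))
  colnames(x) <- cn
  x
}
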