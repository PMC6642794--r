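test_that("HSV decomposition matches the colour model and round-trips", {
  red <- stimulus_image(array(rep(c(255, 0, 0), each = 64), c(8, 8, 3)))
  pl <- rgb_to_hsv_planes(red)
  expect_true(all(pl$S$values == 1))
  expect_true(all(pl$V$values == 1))

  gray <- stimulus_image(array(128, c(8, 8, 3)))
  expect_true(all(rgb_to_hsv_planes(gray)$S$values == 0))

  img <- make_image("uniform_noise", c(16, 16), seed = 4)
  pl <- rgb_to_hsv_planes(img)
  ## independent inverse conversion via grDevices::hsv + col2rgb
  back <- grDevices::col2rgb(grDevices::hsv(pl$H$values, pl$S$values,
                                            pl$V$values))
  expect_lt(max(abs(back[1, ] - as.vector(img$pixels[, , 1]))), 1.0001)
  expect_lt(max(abs(back[2, ] - as.vector(img$pixels[, , 2]))), 1.0001)
  expect_lt(max(abs(back[3, ] - as.vector(img$pixels[, , 3]))), 1.0001)

  expect_error(stimulus_image(array(0, c(8, 8, 2))), "3")
})

test_that("edge filters honour orientation and degenerate inputs", {
  const <- channel_plane(matrix(0.5, 16, 16))
  for (k in c("canny_all", "sobel_all", "canny_v", "sobel_h")) {
    out <- apply_edge_filter(const, edge_filter_spec(k))
    expect_true(all(out$values == 0), info = k)
  }

  ## vertical step edge: canny thins it to a single one-pixel column
  step <- channel_plane(cbind(matrix(0, 8, 4), matrix(1, 8, 4)))
  e <- apply_edge_filter(step, edge_filter_spec("canny_all"))
  expect_true(all(e$values %in% c(0, 1)))
  on_cols <- which(colSums(e$values) > 0)
  expect_length(on_cols, 1)
  expect_equal(sum(e$values), 8)  # the full column, hand-counted

  ## horizontal stripes have no vertical edges
  stripes <- channel_plane(matrix(rep(c(0, 1), each = 8), 16, 16))
  sv <- apply_edge_filter(stripes, edge_filter_spec("sobel_v"))
  expect_true(all(sv$values == 0))
  sh <- apply_edge_filter(stripes, edge_filter_spec("sobel_h"))
  expect_gt(max(sh$values), 0)
})

test_that("edge density counts edge pixels and rejects non-binary planes", {
  expect_equal(edge_density(channel_plane(matrix(0, 8, 8))), 0)
  expect_equal(edge_density(channel_plane(matrix(1, 8, 8))), 1)
  m <- matrix(0, 8, 8); m[1:4, 1:4] <- 1
  expect_equal(edge_density(channel_plane(m)), 0.25)
  expect_error(edge_density(channel_plane(matrix(0.5, 8, 8))), "binary")
})

test_that("edge density is invariant under seamless tiling", {
  ## centred square on a constant background: the 2x2 tiling seam carries
  ## no contrast, so edge density is intensive
  gray <- matrix(0, 32, 32)
  gray[13:20, 13:20] <- 1
  px <- array(rep(255 * gray, 3), c(32, 32, 3))
  img <- stimulus_image(px, "square")
  tiled <- stimulus_image(px[rep(1:32, 2), rep(1:32, 2), ], "square4")
  d1 <- edge_density(apply_edge_filter(rgb_to_hsv_planes(img)$V,
                                       edge_filter_spec("canny_all")))
  d2 <- edge_density(apply_edge_filter(rgb_to_hsv_planes(tiled)$V,
                                       edge_filter_spec("canny_all")))
  expect_gt(d1, 0)
  expect_lte(abs(d1 - d2), 2 / (32 * 32) + 1e-12)
})

test_that("jpeg error is near zero on flat fields and codec-consistent", {
  flat <- channel_plane(matrix(0.5, 32, 32))
  expect_lte(jpeg_error(flat, "Low"), 1 / 255)
  expect_lte(jpeg_error(flat, "High"), 1 / 255)

  pl <- noise_plane(11, 64)
  expect_gte(jpeg_error(pl, "Low"), jpeg_error(pl, "High"))

  ## independent codec round trip at the mapped quality
  tmp <- tempfile(fileext = ".jpg")
  jpeg::writeJPEG(pl$values, tmp, quality = 0.5)
  dec <- jpeg::readJPEG(tmp)
  expect_equal(jpeg_error(pl, "Medium"), sqrt(mean((pl$values - dec)^2)),
               tolerance = 1e-12)
  expect_error(jpeg_error(channel_plane(matrix(0.5, 4, 4))), "8 x 8")
})

test_that("fractal error vanishes on flat planes and matches the brute-force
           PIFS oracle at a fixed block size", {
  flat <- channel_plane(matrix(0.25, 32, 32))
  expect_lt(fractal_error(flat, "Low"), 1e-6)

  pl <- noise_plane(3, 32)
  mine <- fractal_error(pl, "High", range_max = 8L, range_min = 8L)
  oracle <- pifs_oracle_error(pl$values, block = 8L)
  expect_equal(mine, oracle, tolerance = 1e-12)
})

test_that("compression errors are monotone in the fidelity level", {
  for (s in 1:20) {
    pl <- noise_plane(100 + s, 32)
    expect_gte(jpeg_error(pl, "Low") + 1e-12, jpeg_error(pl, "High"))
    expect_gte(fractal_error(pl, "Low") + 1e-9, fractal_error(pl, "High"))
  }
})

test_that("Zipf fits recover exact power laws and match the regression
           oracle on noise", {
  ## rank-frequency: counts proportional to rank^-1
  counts <- round(10000 / (1:40))
  vals <- rep((seq_len(40) - 0.5) / 256, counts)   # 40 distinct bins
  pl <- channel_plane(matrix(vals[1:1024], 32, 32))
  ## construct the plane from the full multiset to keep exact proportions
  n2 <- ceiling(sqrt(length(vals)))
  padded <- c(vals, rep(vals[1], n2^2 - length(vals)))
  pl <- channel_plane(matrix(sort(padded), n2, n2))
  z <- zipf_rank_metrics(pl)
  expect_equal(unname(z["M"]), -1.0, tolerance = 0.05)
  expect_gt(z["R2"], 0.99)

  ## size-frequency: counts proportional to value^-2
  v_idx <- 10:49
  counts2 <- round(20000 / v_idx^2)
  vals2 <- rep((v_idx - 0.5) / 256, counts2)
  n3 <- ceiling(sqrt(length(vals2)))
  padded2 <- c(vals2, rep(vals2[1], n3^2 - length(vals2)))
  z2 <- zipf_size_metrics(channel_plane(matrix(padded2, n3, n3)))
  expect_equal(unname(z2["M"]), -2.0, tolerance = 0.05)
  expect_gt(z2["R2"], 0.99)

  ## degenerate: constant plane
  expect_warning(z0 <- zipf_rank_metrics(channel_plane(matrix(0.5, 8, 8))),
                 "nonzero")
  expect_equal(unname(z0), c(0, 0))

  ## closed-form fit equals stats::lm on the identical log points
  for (s in 1:5) {
    pl <- noise_plane(200 + s, 24)
    cnt <- sort(tabulate(floor(pl$values * 256) + 1, 256), decreasing = TRUE)
    cnt <- cnt[cnt > 0]
    o <- lm_slope_r2(log(seq_along(cnt)), log(cnt))
    z <- zipf_rank_metrics(pl)
    expect_equal(unname(z["M"]), unname(o["M"]), tolerance = 1e-10)
    expect_equal(unname(z["R2"]), unname(o["R2"]), tolerance = 1e-10)
  }
})

test_that("basic stats are exact on constructed planes", {
  expect_equal(basic_stats(channel_plane(matrix(0.3, 8, 8))),
               c(mean = 0.3, std = 0))
  half <- channel_plane(matrix(rep(c(0, 1), 32), 8, 8))
  expect_equal(basic_stats(half), c(mean = 0.5, std = 0.5))
  pl <- noise_plane(7, 16)
  v <- pl$values
  expect_equal(unname(basic_stats(pl)["std"]),
               sqrt(sum((v - mean(v))^2) / length(v)), tolerance = 1e-12)
})

test_that("feature extraction is complete, deterministic and renders the
           canonical naming dialect", {
  reg <- feature_registry(filters = c("none", "canny_all"),
                          channels = c("S", "V"))
  img <- make_image("blended_texture", c(32, 32), cell = 8, seed = 9)
  fv <- extract_features(img, reg)
  expect_length(fv, nrow(reg$grid))
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), reg$grid$name)

  fv2 <- extract_features(make_image("blended_texture", c(32, 32),
                                     cell = 8, seed = 9), reg)
  expect_identical(fv, fv2)

  ## flat gray image: compression errors ~0, edge density exactly 0
  flat <- make_image("flat", c(32, 32), value = 128)
  fvf <- extract_features(flat, reg)
  expect_lt(max(fvf[reg$grid$family %in% c("JPEG", "Fractal")]), 1 / 255)
  expect_equal(unname(fvf[reg$grid$family == "EdgeDensity"]),
               rep(0, sum(reg$grid$family == "EdgeDensity")))

  ## the full default grid covers the published dialect
  full <- feature_registry()
  expect_true(all(c("JPEG(Canny(S),High)", "Rank(NoFilter(S),R2)",
                    "Fractal(NoFilter(V),Medium)", "Size(Canny(V),M)",
                    "Size(NoFilter(H+CS),R2)", "EdgeDensity(Canny(S))",
                    "Mean(NoFilter(V))") %in% full$grid$name))

  ## registry JSON round trip
  tmp <- tempfile(fileext = ".json")
  write_feature_registry(full, tmp)
  back <- read_feature_registry(tmp)
  expect_equal(back$grid$name, full$grid$name)
  expect_equal(back$params$bins, full$params$bins)
})
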