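# Preprocessing: every operation is pinned either to a closed-form value or
# to an independent brute-force oracle.

# direct weight-sum bilinear oracle, independent of the vectorized path
naive_bilinear <- function(img, h0, w0) {
  d <- dim(img)
  out <- array(0, c(h0, w0, d[3]))
  for (i in seq_len(h0)) {
    for (j in seq_len(w0)) {
      sy <- (i - 0.5) * d[1] / h0 - 0.5
      sx <- (j - 0.5) * d[2] / w0 - 0.5
      y0 <- min(max(floor(sy), 0), d[1] - 1); y1 <- min(max(floor(sy) + 1, 0), d[1] - 1)
      x0 <- min(max(floor(sx), 0), d[2] - 1); x1 <- min(max(floor(sx) + 1, 0), d[2] - 1)
      wy <- sy - floor(sy); wx <- sx - floor(sx)
      for (ch in seq_len(d[3])) {
        out[i, j, ch] <-
          (1 - wy) * ((1 - wx) * img[y0 + 1, x0 + 1, ch] + wx * img[y0 + 1, x1 + 1, ch]) +
          wy * ((1 - wx) * img[y1 + 1, x0 + 1, ch] + wx * img[y1 + 1, x1 + 1, ch])
      }
    }
  }
  out
}

test_that("resize matches the direct bilinear oracle and fixes the convention", {
  set.seed(42)
  for (case in list(c(7, 5, 12, 9), c(10, 10, 4, 4), c(3, 8, 8, 3))) {
    img <- array(runif(case[1] * case[2] * 3), c(case[1], case[2], 3))
    expect_equal(resize_image(img, case[3], case[4]),
                 naive_bilinear(img, case[3], case[4]), tolerance = 1e-12)
  }
  # half-pixel-centred upsampling of a 2-pixel ramp: interior samples fall
  # at 0.25 / 0.75 between the two source pixels
  ramp <- array(rep(c(0, 0, 1, 1), 3), c(2, 2, 3))  # columns 0 and 1
  up <- resize_image(ramp, 2, 4)
  expect_equal(up[1, , 1], c(0, 0.25, 0.75, 1), tolerance = 1e-12)
  # collapsing the row axis of the same image averages rows; columns keep
  # their values (frozen from the weight-sum oracle)
  down <- resize_image(ramp, 1, 2)
  expect_equal(as.vector(down[1, , 1]), c(0, 1), tolerance = 1e-12)
  expect_equal(down, naive_bilinear(ramp, 1, 2), tolerance = 1e-12)
})

test_that("identity-parameter augmentations are exact no-ops", {
  set.seed(7)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(resize_image(img, 16, 16), img)
  expect_equal(crop_and_rescale(img, 0, 0, 16, 16), img, tolerance = 1e-12)
  expect_identical(random_scale_perturbation(img, 1, 1), img)
  const <- array(0.42, c(10, 10, 3))
  expect_equal(resize_image(const, 5, 17), array(0.42, c(5, 17, 3)),
               tolerance = 1e-12)
})

test_that("crop magnifies target pixel fractions as expected", {
  cfg <- desk_synth_config(seed = 3, target_scale_range = c(0.01, 0.02))
  # find a rendering whose targets fit a quarter-frame window around them
  found <- FALSE
  for (seed in 1:25) {
    img <- render_image(1, "sparse", cfg, seed = seed)
    mask <- attr(img, "mask")
    if (!any(mask)) next
    cy <- round(mean(which(mask, arr.ind = TRUE)[, 1]))
    cx <- round(mean(which(mask, arr.ind = TRUE)[, 2]))
    y <- min(max(cy - 4, 0), 8); x <- min(max(cx - 4, 0), 8)
    sub <- mask[(y + 1):(y + 8), (x + 1):(x + 8)]
    if (sum(sub) == sum(mask)) { found <- TRUE; break }
  }
  expect_true(found)
  m3 <- array(mask, c(16, 16, 3)) * 1
  out <- crop_and_rescale(m3, x, y, 8, 8)
  frac_before <- mean(mask)
  frac_after <- mean(out[, , 1] > 0.5)
  expect_gt(frac_after, 2.5 * frac_before)
  expect_lt(frac_after, 6 * frac_before)
  expect_error(crop_and_rescale(m3, 12, 0, 8, 8), "outside")
})

test_that("scale perturbation follows its uniform law and area scaling", {
  set.seed(11)
  a <- replicate(1e4, runif(1, 0.8, 1.2))
  expect_gt(mean(a), 0.99); expect_lt(mean(a), 1.01)
  # a centred disc doubled in scale quadruples its pixel area
  img <- array(0, c(40, 40, 3))
  xs <- matrix(rep(1:40, each = 40), 40, 40)
  ys <- t(xs)
  disc <- (xs - 20.5)^2 + (ys - 20.5)^2 <= 25
  img[, , 1] <- disc
  out <- random_scale_perturbation(img, 2, 2)
  ratio <- sum(out[, , 1] > 0.5) / sum(disc)
  expect_gt(ratio, 3.4); expect_lt(ratio, 4.6)
})

test_that("sigma-rule outlier detection matches a brute-force oracle", {
  # worked example: population stats of [10,10,10,10,100] are mu=28,
  # sigma=36; only the excursion exceeds 1 sigma
  s <- data.frame(timestamp = (0:4) * 600, temperature_c = c(10, 10, 10, 10, 100))
  m <- detect_outliers(s, lambda = 1)
  expect_identical(as.vector(m[, 1]), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  mu <- mean(s$temperature_c); sg <- sqrt(mean((s$temperature_c - mu)^2))
  expect_equal(mu, 28); expect_equal(sg, 36)
  # huge lambda: empty mask
  expect_false(any(detect_outliers(s, lambda = 1e9)))
  # randomized series against an independent re-computation
  for (seed in 1:5) {
    ser <- random_series(80, missing = 6, seed = seed)
    got <- detect_outliers(ser, lambda = 1.5)
    for (ch in c("temperature_c", "humidity_rh", "illumination_lux")) {
      v <- ser[[ch]]; obs <- !is.na(v)
      mu <- mean(v[obs]); sg <- sqrt(sum((v[obs] - mu)^2) / sum(obs))
      ref <- !is.na(v) & abs(v - mu) > 1.5 * sg
      expect_identical(as.vector(got[, ch]), ref)
    }
  }
  # constant channel: no flags, warning
  cs <- data.frame(timestamp = (0:3) * 600, temperature_c = rep(5, 4))
  expect_warning(mc <- detect_outliers(cs, lambda = 2), "constant")
  expect_false(any(mc))
})

test_that("linear interpolation fills gaps exactly and is identity when complete", {
  s <- data.frame(timestamp = c(0, 10, 20), temperature_c = c(0, NA, 20))
  expect_equal(interpolate_missing(s)$temperature_c, c(0, 10, 20))
  full <- random_series(30, missing = 0, seed = 2)
  expect_identical(interpolate_missing(full), full)
  # random gaps in a linear ramp reconstruct exactly
  set.seed(3)
  ramp <- data.frame(timestamp = seq(0, 290, by = 10),
                     temperature_c = seq(5, by = 0.7, length.out = 30))
  truth <- ramp$temperature_c
  ramp$temperature_c[sample(2:29, 10)] <- NA
  expect_equal(interpolate_missing(ramp)$temperature_c, truth, tolerance = 1e-12)
  # boundary gaps take the nearest observed value
  bd <- data.frame(timestamp = c(0, 10, 20), humidity_rh = c(NA, 50, NA))
  expect_equal(interpolate_missing(bd)$humidity_rh, c(50, 50, 50))
  allna <- data.frame(timestamp = c(0, 10), humidity_rh = c(NA_real_, NA))
  expect_error(interpolate_missing(allna), "no observed values")
})

test_that("nearest-timestamp alignment matches brute force and breaks ties early", {
  rec <- data.frame(timestamp = c(36000, 36600),   # 10:00 and 10:10
                    temperature_c = c(1, 2), humidity_rh = c(3, 4),
                    illumination_lux = c(5, 6))
  v <- align_sensor_to_image(36420, rec, delta_t = 420)  # 10:07
  expect_equal(unname(v["temperature_c"]), 2)            # 10:10 is nearer
  expect_equal(attr(v, "timestamp"), 36600)
  # exact hit
  v2 <- align_sensor_to_image(36000, rec, delta_t = 60)
  expect_equal(unname(v2["temperature_c"]), 1)
  # equidistant: earlier record wins
  v3 <- align_sensor_to_image(36300, rec, delta_t = 600)
  expect_equal(attr(v3, "timestamp"), 36000)
  expect_error(align_sensor_to_image(40000, rec, delta_t = 600), "no sensor record")
  # brute-force argmin agreement on random series
  for (seed in 1:5) {
    ser <- random_series(40, seed = seed)
    tq <- runif(20, -500, max(ser$timestamp) + 500)
    for (t_i in tq) {
      dev <- abs(ser$timestamp - t_i)
      best <- which(dev == min(dev))[1]
      if (dev[best] >= 300) next
      got <- align_sensor_to_image(t_i, ser, delta_t = 300)
      expect_equal(attr(got, "timestamp"), ser$timestamp[best])
    }
  }
})

test_that("standardization matches the closed form and round-trips stats", {
  x <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "temperature_c"))
  st <- sensor_stats(x)
  z <- standardize(x, st)
  expect_equal(as.vector(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(as.vector(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # already standardized + identity stats -> unchanged
  ident <- structure(list(mu = c(temperature_c = 0), sigma = c(temperature_c = 1)),
                     class = "sensor_stats")
  expect_equal(standardize(z, ident), z)
  # post-fit training channels have mean 0 sd 1
  ser <- random_series(100, seed = 9)
  st2 <- sensor_stats(ser)
  z2 <- standardize(as.matrix(ser[-1]), st2)
  expect_equal(max(abs(colMeans(z2))), 0, tolerance = 1e-9)
  expect_equal(max(abs(sqrt(colMeans(z2^2)) - 1)), 0, tolerance = 1e-9)
  const <- structure(list(mu = c(humidity_rh = 1), sigma = c(humidity_rh = 0)),
                     class = "sensor_stats")
  expect_error(standardize(c(humidity_rh = 2), const), "humidity_rh")
})

test_that("pipeline fits standardization statistics on the training split only", {
  ds <- generate_dataset(tiny_synth_config(seed = 4))
  pp <- preprocess_config(h0 = 16, w0 = 16)
  plan <- make_split(ds$groups, seed = 4)
  idx <- split(seq_along(ds$groups), plan$partition)
  tr <- prepare_samples(ds, pp, indices = idx$train)
  te <- prepare_samples(ds, pp, stats = tr$stats, indices = idx$test)
  # training sensors are z-scored under their own stats...
  expect_lt(max(abs(colMeans(tr$sensor))), 1e-9)
  # ...and the test partition reuses them verbatim (leakage guard)
  expect_identical(te$stats, tr$stats)
  expect_gt(max(abs(colMeans(te$sensor))), 1e-9)
  expect_equal(dim(te$sensor)[2], 3)
  expect_true(all(abs(te$timestamps - te$matched_timestamps) < pp$delta_t))
})
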