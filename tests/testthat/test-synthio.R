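# Synthetic generator: seeded determinism, density regimes, injected
# ground truth, environmental class signal, and the on-disk layout.

test_that("rendering is a pure function of (class, density, seed)", {
  cfg <- desk_synth_config(seed = 1)
  a <- render_image(2, "dense", cfg, seed = 99)
  b <- render_image(2, "dense", cfg, seed = 99)
  expect_identical(a, b)
  c <- render_image(2, "dense", cfg, seed = 100)
  expect_false(identical(a, c))
  expect_error(render_image(1, "clustered", cfg), "arg")
})

test_that("sparse images hold at most 3 isolated targets, dense at least 5", {
  cfg <- synth_config(image_size = c(32L, 32L), seed = 2)
  for (seed in 1:8) {
    sp <- render_image(1, "sparse", cfg, seed = seed)
    expect_lte(attr(sp, "n_targets"), 3)
    expect_gte(attr(sp, "n_targets"), 1)
    # connected components of the sparse mask <= 3 (flood fill oracle)
    m <- attr(sp, "mask")
    lab <- matrix(0L, nrow(m), ncol(m)); comp <- 0L
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (m[i, j] && lab[i, j] == 0L) {
        comp <- comp + 1L
        stack <- list(c(i, j))
        while (length(stack)) {
          p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
          if (p[1] < 1 || p[2] < 1 || p[1] > nrow(m) || p[2] > ncol(m)) next
          if (!m[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
          lab[p[1], p[2]] <- comp
          for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
            stack[[length(stack) + 1L]] <- p + d
          }
        }
      }
    }
    expect_lte(comp, 3)
    dn <- render_image(1, "dense", cfg, seed = seed)
    expect_gte(attr(dn, "n_targets"), 5)
  }
})

test_that("targets are small and zero contrast hides them", {
  cfg <- synth_config(image_size = c(64L, 64L), seed = 3,
                      target_scale_range = c(0.005, 0.02))
  img <- render_image(4, "sparse", cfg, seed = 5)
  n_t <- attr(img, "n_targets")
  # union mask of isolated targets stays near n_t * per-target fraction
  expect_lt(mean(attr(img, "mask")), n_t * 0.02 * 1.5)
  cfg0 <- synth_config(image_size = c(64L, 64L), seed = 3, target_contrast = 0)
  flat <- render_image(4, "sparse", cfg0, seed = 5)
  bg <- flat
  attributes(bg) <- attributes(flat)["dim"]
  # zero-contrast pixels are statistically indistinguishable: the target
  # region equals the background that would have been drawn there
  set.seed(5); ref_bg <- pestfusion:::.render_background(64, 64)
  expect_equal(bg, pmin(pmax(ref_bg, 0), 1), tolerance = 1e-12)
})

test_that("environmental records follow the configured law", {
  cfg <- desk_synth_config(seed = 6, outlier_rate = 0, missing_rate = 0)
  noon <- as.numeric(as.POSIXct("2023-06-01 12:00:00", tz = "UTC"))
  midnight <- as.numeric(as.POSIXct("2023-06-01 00:00:00", tz = "UTC"))
  r <- sample_environment(NA, noon, cfg, seed = 1)
  expect_false(any(r$missing) || any(r$outlier))
  night <- replicate(20, sample_environment(NA, midnight, cfg)$values[3])
  expect_true(all(night == 0))   # illumination clipped at night
  # no gaps, values within base +/- 6 sd when no outliers are injected
  ts <- seq(noon, noon + 3600 * 5, by = 600)
  rec <- pestfusion:::.env_records(rep(NA_integer_, length(ts)), ts, cfg)
  expect_false(anyNA(rec$values))
  base <- pestfusion:::.env_base(ts)
  expect_true(all(abs(rec$values[, 1] - base[, 1]) <= 6 * cfg$env_noise_sd[1]))
  # class shift moves the mean by the configured offset
  cfgs <- desk_synth_config(seed = 6, outlier_rate = 0, missing_rate = 0)
  set.seed(2)
  r1 <- pestfusion:::.env_records(rep(1L, 500), rep(noon, 500), cfgs)$values
  set.seed(2)
  r4 <- pestfusion:::.env_records(rep(4L, 500), rep(noon, 500), cfgs)$values
  expect_equal(unname(colMeans(r1 - r4)),
               cfgs$env_class_shift[1, ] - cfgs$env_class_shift[4, ],
               tolerance = 1e-9)
  # zero shift: distributions identical across classes under matched seeds
  cfg0 <- desk_synth_config(seed = 6, env_class_shift = matrix(0, 6, 3),
                            outlier_rate = 0, missing_rate = 0)
  set.seed(3); a <- pestfusion:::.env_records(rep(2L, 500), rep(noon, 500), cfg0)$values
  set.seed(3); b <- pestfusion:::.env_records(rep(5L, 500), rep(noon, 500), cfg0)$values
  expect_equal(a, b)
})

test_that("injected outliers are recovered by the sigma rule", {
  cfg <- desk_synth_config(seed = 8, outlier_rate = 0.05, missing_rate = 0)
  noon <- as.numeric(as.POSIXct("2023-06-01 12:00:00", tz = "UTC"))
  ts <- seq(noon, by = 600, length.out = 1000)
  set.seed(8)
  rec <- pestfusion:::.env_records(rep(NA_integer_, 1000), ts, cfg)
  n_inj <- sum(rec$outlier)
  # injected count within the binomial 99% CI of 1000 * 0.05
  ci <- qbinom(c(0.005, 0.995), 1000, 0.05)
  expect_gte(n_inj, ci[1]); expect_lte(n_inj, ci[2])
  ser <- data.frame(timestamp = ts, rec$values)
  got <- detect_outliers(ser, lambda = 3)
  recall <- sum(got & rec$outlier) / n_inj
  expect_gte(recall, 0.9)
})

test_that("dataset assembly is deterministic, balanced and group-consistent", {
  cfg <- tiny_synth_config(seed = 10)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(ds1$images[[7]], ds2$images[[7]])
  expect_identical(as.vector(table(ds1$labels)), rep(10L, 6))
  # every image timestamp inside the sensor span
  expect_true(all(ds1$timestamps >= min(ds1$sensors$timestamp) &
                    ds1$timestamps <= max(ds1$sensors$timestamp)))
  # one class, one density tag per group
  cross <- table(ds1$groups, ds1$density)
  expect_true(all(rowSums(cross > 0) == 1))
  crossl <- table(ds1$groups, ds1$labels)
  expect_true(all(rowSums(crossl > 0) == 1))
  # ground truth retained
  expect_length(ds1$truth$masks, length(ds1$images))
  expect_identical(dim(ds1$truth$outlier_mask), c(nrow(ds1$sensors), 3L))
  # a sub-hour sensor period cannot cover a session: rejected
  expect_error(generate_dataset(tiny_synth_config(sensor_period = 1e6)),
               "span too short")
})

test_that("the on-disk layout round-trips", {
  dir <- withr::local_tempdir()
  cfg <- tiny_synth_config(seed = 12)
  ds <- generate_dataset(cfg)
  write_dataset(ds, file.path(dir, "d1"))
  expect_error(write_dataset(ds, file.path(dir, "d1")), "not empty")
  expect_true(file.exists(file.path(dir, "d1", "sensors.csv")))
  back <- read_dataset(file.path(dir, "d1"))
  expect_identical(length(back$images), length(ds$images))
  expect_identical(back$groups, ds$groups)
  # labels survive the name/index round trip
  expect_identical(ds$class_names[ds$labels], back$class_names[back$labels])
  # PNG quantization keeps images within 1/255
  expect_lt(max(abs(back$images[[3]] - ds$images[[3]])), 1 / 255)
  expect_error(read_dataset(file.path(dir, "nowhere")), "sensors.csv")
})
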