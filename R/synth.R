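# Synthetic multimodal field-data generator. Emulates the statistical
# structure of a pest-monitoring campaign: tiny class-parameterized targets
# on cluttered leaf-like backgrounds, sparse vs dense aggregation regimes,
# per-plot acquisition sessions, and a shared environmental sensor stream
# (temperature / relative humidity / illumination) sampled on a fixed period
# with class-conditional means, injected outliers, missing records and
# image-vs-sensor clock mismatch. All injected ground truth (target masks,
# outlier and missing masks, class shifts) is retained for validation.

DEFAULT_CLASSES <- c("aphid", "thrips", "whitefly", "leafhopper",
                     "spider_mite", "leaf_beetle")

# class-specific visual parameters: body colour, ellipse eccentricity and
# micro-texture frequency (recycled beyond six classes)
.class_visuals <- function(k) {
  base <- list(
    col = rbind(c(0.60, 0.78, 0.25), c(0.78, 0.62, 0.18),
                c(0.95, 0.95, 0.88), c(0.68, 0.90, 0.55),
                c(0.70, 0.25, 0.15), c(0.16, 0.13, 0.10)),
    ecc = c(1.5, 3.0, 1.8, 2.2, 1.1, 1.4),
    tex_freq = c(2, 5, 3, 4, 6, 2)
  )
  i <- ((k - 1L) %% 6L) + 1L
  list(col = base$col[i, ], ecc = base$ecc[i], tex_freq = base$tex_freq[i])
}

#' Configuration of the synthetic multimodal generator
#'
#' Defaults encode the emulated study conditions: six pest classes with
#' imbalanced counts (proportions of a 12,130-image field campaign scaled to
#' ~600 images), targets occupying 1.2-2% of image pixels, a 10-minute
#' sensor period, and small per-class microclimate shifts.
#'
#' @param n_classes number of pest classes (>= 2).
#' @param n_samples_per_class integer vector of per-class image counts
#'   (recycled to `n_classes`).
#' @param image_size `(H, W)` in pixels.
#' @param target_scale_range fraction of image area occupied by one target,
#'   as `(min, max)` within (0, 1).
#' @param density_mix fraction of acquisition groups tagged `"dense"`
#'   (>= 5 overlapping targets) rather than `"sparse"` (1-3 isolated ones).
#' @param target_contrast blending weight of targets over the background in
#'   `[0, 1]`; 0 renders targets invisible (chance-level control).
#' @param env_class_shift `n_classes x 3` matrix of per-class mean offsets
#'   for (temperature degC, humidity %RH, illumination lux).
#' @param env_noise_sd per-channel Gaussian noise standard deviations.
#' @param outlier_rate probability that a sensor record carries an injected
#'   extreme excursion (one channel).
#' @param missing_rate probability that a record channel is missing.
#' @param sensor_period sensor sampling period in seconds.
#' @param clock_jitter maximum image-vs-sensor clock offset in seconds.
#' @param confusable_pair optional length-2 vector of class indices rendered
#'   visually identical (separable only through the environment channel), or
#'   `NULL`.
#' @param groups_per_class number of acquisition groups (plot x session) per
#'   class; group structure drives leak-free splitting.
#' @param seed integer seed making the whole dataset a pure function of the
#'   configuration.
#' @return a list of class `"synth_config"`.
#' @export
synth_config <- function(n_classes = 6L,
                         n_samples_per_class = c(157L, 122L, 98L, 76L, 92L, 54L),
                         image_size = c(64L, 64L),
                         target_scale_range = c(0.012, 0.02),
                         density_mix = 0.35,
                         target_contrast = 0.95,
                         env_class_shift = NULL,
                         env_noise_sd = c(1.5, 5, 4000),
                         outlier_rate = 0.01,
                         missing_rate = 0.01,
                         sensor_period = 600,
                         clock_jitter = 120,
                         confusable_pair = NULL,
                         groups_per_class = 8L,
                         seed = 1L) {
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 2,
            all(target_scale_range > 0), all(target_scale_range < 1),
            target_scale_range[1] <= target_scale_range[2],
            density_mix >= 0, density_mix <= 1,
            target_contrast >= 0, target_contrast <= 1,
            outlier_rate >= 0, outlier_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            sensor_period > 0, clock_jitter >= 0, groups_per_class >= 1)
  if (is.null(env_class_shift)) {
    base_shift <- rbind(c(2, 5, -5000), c(4, -8, 8000), c(3, 10, 4000),
                        c(0, 0, 0), c(5, -12, 10000), c(-2, 6, -8000))
    env_class_shift <- base_shift[((seq_len(n_classes) - 1L) %% 6L) + 1L, ,
                                  drop = FALSE]
  }
  env_class_shift <- matrix(as.numeric(env_class_shift), n_classes, 3)
  if (!is.null(confusable_pair)) {
    confusable_pair <- as.integer(confusable_pair)
    stopifnot(length(confusable_pair) == 2,
              all(confusable_pair >= 1), all(confusable_pair <= n_classes))
  }
  class_names <- if (n_classes <= 6L) DEFAULT_CLASSES[seq_len(n_classes)] else
    c(DEFAULT_CLASSES, sprintf("pest_%02d", 7:n_classes))
  structure(list(
    n_classes = n_classes,
    n_samples_per_class = rep_len(as.integer(n_samples_per_class), n_classes),
    image_size = as.integer(image_size),
    target_scale_range = target_scale_range,
    density_mix = density_mix,
    target_contrast = target_contrast,
    env_class_shift = env_class_shift,
    env_noise_sd = as.numeric(env_noise_sd),
    outlier_rate = outlier_rate,
    missing_rate = missing_rate,
    sensor_period = sensor_period,
    clock_jitter = clock_jitter,
    confusable_pair = confusable_pair,
    groups_per_class = as.integer(groups_per_class),
    class_names = class_names,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# multi-octave value noise in [0, 1]
value_noise <- function(h, w, octaves = 3L) {
  acc <- matrix(0, h, w)
  amp <- 0
  for (o in seq_len(octaves)) {
    k <- 2L^(o + 1L)
    g <- matrix(stats::runif(k * k), k, k)
    acc <- acc + 0.5^o * (bilinear_matrix(k, h) %*% g %*% t(bilinear_matrix(k, w)))
    amp <- amp + 0.5^o
  }
  acc / amp
}

# procedural leaf background: green base modulated by value noise plus a
# few bright vein lines
.render_background <- function(h, w) {
  noise <- value_noise(h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w) / w
  ys <- matrix(rep(seq_len(h), times = w), h, w) / h
  veins <- matrix(0, h, w)
  for (v in seq_len(3L)) {
    x0 <- stats::runif(1); y0 <- stats::runif(1)
    th <- stats::runif(1, 0, pi)
    d <- abs((xs - x0) * sin(th) - (ys - y0) * cos(th))
    veins <- veins + 0.25 * exp(-(d / 0.02)^2)
  }
  base <- c(0.25, 0.45, 0.18)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- base[ch] * (0.6 + 0.8 * noise) + veins * 0.5 * base[ch] / 0.45
  }
  pmin(pmax(img, 0), 1)
}

.place_target <- function(mask, h, w, cx, cy, area, ecc, theta) {
  ra <- max(sqrt(area * ecc / pi), 0.6)
  rb <- max(area / (pi * ra), 0.5)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  xr <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
  yr <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
  mask | ((xr / ra)^2 + (yr / rb)^2 <= 1)
}

#' Render one synthetic pest image
#'
#' Produces a textured, cluttered leaf background with one or more small
#' elliptical targets carrying class-specific shape eccentricity, hue and
#' micro-texture. `"sparse"` places 1-3 non-overlapping targets, `"dense"`
#' places 5-8 overlapping ones in a cluster. If the configuration names a
#' confusable pair, both member classes are drawn with the first member's
#' visual parameters.
#'
#' @param class_id class index in `1..n_classes`.
#' @param density `"sparse"` or `"dense"`.
#' @param cfg a [synth_config()].
#' @param seed optional seed for a bit-identical rendering.
#' @return an `H x W x 3` array in `[0, 1]` with attributes `"mask"`
#'   (logical target-pixel matrix) and `"n_targets"`.
#' @export
render_image <- function(class_id, density = c("sparse", "dense"),
                         cfg = synth_config(), seed = NULL) {
  density <- match.arg(density)
  stopifnot(class_id >= 1, class_id <= cfg$n_classes)
  if (!is.null(seed)) set.seed(seed)
  vis_id <- class_id
  cp <- cfg$confusable_pair
  if (!is.null(cp) && class_id %in% cp) vis_id <- cp[1]
  vis <- .class_visuals(vis_id)
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  img <- .render_background(h, w)
  bg <- img                              # kept for foreground occluders
  n_t <- if (density == "sparse") sample(1:3, 1) else sample(5:8, 1)
  mask <- matrix(FALSE, h, w)
  centers <- NULL
  if (density == "dense") {
    ccx <- stats::runif(1, 0.3 * w, 0.7 * w)
    ccy <- stats::runif(1, 0.3 * h, 0.7 * h)
  }
  for (t in seq_len(n_t)) {
    frac <- stats::runif(1, cfg$target_scale_range[1], cfg$target_scale_range[2])
    area <- frac * h * w
    rad <- sqrt(area / pi)
    placed <- FALSE
    for (try in 1:60) {
      if (density == "sparse") {
        cx <- stats::runif(1, rad + 1, w - rad)
        cy <- stats::runif(1, rad + 1, h - rad)
        # major semi-axis <= sqrt(ecc) * rad; 1.8 covers eccentricity up to 3
        ok_sep <- is.null(centers) ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                1.8 * (centers[, 3] + rad))
        if (!ok_sep) next                # enforce non-overlap
      } else {
        cx <- min(max(ccx + stats::rnorm(1, 0, 1.2 * rad), 1), w)
        cy <- min(max(ccy + stats::rnorm(1, 0, 1.2 * rad), 1), h)
      }
      placed <- TRUE
      break
    }
    if (!placed) next
    centers <- rbind(centers, c(cx, cy, rad))
    tm <- .place_target(matrix(FALSE, h, w), h, w, cx, cy, area,
                        vis$ecc, stats::runif(1, 0, pi))
    if (!any(tm)) next
    phase <- stats::runif(1, 0, 2 * pi)
    ang <- stats::runif(1, 0, pi)
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), times = w), h, w)
    tex <- 0.5 + 0.5 * sin(2 * pi * vis$tex_freq *
                             (xs * cos(ang) + ys * sin(ang)) / (2 * rad + 1) + phase)
    cc <- cfg$target_contrast
    for (ch in 1:3) {
      lay <- img[, , ch]
      val <- vis$col[ch] * (0.75 + 0.5 * tex[tm])
      lay[tm] <- lay[tm] * (1 - cc) + val * cc
      img[, , ch] <- lay
    }
    mask <- mask | tm
  }
  # dense colonies suffer frequent occlusion: leaf-like foreground blobs
  # (re-painted background) cover parts of the cluster, eroding the
  # visible target evidence
  if (density == "dense" && !is.null(centers)) {
    for (o in seq_len(sample(2:3, 1))) {
      pick <- sample(nrow(centers), 1)
      ox <- centers[pick, 1] + stats::rnorm(1, 0, 1.5 * centers[pick, 3])
      oy <- centers[pick, 2] + stats::rnorm(1, 0, 1.5 * centers[pick, 3])
      oarea <- stats::runif(1, 2, 4) * pi * centers[pick, 3]^2
      om <- .place_target(matrix(FALSE, h, w), h, w, ox, oy, oarea,
                          stats::runif(1, 1, 2), stats::runif(1, 0, pi))
      for (ch in 1:3) {
        lay <- img[, , ch]
        lay[om] <- bg[, , ch][om] * 0.9
        img[, , ch] <- lay
      }
      mask <- mask & !om
    }
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "mask") <- mask
  attr(img, "n_targets") <- if (is.null(centers)) 0L else nrow(centers)
  img
}

# vectorized diurnal base curves; t in POSIX seconds (UTC)
.env_base <- function(t) {
  hr <- (t / 3600) %% 24
  temp <- 18 + 8 * sin(2 * pi * (hr - 9) / 24)
  hum <- 65 - 20 * sin(2 * pi * (hr - 9) / 24)
  lux <- pmax(0, 60000 * sin(pi * (hr - 6) / 14))
  lux[hr < 6 | hr > 20] <- 0
  cbind(temperature_c = temp, humidity_rh = hum, illumination_lux = lux)
}

# channel scales used to size extreme excursions
.env_excursion_scale <- c(6, 18, 25000)

# bulk record generator shared by sample_environment() and the dataset
# builder; class_ids may contain NA (no class active -> baseline curve)
.env_records <- function(class_ids, t, cfg) {
  n <- length(t)
  vals <- .env_base(t)
  shift <- matrix(0, n, 3)
  ok <- !is.na(class_ids)
  if (any(ok)) shift[ok, ] <- cfg$env_class_shift[class_ids[ok], , drop = FALSE]
  noise <- cbind(stats::rnorm(n, 0, cfg$env_noise_sd[1]),
                 stats::rnorm(n, 0, cfg$env_noise_sd[2]),
                 stats::rnorm(n, 0, cfg$env_noise_sd[3]))
  dark <- vals[, 3] == 0                 # night: the sensor reads 0 lux
  vals <- vals + shift + noise
  vals[, 2] <- pmin(pmax(vals[, 2], 2), 100)
  vals[, 3] <- pmax(vals[, 3], 0)
  vals[dark, 3] <- 0
  # injected extreme excursions: one channel per affected record
  outlier <- matrix(FALSE, n, 3)
  hit <- stats::runif(n) < cfg$outlier_rate
  if (any(hit)) {
    chan <- sample.int(3, sum(hit), replace = TRUE)
    mag <- stats::runif(sum(hit), 10, 16) * .env_excursion_scale[chan]
    sgn <- sample(c(-1, 1), sum(hit), replace = TRUE)
    vals[cbind(which(hit), chan)] <- vals[cbind(which(hit), chan)] + sgn * mag
    outlier[cbind(which(hit), chan)] <- TRUE
  }
  missing <- matrix(stats::runif(n * 3) < cfg$missing_rate, n, 3)
  vals[missing] <- NA
  colnames(outlier) <- colnames(missing) <- colnames(vals)
  list(values = vals, outlier = outlier, missing = missing)
}

#' Draw one environmental sensor record
#'
#' The record is a diurnal base curve (sinusoidal temperature and humidity,
#' illumination clipped to 0 lux at night) plus the per-class mean shift and
#' Gaussian noise; with probability `outlier_rate` one channel carries an
#' extreme excursion, and each channel is missing with probability
#' `missing_rate`.
#'
#' @param class_id class index, or `NA` for the baseline (no class active).
#' @param t timestamp in POSIX seconds.
#' @param cfg a [synth_config()].
#' @param seed optional seed.
#' @return a list with `values` (named numeric 3-vector, `NA` = missing),
#'   `outlier` and `missing` logical flags.
#' @export
sample_environment <- function(class_id, t, cfg = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- .env_records(class_id, t, cfg)
  list(values = r$values[1, ], outlier = r$outlier[1, ], missing = r$missing[1, ])
}

#' Generate a complete synthetic multimodal dataset
#'
#' Images are organized into acquisition groups (one plot x session per
#' group, a single class and density tag each); each group occupies a
#' disjoint daily session window, and the shared sensor stream covers the
#' whole campaign at `sensor_period` spacing, with records inside a session
#' carrying that group's class shift. Image timestamps are jittered by up to
#' `clock_jitter` seconds against the sensor clock. The result retains all
#' injected ground truth.
#'
#' @param cfg a [synth_config()].
#' @return a list of class `"synth_dataset"` with `images`, `sensors` (data
#'   frame: timestamp, temperature_c, humidity_rh, illumination_lux, session),
#'   `labels` (1-based class ids), `groups`, `density`, `timestamps`,
#'   `manifest`, and a `truth` list (target masks, outlier/missing masks,
#'   session table, class shifts).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  day <- 86400
  t0 <- as.numeric(as.POSIXct("2023-05-01 00:00:00", tz = "UTC"))
  win_start <- 9 * 3600
  win_len <- 6 * 3600
  if (cfg$sensor_period > win_len) {
    stop("generate_dataset(): sensor_period exceeds the session window; span too short",
         call. = FALSE)
  }

  # group plan: class, density, session day
  gtab <- NULL
  gid <- 0L
  for (k in seq_len(cfg$n_classes)) {
    g <- cfg$groups_per_class
    n_dense <- round(g * cfg$density_mix)
    dens <- c(rep("dense", n_dense), rep("sparse", g - n_dense))
    nk <- cfg$n_samples_per_class[k]
    per <- diff(floor(seq(0, nk, length.out = g + 1)))
    for (j in seq_len(g)) {
      gid <- gid + 1L
      gtab <- rbind(gtab, data.frame(group = sprintf("g%03d", gid), class = k,
                                     density = dens[j], n = per[j]))
    }
  }
  gtab <- gtab[sample.int(nrow(gtab)), ]      # shuffle session order
  gtab$day <- seq_len(nrow(gtab)) - 1L
  gtab$t_start <- t0 + gtab$day * day + win_start
  gtab$t_end <- gtab$t_start + win_len

  # shared sensor stream over the whole campaign
  span_end <- t0 + nrow(gtab) * day
  ts <- seq(t0, span_end, by = cfg$sensor_period)
  rec_class <- rep(NA_integer_, length(ts))
  rec_session <- rep(NA_character_, length(ts))
  for (j in seq_len(nrow(gtab))) {
    inwin <- ts >= gtab$t_start[j] & ts <= gtab$t_end[j]
    rec_class[inwin] <- gtab$class[j]
    rec_session[inwin] <- gtab$group[j]
  }
  env <- .env_records(rec_class, ts, cfg)
  sensors <- data.frame(timestamp = ts, env$values)
  sensors$session <- rec_session

  # images
  n_total <- sum(gtab$n)
  images <- vector("list", n_total)
  masks <- vector("list", n_total)
  labels <- integer(n_total)
  groups <- character(n_total)
  density <- character(n_total)
  timestamps <- numeric(n_total)
  fname <- character(n_total)
  i <- 0L
  for (j in seq_len(nrow(gtab))) {
    if (gtab$n[j] == 0) next
    t_img <- sort(stats::runif(gtab$n[j], gtab$t_start[j] + cfg$clock_jitter,
                               gtab$t_end[j] - cfg$clock_jitter))
    t_img <- t_img + stats::runif(gtab$n[j], -cfg$clock_jitter, cfg$clock_jitter)
    for (m in seq_len(gtab$n[j])) {
      i <- i + 1L
      img <- render_image(gtab$class[j], gtab$density[j], cfg)
      masks[[i]] <- attr(img, "mask")
      attr(img, "mask") <- NULL
      images[[i]] <- img
      labels[i] <- gtab$class[j]
      groups[i] <- gtab$group[j]
      density[i] <- gtab$density[j]
      timestamps[i] <- t_img[m]
      fname[i] <- sprintf("%s/%s_%03d.png", cfg$class_names[gtab$class[j]],
                          gtab$group[j], m)
    }
  }
  manifest <- data.frame(filename = fname,
                         label = cfg$class_names[labels],
                         group = groups, density = density,
                         timestamp = timestamps)
  structure(list(
    images = images, sensors = sensors, labels = labels, groups = groups,
    density = density, timestamps = timestamps, manifest = manifest,
    class_names = cfg$class_names, config = cfg,
    truth = list(masks = masks, outlier_mask = env$outlier,
                 missing_mask = env$missing, sessions = gtab,
                 env_class_shift = cfg$env_class_shift)
  ), class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("Synthetic multimodal pest dataset: %d images (%d x %d), %d classes\n",
              length(x$images), dim(x$images[[1]])[1], dim(x$images[[1]])[2],
              length(x$class_names)))
  cat(sprintf("  groups: %d | dense fraction: %.2f | sensor records: %d\n",
              length(unique(x$groups)), mean(x$density == "dense"),
              nrow(x$sensors)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Layout: `images/<class_name>/<group>_<idx>.png`, `sensors.csv`
#' (timestamp, temperature_c, humidity_rh, illumination_lux) and
#' `manifest.csv` (filename, label, group, density, timestamp), all UTF-8
#' comma-separated with header rows.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop(sprintf("write_dataset(): '%s' exists and is not empty (use force = TRUE)", dir),
         call. = FALSE)
  }
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$images)) {
    f <- file.path(dir, "images", dataset$manifest$filename[i])
    dir.create(dirname(f), recursive = TRUE, showWarnings = FALSE)
    png::writePNG(dataset$images[[i]], f)
  }
  sens <- dataset$sensors[c("timestamp", "temperature_c", "humidity_rh",
                            "illumination_lux")]
  utils::write.csv(sens, file.path(dir, "sensors.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' Read a dataset from the on-disk layout
#'
#' @param dir a directory produced by [write_dataset()] (or any dataset in
#'   the same layout).
#' @return a `"synth_dataset"`-shaped list (without generator ground truth).
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  spath <- file.path(dir, "sensors.csv")
  if (!file.exists(spath)) {
    stop("read_dataset(): sensors.csv not found; this pipeline needs both the image and the sensor modality",
         call. = FALSE)
  }
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  sensors <- utils::read.csv(spath, stringsAsFactors = FALSE)
  class_names <- sort(unique(manifest$label))
  images <- lapply(manifest$filename, function(f) {
    img <- png::readPNG(file.path(dir, "images", f))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  structure(list(
    images = images, sensors = sensors,
    labels = match(manifest$label, class_names),
    groups = manifest$group, density = manifest$density,
    timestamps = manifest$timestamp, manifest = manifest,
    class_names = class_names, config = NULL, truth = NULL
  ), class = "synth_dataset")
}
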