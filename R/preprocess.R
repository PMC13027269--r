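# Multimodal preprocessing: image resolution normalization and small-target
# augmentation, sensor cleaning (sigma-rule outliers -> linear interpolation),
# nearest-timestamp image-sensor alignment, and z-scoring. The pipeline order
# is fixed: outlier removal -> interpolation -> alignment -> standardization.

#' Preprocessing configuration
#'
#' @param h0,w0 target image resolution in pixels after resolution
#'   normalization.
#' @param crop_w,crop_h crop-window extent in pixels for the local
#'   small-target enhancement step; must not exceed `(w0, h0)`.
#' @param alpha_min,alpha_max bounds of the uniform random scale
#'   perturbation factor (dimensionless, `0 < alpha_min <= alpha_max`).
#' @param lambda outlier threshold in units of per-channel standard
#'   deviations.
#' @param delta_t maximum tolerated image-to-sensor timestamp deviation in
#'   seconds; alignment fails beyond it.
#' @return a list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(h0 = 64L, w0 = 64L,
                              crop_w = NULL, crop_h = NULL,
                              alpha_min = 0.8, alpha_max = 1.2,
                              lambda = 3, delta_t = 600) {
  if (is.null(crop_w)) crop_w <- as.integer(round(w0 / 2))
  if (is.null(crop_h)) crop_h <- as.integer(round(h0 / 2))
  stopifnot(h0 >= 1, w0 >= 1,
            alpha_min > 0, alpha_min <= alpha_max,
            lambda > 0, delta_t > 0,
            crop_w >= 1, crop_h >= 1, crop_w <= w0, crop_h <= h0)
  structure(list(h0 = as.integer(h0), w0 = as.integer(w0),
                 crop_w = as.integer(crop_w), crop_h = as.integer(crop_h),
                 alpha_min = alpha_min, alpha_max = alpha_max,
                 lambda = lambda, delta_t = delta_t),
            class = "preprocess_config")
}

sensor_channels <- function(series) {
  setdiff(names(series), c("timestamp", "session"))
}

#' Resolution normalization by bilinear resampling
#'
#' Maps a raw image of any size to a fixed `h0 x w0` grid with
#' half-pixel-centred bilinear interpolation (edge-clamped), preserving the
#' channel count. An input already at the target size passes through
#' unchanged.
#'
#' @param img an `H x W x C` numeric array (values typically in `[0, 1]`).
#' @param h0,w0 target height and width in pixels.
#' @return an `h0 x w0 x C` array.
#' @export
resize_image <- function(img, h0, w0) {
  stopifnot(h0 >= 1, w0 >= 1)
  if (length(dim(img)) != 3 || any(dim(img)[1:2] < 1)) {
    stop("resize_image(): expected a non-empty H x W x C array", call. = FALSE)
  }
  if (dim(img)[1] == h0 && dim(img)[2] == w0) return(img)
  resample_array(img, h0, w0)
}

#' Crop a sub-window and rescale it back to the full frame
#'
#' Extracts the 0-based half-open window `[x, x + w_c) x [y, y + h_c)` and
#' bilinearly rescales it to the input size, so that small targets inside
#' the window occupy a proportionally larger pixel fraction.
#'
#' @param img an `H x W x C` array.
#' @param x,y 0-based top-left corner of the crop window (x = column,
#'   y = row).
#' @param w_c,h_c crop width and height in pixels.
#' @return an array of the same dimensions as `img`.
#' @export
crop_and_rescale <- function(img, x, y, w_c, h_c) {
  d <- dim(img)
  if (x < 0 || y < 0 || w_c < 1 || h_c < 1 ||
      x + w_c > d[2] || y + h_c > d[1]) {
    stop(sprintf(
      "crop_and_rescale(): window [x=%d, x+w=%d) x [y=%d, y+h=%d) outside %d x %d image",
      x, x + w_c, y, y + h_c, d[2], d[1]), call. = FALSE)
  }
  crop <- img[(y + 1):(y + h_c), (x + 1):(x + w_c), , drop = FALSE]
  resample_array(crop, d[1], d[2])
}

#' Random scale perturbation
#'
#' Draws `alpha ~ U(alpha_min, alpha_max)`, rescales the image by `alpha`,
#' and centre-crops (alpha > 1) or zero-pads (alpha < 1) back to the
#' original size so batch geometry stays constant. At
#' `alpha_min = alpha_max = 1` the op is an exact no-op.
#'
#' @param img an `H x W x C` array.
#' @param alpha_min,alpha_max perturbation bounds.
#' @param alpha optional fixed factor overriding the random draw.
#' @return an array of the same dimensions as `img`.
#' @export
random_scale_perturbation <- function(img, alpha_min = 0.8, alpha_max = 1.2,
                                      alpha = NULL) {
  stopifnot(alpha_min > 0, alpha_min <= alpha_max)
  if (is.null(alpha)) alpha <- stats::runif(1, alpha_min, alpha_max)
  d <- dim(img)
  hs <- max(1L, as.integer(round(d[1] * alpha)))
  ws <- max(1L, as.integer(round(d[2] * alpha)))
  if (hs == d[1] && ws == d[2]) return(img)
  scaled <- resample_array(img, hs, ws)
  out <- array(0, d)
  if (hs >= d[1]) {                      # centre crop
    oy <- (hs - d[1]) %/% 2
    ox <- (ws - d[2]) %/% 2
    out <- scaled[(oy + 1):(oy + d[1]), (ox + 1):(ox + d[2]), , drop = FALSE]
  } else {                               # centre pad
    oy <- (d[1] - hs) %/% 2
    ox <- (d[2] - ws) %/% 2
    out[(oy + 1):(oy + hs), (ox + 1):(ox + ws), ] <- scaled
  }
  out
}

#' Sigma-rule sensor outlier detection
#'
#' Flags record `t` of channel `k` when `|s_k(t) - mu_k| > lambda * sigma_k`,
#' where `mu_k` and `sigma_k` are the mean and population standard deviation
#' of the non-missing records of that channel. When a `by` column is given
#' (e.g. an acquisition session id) the statistics are computed within each
#' stratum, so a level shift between sites is not mass-flagged. A constant
#' channel (`sigma_k = 0`) produces no flags and a warning.
#'
#' @param series a data frame with a `timestamp` column and one numeric
#'   column per sensor channel; `NA` marks missing records.
#' @param lambda threshold in standard-deviation units.
#' @param by optional name of a stratification column in `series`.
#' @return a logical matrix (records x channels); `NA` inputs are `FALSE`.
#' @export
detect_outliers <- function(series, lambda = 3, by = NULL) {
  stopifnot(lambda > 0)
  chans <- sensor_channels(series)
  mask <- matrix(FALSE, nrow(series), length(chans),
                 dimnames = list(NULL, chans))
  strata <- if (is.null(by)) rep(1L, nrow(series)) else series[[by]]
  for (ch in chans) {
    v <- series[[ch]]
    for (s in unique(strata)) {
      rows <- which(strata == s)
      x <- v[rows]
      obs <- !is.na(x)
      if (sum(obs) < 2) next
      mu <- mean(x[obs])
      sg <- sqrt(mean((x[obs] - mu)^2))
      if (sg == 0) {
        warning(sprintf("detect_outliers(): channel '%s' is constant; no flags", ch),
                call. = FALSE)
        next
      }
      mask[rows, ch] <- obs & abs(x - mu) > lambda * sg
    }
  }
  mask
}

#' Fill missing sensor records by linear interpolation in time
#'
#' Interior gaps are filled linearly against the timestamp axis; records
#' before the first or after the last observation take the nearest observed
#' value (pure linear interpolation is undefined there).
#'
#' @param series a sensor data frame (see [detect_outliers()]).
#' @return the series with no remaining `NA` in any channel.
#' @export
interpolate_missing <- function(series) {
  chans <- sensor_channels(series)
  for (ch in chans) {
    v <- series[[ch]]
    obs <- !is.na(v)
    if (!any(obs)) {
      stop(sprintf("interpolate_missing(): channel '%s' has no observed values", ch),
           call. = FALSE)
    }
    if (all(obs)) next
    series[[ch]] <- if (sum(obs) == 1) rep(v[obs], nrow(series)) else
      stats::approx(series$timestamp[obs], v[obs],
                    xout = series$timestamp, rule = 2)$y
  }
  series
}

#' Align a sensor record to an image timestamp
#'
#' Returns the record at the timestamp nearest to `t_i`, provided the
#' deviation is strictly below `delta_t`; equidistant ties resolve to the
#' earlier (causally available) record.
#'
#' @param t_i image acquisition time (POSIX seconds).
#' @param series a cleaned, gap-free sensor data frame.
#' @param delta_t maximum allowed deviation in seconds.
#' @return a named numeric vector of channel values, with the matched
#'   timestamp in attribute `"timestamp"`.
#' @export
align_sensor_to_image <- function(t_i, series, delta_t = 600) {
  dev <- abs(series$timestamp - t_i)
  j <- which(dev == min(dev))
  j <- j[which.min(series$timestamp[j])]    # tie -> earlier timestamp
  if (dev[j] >= delta_t) {
    stop(sprintf(
      "align_sensor_to_image(): no sensor record within %g s of t_i = %.0f (nearest %.0f s away)",
      delta_t, t_i, dev[j]), call. = FALSE)
  }
  chans <- sensor_channels(series)
  out <- vapply(chans, function(ch) series[[ch]][j], numeric(1))
  attr(out, "timestamp") <- series$timestamp[j]
  out
}

#' Per-channel mean and population standard deviation
#'
#' @param x a sensor data frame or a numeric matrix with one column per
#'   channel.
#' @return a list of class `"sensor_stats"` with named vectors `mu` and
#'   `sigma`.
#' @export
sensor_stats <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[sensor_channels(x)])
  mu <- colMeans(x, na.rm = TRUE)
  sigma <- sqrt(colMeans((x - rep(mu, each = nrow(x)))^2, na.rm = TRUE))
  structure(list(mu = mu, sigma = sigma), class = "sensor_stats")
}

#' Z-score standardization with externally fitted statistics
#'
#' Computes `(s_k - mu_k) / sigma_k` per channel. Statistics fitted on a
#' training split must be passed unchanged for validation and test data
#' (leakage guard).
#'
#' @param x a named numeric vector, a matrix with channel columns, or a
#'   sensor data frame.
#' @param stats a [sensor_stats()] object.
#' @return standardized values in the shape of the input.
#' @export
standardize <- function(x, stats) {
  bad <- names(stats$sigma)[stats$sigma == 0]
  if (length(bad)) {
    stop(sprintf("standardize(): zero standard deviation in channel '%s'", bad[1]),
         call. = FALSE)
  }
  if (is.data.frame(x)) {
    for (ch in sensor_channels(x)) {
      x[[ch]] <- (x[[ch]] - stats$mu[[ch]]) / stats$sigma[[ch]]
    }
    return(x)
  }
  if (is.matrix(x)) {
    return(sweep(sweep(x, 2, stats$mu[colnames(x)]), 2,
                 stats$sigma[colnames(x)], "/"))
  }
  (x - stats$mu[names(x)]) / stats$sigma[names(x)]
}

#' Run the full preprocessing pipeline on a synthetic or on-disk dataset
#'
#' Applies, in order: sigma-rule outlier removal (flagged records become
#' missing), linear gap interpolation, image resolution normalization,
#' nearest-timestamp sensor alignment, and z-scoring. When `stats` is `NULL`
#' the standardization statistics are fitted on the aligned sensor vectors
#' of this dataset (use this only for the training partition, then pass the
#' returned `$stats` for validation and test data).
#'
#' @param dataset a [generate_dataset()] result or [read_dataset()] result.
#' @param cfg a [preprocess_config()].
#' @param stats optional pre-fitted [sensor_stats()].
#' @param indices optional subset of sample indices to process.
#' @return a list of class `"aligned_samples"`: normalized images, the
#'   standardized `n x K` sensor matrix, labels, groups, density tags,
#'   timestamps, matched sensor timestamps and the statistics used.
#' @export
prepare_samples <- function(dataset, cfg = preprocess_config(),
                            stats = NULL, indices = NULL) {
  if (is.null(indices)) indices <- seq_along(dataset$images)
  series <- dataset$sensors
  mask <- detect_outliers(series, lambda = cfg$lambda,
                          by = if ("session" %in% names(series)) "session")
  for (ch in colnames(mask)) series[[ch]][mask[, ch]] <- NA
  series <- interpolate_missing(series)

  n <- length(indices)
  chans <- sensor_channels(series)
  raw <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  matched <- numeric(n)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    j <- indices[i]
    images[[i]] <- resize_image(dataset$images[[j]], cfg$h0, cfg$w0)
    rec <- align_sensor_to_image(dataset$timestamps[j], series, cfg$delta_t)
    raw[i, ] <- rec
    matched[i] <- attr(rec, "timestamp")
  }
  if (is.null(stats)) stats <- sensor_stats(raw)
  structure(list(
    images = images,
    sensor = standardize(raw, stats),
    sensor_raw = raw,
    labels = dataset$labels[indices],
    groups = dataset$groups[indices],
    density = dataset$density[indices],
    timestamps = dataset$timestamps[indices],
    matched_timestamps = matched,
    class_names = dataset$class_names,
    stats = stats
  ), class = "aligned_samples")
}

#' @export
print.aligned_samples <- function(x, ...) {
  cat(sprintf("Aligned multimodal samples: %d images (%d x %d), %d sensor channels\n",
              length(x$images), dim(x$images[[1]])[1], dim(x$images[[1]])[2],
              ncol(x$sensor)))
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  invisible(x)
}

# training-time augmentation: random local crop + random scale perturbation
augment_image <- function(img, cfg) {
  d <- dim(img)
  x <- sample.int(d[2] - cfg$crop_w + 1L, 1L) - 1L
  y <- sample.int(d[1] - cfg$crop_h + 1L, 1L) - 1L
  img <- crop_and_rescale(img, x, y, cfg$crop_w, cfg$crop_h)
  random_scale_perturbation(img, cfg$alpha_min, cfg$alpha_max)
}
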