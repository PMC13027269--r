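# Shared fixtures, built in code. Desk-scale geometry: 16x16 images,
# quarter-width channels, identical topology to the reference model.

desk_spec <- function() pyramid_spec(scale_factor = 1 / 4, width_factor = 1 / 4)

desk_synth_config <- function(...) {
  synth_config(image_size = c(16L, 16L), ...)
}

tiny_synth_config <- function(...) {
  synth_config(image_size = c(16L, 16L),
               n_samples_per_class = rep(10L, 6),
               groups_per_class = 2L, ...)
}

# small random sensor series with optional missing values
random_series <- function(n = 50, missing = 0, seed = 1) {
  set.seed(seed)
  s <- data.frame(
    timestamp = seq(0, by = 600, length.out = n),
    temperature_c = rnorm(n, 20, 3),
    humidity_rh = rnorm(n, 60, 8),
    illumination_lux = runif(n, 0, 5e4)
  )
  if (missing > 0) {
    for (ch in c("temperature_c", "humidity_rh", "illumination_lux")) {
      # keep endpoints observed so interior interpolation is well-defined
      idx <- sample(2:(n - 1), missing)
      s[[ch]][idx] <- NA
    }
  }
  s
}

# one random aligned batch at the desk geometry
random_batch <- function(n = 4, h0 = 16, seed = 1) {
  set.seed(seed)
  list(images = replicate(n, array(runif(h0 * h0 * 3), c(h0, h0, 3)),
                          simplify = FALSE),
       sensor = matrix(rnorm(n * 3), n, 3),
       labels = sample.int(6, n, replace = TRUE))
}
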