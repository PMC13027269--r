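# The multi-scale vision-sensor collaborative classifier.
#
# Reference geometry: a 64x64x3 input produces a four-level pyramid with
# spatial sizes (64, 32, 16, 8) and channel widths (64, 128, 192, 256);
# each level passes through squeeze-style channel attention; a learnable
# convex combination of 1x1-projected, bilinearly upsampled levels yields
# the fused map F_ms (64x64x256), refined by a cross-scale relational unit
# (3x3 conv + ReLU). A three-layer environmental encoder (3 -> 32 -> 128
# with per-level sigmoid heads; the level-4 head is 128 -> 256) emits
# channel gates that modulate each level and the fused map. The
# collaborative head encodes the sensor vector to u (3 -> 32 -> 64),
# projects it per level to conditional gates, injects them residually
# (M_i = F_i + ReLU(conv1x1(F_i * G_i))), upsamples everything to level-1
# size, concatenates 640 channels, compresses to 256, adds the modulated
# fused map, pools, and classifies through 256 -> 128 -> 6 with softmax.
#
# `scale_factor` shrinks spatial sizes and `width_factor` shrinks channel
# widths for desk-scale experiments with identical topology.

#' Pyramid geometry specification
#'
#' @param scale_factor multiplier on the reference spatial sizes
#'   (64, 32, 16, 8); all scaled sizes must stay >= 1.
#' @param width_factor multiplier on the reference channel widths
#'   (64, 128, 192, 256).
#' @return a list of class `"pyramid_spec"`.
#' @export
pyramid_spec <- function(scale_factor = 1, width_factor = 1) {
  sizes <- as.integer(round(c(64, 32, 16, 8) * scale_factor))
  channels <- as.integer(round(c(64, 128, 192, 256) * width_factor))
  stopifnot(all(sizes >= 1), all(channels >= 4),
            all(diff(channels) > 0))
  structure(list(sizes = sizes, channels = channels,
                 scale_factor = scale_factor, width_factor = width_factor,
                 h0 = sizes[1]),
            class = "pyramid_spec")
}

.variant_names <- c("full", "no_multiscale", "no_sensor_prior",
                    "no_collab_head", "concat_fusion", "vision_only")

parse_variant <- function(name) {
  if (!length(name) || !all(name %in% .variant_names)) {
    stop(sprintf("unknown variant '%s'; valid: %s",
                 paste(setdiff(name, .variant_names), collapse = ", "),
                 paste(.variant_names, collapse = ", ")), call. = FALSE)
  }
  if ("vision_only" %in% name) name <- union(name, c("no_sensor_prior", "no_collab_head"))
  list(
    multiscale = !("no_multiscale" %in% name),
    sensor_prior = !("no_sensor_prior" %in% name) && !("concat_fusion" %in% name),
    collab_head = !("no_collab_head" %in% name),
    concat_fusion = "concat_fusion" %in% name
  )
}

he_init <- function(n_in, n_out, gain = 2) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(gain / n_in)), n_in, n_out)
}

new_bn <- function(c) {
  e <- new.env(parent = emptyenv())
  e$run_mean <- numeric(c)
  e$run_var <- rep(1, c)
  e
}

#' Build a model variant
#'
#' `"full"` enables every component. Ablations: `"no_multiscale"`
#' classifies from the (modulated) level-4 features only, attention kept;
#' `"no_sensor_prior"` fixes every modulation gate at 1 (the collaborative
#' head still consumes the sensor vector); `"no_collab_head"` classifies
#' from the pooled fused map, skipping the conditional-gating head;
#' `"concat_fusion"` replaces all conditional gating with concatenation of
#' the raw standardized sensor vector to the pooled feature;
#' `"vision_only"` (= no_sensor_prior + no_collab_head) has no sensor
#' dependence at all. Ablation names may be combined in a vector.
#'
#' @param variant a name (or vector of combinable ablation names) from
#'   `full`, `no_multiscale`, `no_sensor_prior`, `no_collab_head`,
#'   `concat_fusion`, `vision_only`.
#' @param spec a [pyramid_spec()].
#' @param n_classes number of output classes.
#' @param attention_ratio bottleneck reduction ratio of the channel
#'   attention blocks.
#' @param relational enable the cross-scale relational unit (3x3 conv +
#'   ReLU on the fused map).
#' @param seed seed for weight initialization.
#' @return an object of class `"mvcf_model"`.
#' @export
build_variant <- function(variant = "full", spec = pyramid_spec(),
                          n_classes = 6L, attention_ratio = 4L,
                          relational = TRUE, seed = 1L) {
  flags <- parse_variant(variant)
  set.seed(seed)
  ch <- spec$channels
  cf <- ch[4]
  hidden <- max(8L, as.integer(round(128 * spec$width_factor)))
  p <- list()
  bn <- list()

  # backbone: stem (two stride-1 3x3 convs) + three stride-2 stages
  p$bb.conv1a.W <- he_init(9 * 3, ch[1]);  p$bb.conv1a.b <- numeric(ch[1])
  p$bb.conv1b.W <- he_init(9 * ch[1], ch[1]); p$bb.conv1b.b <- numeric(ch[1])
  p$bb.conv2.W <- he_init(9 * ch[1], ch[2]); p$bb.conv2.b <- numeric(ch[2])
  p$bb.conv3.W <- he_init(9 * ch[2], ch[3]); p$bb.conv3.b <- numeric(ch[3])
  p$bb.conv4.W <- he_init(9 * ch[3], ch[4]); p$bb.conv4.b <- numeric(ch[4])
  for (nm in c("1a", "1b", "2", "3", "4")) {
    cl <- ch[match(substr(nm, 1, 1), c("1", "2", "3", "4"))]
    p[[paste0("bb.bn", nm, ".gamma")]] <- rep(1, cl)
    p[[paste0("bb.bn", nm, ".beta")]] <- numeric(cl)
    bn[[paste0("bb.bn", nm)]] <- new_bn(cl)
  }
  # level-4 global context branch (global pooling broadcast added back)
  p$bb.gctx.W <- he_init(ch[4], ch[4]); p$bb.gctx.b <- numeric(ch[4])

  # channel attention per level (only level 4 exists without multi-scale)
  lv <- if (flags$multiscale) 1:4 else 4L
  for (l in lv) {
    cr <- max(2L, ch[l] %/% attention_ratio)
    p[[sprintf("att.%d.W1", l)]] <- he_init(ch[l], cr)
    p[[sprintf("att.%d.b1", l)]] <- numeric(cr)
    p[[sprintf("att.%d.W2", l)]] <- he_init(cr, ch[l], gain = 1)
    p[[sprintf("att.%d.b2", l)]] <- numeric(ch[l])
  }

  # environmental encoder trunk + per-level sigmoid heads
  if (flags$sensor_prior) {
    p$env.W1 <- he_init(3, 32); p$env.b1 <- numeric(32)
    p$env.W2 <- he_init(32, 128); p$env.b2 <- numeric(128)
    # per-level heads exist only where a gate is consumed: every level on
    # the collaborative path, otherwise just the 256-wide level-4 head
    # (which also modulates the fused map)
    gl <- if (flags$multiscale && flags$collab_head) lv else 4L
    for (l in gl) {
      p[[sprintf("env.head.%d.W", l)]] <- he_init(128, ch[l], gain = 1)
      p[[sprintf("env.head.%d.b", l)]] <- numeric(ch[l])
    }
  }

  # cross-scale fusion: per-level 1x1 projections + learnable simplex weights
  if (flags$multiscale) {
    for (l in 1:4) {
      p[[sprintf("fus.proj.%d.W", l)]] <- he_init(ch[l], cf)
      p[[sprintf("fus.proj.%d.b", l)]] <- numeric(cf)
    }
    p$fus.logits <- numeric(4)
    if (relational) {
      p$rel.W <- he_init(9 * cf, cf); p$rel.b <- numeric(cf)
    }
  }

  # collaborative head
  use_head <- flags$multiscale && (flags$collab_head || flags$concat_fusion)
  if (use_head && flags$collab_head && !flags$concat_fusion) {
    p$head.Wa <- he_init(3, 32); p$head.ba <- numeric(32)
    p$head.Wb <- he_init(32, 64); p$head.bb <- numeric(64)
    for (l in 1:4) {
      p[[sprintf("head.P.%d", l)]] <- he_init(64, ch[l], gain = 1)
      p[[sprintf("head.q.%d", l)]] <- numeric(ch[l])
      p[[sprintf("head.phi.%d.W", l)]] <- he_init(ch[l], ch[l])
      p[[sprintf("head.phi.%d.b", l)]] <- numeric(ch[l])
    }
  }
  if (use_head) {
    p$head.compress.W <- he_init(sum(ch), cf)
    p$head.compress.b <- numeric(cf)
  }

  # classifier
  zdim <- if (!flags$multiscale) ch[4]
          else if (flags$concat_fusion) cf + 3L
          else cf
  p$cls.W1 <- he_init(zdim, hidden); p$cls.b1 <- numeric(hidden)
  p$cls.W2 <- he_init(hidden, n_classes, gain = 1); p$cls.b2 <- numeric(n_classes)

  structure(list(
    params = p, bn = bn, spec = spec, flags = flags,
    variant = variant, n_classes = as.integer(n_classes),
    attention_ratio = attention_ratio, relational = relational,
    hidden = hidden, zdim = zdim, seed = seed
  ), class = "mvcf_model")
}

#' Number of trainable parameters
#' @param model an `"mvcf_model"` or `"mvcf_fit"`.
#' @return integer parameter count.
#' @export
num_params <- function(model) {
  if (inherits(model, "mvcf_fit")) model <- model$model
  sum(vapply(model$params, length, integer(1)))
}

#' Normalized cross-scale fusion weights
#'
#' Softmax of the learnable fusion logits; a probability vector over the
#' four pyramid levels at every training step.
#'
#' @param model an `"mvcf_model"` or `"mvcf_fit"`.
#' @return numeric vector of length 4 summing to 1.
#' @export
fusion_weights <- function(model) {
  if (inherits(model, "mvcf_fit")) model <- model$model
  if (is.null(model$params$fus.logits)) {
    stop("fusion_weights(): this variant has no fusion unit", call. = FALSE)
  }
  x <- model$params$fus.logits
  e <- exp(x - max(x))
  e / sum(e)
}

# ---- forward pass ---------------------------------------------------------

# x: (B*H0*W0) x 3 pixel matrix (row-major pixels, sample-major rows)
# s: B x 3 standardized sensor matrix
mvcf_forward <- function(model, x, s, training = FALSE, details = FALSE,
                         bn_momentum = 0.1) {
  p <- model$params
  fl <- model$flags
  sp <- model$spec
  ch <- sp$channels
  b <- nrow(s)
  if (ncol(s) != 3) stop("sensor input must have K = 3 channels", call. = FALSE)
  if (nrow(x) != b * sp$h0 * sp$h0) {
    stop(sprintf("image input has %d pixel rows; expected %d x %d x %d",
                 nrow(x), b, sp$h0, sp$h0), call. = FALSE)
  }
  ctx <- new.env(parent = emptyenv())
  ctx$leaves <- list()
  P <- function(name) {
    nd <- ag_leaf(p[[name]])
    ctx$leaves[[name]] <- nd
    nd
  }
  BN <- function(a, name, training) {
    ag_batchnorm(a, P(paste0(name, ".gamma")), P(paste0(name, ".beta")),
                 model$bn[[name]], training = training,
                 momentum = bn_momentum)
  }
  xin <- ag_const(x)
  sin <- ag_const(as.matrix(s))
  hs <- sp$sizes
  shp <- list()

  # backbone
  f <- ag_relu(BN(ag_conv(xin, P("bb.conv1a.W"), P("bb.conv1a.b"), b, hs[1], hs[1]),
                  "bb.bn1a", training))
  f1 <- ag_relu(BN(ag_conv(f, P("bb.conv1b.W"), P("bb.conv1b.b"), b, hs[1], hs[1]),
                   "bb.bn1b", training))
  f2 <- ag_relu(BN(ag_conv(f1, P("bb.conv2.W"), P("bb.conv2.b"), b, hs[1], hs[1],
                           stride = 2L), "bb.bn2", training))
  f3 <- ag_relu(BN(ag_conv(f2, P("bb.conv3.W"), P("bb.conv3.b"), b, hs[2], hs[2],
                           stride = 2L), "bb.bn3", training))
  f4 <- ag_relu(BN(ag_conv(f3, P("bb.conv4.W"), P("bb.conv4.b"), b, hs[3], hs[3],
                           stride = 2L), "bb.bn4", training))
  # global-context stage standing in for the global-scale feature
  g4 <- ag_relu(ag_addbias(ag_mm(ag_gap(f4, b, hs[4]^2), P("bb.gctx.W")),
                           P("bb.gctx.b")))
  f4 <- ag_add(f4, ag_expand(g4, b, hs[4]^2))
  pyr <- list(f1, f2, f3, f4)
  shp$pyramid <- lapply(1:4, function(l) c(hs[l], hs[l], ch[l]))

  # channel attention
  lv <- if (fl$multiscale) 1:4 else 4L
  att <- vector("list", 4)
  attw <- vector("list", 4)
  for (l in lv) {
    z <- ag_gap(pyr[[l]], b, hs[l]^2)
    a <- ag_sigmoid(ag_addbias(ag_mm(
      ag_relu(ag_addbias(ag_mm(z, P(sprintf("att.%d.W1", l))),
                         P(sprintf("att.%d.b1", l)))),
      P(sprintf("att.%d.W2", l))), P(sprintf("att.%d.b2", l))))
    attw[[l]] <- a
    att[[l]] <- ag_mul(pyr[[l]], ag_expand(a, b, hs[l]^2))
  }

  # environmental prior gates
  gates <- NULL
  if (fl$sensor_prior) {
    e1 <- ag_relu(ag_addbias(ag_mm(sin, P("env.W1")), P("env.b1")))
    e2 <- ag_relu(ag_addbias(ag_mm(e1, P("env.W2")), P("env.b2")))
    gates <- vector("list", 4)
    gl <- if (fl$multiscale && fl$collab_head) lv else 4L
    for (l in gl) {
      gates[[l]] <- ag_sigmoid(ag_addbias(ag_mm(e2, P(sprintf("env.head.%d.W", l))),
                                          P(sprintf("env.head.%d.b", l))))
    }
    shp$modulation_head <- dim(p$env.head.4.W)   # 128 x C4
  }
  mod <- vector("list", 4)
  for (l in lv) {
    mod[[l]] <- if (is.null(gates) || is.null(gates[[l]])) att[[l]] else
      ag_mul(att[[l]], ag_expand(gates[[l]], b, hs[l]^2))
  }

  fms <- NULL
  alpha <- NULL
  if (fl$multiscale) {
    proj <- lapply(1:4, function(l) {
      pl <- ag_addbias(ag_mm(att[[l]], P(sprintf("fus.proj.%d.W", l))),
                       P(sprintf("fus.proj.%d.b", l)))
      if (l == 1) pl else
        ag_pixop(pl, pixel_resize_op(hs[l], hs[l], hs[1], hs[1]), b)
    })
    alpha <- ag_softmax_vec(P("fus.logits"))
    fms <- ag_wsum(alpha, proj)
    if (model$relational) {
      fms <- ag_relu(ag_conv(fms, P("rel.W"), P("rel.b"), b, hs[1], hs[1]))
    }
    if (fl$sensor_prior) {
      fms <- ag_mul(fms, ag_expand(gates[[4]], b, hs[1]^2))
    }
    shp$fused <- c(hs[1], hs[1], ch[4])
  }

  if (!fl$multiscale) {
    z <- ag_gap(mod[[4]], b, hs[4]^2)
  } else if (!fl$collab_head && !fl$concat_fusion) {
    z <- ag_gap(fms, b, hs[1]^2)
  } else {
    if (fl$collab_head && !fl$concat_fusion) {
      hh <- ag_relu(ag_addbias(ag_mm(sin, P("head.Wa")), P("head.ba")))
      u <- ag_relu(ag_addbias(ag_mm(hh, P("head.Wb")), P("head.bb")))
      m <- lapply(1:4, function(l) {
        cl <- ag_addbias(ag_mm(u, P(sprintf("head.P.%d", l))),
                         P(sprintf("head.q.%d", l)))
        gate <- ag_mul(mod[[l]], ag_expand(cl, b, hs[l]^2))
        phi <- ag_relu(ag_addbias(ag_mm(gate, P(sprintf("head.phi.%d.W", l))),
                                  P(sprintf("head.phi.%d.b", l))))
        ag_add(mod[[l]], phi)
      })
    } else {
      m <- mod                       # gating replaced by late concatenation
    }
    mb <- lapply(1:4, function(l) {
      if (l == 1) m[[l]] else
        ag_pixop(m[[l]], pixel_resize_op(hs[l], hs[l], hs[1], hs[1]), b)
    })
    cat640 <- ag_concat_cols(mb)
    shp$concat_channels <- ncol(ag_value(cat640))
    fcs <- ag_relu(ag_addbias(ag_mm(cat640, P("head.compress.W")),
                              P("head.compress.b")))
    fcs <- ag_add(fcs, fms)          # fused-map residual
    shp$compressed_channels <- ncol(ag_value(fcs))
    z <- ag_gap(fcs, b, hs[1]^2)
    if (fl$concat_fusion) z <- ag_concat_cols(list(z, sin))
  }

  logits <- ag_addbias(ag_mm(
    ag_relu(ag_addbias(ag_mm(z, P("cls.W1")), P("cls.b1"))),
    P("cls.W2")), P("cls.b2"))
  shp$classifier <- c(ncol(ag_value(z)), model$hidden, model$n_classes)
  shp$sensor_dim <- ncol(s)

  out <- list(logits = logits, leaves = ctx$leaves, shapes = shp,
              alpha = alpha)
  if (details) {
    out$pyramid <- lapply(pyr, ag_value)
    out$attended <- lapply(att, ag_value)
    out$attention_weights <- lapply(attw, ag_value)
    out$gates <- if (is.null(gates)) NULL else lapply(gates, ag_value)
    out$modulated <- lapply(mod, ag_value)
    out$fused <- if (is.null(fms)) NULL else ag_value(fms)
  }
  out
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# stack a list of H x W x 3 arrays into the (B*H*W) x 3 pixel-row matrix
images_to_input <- function(images) {
  do.call(rbind, lapply(images, function(img) {
    cbind(as.vector(t(img[, , 1])), as.vector(t(img[, , 2])),
          as.vector(t(img[, , 3])))
  }))
}

#' Predict class probabilities
#'
#' @param object an `"mvcf_model"`.
#' @param samples an `"aligned_samples"` object, or a list with elements
#'   `images` (list of `H0 x W0 x 3` arrays) and `sensor` (`n x 3` matrix).
#' @param type `"prob"` for the class-probability matrix, `"class"` for
#'   1-based class indices.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return probability matrix (rows sum to 1) or integer class vector.
#' @export
predict.mvcf_model <- function(object, samples, type = c("prob", "class"),
                               batch_size = 64L, ...) {
  type <- match.arg(type)
  n <- length(samples$images)
  probs <- matrix(0, n, object$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- images_to_input(samples$images[idx])
    s <- samples$sensor[idx, , drop = FALSE]
    fw <- mvcf_forward(object, x, s, training = FALSE)
    probs[idx, ] <- softmax_rows(ag_value(fw$logits))
  }
  if (type == "class") max.col(probs, ties.method = "first") else probs
}

#' Forward-pass diagnostics
#'
#' Runs one inference pass and returns every printed structural dimension:
#' pyramid shapes, concatenated and compressed channel widths, classifier
#' widths, modulation-head shape, and the sensor input dimension — plus the
#' intermediate feature maps.
#'
#' @param model an `"mvcf_model"`.
#' @param samples as in [predict.mvcf_model()]; defaults to one random
#'   image/sensor pair at the model's geometry.
#' @return a list with `shapes` and intermediate values.
#' @export
forward_diagnostics <- function(model, samples = NULL) {
  if (is.null(samples)) {
    h0 <- model$spec$h0
    set.seed(0)
    samples <- list(images = list(array(stats::runif(h0 * h0 * 3), c(h0, h0, 3))),
                    sensor = matrix(stats::rnorm(3), 1, 3))
  }
  x <- images_to_input(samples$images)
  fw <- mvcf_forward(model, x, samples$sensor, training = FALSE, details = TRUE)
  fw$probs <- softmax_rows(ag_value(fw$logits))
  fw
}

#' Channel-wise feature modulation
#'
#' Multiplies each channel of a feature map by its gate,
#' `F[h, w, c] <- g[c] * F[h, w, c]`, leaving spatial structure untouched.
#'
#' @param f an `H x W x C` array, or a `(pixels x C)` matrix.
#' @param g numeric gate vector of length `C`.
#' @return the modulated feature in the shape of the input.
#' @export
modulate <- function(f, g) {
  if (is.matrix(f)) {
    if (ncol(f) != length(g)) stop("modulate(): channel mismatch", call. = FALSE)
    return(f * rep(g, each = nrow(f)))
  }
  d <- dim(f)
  if (d[3] != length(g)) stop("modulate(): channel mismatch", call. = FALSE)
  sweep(f, 3, g, "*")
}

#' @export
print.mvcf_model <- function(x, ...) {
  cat(sprintf("Multi-scale vision-sensor classifier (variant: %s)\n",
              paste(x$variant, collapse = "+")))
  cat(sprintf("  pyramid: %s | channels: %s\n",
              paste(x$spec$sizes, collapse = "/"),
              paste(x$spec$channels, collapse = "/")))
  cat(sprintf("  classes: %d | parameters: %s\n", x$n_classes,
              format(num_params(x), big.mark = ",")))
  invisible(x)
}
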