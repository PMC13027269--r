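# Minimal reverse-mode autodiff tape over dense matrices.
#
# Every differentiable quantity is a node: an environment holding `value`
# (a numeric matrix or vector), an accumulated `grad`, and a list of
# (parent, backfn) pairs. Nodes are recorded on a tape in creation order;
# `ag_backward()` walks the tape in reverse, so topological order is free.
# When no tape is active (inference), ops still compute values but record
# nothing, which keeps prediction allocation-light.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_tape_start <- function() {
  .ag$tape <- new.env(parent = emptyenv())
  .ag$tape$nodes <- vector("list", 256L)
  .ag$tape$n <- 0L
  invisible(.ag$tape)
}

ag_tape_stop <- function() {
  tape <- .ag$tape
  .ag$tape <- NULL
  invisible(tape)
}

ag_recording <- function() !is.null(.ag$tape)

ag_node <- function(value, parents = list(), backfns = list(), leaf = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfns <- backfns
  nd$leaf <- leaf
  tape <- .ag$tape
  if (!is.null(tape) && (leaf || length(parents))) {
    n <- tape$n + 1L
    if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[n]] <- nd
    tape$n <- n
  }
  nd
}

ag_const <- function(value) ag_node(value)
ag_leaf <- function(value) ag_node(value, leaf = TRUE)

ag_value <- function(x) if (is.environment(x)) x$value else x

.acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' @noRd
ag_backward <- function(loss) {
  tape <- .ag$tape
  if (is.null(tape)) stop("ag_backward() called with no active tape", call. = FALSE)
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || !length(nd$parents)) next
    for (j in seq_along(nd$parents)) {
      .acc(nd$parents[[j]], nd$backfns[[j]](nd$grad))
    }
  }
  invisible(NULL)
}

# ---- elementary ops -------------------------------------------------------

ag_mm <- function(a, b) {
  v <- ag_value(a) %*% ag_value(b)
  ag_node(v,
    parents = list(a, b),
    backfns = list(
      function(g) g %*% t(ag_value(b)),
      function(g) crossprod(ag_value(a), g)
    ))
}

ag_add <- function(a, b) {
  ag_node(ag_value(a) + ag_value(b),
    parents = list(a, b),
    backfns = list(function(g) g, function(g) g))
}

# bias: b is a vector of length ncol(a)
ag_addbias <- function(a, b) {
  av <- ag_value(a)
  v <- av + rep(ag_value(b), each = nrow(av))
  ag_node(v,
    parents = list(a, b),
    backfns = list(function(g) g, function(g) colSums(g)))
}

ag_mul <- function(a, b) {
  ag_node(ag_value(a) * ag_value(b),
    parents = list(a, b),
    backfns = list(
      function(g) g * ag_value(b),
      function(g) g * ag_value(a)
    ))
}

ag_relu <- function(a) {
  v <- ag_value(a)
  keep <- v > 0
  ag_node(v * keep, parents = list(a), backfns = list(function(g) g * keep))
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ag_value(a)))
  ag_node(v, parents = list(a), backfns = list(function(g) g * v * (1 - v)))
}

# softmax over a plain vector (used for the cross-scale fusion weights)
ag_softmax_vec <- function(a) {
  x <- as.vector(ag_value(a))
  e <- exp(x - max(x))
  p <- e / sum(e)
  ag_node(p, parents = list(a),
    backfns = list(function(g) {
      g <- as.vector(g)
      p * (g - sum(g * p))
    }))
}

# weighted sum of L same-shaped matrices with node weights: sum_l w[l] * xs[[l]]
ag_wsum <- function(w, xs) {
  wv <- as.vector(ag_value(w))
  v <- wv[1] * ag_value(xs[[1]])
  if (length(xs) > 1) for (l in 2:length(xs)) v <- v + wv[l] * ag_value(xs[[l]])
  parents <- c(list(w), xs)
  backfns <- c(
    list(function(g) vapply(xs, function(x) sum(g * ag_value(x)), numeric(1))),
    lapply(seq_along(xs), function(l) {
      force(l)
      function(g) wv[l] * g
    })
  )
  ag_node(v, parents = parents, backfns = backfns)
}

# global average pool: rows of `a` are pixels grouped per sample (hw rows each)
ag_gap <- function(a, b, hw) {
  grp <- rep(seq_len(b), each = hw)
  v <- rowsum(ag_value(a), grp, reorder = FALSE) / hw
  ag_node(v, parents = list(a),
    backfns = list(function(g) g[grp, , drop = FALSE] / hw))
}

# expand a (b x C) matrix to (b*hw x C) by repeating each sample's row
ag_expand <- function(a, b, hw) {
  grp <- rep(seq_len(b), each = hw)
  v <- ag_value(a)[grp, , drop = FALSE]
  ag_node(v, parents = list(a),
    backfns = list(function(g) rowsum(g, grp, reorder = FALSE)))
}

ag_concat_cols <- function(xs) {
  vals <- lapply(xs, ag_value)
  v <- do.call(cbind, vals)
  nc <- vapply(vals, ncol, integer(1))
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  backfns <- lapply(seq_along(xs), function(l) {
    force(l)
    function(g) g[, starts[l]:ends[l], drop = FALSE]
  })
  ag_node(v, parents = xs, backfns = backfns)
}

ag_slice_cols <- function(a, from, to) {
  v <- ag_value(a)[, from:to, drop = FALSE]
  nc <- ncol(ag_value(a))
  ag_node(v, parents = list(a),
    backfns = list(function(g) {
      out <- matrix(0, nrow(g), nc)
      out[, from:to] <- g
      out
    }))
}

# ---- structured ops -------------------------------------------------------

# im2col patch extraction. `plan` comes from conv_plan(); columns of the
# result hold, for each of the K kernel offsets, all Cin input channels.
ag_im2col <- function(a, plan) {
  av <- ag_value(a)
  cin <- ncol(av)
  k <- length(plan$idx)
  m <- matrix(0, plan$n_out, k * cin)
  for (kk in seq_len(k)) {
    ids <- plan$idx[[kk]]
    ok <- plan$ok[[kk]]
    cols <- ((kk - 1L) * cin + 1L):(kk * cin)
    m[ok, cols] <- av[ids, , drop = FALSE]
  }
  ag_node(m, parents = list(a),
    backfns = list(function(g) {
      dx <- matrix(0, nrow(av), cin)
      for (kk in seq_len(k)) {
        ids <- plan$idx[[kk]]
        ok <- plan$ok[[kk]]
        cols <- ((kk - 1L) * cin + 1L):(kk * cin)
        dx[ids, ] <- dx[ids, , drop = FALSE] + g[ok, cols, drop = FALSE]
      }
      dx
    }))
}

# apply a (sparse) pixel-space linear operator U per sample. Rows of `a`
# are sample-major pixels, so a zero-copy reshape to (hw, b*C) lets all
# samples share one sparse multiply.
.pixop_apply <- function(x, u, b, hw_in, hw_out) {
  nc <- ncol(x)
  dim(x) <- NULL
  xp <- matrix(x, hw_in, b * nc)
  yp <- u %*% xp
  if (!is.matrix(yp)) yp <- as.matrix(yp)
  dim(yp) <- NULL
  matrix(yp, b * hw_out, nc)
}

ag_pixop <- function(a, u, b) {
  av <- ag_value(a)
  hw_in <- nrow(av) %/% b
  hw_out <- nrow(u)
  v <- .pixop_apply(av, u, b, hw_in, hw_out)
  ag_node(v, parents = list(a),
    backfns = list(function(g) {
      .pixop_apply(g, Matrix::t(u), b, hw_out, hw_in)
    }))
}

# batch normalization over rows, per column; population variance.
# `state` is an environment with run_mean / run_var, updated as a side
# effect in training mode and used verbatim in eval mode.
ag_batchnorm <- function(a, gamma, beta, state, training = TRUE, momentum = 0.1,
                         eps = 1e-5) {
  av <- ag_value(a)
  n <- nrow(av)
  if (training) {
    mu <- colMeans(av)
    xc <- av - rep(mu, each = n)
    va <- colMeans(xc * xc)
    state$run_mean <- (1 - momentum) * state$run_mean + momentum * mu
    state$run_var <- (1 - momentum) * state$run_var + momentum * va
  } else {
    mu <- state$run_mean
    va <- state$run_var
    xc <- av - rep(mu, each = n)
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * rep(inv, each = n)
  gv <- ag_value(gamma)
  v <- xhat * rep(gv, each = n) + rep(ag_value(beta), each = n)
  if (training) {
    ag_node(v,
      parents = list(a, gamma, beta),
      backfns = list(
        function(g) {
          # exact gradient for population-variance batch norm
          m1 <- colMeans(g)
          m2 <- colMeans(g * xhat)
          (g - rep(m1, each = n) - xhat * rep(m2, each = n)) *
            rep(gv * inv, each = n)
        },
        function(g) colSums(g * xhat),
        function(g) colSums(g)
      ))
  } else {
    ag_node(v,
      parents = list(a, gamma, beta),
      backfns = list(
        function(g) g * rep(gv * inv, each = n),
        function(g) colSums(g * xhat),
        function(g) colSums(g)
      ))
  }
}

# fused softmax + mean cross-entropy; labels are 1-based class indices
ag_softmax_ce <- function(logits, labels) {
  lv <- ag_value(logits)
  n <- nrow(lv)
  lv <- lv - apply(lv, 1, max)
  e <- exp(lv)
  p <- e / rowSums(e)
  picked <- p[cbind(seq_len(n), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  y <- matrix(0, n, ncol(lv))
  y[cbind(seq_len(n), labels)] <- 1
  node <- ag_node(loss, parents = list(logits),
    backfns = list(function(g) as.numeric(g) * (p - y) / n))
  list(loss = node, probs = p)
}

# ---- convolution geometry -------------------------------------------------

.conv_plans <- new.env(parent = emptyenv())

# index plan for im2col: for each kernel offset, the input-row index of every
# output pixel (b-major, then row-major pixels), with out-of-bounds dropped
conv_plan <- function(b, h, w, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  key <- paste(b, h, w, k, stride, pad, sep = "_")
  hit <- .conv_plans[[key]]
  if (!is.null(hit)) return(hit)
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  n_out <- b * ho * wo
  bs <- rep(seq_len(b), each = ho * wo)
  yo <- rep(rep(seq_len(ho), each = wo), times = b)
  xo <- rep(rep(seq_len(wo), times = ho), times = b)
  idx <- vector("list", k * k)
  ok <- vector("list", k * k)
  kk <- 0L
  for (ky in seq_len(k)) {
    for (kx in seq_len(k)) {
      kk <- kk + 1L
      yi <- (yo - 1L) * stride + ky - pad
      xi <- (xo - 1L) * stride + kx - pad
      valid <- yi >= 1L & yi <= h & xi >= 1L & xi <= w
      id <- (bs - 1L) * h * w + (yi - 1L) * w + xi
      idx[[kk]] <- id[valid]
      ok[[kk]] <- which(valid)
    }
  }
  plan <- list(ho = ho, wo = wo, n_out = n_out, idx = idx, ok = ok, k2 = k * k)
  .conv_plans[[key]] <- plan
  plan
}

# 3x3 (or kxk) convolution as im2col + matmul; weight shape (k*k*Cin, Cout)
ag_conv <- function(a, weight, bias, b, h, w, k = 3L, stride = 1L) {
  plan <- conv_plan(b, h, w, k, stride)
  m <- ag_im2col(a, plan)
  out <- ag_addbias(ag_mm(m, weight), bias)
  attr(out, "ho") <- plan$ho
  attr(out, "wo") <- plan$wo
  out
}
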