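# The 3D convolutional encoder-decoder mapping a reversed-PE image pair to a
# displacement field, with hand-rolled forward/backward passes.  Convolutions
# are 3x3x3 (zero padding 1) evaluated as im2col + GEMM; the encoder
# downsamples by stride-2 convolutions over 4 levels (hence the
# divisible-by-16 size normalization), the decoder upsamples back with skip
# concatenations of the matching encoder features and finally of the input
# pair, and a near-zero-initialized 3x3x3 head regresses the field.

#' Network architecture configuration
#'
#' @param norm_kind `"batch"` (default), `"instance"`, or `"none"`.
#' @param upsample_kind `"upsample"` (parameter-free nearest-neighbour x2,
#'   default) or `"transposed_conv"` (learned 2x2x2 stride-2 kernels).
#' @param head_kind `"field3d"` (3-channel displacement head, default) or
#'   `"field1d"` (single channel on the phase-encoding axis only).
#' @param pe_axis phase-encoding axis, `"x"`, `"y"` or `"z"`; used by the
#'   1D head.
#' @param encoder_channels four integers: output channels of the stride-2
#'   encoder stages.
#' @param decoder_channels six integers: output channels of the decoder
#'   convolutions (the last two run at full resolution).
#' @param leaky_slope negative-side slope of the leaky rectifier.
#' @param seed integer seed making parameter initialization deterministic.
#' @return object of class `sac_net_config`.
#' @export
network_config <- function(norm_kind = c("batch", "instance", "none"),
                           upsample_kind = c("upsample", "transposed_conv"),
                           head_kind = c("field3d", "field1d"),
                           pe_axis = c("y", "x", "z"),
                           encoder_channels = c(16L, 32L, 32L, 32L),
                           decoder_channels = c(32L, 32L, 32L, 32L, 8L, 8L),
                           leaky_slope = 0.2, seed = 1L) {
  cfg <- list(norm_kind = match.arg(norm_kind),
              upsample_kind = match.arg(upsample_kind),
              head_kind = match.arg(head_kind),
              pe_axis = match.arg(pe_axis),
              encoder_channels = as.integer(encoder_channels),
              decoder_channels = as.integer(decoder_channels),
              leaky_slope = leaky_slope, seed = as.integer(seed))
  if (length(cfg$encoder_channels) != 4L)
    stop("encoder must have exactly 4 stride-2 levels", call. = FALSE)
  if (length(cfg$decoder_channels) != 6L)
    stop("decoder must have exactly 6 convolution stages", call. = FALSE)
  structure(cfg, class = "sac_net_config")
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

glorot_conv <- function(cin, cout, k = 27L) {
  lim <- sqrt(6 / (k * cin + k * cout))
  matrix(runif(k * cin * cout, -lim, lim), k * cin, cout)
}

new_conv_layer <- function(cin, cout, norm_kind) {
  layer <- list(kind = "conv", cin = cin, cout = cout,
                W = glorot_conv(cin, cout), b = numeric(cout), norm = NULL)
  if (norm_kind %in% c("batch", "instance"))
    layer$norm <- list(kind = norm_kind, gamma = rep(1, cout),
                       beta = numeric(cout), rmean = numeric(cout),
                       rvar = rep(1, cout), seen = FALSE)
  layer
}

new_tconv_layer <- function(c_io) {
  list(kind = "tconv", cin = c_io, cout = c_io,
       W = glorot_conv(c_io, c_io, k = 8L), b = numeric(c_io))
}

#' Build the encoder-decoder network
#'
#' Instantiates the trainable mapping `(I1, I2) -> U` described by a
#' [network_config()]: a two-channel input, four stride-2 encoder stages,
#' six decoder convolutions with x2 resolution increases and skip
#' concatenations (encoder levels 3, 2, 1, then the raw input pair), and a
#' 3x3x3 output head initialized near zero so the initial predicted field is
#' essentially the identity.  Initialization is seed-deterministic.
#'
#' @param config a [network_config()].
#' @return object of class `sac_network`.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "sac_net_config"))
  e <- config$encoder_channels
  d <- config$decoder_channels
  set.seed(config$seed)
  layers <- list()
  cin <- c(2L, e[1:3])
  for (i in 1:4)
    layers[[paste0("enc", i)]] <- new_conv_layer(cin[i], e[i], config$norm_kind)
  dec_in <- c(e[4], d[1] + e[3], d[2] + e[2], d[3] + e[1], d[4] + 2L, d[5])
  for (i in 1:6)
    layers[[paste0("dec", i)]] <- new_conv_layer(dec_in[i], d[i], config$norm_kind)
  if (config$upsample_kind == "transposed_conv")
    for (i in 1:4)
      layers[[paste0("up", i)]] <- new_tconv_layer(d[i])
  head_ch <- if (config$head_kind == "field3d") 3L else 1L
  head <- list(kind = "conv", cin = d[6], cout = head_ch,
               W = matrix(rnorm(27 * d[6] * head_ch, 0, 1e-3),
                          27 * d[6], head_ch),
               b = numeric(head_ch), norm = NULL)
  layers$head <- head
  structure(list(config = config, layers = layers), class = "sac_network")
}

#' Count trainable parameters
#'
#' Counts convolution weights and biases plus normalization scale/shift
#' pairs; running statistics are not trainable and are excluded.
#'
#' @param net a `sac_network`.
#' @return integer parameter count.
#' @export
n_parameters <- function(net) {
  stopifnot(inherits(net, "sac_network"))
  total <- 0L
  for (layer in net$layers) {
    total <- total + length(layer$W) + length(layer$b)
    if (!is.null(layer$norm))
      total <- total + length(layer$norm$gamma) + length(layer$norm$beta)
  }
  total
}

#' @export
print.sac_network <- function(x, ...) {
  cat(sprintf("<sac_network %s/%s/%s head, %d trainable parameters>\n",
              x$config$norm_kind, x$config$upsample_kind, x$config$head_kind,
              n_parameters(x)))
  invisible(x)
}

# --- low-level layer passes ---------------------------------------------

# im2col slab size: keep the patch matrix under ~160 MB of doubles.
conv_chunk_slabs <- function(XoYo, Zo, ncol_patch) {
  per_slab <- XoYo * ncol_patch
  max(1L, min(Zo, as.integer(floor(2e7 / per_slab))))
}

conv_forward <- function(x, W, b, stride) {
  d <- dim(x)
  Xo <- (d[1] - 1L) %/% stride + 1L
  Yo <- (d[2] - 1L) %/% stride + 1L
  Zo <- (d[3] - 1L) %/% stride + 1L
  cout <- ncol(W)
  out <- array(0, c(Xo, Yo, Zo, cout))
  step <- conv_chunk_slabs(Xo * Yo, Zo, nrow(W))   # patch width = 27 * Cin
  z0 <- 0L
  while (z0 < Zo) {
    zn <- min(step, Zo - z0)
    M <- im2col3(x, stride, z0, zn) %*% W
    for (j in seq_len(cout)) M[, j] <- M[, j] + b[j]
    out[, , (z0 + 1L):(z0 + zn), ] <- array(M, c(Xo, Yo, zn, cout))
    z0 <- z0 + zn
  }
  out
}

# Training-time conv: computes the patch matrix once and keeps it for the
# backward pass (desk-scale volumes; inference uses the chunked conv_forward).
conv_forward_cached <- function(x, W, b, stride) {
  d <- dim(x)
  Xo <- (d[1] - 1L) %/% stride + 1L
  Yo <- (d[2] - 1L) %/% stride + 1L
  Zo <- (d[3] - 1L) %/% stride + 1L
  P <- im2col3(x, stride, 0L, Zo)
  out <- array(P %*% W, c(Xo, Yo, Zo, ncol(W)))
  list(out = sweep(out, 4, b, "+"), P = P, xdim = d)
}

conv_backward <- function(P, xdim, W, stride, gout) {
  G <- matrix(gout, ncol = ncol(W))
  list(gW = crossprod(P, G), gb = colSums(G),
       gx = col2im3(G %*% t(W), xdim, stride))
}

# Channel-wise normalization keeps transients to a few channel slices
# rather than whole-activation copies (volumes can run to millions of
# voxels at inference time).
norm_forward <- function(layer, z, mode, need_cache = FALSE) {
  nm <- layer$norm
  if (is.null(nm)) return(list(y = z, cache = NULL, norm = NULL))
  d <- dim(z)
  C <- d[4]
  use_running <- nm$kind == "batch" && mode == "eval" && isTRUE(nm$seen)
  mu <- numeric(C); vv <- numeric(C)
  y <- z
  xhat <- if (need_cache) array(0, d) else NULL
  for (ch in seq_len(C)) {
    zi <- z[, , , ch]
    if (use_running) {
      mu[ch] <- nm$rmean[ch]; vv[ch] <- nm$rvar[ch]
    } else {
      # batch/instance statistics of the current volume; an untrained batch
      # layer also lands here in eval mode, where 0/1 running statistics
      # would be meaningless for un-normalized intensities
      mu[ch] <- mean(zi)
      vv[ch] <- mean(zi * zi) - mu[ch]^2
    }
    xh <- (zi - mu[ch]) / sqrt(vv[ch] + BN_EPS)
    if (need_cache) xhat[, , , ch] <- xh
    y[, , , ch] <- xh * nm$gamma[ch] + nm$beta[ch]
  }
  if (nm$kind == "batch" && mode == "train") {
    if (isTRUE(nm$seen)) {
      nm$rmean <- BN_MOMENTUM * nm$rmean + (1 - BN_MOMENTUM) * mu
      nm$rvar <- BN_MOMENTUM * nm$rvar + (1 - BN_MOMENTUM) * vv
    } else {
      nm$rmean <- mu
      nm$rvar <- vv
      nm$seen <- TRUE
    }
  }
  list(y = y,
       cache = if (need_cache) list(xhat = xhat, inv = 1 / sqrt(vv + BN_EPS))
               else NULL,
       norm = nm)
}

norm_backward <- function(layer, cache, gy, train_stats) {
  nm <- layer$norm
  d <- dim(gy)
  C <- d[4]
  n <- prod(d[1:3])
  gz <- gy
  ggamma <- numeric(C); gbeta <- numeric(C)
  for (ch in seq_len(C)) {
    g <- gy[, , , ch]
    xh <- cache$xhat[, , , ch]
    ggamma[ch] <- sum(g * xh)
    gbeta[ch] <- sum(g)
    if (train_stats) {
      # statistics were computed from this activation: full normalization grad
      gz[, , , ch] <- (g - gbeta[ch] / n - xh * (ggamma[ch] / n)) *
        (nm$gamma[ch] * cache$inv[ch])
    } else {
      gz[, , , ch] <- g * (nm$gamma[ch] * cache$inv[ch])
    }
  }
  list(gz = gz, ggamma = ggamma, gbeta = gbeta)
}

lrelu_forward <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  list(y = x, neg = neg)
}

upsample_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

upsample_backward <- function(g) {
  d <- dim(g)
  g <- g[seq(1, d[1], 2), , , , drop = FALSE] + g[seq(2, d[1], 2), , , , drop = FALSE]
  g <- g[, seq(1, d[2], 2), , , drop = FALSE] + g[, seq(2, d[2], 2), , , drop = FALSE]
  g[, , seq(1, d[3], 2), , drop = FALSE] + g[, , seq(2, d[3], 2), , drop = FALSE]
}

tconv_forward <- function(layer, x) {
  d <- dim(x)
  C <- d[4]
  Xm <- matrix(x, ncol = C)
  out <- array(0, c(2L * d[1], 2L * d[2], 2L * d[3], layer$cout))
  o <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    M <- Xm %*% layer$W[o * C + seq_len(C), , drop = FALSE]
    out[seq(1 + dx, 2 * d[1], 2), seq(1 + dy, 2 * d[2], 2),
        seq(1 + dz, 2 * d[3], 2), ] <- array(M, c(d[1:3], layer$cout))
    o <- o + 1L
  }
  sweep(out, 4, layer$b, "+")
}

tconv_backward <- function(layer, x, gout) {
  d <- dim(x)
  C <- d[4]
  Xm <- matrix(x, ncol = C)
  gW <- matrix(0, 8L * C, layer$cout)
  gx <- matrix(0, nrow(Xm), C)
  gb <- numeric(layer$cout)
  o <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    Gs <- gout[seq(1 + dx, 2 * d[1], 2), seq(1 + dy, 2 * d[2], 2),
               seq(1 + dz, 2 * d[3], 2), , drop = FALSE]
    Gm <- matrix(Gs, ncol = layer$cout)
    rows <- o * C + seq_len(C)
    gW[rows, ] <- crossprod(Xm, Gm)
    gx <- gx + Gm %*% t(layer$W[rows, , drop = FALSE])
    gb <- gb + colSums(Gm)
    o <- o + 1L
  }
  dim(gx) <- d
  list(gW = gW, gb = gb, gx = gx)
}

concat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# conv -> norm -> leaky ReLU; returns output plus the cache needed to
# backpropagate (patch matrix, normalization intermediates, sign mask).
block_forward <- function(layer, x, stride, mode, slope, keep_cache) {
  if (keep_cache) {
    cf <- conv_forward_cached(x, layer$W, layer$b, stride)
    z <- cf$out
  } else {
    z <- conv_forward(x, layer$W, layer$b, stride)
  }
  nf <- norm_forward(layer, z, mode, need_cache = keep_cache)
  af <- lrelu_forward(nf$y, slope)
  cache <- if (keep_cache)
    list(P = cf$P, xdim = cf$xdim, norm = nf$cache, neg = af$neg,
         stride = stride) else NULL
  list(y = af$y, cache = cache, norm = nf$norm)
}

block_backward <- function(layer, cache, gy, slope, train_stats) {
  gy[cache$neg] <- slope * gy[cache$neg]
  if (is.null(layer$norm)) {
    gz <- gy
    ggamma <- NULL; gbeta <- NULL
  } else {
    nb <- norm_backward(layer, cache$norm, gy, train_stats)
    gz <- nb$gz; ggamma <- nb$ggamma; gbeta <- nb$gbeta
  }
  cb <- conv_backward(cache$P, cache$xdim, layer$W, cache$stride, gz)
  list(gW = cb$gW, gb = cb$gb, ggamma = ggamma, gbeta = gbeta, gx = cb$gx)
}

up_forward <- function(net, i, x, keep_cache) {
  if (net$config$upsample_kind == "upsample")
    list(y = upsample_forward(x), cache = if (keep_cache) list(kind = "up") else NULL)
  else {
    layer <- net$layers[[paste0("up", i)]]
    list(y = tconv_forward(layer, x),
         cache = if (keep_cache) list(kind = "tconv", x = x) else NULL)
  }
}

# Full forward pass on a padded (X, Y, Z, 2) input.  mode "train" uses batch
# statistics, updates running statistics, and (with cache=TRUE) retains all
# intermediates for net_backward.
net_forward <- function(net, x, mode = c("eval", "train"), cache = FALSE) {
  mode <- match.arg(mode)
  slope <- net$config$leaky_slope
  cc <- list()
  acts <- list()
  run <- function(name, input, stride) {
    bf <- block_forward(net$layers[[name]], input, stride, mode, slope, cache)
    if (!is.null(bf$norm)) net$layers[[name]]$norm <<- bf$norm
    if (cache) cc[[name]] <<- bf$cache
    bf$y
  }
  e1 <- run("enc1", x, 2L)
  e2 <- run("enc2", e1, 2L)
  e3 <- run("enc3", e2, 2L)
  e4 <- run("enc4", e3, 2L)
  d1 <- run("dec1", e4, 1L); rm(e4)
  u1 <- up_forward(net, 1L, d1, cache); if (cache) cc$u1 <- u1$cache
  rm(d1)
  c1 <- concat4(u1$y, e3); rm(u1, e3)
  d2 <- run("dec2", c1, 1L); rm(c1)
  u2 <- up_forward(net, 2L, d2, cache); if (cache) cc$u2 <- u2$cache
  rm(d2)
  c2 <- concat4(u2$y, e2); rm(u2, e2)
  d3 <- run("dec3", c2, 1L); rm(c2)
  u3 <- up_forward(net, 3L, d3, cache); if (cache) cc$u3 <- u3$cache
  rm(d3)
  c3 <- concat4(u3$y, e1); rm(u3, e1)
  d4 <- run("dec4", c3, 1L); rm(c3)
  u4 <- up_forward(net, 4L, d4, cache); if (cache) cc$u4 <- u4$cache
  rm(d4)
  c4 <- concat4(u4$y, x); rm(u4, x)
  d5 <- run("dec5", c4, 1L); rm(c4)
  d6 <- run("dec6", d5, 1L); rm(d5)
  if (cache) {
    cf <- conv_forward_cached(d6, net$layers$head$W, net$layers$head$b, 1L)
    out <- cf$out
    cc$head_P <- cf$P
    cc$head_xdim <- cf$xdim
  } else {
    out <- conv_forward(d6, net$layers$head$W, net$layers$head$b, 1L)
  }
  list(out = out, cache = cc, net = net)
}

# Backward pass through the whole network given the gradient at the head
# output; returns per-layer parameter gradients.  Encoder outputs receive
# gradient both from the next encoder stage and from their skip branch.
net_backward <- function(net, cache, gout) {
  slope <- net$config$leaky_slope
  grads <- list()
  hb <- conv_backward(cache$head_P, cache$head_xdim, net$layers$head$W, 1L, gout)
  grads$head <- list(gW = hb$gW, gb = hb$gb)
  back <- function(name, g) {
    bb <- block_backward(net$layers[[name]], cache[[name]], g, slope, TRUE)
    grads[[name]] <<- list(gW = bb$gW, gb = bb$gb,
                           ggamma = bb$ggamma, gbeta = bb$gbeta)
    bb$gx
  }
  up_back <- function(i, g) {
    if (net$config$upsample_kind == "upsample") return(upsample_backward(g))
    layer <- net$layers[[paste0("up", i)]]
    tb <- tconv_backward(layer, cache[[paste0("u", i)]]$x, g)
    grads[[paste0("up", i)]] <<- list(gW = tb$gW, gb = tb$gb)
    tb$gx
  }
  d <- net$config$decoder_channels
  g <- back("dec6", hb$gx)
  g <- back("dec5", g)
  gu4 <- g[, , , seq_len(d[4]), drop = FALSE]   # input-pair slice discarded
  g <- back("dec4", up_back(4L, gu4))
  gu3 <- g[, , , seq_len(d[3]), drop = FALSE]
  ge1_skip <- g[, , , -seq_len(d[3]), drop = FALSE]
  g <- back("dec3", up_back(3L, gu3))
  gu2 <- g[, , , seq_len(d[2]), drop = FALSE]
  ge2_skip <- g[, , , -seq_len(d[2]), drop = FALSE]
  g <- back("dec2", up_back(2L, gu2))
  gu1 <- g[, , , seq_len(d[1]), drop = FALSE]
  ge3_skip <- g[, , , -seq_len(d[1]), drop = FALSE]
  g <- back("dec1", up_back(1L, gu1))           # gradient w.r.t. e4
  g <- back("enc4", g)
  g <- back("enc3", g + ge3_skip)
  g <- back("enc2", g + ge2_skip)
  invisible(back("enc1", g + ge1_skip))
  grads
}

#' Predict the displacement field for a reversed-PE pair
#'
#' Stacks the two volumes as channels, zero-pads each spatial extent up to a
#' multiple of 16, runs the network in evaluation mode, and crops the output
#' back to the input extents.  With a `field1d` head the returned field has
#' the prediction on the phase-encoding axis and exact zeros elsewhere.
#'
#' @param net a trained (or fresh) `sac_network`.
#' @param i1,i2 the two reversed-PE volumes (identical extents).
#' @return list of class `sac_prediction` with `field` (a `sac_field`),
#'   `padded_extents` and `original_extents`.
#' @export
predict_field <- function(net, i1, i2) {
  a1 <- as_vol_array(i1); a2 <- as_vol_array(i2)
  if (!all(dim(a1) == dim(a2)))
    stop("the two volumes must have identical extents", call. = FALSE)
  x <- array(c(a1, a2), c(dim(a1), 2L))
  pad <- pad_to_multiple(x, 16L)
  fw <- net_forward(net, pad$data, mode = "eval", cache = FALSE)
  out <- crop_to_size(fw$out, pad$extents)
  if (net$config$head_kind == "field3d") {
    u <- out
  } else {
    u <- array(0, c(pad$extents, 3L))
    u[, , , match(net$config$pe_axis, c("x", "y", "z"))] <- out[, , , 1]
  }
  structure(list(field = displacement_field(u),
                 padded_extents = dim(pad$data)[1:3],
                 original_extents = pad$extents),
            class = "sac_prediction")
}

#' Correct a reversed-PE pair with a trained network
#'
#' Convenience wrapper: [predict_field()] then [correct_pair()].  No
#' anatomical volume is involved; inference needs only the image pair.
#'
#' @inheritParams predict_field
#' @return list with `e1`, `e2` (corrected volumes) and `field`.
#' @export
correct_with_network <- function(net, i1, i2) {
  pred <- predict_field(net, i1, i2)
  e <- correct_pair(i1, i2, pred$field)
  list(e1 = e$e1, e2 = e$e2, field = pred$field)
}

# --- parameter bookkeeping ----------------------------------------------

trainable_fields <- function(layer) {
  f <- c("W", "b")
  if (!is.null(layer$norm)) f <- c(f, "gamma", "beta")
  f
}

get_param <- function(net, name, field) {
  if (field %in% c("gamma", "beta")) net$layers[[name]]$norm[[field]]
  else net$layers[[name]][[field]]
}

set_param <- function(net, name, field, value) {
  if (field %in% c("gamma", "beta")) net$layers[[name]]$norm[[field]] <- value
  else net$layers[[name]][[field]] <- value
  net
}

# Flat named list of all trainable arrays, in a fixed traversal order.
net_params <- function(net) {
  out <- list()
  for (name in names(net$layers)) {
    for (field in trainable_fields(net$layers[[name]]))
      out[[paste(name, field, sep = ".")]] <- get_param(net, name, field)
  }
  out
}

net_set_params <- function(net, params) {
  for (key in names(params)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    cur <- get_param(net, parts[1], parts[2])
    if (length(cur) != length(params[[key]]))
      stop("checkpoint transfer error: shape mismatch for ", key, call. = FALSE)
    v <- as.vector(params[[key]])
    if (!is.null(dim(cur))) dim(v) <- dim(cur)
    net <- set_param(net, parts[1], parts[2], v)
  }
  net
}

# Gradients in the same flat naming as net_params (missing entries = 0).
grads_to_flat <- function(net, grads) {
  out <- list()
  map <- c(W = "gW", b = "gb", gamma = "ggamma", beta = "gbeta")
  for (name in names(net$layers)) {
    for (field in trainable_fields(net$layers[[name]])) {
      g <- grads[[name]][[map[[field]]]]
      if (is.null(g)) g <- array(0, dim(as.array(get_param(net, name, field))))
      out[[paste(name, field, sep = ".")]] <- g
    }
  }
  out
}

# --- checkpoints ---------------------------------------------------------

#' Save network parameters to a plain-text checkpoint
#'
#' Writes all trainable parameters and normalization running statistics to
#' `path` (text, full double precision) and the architecture configuration
#' to `<path>.cfg` as a YAML key/value document.
#'
#' @param net a `sac_network`.
#' @param path checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sacnet-checkpoint-v1", con)
  dump_arr <- function(key, v) {
    writeLines(sprintf("@%s %d", key, length(v)), con)
    writeLines(paste(sprintf("%.17g", as.vector(v)), collapse = " "), con)
  }
  for (name in names(net$layers)) {
    layer <- net$layers[[name]]
    for (field in trainable_fields(layer))
      dump_arr(paste(name, field, sep = "."), get_param(net, name, field))
    if (!is.null(layer$norm)) {
      dump_arr(paste(name, "rmean", sep = "."), layer$norm$rmean)
      dump_arr(paste(name, "rvar", sep = "."), layer$norm$rvar)
      dump_arr(paste(name, "seen", sep = "."), as.numeric(isTRUE(layer$norm$seen)))
    }
  }
  yaml::write_yaml(unclass(net$config), paste0(path, ".cfg"))
  invisible(path)
}

#' Load a network from a checkpoint
#'
#' Rebuilds the architecture from `<path>.cfg` and restores all parameters
#' and running statistics from `path`.
#'
#' @param path checkpoint file path written by [save_checkpoint()].
#' @return a `sac_network`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".cfg")))
    stop("checkpoint or its .cfg companion not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(paste0(path, ".cfg"))
  config <- network_config(norm_kind = cfg$norm_kind,
                           upsample_kind = cfg$upsample_kind,
                           head_kind = cfg$head_kind, pe_axis = cfg$pe_axis,
                           encoder_channels = cfg$encoder_channels,
                           decoder_channels = cfg$decoder_channels,
                           leaky_slope = cfg$leaky_slope, seed = cfg$seed)
  net <- build_network(config)
  lines <- readLines(path)
  if (lines[1] != "sacnet-checkpoint-v1")
    stop("not a sacnet checkpoint: ", path, call. = FALSE)
  i <- 2L
  while (i < length(lines)) {
    hdr <- strsplit(sub("^@", "", lines[i]), " ")[[1]]
    key <- hdr[1]; n <- as.integer(hdr[2])
    vals <- as.numeric(strsplit(lines[i + 1L], " ")[[1]])
    if (length(vals) != n)
      stop("corrupt checkpoint entry ", key, call. = FALSE)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    name <- parts[1]; field <- parts[2]
    if (field %in% c("rmean", "rvar")) {
      net$layers[[name]]$norm[[field]] <- vals
    } else if (field == "seen") {
      net$layers[[name]]$norm$seen <- vals > 0
    } else {
      cur <- get_param(net, name, field)
      if (length(cur) != n)
        stop("checkpoint transfer error: shape mismatch for ", key, call. = FALSE)
      if (!is.null(dim(cur))) dim(vals) <- dim(cur)
      net <- set_param(net, name, field, vals)
    }
    i <- i + 2L
  }
  net
}
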