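# Self-supervised training: Adam on the batch-mean of the per-pair objective
# (similarity + smoothness + optional anatomy), with subject-level splitting,
# per-epoch validation tracking, and warm starts from a checkpoint.

#' Training configuration
#'
#' Defaults follow the method's protocol: Adam with learning rate 0.001 and
#' exponential decay rates 0.9 / 0.999, a 9:1 train/validation split, and a
#' fixed epoch budget (1500 at full scale; configurable for desk scale).
#'
#' @param learning_rate Adam step size.
#' @param adam_beta1,adam_beta2 Adam exponential decay rates.
#' @param epochs number of passes over the training pairs.
#' @param batch_size pairs per parameter update.
#' @param loss_weights a [loss_weights()] object.
#' @param seed master seed for initialization-independent randomness
#'   (shuffling, splitting).
#' @param warm_start_checkpoint optional path to a checkpoint whose
#'   parameters initialize the network (shapes must match).
#' @param validation_fraction fraction of pairs held out for validation.
#' @return object of class `sac_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, epochs = 1500L, batch_size = 1L,
                         loss_weights = sacnet::loss_weights(),
                         seed = 1L, warm_start_checkpoint = NULL,
                         validation_fraction = 0.1) {
  stopifnot(validation_fraction > 0, validation_fraction < 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 loss_weights = loss_weights, seed = as.integer(seed),
                 warm_start_checkpoint = warm_start_checkpoint,
                 validation_fraction = validation_fraction),
            class = "sac_train_config")
}

#' Split subjects into train / validation / test sets
#'
#' Subject-level randomized split: every subject lands in exactly one set, so
#' no image pair of a held-out subject can leak into training.  Counts use
#' largest-remainder rounding of `fractions`; the draw is seed-deterministic.
#'
#' @param subject_ids character or integer vector of subject identifiers.
#' @param fractions length-3 non-negative fractions summing to 1.
#' @param seed integer seed.
#' @return list with `train`, `validation`, `test` id vectors.
#' @export
split_subjects <- function(subject_ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(subject_ids) == 0) stop("no subjects to split", call. = FALSE)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids", call. = FALSE)
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  n <- length(subject_ids)
  if (n < sum(fractions > 0))
    stop("fewer subjects than non-empty splits", call. = FALSE)
  counts <- floor(n * fractions)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_frac <- order(n * fractions - counts, decreasing = TRUE)
    counts[order_frac[seq_len(rem)]] <- counts[order_frac[seq_len(rem)]] + 1
  }
  set.seed(seed)
  ids <- sample(subject_ids)
  list(train = ids[seq_len(counts[1])],
       validation = ids[counts[1] + seq_len(counts[2])],
       test = ids[counts[1] + counts[2] + seq_len(counts[3])])
}

# Adam update; state carries first/second moment estimates and step count.
adam_step <- function(params, grads, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  corr <- lr * sqrt(1 - b2^state$t) / (1 - b1^state$t)
  for (key in names(params)) {
    g <- as.vector(grads[[key]])
    state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * g
    state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * g^2
    step <- corr * state$m[[key]] / (sqrt(state$v[[key]]) + eps)
    params[[key]] <- params[[key]] - array(step, dim(as.array(params[[key]])))
  }
  list(params = params, state = state)
}

# Prepare one training pair: validate, pad to /16, cache padded stacks.
prep_pair <- function(pair, need_anat) {
  i1 <- as_vol_array(pair$i1); i2 <- as_vol_array(pair$i2)
  if (!all(dim(i1) == dim(i2)))
    stop("pair volumes must have identical extents", call. = FALSE)
  anat <- NULL
  if (!is.null(pair$anat)) {
    anat <- as_vol_array(pair$anat)
    if (!all(dim(anat) == dim(i1)))
      stop("anatomical volume extents must match the pair", call. = FALSE)
  } else if (need_anat) {
    stop("gamma_anat > 0 requires an anatomical volume for every pair",
         call. = FALSE)
  }
  pad <- pad_to_multiple(array(c(i1, i2), c(dim(i1), 2L)), 16L)
  list(i1 = i1, i2 = i2, anat = anat, x = pad$data, extents = pad$extents)
}

# Forward + loss + full gradient for one pair; returns flat parameter grads.
pair_backprop <- function(net, pp, weights) {
  fw <- net_forward(net, pp$x, mode = "train", cache = TRUE)
  net <- fw$net
  ext <- pp$extents
  out <- crop_to_size(fw$out, ext)
  if (net$config$head_kind == "field3d") {
    u <- out
  } else {
    u <- array(0, c(ext, 3L))
    u[, , , match(net$config$pe_axis, c("x", "y", "z"))] <- out[, , , 1]
  }
  pl <- pair_loss_grad(pp$i1, pp$i2, u, weights, pp$anat)
  # gradient w.r.t. the (padded) head output
  pd <- dim(fw$out)
  if (net$config$head_kind == "field3d") {
    ghead <- array(0, pd)
    ghead[seq_len(ext[1]), seq_len(ext[2]), seq_len(ext[3]), ] <- pl$gu
  } else {
    ghead <- array(0, pd)
    ghead[seq_len(ext[1]), seq_len(ext[2]), seq_len(ext[3]), 1] <-
      pl$gu[, , , match(net$config$pe_axis, c("x", "y", "z"))]
  }
  grads <- net_backward(net, fw$cache, ghead)
  list(net = net, flat = grads_to_flat(net, grads),
       loss = pl[c("total", "sim", "smooth", "anat")])
}

#' Train the correction network
#'
#' Minimizes the batch-mean objective
#' `Lsim(E1,E2) + lambda * Lsmooth(U) + gamma * Lanat(E1,E2,A)` by Adam.
#' Pairs are reshuffled every epoch with an epoch-indexed seed; a held-out
#' fraction
#' of pairs is scored (similarity loss, evaluation mode) after every epoch.
#' Fully deterministic for a fixed seed under single-threaded execution.
#'
#' @param pairs list of pairs; each a list with volumes `i1`, `i2` and
#'   optionally `anat` (required for every pair when `gamma_anat > 0`).
#' @param config a [train_config()].
#' @param net_config a [network_config()]; ignored when `net` is supplied.
#' @param net optionally a pre-built `sac_network` to continue training.
#' @return list with `net` (trained network) and `record` (one row per
#'   epoch: mean training loss components and validation similarity loss).
#' @export
train <- function(pairs, config = train_config(), net_config = network_config(),
                  net = NULL) {
  stopifnot(inherits(config, "sac_train_config"), length(pairs) >= 1)
  weights <- config$loss_weights
  need_anat <- weights$gamma_anat > 0
  prepped <- lapply(pairs, prep_pair, need_anat = need_anat)

  if (is.null(net)) net <- build_network(net_config)
  if (!is.null(config$warm_start_checkpoint)) {
    donor <- load_checkpoint(config$warm_start_checkpoint)
    net <- net_set_params(net, net_params(donor))
    for (name in names(net$layers))
      if (!is.null(net$layers[[name]]$norm)) {
        net$layers[[name]]$norm$rmean <- donor$layers[[name]]$norm$rmean
        net$layers[[name]]$norm$rvar <- donor$layers[[name]]$norm$rvar
        net$layers[[name]]$norm$seen <- donor$layers[[name]]$norm$seen
      }
  }

  n_val <- max(1L, floor(length(prepped) * config$validation_fraction))
  if (length(prepped) < 2L) n_val <- 0L
  set.seed(derive_seed(config$seed, 0L))
  perm <- sample(length(prepped))
  val_idx <- perm[seq_len(n_val)]
  train_idx <- setdiff(perm, val_idx)

  params <- net_params(net)
  state <- list(t = 0L,
                m = lapply(params, function(p) numeric(length(p))),
                v = lapply(params, function(p) numeric(length(p))))
  record <- data.frame()

  for (epoch in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, epoch))
    order_ep <- sample(train_idx)
    ep_loss <- c(total = 0, sim = 0, smooth = 0, anat = 0)
    n_anat <- 0L
    i <- 1L
    while (i <= length(order_ep)) {
      batch <- order_ep[i:min(i + config$batch_size - 1L, length(order_ep))]
      acc <- NULL
      for (j in batch) {
        pb <- pair_backprop(net, prepped[[j]], weights)
        net <- pb$net
        if (is.null(acc)) acc <- pb$flat
        else for (k in names(acc)) acc[[k]] <- acc[[k]] + pb$flat[[k]]
        ep_loss["total"] <- ep_loss["total"] + pb$loss$total
        ep_loss["sim"] <- ep_loss["sim"] + pb$loss$sim
        ep_loss["smooth"] <- ep_loss["smooth"] + pb$loss$smooth
        if (!is.na(pb$loss$anat)) {
          ep_loss["anat"] <- ep_loss["anat"] + pb$loss$anat
          n_anat <- n_anat + 1L
        }
      }
      for (k in names(acc)) acc[[k]] <- acc[[k]] / length(batch)
      upd <- adam_step(params, acc, state, config$learning_rate,
                       config$adam_beta1, config$adam_beta2)
      params <- upd$params
      state <- upd$state
      net <- net_set_params(net, params)
      i <- i + length(batch)
    }
    ntr <- length(order_ep)
    val <- if (n_val > 0)
      validate(net, pairs[val_idx], metric = weights) else NA_real_
    record <- rbind(record, data.frame(
      epoch = epoch,
      loss_total = ep_loss[["total"]] / ntr,
      loss_sim = ep_loss[["sim"]] / ntr,
      loss_smooth = ep_loss[["smooth"]] / ntr,
      loss_anat = if (n_anat > 0) ep_loss[["anat"]] / n_anat else NA_real_,
      val_sim = val,
      time = as.numeric(Sys.time())))
  }
  list(net = net, record = record)
}

#' Validation similarity loss of a network on held-out pairs
#'
#' Mean similarity loss ([sim_loss()]) of the corrected image pairs under the
#' stated metric, computed in evaluation mode with no parameter updates.
#'
#' @param net a `sac_network`.
#' @param pairs list of pairs (`i1`, `i2`; anatomy ignored).
#' @param metric a [loss_weights()] object naming the metric and window.
#' @return mean similarity loss (scalar).
#' @export
validate <- function(net, pairs, metric = loss_weights()) {
  stopifnot(length(pairs) >= 1)
  vals <- vapply(pairs, function(p) {
    pred <- predict_field(net, p$i1, p$i2)
    e <- correct_pair(p$i1, p$i2, pred$field)
    sim_loss(e$e1, e$e2, metric)
  }, numeric(1))
  mean(vals)
}
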