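# Desk-scale study harnesses shared by the acceptance tests.  Sizes are the
# package's desk-scale study design (see the methods vignette): 32x32x16
# phantoms, PE amplitude 3 voxels / off-PE 0.5, field smoothness 6 voxels,
# noise 2% of tissue contrast.

desk_phantom_spec <- function() {
  phantom_spec(extents = c(32L, 32L, 16L), noise_sigma = 2.4)
}

desk_field_spec <- function() {
  field_spec(pe_axis = "y", amplitude_pe = 3, amplitude_offpe = 0.5,
             smoothness_sigma = 6)
}

desk_weights <- function(gamma = 0.01) {
  loss_weights(lambda_smooth = 0.1, gamma_anat = gamma,
               sim_metric = "LNCC", lncc_window = 9)
}

# Parameter recovery: train the 3D model on simulated reversed-PE pairs,
# then measure on fresh held-out pairs how well the predicted field matches
# the simulated ground truth (endpoint error and PE-component correlation
# inside the mask) and how much correction improves the pair's LNCC.
recovery_study <- function(seed, n_train = 12, n_test = 10, epochs = 50) {
  tr <- make_dataset(n_train, desk_phantom_spec(), desk_field_spec(),
                     seed = seed)
  te <- make_dataset(n_test, desk_phantom_spec(), desk_field_spec(),
                     seed = seed + 5000L)
  fit <- train(tr, train_config(epochs = epochs, loss_weights = desk_weights(),
                                seed = seed),
               network_config(seed = seed))
  stats <- vapply(te, function(it) {
    pred <- predict_field(fit$net, it$i1, it$i2)
    fe <- field_error(pred$field, it$true_field, it$mask, pe_axis = "y")
    e <- correct_pair(it$i1, it$i2, pred$field)
    s <- score_pair(it$i1, it$i2, e$e1, e$e2, window = 9)
    c(fe$mean_endpoint_error, fe$pe_component_correlation,
      s$lncc_uncorrected, s$lncc_corrected)
  }, numeric(4))
  gc(verbose = FALSE)
  list(mean_endpoint_error = mean(stats[1, ]),
       pe_component_correlation = mean(stats[2, ]),
       lncc_uncorrected = mean(stats[3, ]),
       lncc_corrected = mean(stats[4, ]),
       per_pair = stats,
       net = fit$net)
}

# Ablation harness: short runs on a common dataset differing only in the
# ablation switch; validation similarity loss (two held-out pairs inside
# train()) is the comparison measure.  Runs use 32x16x16 volumes so three
# seeds of four runs each stay cheap.  The warm-start donor is pre-trained
# once on a phantom family with different tissue contrast.
ablation_phantom_spec <- function(levels = c(60, 100, 140, 180)) {
  phantom_spec(extents = c(32L, 16L, 16L), noise_sigma = 2.4,
               intensity_levels = levels)
}

ablation_pretrain <- local({
  ck <- NULL
  function() {
    if (!is.null(ck) && file.exists(ck)) return(ck)
    prA <- make_dataset(8, ablation_phantom_spec(c(40, 90, 150, 200)),
                        desk_field_spec(), seed = 5000)
    fitA <- train(prA, train_config(epochs = 15, loss_weights = desk_weights(),
                                    seed = 99, validation_fraction = 0.25),
                  network_config(seed = 99))
    ck <<- file.path(tempdir(), "ablation_pretrain.ckpt")
    save_checkpoint(fitA$net, ck)
    ck
  }
})

ablation_study <- function(seed, epochs = 12) {
  dsB <- make_dataset(8, ablation_phantom_spec(), desk_field_spec(),
                      seed = 100 + seed)
  run <- function(head, gamma, warm = NULL) {
    train(dsB, train_config(epochs = epochs, loss_weights = desk_weights(gamma),
                            seed = seed, validation_fraction = 0.25,
                            warm_start_checkpoint = warm),
          network_config(head_kind = head, pe_axis = "y", seed = seed))
  }
  r3 <- run("field3d", 0.01)                 # the proposed model; also the
  r1 <- run("field1d", 0.01)                 # scratch baseline for warm start
  rg0 <- run("field3d", 0)
  rw <- run("field3d", 0.01, warm = ablation_pretrain())
  gc(verbose = FALSE)
  scratch_final <- tail(r3$record$val_sim, 1)
  reach <- which(rw$record$val_sim <= scratch_final)[1]
  list(val_3d = tail(r3$record$val_sim, 1),
       val_1d = tail(r1$record$val_sim, 1),
       val_gamma = tail(r3$record$val_sim, 1),
       val_nogamma = tail(rg0$record$val_sim, 1),
       scratch_epochs = epochs,
       warm_epochs_to_reach = if (is.na(reach)) Inf else reach)
}
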