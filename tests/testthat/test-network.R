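test_that("network building is seed-deterministic", {
  n1 <- build_network(network_config(seed = 42))
  n2 <- build_network(network_config(seed = 42))
  expect_identical(sacnet:::net_params(n1), sacnet:::net_params(n2))
  n3 <- build_network(network_config(seed = 43))
  expect_false(identical(sacnet:::net_params(n1)$enc1.W,
                         sacnet:::net_params(n3)$enc1.W))
})

test_that("parameter count matches independent per-layer arithmetic", {
  e <- c(16L, 32L, 32L, 32L); d <- c(32L, 32L, 32L, 32L, 8L, 8L)
  conv_p <- function(cin, cout) 27 * cin * cout + cout
  expected <- 0
  for (io in list(c(2, e[1]), c(e[1], e[2]), c(e[2], e[3]), c(e[3], e[4]),
                  c(e[4], d[1]), c(d[1] + e[3], d[2]), c(d[2] + e[2], d[3]),
                  c(d[3] + e[1], d[4]), c(d[4] + 2, d[5]), c(d[5], d[6])))
    expected <- expected + conv_p(io[1], io[2]) + 2 * io[2]  # conv + BN pair
  expected <- expected + conv_p(d[6], 3)                     # head, no BN
  expect_equal(n_parameters(build_network(network_config())), expected)
})

test_that("architecture switches move the parameter count as expected", {
  base <- n_parameters(build_network(network_config()))
  none <- n_parameters(build_network(network_config(norm_kind = "none")))
  inst <- n_parameters(build_network(network_config(norm_kind = "instance")))
  tc <- n_parameters(build_network(network_config(upsample_kind = "transposed_conv")))
  head1 <- n_parameters(build_network(network_config(head_kind = "field1d")))
  expect_lt(none, base)                    # removes all scale/shift pairs
  expect_equal(base - none,
               2 * sum(c(16, 32, 32, 32, 32, 32, 32, 32, 8, 8)))
  expect_equal(inst, base)                 # same trainables, no running use
  expect_gt(tc, base)                      # learned upsampling adds kernels
  expect_equal(base - head1, 2 * (27 * 8) + 2)
  expect_error(build_network(network_config(encoder_channels = c(8, 8, 8))),
               "4")
})

test_that("predicted field extents always equal the input extents", {
  net <- build_network(network_config(seed = 3))
  set.seed(90)
  for (trial in 1:3) {
    d <- sample(17:48, 3, replace = TRUE)
    p <- predict_field(net, seeded_array(d, trial), seeded_array(d, trial + 50))
    expect_equal(dim(p$field$u)[1:3], d)
    expect_equal(p$original_extents, d)
    expect_equal(p$padded_extents, as.integer(ceiling(d / 16) * 16))
  }
  expect_error(predict_field(net, seeded_array(c(16, 16, 16), 1),
                             seeded_array(c(16, 16, 17), 2)), "extents")
})

test_that("near-zero head keeps the initial field under 0.1 voxel", {
  net <- build_network(network_config(seed = 8))
  d <- c(32, 32, 16)
  p <- predict_field(net, seeded_array(d, 61, 100, 20), seeded_array(d, 62, 100, 20))
  expect_lt(max(abs(p$field$u)), 0.1)
})

test_that("the 1D head predicts only the phase-encoding component", {
  for (axis in c("x", "y", "z")) {
    net <- build_network(network_config(head_kind = "field1d", pe_axis = axis,
                                        seed = 4))
    d <- c(18, 20, 17)
    p <- predict_field(net, seeded_array(d, 71), seeded_array(d, 72))
    pe <- match(axis, c("x", "y", "z"))
    for (comp in setdiff(1:3, pe))
      expect_true(all(p$field$u[, , , comp] == 0))
    expect_gt(max(abs(p$field$u[, , , pe])), 0)
  }
})

test_that("evaluation-mode prediction is bitwise reproducible", {
  net <- build_network(network_config(seed = 5))
  d <- c(20, 24, 18)
  i1 <- seeded_array(d, 81); i2 <- seeded_array(d, 82)
  p1 <- predict_field(net, i1, i2)
  p2 <- predict_field(net, i1, i2)
  expect_identical(p1$field$u, p2$field$u)
})

test_that("checkpoints round-trip parameters and predictions exactly", {
  net <- build_network(network_config(seed = 6))
  ck <- file.path(tempdir(), "net.ckpt")
  save_checkpoint(net, ck)
  net2 <- load_checkpoint(ck)
  expect_identical(sacnet:::net_params(net), sacnet:::net_params(net2))
  d <- c(18, 18, 18)
  i1 <- seeded_array(d, 91); i2 <- seeded_array(d, 92)
  expect_identical(predict_field(net, i1, i2)$field$u,
                   predict_field(net2, i1, i2)$field$u)
  file.remove(ck, paste0(ck, ".cfg"))
})
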