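test_that("mse matches its definition and a loop oracle", {
  d <- c(5, 5, 5)
  a <- seeded_array(d, 1); b <- seeded_array(d, 2)
  expect_equal(mse(a, a), 0)
  expect_equal(mse(array(0, d), array(1, d)), 1)
  oracle <- 0
  for (i in seq_along(a)) oracle <- oracle + (a[i] - b[i])^2
  expect_equal(mse(a, b), oracle / length(a), tolerance = 1e-10)
  expect_error(mse(a, seeded_array(c(5, 5, 6), 3)), "extents")
})

test_that("lncc matches the brute-force windowed oracle", {
  d <- c(9, 9, 9)
  a <- seeded_array(d, 11); b <- seeded_array(d, 12)
  expect_lt(abs(lncc(a, b, 3) - windowed_cc_oracle(a, b, 3, TRUE)), 1e-6)
  expect_lt(abs(lncc(a, b, 5) - windowed_cc_oracle(a, b, 5, TRUE)), 1e-6)
})

test_that("lncc is a squared correlation: identity, affine invariance, range", {
  a <- seeded_array(c(9, 9, 9), 13)
  expect_equal(lncc(a, a, 3), 1, tolerance = 1e-12)
  expect_equal(lncc(a, 2.5 * a + 7, 3), 1, tolerance = 1e-10)
  expect_equal(lncc(a, -3 * a + 1, 3), 1, tolerance = 1e-10)
  for (s in 1:3) {
    b <- seeded_array(c(9, 9, 9), 20 + s)
    v <- lncc(a, b, 3)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_error(lncc(a, a, 4), "odd")
  expect_error(lncc(a, a, 11), "extent")
})

test_that("lcc is sign-sensitive and matches its oracle", {
  a <- seeded_array(c(9, 9, 9), 31); b <- seeded_array(c(9, 9, 9), 32)
  expect_equal(lcc(a, a, 3), 1, tolerance = 1e-12)
  expect_equal(lcc(a, -a + 4, 3), -1, tolerance = 1e-10)
  expect_lt(abs(lcc(a, b, 3) - windowed_cc_oracle(a, b, 3, FALSE)), 1e-6)
})

test_that("sim_loss returns the configured dissimilarity", {
  a <- seeded_array(c(9, 9, 9), 41); b <- seeded_array(c(9, 9, 9), 42)
  expect_equal(sim_loss(a, a, loss_weights(sim_metric = "LNCC", lncc_window = 3)), 0,
               tolerance = 1e-12)
  expect_equal(sim_loss(a, b, loss_weights(sim_metric = "MSE")), mse(a, b))
  expect_equal(sim_loss(a, -a, loss_weights(sim_metric = "LCC", lncc_window = 3)), 2,
               tolerance = 1e-10)
})

test_that("smooth_loss: constant fields, closed form, loop oracle, translation", {
  d <- c(7, 5, 6)
  expect_equal(smooth_loss(array(3.7, c(d, 3))), 0)

  aa <- 2
  u <- array(0, c(d, 3))
  u[, , , 1] <- array(rep((0:(d[1] - 1)) * aa, times = d[2] * d[3]), d)
  expect_equal(smooth_loss(u), aa^2 * (d[1] - 1) / d[1], tolerance = 1e-12)

  ur <- seeded_field(c(5, 5, 5), 51)
  expect_equal(smooth_loss(ur), smooth_oracle(ur), tolerance = 1e-10)
  expect_equal(smooth_loss(ur + 2.5), smooth_loss(ur), tolerance = 1e-10)
})

test_that("nmi follows the Studholme convention", {
  a <- seeded_array(c(9, 9, 9), 61, mean = 100, sd = 20)
  expect_equal(nmi(a, a, 32), 2, tolerance = 1e-12)
  set.seed(62)
  u1 <- array(runif(32^3), c(32, 32, 32))
  u2 <- array(runif(32^3), c(32, 32, 32))
  expect_lt(abs(nmi(u1, u2, 32) - 1), 0.05)
  b <- seeded_array(c(9, 9, 9), 63, mean = 50, sd = 10)
  expect_equal(nmi(a, b, 16), nmi_oracle(a, b, 16), tolerance = 1e-10)
  expect_error(nmi(array(1, c(9, 9, 9)), a), "degenerate")
})

test_that("parzen-mode nmi agrees with hard binning on a smooth phantom", {
  ph <- gen_phantom(phantom_spec(extents = c(32, 32, 32), seed = 5))
  h <- nmi(ph$epi_like, ph$anat_like, 32, mode = "hard")
  p <- nmi(ph$epi_like, ph$anat_like, 32, mode = "parzen")
  expect_lt(abs(h - p), 0.05)
})

test_that("anat_loss is exactly the NMI average form", {
  a <- seeded_array(c(9, 9, 9), 71, mean = 100, sd = 25)
  expect_equal(anat_loss(a, a, a), -1, tolerance = 1e-12)
  e1 <- seeded_array(c(9, 9, 9), 72); e2 <- seeded_array(c(9, 9, 9), 73)
  expect_equal(anat_loss(e1, e2, a, bins = 32),
               1 - (nmi(e1, a, 32) + nmi(e2, a, 32)) / 2, tolerance = 1e-12)
  set.seed(74)
  big1 <- array(runif(32^3), c(32, 32, 32))
  big2 <- array(runif(32^3), c(32, 32, 32))
  biga <- array(runif(32^3), c(32, 32, 32))
  expect_lt(abs(anat_loss(big1, big2, biga, 32)), 0.05)
})

test_that("total_loss composes its terms with the configured weights", {
  d <- c(16, 16, 16)
  it <- tiny_dataset(1, seed = 81)[[1]]
  u <- seeded_field(dim(it$i1$data), 82, max_abs = 1)
  w <- loss_weights(lambda_smooth = 0.1771, gamma_anat = 0.01, lncc_window = 5)
  tl <- total_loss(it$i1, it$i2, u, w, anatomy = it$anat)
  e <- correct_pair(it$i1, it$i2, u)
  expect_equal(tl$sim, sim_loss(e$e1, e$e2, w), tolerance = 1e-12)
  expect_equal(tl$smooth, smooth_loss(u), tolerance = 1e-12)
  expect_equal(tl$anat, anat_loss(e$e1, e$e2, it$anat, w$nmi_bins), tolerance = 1e-12)
  expect_equal(tl$total, tl$sim + 0.1771 * tl$smooth + 0.01 * tl$anat,
               tolerance = 1e-6)

  noanat <- total_loss(it$i1, it$i2, u, w)
  expect_true(is.na(noanat$anat))
  expect_equal(noanat$total, noanat$sim + 0.1771 * noanat$smooth)

  # zero field, identical inputs, no regularization: exactly zero
  z <- array(0, c(d, 3))
  w0 <- loss_weights(lambda_smooth = 0, gamma_anat = 0, lncc_window = 5)
  expect_equal(total_loss(it$i1, it$i1, z, w0)$total, 0, tolerance = 1e-12)
})

test_that("total_loss is monotone in each regularization weight", {
  it <- tiny_dataset(1, seed = 91)[[1]]
  u <- seeded_field(dim(it$i1$data), 92, max_abs = 1)
  base <- total_loss(it$i1, it$i2, u,
                     loss_weights(lambda_smooth = 0.01, gamma_anat = 0.01,
                                  lncc_window = 5), anatomy = it$anat)
  more_lam <- total_loss(it$i1, it$i2, u,
                         loss_weights(lambda_smooth = 0.5, gamma_anat = 0.01,
                                      lncc_window = 5), anatomy = it$anat)
  expect_gt(more_lam$total, base$total)   # smooth component is positive
})
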