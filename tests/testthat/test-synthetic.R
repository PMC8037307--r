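test_that("gen_phantom is deterministic with head-like geometry", {
  spec <- phantom_spec(extents = c(24, 24, 20), seed = 7)
  p1 <- gen_phantom(spec)
  p2 <- gen_phantom(spec)
  expect_identical(p1$epi_like$data, p2$epi_like$data)
  expect_identical(p1$anat_like$data, p2$anat_like$data)

  frac <- mean(p1$mask$data)
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.6)
})

test_that("epi and anat phantoms share anatomy but differ in contrast", {
  p <- gen_phantom(phantom_spec(extents = c(24, 24, 20), seed = 8))
  m <- p$mask$data != 0
  rc <- cor(rank(p$epi_like$data[m]), rank(p$anat_like$data[m]))
  expect_gt(rc, 0.5)
  expect_lt(rc, 0.999)
})

test_that("gen_field respects amplitudes, dominance and smoothness", {
  d <- c(24, 24, 20)
  f <- gen_field(d, field_spec(pe_axis = "y", amplitude_pe = 3,
                               amplitude_offpe = 0, smoothness_sigma = 4,
                               seed = 9))
  expect_true(all(f$u[, , , 1] == 0))
  expect_true(all(f$u[, , , 3] == 0))
  expect_equal(max(abs(f$u[, , , 2])), 3, tolerance = 1e-6)

  f2 <- gen_field(d, field_spec(pe_axis = "y", amplitude_pe = 3,
                                amplitude_offpe = 0.5, smoothness_sigma = 4,
                                seed = 9))
  expect_gt(mean(abs(f2$u[, , , 2])),
            mean(abs(f2$u[, , , c(1, 3)])))
  expect_equal(max(abs(f2$u[, , , 1])), 0.5, tolerance = 1e-6)

  smoothness <- vapply(c(2, 4, 8), function(s) {
    smooth_loss(gen_field(d, field_spec(smoothness_sigma = s, seed = 10)))
  }, numeric(1))
  expect_true(all(diff(smoothness) < 0))

  expect_error(field_spec(amplitude_pe = 1, amplitude_offpe = 2), "dominance")
})

test_that("distorting with a zero field and no noise is the identity", {
  p <- gen_phantom(phantom_spec(extents = c(20, 20, 16), seed = 11))
  z <- displacement_field(array(0, c(20, 20, 16, 3)))
  pair <- distort_pair(p$epi_like, z, noise_sigma = 0)
  expect_equal(pair$i1$data, p$epi_like$data, tolerance = 1e-12)
  expect_equal(pair$i2$data, p$epi_like$data, tolerance = 1e-12)
})

test_that("correcting with the true field recovers the truth in the interior", {
  spec <- phantom_spec(extents = c(48, 48, 32), noise_sigma = 0, seed = 12)
  p <- gen_phantom(spec)
  f <- gen_field(spec$extents, field_spec(pe_axis = "y", amplitude_pe = 3,
                                          amplitude_offpe = 0.5,
                                          smoothness_sigma = 6, seed = 13))
  pair <- distort_pair(p$epi_like, f, noise_sigma = 0)
  e <- correct_pair(pair$i1, pair$i2, f)
  interior <- sacnet:::gauss3(p$mask$data, 2) > 0.999
  scale <- diff(range(p$epi_like$data))
  err1 <- max(abs(e$e1$data[interior] - p$epi_like$data[interior])) / scale
  err2 <- max(abs(e$e2$data[interior] - p$epi_like$data[interior])) / scale
  # double trilinear interpolation of the band-limited phantom bounds the
  # worst voxel near tissue edges at a few percent of the intensity range,
  # and the bulk error well below 1%
  expect_lt(err1, 0.05)
  expect_lt(err2, 0.05)
  expect_lt(mean(abs(e$e1$data[interior] - p$epi_like$data[interior])) / scale,
            0.01)
  # and the corrected pair is far more similar than the distorted pair
  expect_gt(lncc(e$e1, e$e2, 9), lncc(pair$i1, pair$i2, 9))
})

test_that("the exact inverse construction beats the one-step approximation", {
  spec <- phantom_spec(extents = c(32, 32, 24), noise_sigma = 0, seed = 14)
  p <- gen_phantom(spec)
  f <- gen_field(spec$extents, field_spec(pe_axis = "y", amplitude_pe = 3,
                                          amplitude_offpe = 0.5,
                                          smoothness_sigma = 6, seed = 15))
  interior <- sacnet:::gauss3(p$mask$data, 2) > 0.999
  err_of <- function(exact) {
    pair <- distort_pair(p$epi_like, f, noise_sigma = 0, exact = exact)
    e <- correct_pair(pair$i1, pair$i2, f)
    mean(abs(e$e1$data[interior] - p$epi_like$data[interior]))
  }
  expect_lt(err_of(TRUE), err_of(FALSE))
})

test_that("jacobian modulation of a linear PE field is the analytic constant", {
  d <- c(16, 16, 16)
  flat <- volume3d(array(100, d))
  aa <- 0.15
  u <- array(0, c(d, 3))
  u[, , , 2] <- array(rep(rep((0:(d[2] - 1)) * aa, each = d[1]), times = d[3]), d)
  pair <- distort_pair(flat, u, with_jacobian = TRUE)
  interior <- 4:12
  expect_equal(pair$i1$data[interior, interior, interior],
               array(100 * (1 - aa), c(9, 9, 9)), tolerance = 1e-6)
  expect_equal(pair$i2$data[interior, interior, interior],
               array(100 * (1 + aa), c(9, 9, 9)), tolerance = 1e-6)
  expect_false(attr(pair, "folding"))

  ufold <- u * 10                          # derivative 1.5: folding regime
  pairf <- distort_pair(flat, ufold, with_jacobian = TRUE)
  expect_true(attr(pairf, "folding"))
})

test_that("make_dataset draws independent reproducible items", {
  ds1 <- tiny_dataset(5, seed = 16)
  ds2 <- tiny_dataset(5, seed = 16)
  expect_equal(length(ds1), 5)
  for (i in 1:5) {
    expect_identical(ds1[[i]]$i1$data, ds2[[i]]$i1$data)
    expect_equal(dim(ds1[[i]]$i1$data), dim(ds1[[1]]$i1$data))
  }
  sums <- vapply(ds1, function(it) sum(it$i1$data), numeric(1))
  expect_equal(length(unique(round(sums, 6))), 5)  # items differ

  # every draw satisfies the generator's core properties
  for (it in ds1) {
    expect_gt(mean(abs(it$true_field$u[, , , 2])),
              mean(abs(it$true_field$u[, , , c(1, 3)])))
    e <- correct_pair(it$i1, it$i2, it$true_field)
    expect_gt(lncc(e$e1, e$e2, 9), lncc(it$i1, it$i2, 9))
  }
})
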