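test_that("make_grid returns the 0-based identity grid", {
  g <- make_grid(c(2, 2, 2))
  expect_equal(g[2, 1, 1, 1], 1)
  expect_equal(g[1, 2, 1, 2], 1)
  expect_equal(g[1, 1, 2, 3], 1)
  expect_equal(dim(make_grid(c(4, 3, 2))), c(4, 3, 2, 3))
  expect_equal(sum(make_grid(c(3, 3, 3))[, , , 1]), 27)
  expect_error(make_grid(c(0, 3, 3)), "extents")
  expect_error(make_grid(c(4, 1, 4)), "extents")
})

test_that("warp with a zero field is the identity", {
  img <- seeded_array(c(6, 7, 5), 1)
  u0 <- array(0, c(6, 7, 5, 3))
  expect_identical(warp(img, u0, 1), img)
  expect_identical(warp(img, u0, -1), img)
})

test_that("warp reproduces a shifted ramp exactly, clamped at the border", {
  d <- c(8, 8, 8)
  ramp <- array(rep(0:7, times = 64), d)      # I(i,j,k) = i (0-based)
  u <- array(0, c(d, 3)); u[, , , 1] <- 0.5
  out <- warp(ramp, u, 1)
  expect_equal(out[1:7, , ], ramp[1:7, , ] + 0.5)
  expect_equal(out[8, , ], ramp[8, , ])        # clamped at i = 7
})

test_that("warp matches the brute-force trilinear oracle", {
  for (case in 1:3) {
    d <- c(6, 6, 6) + case - 1
    img <- seeded_array(d, 10 + case)
    u <- seeded_field(d, 20 + case, max_abs = 1.5)
    for (s in c(1, -1))
      expect_lt(max(abs(warp(img, u, s) - trilinear_oracle(img, u, s))), 1e-6)
  }
})

test_that("warp is linear in image intensities", {
  d <- c(6, 6, 6)
  i1 <- seeded_array(d, 31); i2 <- seeded_array(d, 32)
  u <- seeded_field(d, 33)
  lhs <- warp(2.5 * i1 - 1.25 * i2, u, 1)
  rhs <- 2.5 * warp(i1, u, 1) - 1.25 * warp(i2, u, 1)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("an integer uniform field is an index shift in the interior", {
  d <- c(8, 7, 6)
  img <- seeded_array(d, 40)
  u <- array(0, c(d, 3)); u[, , , 1] <- 2
  out <- warp(img, u, 1)
  expect_equal(out[1:(d[1] - 2), , ], img[3:d[1], , ])
})

test_that("warp validates its arguments", {
  img <- seeded_array(c(6, 6, 6), 1)
  expect_error(warp(img, array(0, c(5, 6, 6, 3))), "extents")
  expect_error(warp(img, array(0, c(6, 6, 6, 3)), sign = 2), "sign")
  expect_error(warp(array(NaN, c(6, 6, 6)), array(0, c(6, 6, 6, 3))),
               "non-finite")
})

test_that("correct_pair applies one shared field with opposite signs", {
  d <- c(12, 12, 8)
  base <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), d)
  u <- array(0, c(d, 3)); u[, , , 1] <- 1
  i1 <- warp(base, u, -1)                     # ramp shifted by -1 voxel
  i2 <- warp(base, u, +1)
  e <- correct_pair(i1, i2, u)
  interior <- 3:(d[1] - 3)
  expect_lt(max(abs(e$e1[interior, , ] - base[interior, , ])), 1e-6)
  expect_lt(max(abs(e$e2[interior, , ] - base[interior, , ])), 1e-6)

  z <- array(0, c(d, 3))
  e0 <- correct_pair(i1, i2, z)
  expect_identical(e0$e1, i1)
  expect_identical(e0$e2, i2)

  sw <- correct_pair(i2, i1, -u)
  expect_identical(sw$e1, e$e2)
  expect_identical(sw$e2, e$e1)
})

test_that("pad_to_multiple pads trailing to the next multiple of 16", {
  x <- seeded_array(c(90, 104, 72), 5)
  p <- pad_to_multiple(x, 16)
  expect_equal(dim(p$data), c(96, 112, 80))
  expect_equal(p$extents, c(90, 104, 72))
  expect_equal(p$data[1:90, 1:104, 1:72], x)
  expect_equal(p$data[91:96, , ], array(0, c(6, 112, 80)))

  y <- seeded_array(c(32, 32, 32), 6)
  expect_identical(pad_to_multiple(y, 16)$data, y)
})

test_that("pad then crop is the identity for random extents", {
  set.seed(77)
  for (trial in 1:5) {
    d <- sample(17:60, 3, replace = TRUE)
    x <- seeded_array(d, 100 + trial)
    p <- pad_to_multiple(x, 16)
    expect_identical(crop_to_size(p$data, p$extents), x)
  }
  u <- seeded_field(c(21, 34, 18), 9)
  p <- pad_to_multiple(u, 16)
  expect_identical(crop_to_size(p$data, p$extents), u)
})

test_that("crop_to_size validates the record and slices leading blocks", {
  x <- seeded_array(c(20, 20, 20), 8)
  expect_identical(crop_to_size(x, c(20, 20, 20)), x)
  cr <- crop_to_size(x, c(12, 15, 9))
  expect_equal(cr, x[1:12, 1:15, 1:9])
  expect_error(crop_to_size(x, c(21, 20, 20)), "exceed")
})
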