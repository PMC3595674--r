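test_that("defect detection applies the fractional threshold exactly", {
  # uniform magnitude: nothing defected
  d0 <- detect_defected_region(matrix(100, 16, 16))
  expect_identical(sum(d0$mask), 0L)

  # zeroed disk with max 200 elsewhere: mask is that disk, threshold 20
  n <- 32
  x <- matrix(rep(1:n, each = n), n, n); y <- matrix(rep(1:n, n), n, n)
  disk <- (x - 16)^2 + (y - 16)^2 <= 36
  M <- matrix(200, n, n); M[disk] <- 0
  d1 <- detect_defected_region(M)
  expect_identical(d1$mask, disk)
  expect_identical(d1$threshold_used, 20)
})

test_that("random magnitudes match the brute-force comparison loop", {
  set.seed(12)
  M <- matrix(runif(15 * 17, 0, 50), 15, 17)
  dom <- matrix(TRUE, 15, 17); dom[1:3, 1:2] <- FALSE
  d <- detect_defected_region(M, dom, fraction = 0.3)
  thr <- 0.3 * max(M[dom])
  oracle <- matrix(FALSE, 15, 17)
  for (r in 1:15) for (c in 1:17) oracle[r, c] <- dom[r, c] && M[r, c] < thr
  expect_identical(d$mask, oracle)
})

test_that("oversized defects warn and isolated defects error", {
  M <- matrix(0, 16, 16); M[1, 1] <- 100; M[1, 2] <- 60
  expect_warning(detect_defected_region(M), class = "mreit_warning")
  # a defect covering everything has no valid rim to inpaint from
  expect_error(harmonic_inpaint(matrix(1, 8, 8), matrix(TRUE, 8, 8)),
               class = "mreit_validation_error")
})

test_that("linear fields are refilled exactly over interior holes", {
  f <- outer(1:20, 1:20, function(r, c) 0.4 * c - 0.9 * r + 2)
  hole <- matrix(FALSE, 20, 20); hole[7:13, 9:15] <- TRUE
  out <- harmonic_inpaint(f, hole)
  expect_lt(max(abs(out - f)), 1e-10)
})

test_that("inpainted values obey the discrete maximum principle and locality", {
  set.seed(14)
  f <- matrix(rnorm(24 * 24), 24, 24)
  hole <- matrix(FALSE, 24, 24); hole[6:12, 8:16] <- TRUE; hole[18:21, 3:6] <- TRUE
  out <- harmonic_inpaint(f, hole)
  ring <- mreit:::dilate4(hole) & !hole
  expect_gte(min(out[hole]), min(f[ring]))
  expect_lte(max(out[hole]), max(f[ring]))
  # locality: pixels outside the mask bit-identical
  expect_identical(out[!hole], f[!hole])
  # idempotence for a fixed mask
  out2 <- harmonic_inpaint(out, hole)
  expect_lt(max(abs(out2 - out)), 1e-8)
})

test_that("repair matches a dense direct solve and the mean-value property", {
  set.seed(15)
  f <- matrix(0, 16, 16)
  xy <- expand.grid(r = 1:16, c = 1:16)
  f[] <- sin(xy$r / 3) + cos(xy$c / 4)   # smooth boundary data
  hole <- matrix(FALSE, 16, 16); hole[6:11, 5:12] <- TRUE
  out <- harmonic_inpaint(f, hole, tol = 1e-12)
  dense <- oracle_dense_inpaint(f, hole)
  expect_lt(max(abs(out - dense)), 1e-8)
  # five-point mean-value property at every interior inpainted pixel
  for (r in 7:10) for (c in 6:11) {
    expect_lt(abs(out[r, c] - (out[r - 1, c] + out[r + 1, c] +
                               out[r, c - 1] + out[r, c + 1]) / 4), 1e-8)
  }
})

test_that("seam smoothing is an identity for zero duration and harmonic patches", {
  f <- outer(1:16, 1:16, function(r, c) 0.2 * c + 0.1 * r)
  hole <- matrix(FALSE, 16, 16); hole[6:10, 6:10] <- TRUE
  rep0 <- harmonic_inpaint(f, hole)
  expect_identical(isotropic_smooth_defect(rep0, hole, duration = 0), rep0)
  # a linear (hence harmonic) field is a steady state of the heat flow
  out <- isotropic_smooth_defect(rep0, hole, duration = 2)
  expect_lt(max(abs(out - rep0)), 1e-8)
})

test_that("one explicit heat step matches the hand-computed update", {
  # constant along rows, step across the seam in x; defect = middle column
  f <- matrix(rep(c(0, 0, 1, 5, 5), each = 8), 8, 5)
  defect <- matrix(FALSE, 8, 5); defect[, 3] <- TRUE
  dt <- 0.25
  out <- isotropic_smooth_defect(f, defect, duration = dt, dt = dt)
  # dilated region = columns 2:4; vertical neighbors are equal so only the
  # x-direction contributes: u' = u + dt (left - 2u + right)
  expect_equal(out[4, 2], 0 + dt * (0 - 0 + 1), tolerance = 1e-12)
  expect_equal(out[4, 3], 1 + dt * (0 - 2 + 5), tolerance = 1e-12)
  expect_equal(out[4, 4], 5 + dt * (1 - 5), tolerance = 1e-12)
  # clamped outside the dilated region
  expect_identical(out[, c(1, 5)], f[, c(1, 5)])
  # the seam gradient strictly decreases
  expect_lt(max(abs(diff(out[4, ]))), max(abs(diff(f[4, ]))))
})
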