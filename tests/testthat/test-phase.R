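test_that("identical images give zero wrapped phase; delta cancels exactly", {
  M <- matrix(100, 12, 12)
  m <- M * exp(1i * 0.3)
  wp <- extract_wrapped_bz(m, m)
  expect_true(all(wp$phi == 0))

  set.seed(2)
  delta <- matrix(runif(144, -3, 3), 12, 12)
  bz <- matrix(rnorm(144, sd = 1e-8), 12, 12)
  p1 <- synthesize_complex_pair(M, delta, bz, Tc = 0.03)
  p0 <- synthesize_complex_pair(M, 0, bz, Tc = 0.03)
  w1 <- extract_wrapped_bz(p1)
  w0 <- extract_wrapped_bz(p0)
  expect_lt(max(abs(w1$phi - w0$phi)), 1e-12)
})

test_that("phase scaling to Bz is linear in 1/Tc", {
  u <- matrix(runif(64, -1, 1), 8, 8)
  expect_true(all(phase_to_bz(matrix(0, 8, 8), 0.03) == 0))
  expect_equal(phase_to_bz(u, 0.02), 2 * phase_to_bz(u, 0.04), tolerance = 1e-15)
  expect_error(phase_to_bz(u, -1), class = "mreit_validation_error")
})

test_that("the noiseless sub-pi phase chain recovers Bz to machine precision", {
  case <- fixture_case(64, "contrast")
  peak <- 2 * case$pairs[[1]]$gamma * case$electrodes$Tc * max(abs(case$bz_true$bz))
  expect_lt(peak, pi)  # sub-pi condition of this fixture
  meas <- measure_bz(case, magnitude_floor = 1)
  dm <- case$phantom$domain_mask
  err <- abs(meas$bz[, , 1, 1] - case$bz_true$bz[, , 1, 1])[dm]
  expect_lt(max(err, na.rm = TRUE), 1e-12 * max(abs(case$bz_true$bz)))
})

test_that("the chain also recovers Bz when the phase wraps", {
  case <- fixture_case(64, "contrast", electrodes = electrode_config(Tc = 0.12))
  peak <- 2 * case$pairs[[1]]$gamma * case$electrodes$Tc * max(abs(case$bz_true$bz))
  expect_gt(peak, pi)  # the fixture must actually wrap
  meas <- measure_bz(case, magnitude_floor = 1)
  dm <- case$phantom$domain_mask
  err <- abs(meas$bz[, , 1, 1] - case$bz_true$bz[, , 1, 1])[dm]
  expect_lt(max(err, na.rm = TRUE), 1e-12 * max(abs(case$bz_true$bz)))
})

test_that("z-continuity verification flags inter-slice jumps", {
  g <- slice_grid(8, 8, dx = 1e-3)
  xy <- mreit:::grid_xy(g)
  base <- 2 * xy$x + 3 * xy$y
  mk_vol <- function(slices) {
    sl <- lapply(slices, function(m)
      list(structure(list(grid = g, bz = m, valid = matrix(TRUE, 8, 8)),
                     class = "bz_slice")))
    bz_volume(sl, g)
  }
  # identical slices: all pairs pass, 3d recommended
  rep1 <- verify_z_continuity(mk_vol(list(base, base, base)))
  expect_true(all(rep1$pairs$pass))
  expect_identical(rep1$recommended_mode, "3d")

  # a large constant offset on the middle slice (a missed 2 pi jump): fail, 2d
  rep2 <- verify_z_continuity(mk_vol(list(base, base + 1, base)))
  expect_false(any(rep2$pairs$pass))
  expect_identical(rep2$recommended_mode, "2d")

  # single slice: no pairs, 2d by construction
  rep3 <- verify_z_continuity(mk_vol(list(base)))
  expect_identical(nrow(rep3$pairs), 0L)
  expect_identical(rep3$recommended_mode, "2d")
})

test_that("the continuity statistic matches its hand-computed definition", {
  g <- slice_grid(8, 8, dx = 1e-3)
  xy <- mreit:::grid_xy(g)
  base <- xy$x                 # in-plane gradient magnitude 1 everywhere
  c0 <- 2 * g$dx               # inter-slice difference: 2 pixel-increments
  vol <- bz_volume(lapply(list(base, base + c0, base + 2 * c0), function(m)
    list(structure(list(grid = g, bz = m, valid = matrix(TRUE, 8, 8)),
                   class = "bz_slice"))), g)
  rep <- verify_z_continuity(vol)
  # statistic = median |slice difference| / (median |grad| * pixel size)
  expect_equal(rep$pairs$statistic, c(2, 2), tolerance = 1e-12)
  expect_true(all(rep$pairs$pass))
})
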