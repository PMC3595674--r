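test_that("structure tensor closed forms: constants, ramps, quadratics", {
  n <- 16
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), n), n, n)

  U0 <- structure_tensor(matrix(3.7, n, n))
  expect_true(all(abs(U0$u11) < 1e-14) && all(abs(U0$u12) < 1e-14) &&
              all(abs(U0$u22) < 1e-14))

  # linear ramps carry no tensor energy: they are the preserved structure
  Ur <- structure_tensor(0.8 * x - 1.1 * y)
  inner <- 2:(n - 1)
  expect_lt(max(abs(Ur$u11[inner, inner])), 1e-12)
  expect_lt(max(abs(Ur$u22[inner, inner])), 1e-12)

  # quadratic x^2/2: second-derivative information, u11 = 1 interiorly
  Uq <- structure_tensor(x^2 / 2)
  core <- 3:(n - 2)
  expect_equal(Uq$u11[core, core], matrix(1, length(core), length(core)),
               tolerance = 1e-12)
  expect_lt(max(abs(Uq$u12[core, core])), 1e-12)
  expect_lt(max(abs(Uq$u22[core, core])), 1e-12)
})

test_that("diffusivity eigenstructure follows the tensor", {
  mk <- function(u11, u12, u22) list(u11 = matrix(u11, 1, 1),
                                     u12 = matrix(u12, 1, 1),
                                     u22 = matrix(u22, 1, 1))
  gI <- diffusivity(mk(0, 0, 0))
  expect_equal(c(gI$g11, gI$g12, gI$g22), c(1, 0, 1))

  gA <- diffusivity(mk(3, 0, 0))
  expect_equal(c(gA$g11, gA$g12, gA$g22), c(1 / 4, 0, 1), tolerance = 1e-14)

  # random PSD tensors against R's eigendecomposition
  set.seed(21)
  for (i in 1:25) {
    B <- matrix(rnorm(4), 2)
    U <- crossprod(B)
    g <- diffusivity(mk(U[1, 1], U[1, 2], U[2, 2]))
    eg <- eigen(U, symmetric = TRUE)
    Go <- eg$vectors %*% diag(1 / (1 + eg$values)) %*% t(eg$vectors)
    expect_lt(max(abs(c(g$g11 - Go[1, 1], g$g12 - Go[1, 2], g$g22 - Go[2, 2]))), 1e-12)
  }
})

test_that("diffusivity eigenvalues stay in (0, 1] for arbitrary tensors", {
  set.seed(31)
  U <- structure_tensor(matrix(rnorm(400), 20, 20))
  Ureg <- regularize_tensor(U, diffusion_settings())
  g <- diffusivity(Ureg)
  tr <- g$g11 + g$g22
  det <- g$g11 * g$g22 - g$g12^2
  disc <- sqrt(pmax((g$g11 - g$g22)^2 + 4 * g$g12^2, 0))
  lmax <- (tr + disc) / 2; lmin <- (tr - disc) / 2
  expect_true(all(lmax <= 1 + 1e-12))
  expect_true(all(lmin > 0))
})

test_that("tensor regularization preserves trivial fields and conserves mass", {
  n <- 20
  z <- structure_tensor(matrix(0, n, n))
  zr <- regularize_tensor(z, diffusion_settings())
  expect_lt(max(abs(zr$u11)), 1e-14)

  set.seed(13)
  U <- structure_tensor(matrix(rnorm(n * n), n, n))
  Ur <- regularize_tensor(U, diffusion_settings())
  for (comp in c("u11", "u12", "u22")) {
    s0 <- sum(U[[comp]][U$valid]); s1 <- sum(Ur[[comp]][Ur$valid])
    expect_lt(abs(s1 - s0) / max(abs(s0), 1e-300), 1e-10)
  }
})

test_that("denoising preserves constants and conserves mass", {
  n <- 24
  cst <- matrix(5, n, n)
  out <- ramp_preserving_denoise(cst, diffusion_settings(T1 = 1))
  expect_equal(out, cst, tolerance = 1e-12)

  expect_identical(ramp_preserving_denoise(cst, diffusion_settings(T1 = 0)), cst)

  set.seed(17)
  f <- matrix(rnorm(n * n), n, n)
  den <- ramp_preserving_denoise(f, diffusion_settings(T1 = 0.6))
  expect_lt(abs(sum(den) - sum(f)) / abs(sum(f)), 1e-10)
})

test_that("diffusion contracts the centered L2 norm", {
  set.seed(19)
  f <- matrix(rnorm(400), 20, 20)
  st <- diffusion_settings(T1 = 0.2)
  prev <- f
  for (i in 1:3) {
    cur <- ramp_preserving_denoise(prev, st)
    expect_lte(sum((cur - mean(cur))^2), sum((prev - mean(prev))^2) + 1e-12)
    prev <- cur
  }
})

test_that("a clean piecewise-ramp profile passes through nearly unchanged", {
  ramp <- ramp_fixture(128, 64)
  out <- ramp_preserving_denoise(ramp, diffusion_settings(T1 = 1))
  expect_lt(max(abs(out - ramp)) / diff(range(ramp)), 0.01)
})

test_that("denoising noisy Bz improves both the field and its Laplacian", {
  case <- fixture_case(64, "default")
  g <- case$phantom$grid
  dm <- case$phantom$domain_mask
  clean <- case$bz_true$bz[, , 1, 1]
  rng <- diff(range(clean[dm]))
  set.seed(42)
  noisy <- clean + matrix(rnorm(length(clean), sd = 0.05 * rng),
                          nrow(clean), ncol(clean))
  den <- ramp_preserving_denoise(noisy, diffusion_settings(T1 = 1), mask = dm)
  expect_lt(rmse_on(den, clean, dm), rmse_on(noisy, clean, dm))
  lc <- mreit:::laplacian5(clean, g$dx, g$dy, dm)
  ln <- mreit:::laplacian5(noisy, g$dx, g$dy, dm)
  ld <- mreit:::laplacian5(den, g$dx, g$dy, dm)
  ok <- is.finite(lc) & is.finite(ln) & is.finite(ld)
  expect_gt(rmse_on(ln, lc, ok) / rmse_on(ld, lc, ok), 2)
})
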