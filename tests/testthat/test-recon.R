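mk_volume <- function(g, mats, valid = NULL) {
  sl <- lapply(mats, function(m)
    list(structure(list(grid = g, bz = m,
                        valid = if (is.null(valid)) matrix(TRUE, g$ny, g$nx) else valid),
                   class = "bz_slice")))
  bz_volume(sl, g)
}

test_that("the Bz Laplacian stencil is exact on quadratics and linears", {
  g <- slice_grid(16, 16, dx = 2e-3)
  xy <- mreit:::grid_xy(g)
  v <- mk_volume(g, list(xy$x^2))
  lap <- laplacian_bz(v, margin = 0)$lap
  ok <- is.finite(lap)
  expect_equal(lap[ok], rep(2, sum(ok)), tolerance = 1e-10)

  vlin <- mk_volume(g, list(3 * xy$x - 2 * xy$y))
  lap2 <- laplacian_bz(vlin, margin = 0)$lap
  expect_lt(max(abs(lap2[is.finite(lap2)])), 1e-10)
})

test_that("3d mode adds the hand-computed second difference across slices", {
  g <- slice_grid(8, 8, dx = 1e-3, dz = 2e-3)
  xy <- mreit:::grid_xy(g)
  zs <- (0:2) * g$dz
  mats <- lapply(zs, function(z) xy$x^2 + matrix(z^2, 8, 8))
  v <- mk_volume(g, mats)
  rep_ <- verify_z_continuity(v)
  lap3 <- laplacian_bz(v, slice = 2, mode = "3d", report = rep_, margin = 0)$lap
  # d2/dz2 of z^2 adds exactly 2 to the in-plane value 2
  ok <- is.finite(lap3)
  expect_equal(lap3[ok], rep(4, sum(ok)), tolerance = 1e-8)
  # edge slices and refused gates
  expect_error(laplacian_bz(v, slice = 1, mode = "3d", report = rep_),
               class = "mreit_validation_error")
  bad <- mk_volume(g, list(xy$x, xy$x + 1, xy$x))
  bad_rep <- verify_z_continuity(bad)
  expect_error(laplacian_bz(bad, slice = 2, mode = "3d", report = bad_rep),
               class = "mreit_quality_error")
})

test_that("the transverse-current matrix follows its closed form", {
  g <- slice_grid(8, 8, dx = 1e-3)
  cJ <- function(jx, jy) structure(list(grid = g, Jx = matrix(jx, 8, 8),
                                        Jy = matrix(jy, 8, 8),
                                        valid = matrix(TRUE, 8, 8)),
                                   class = "current_density")
  cc <- 3
  A <- build_a_matrix(cJ(-cc, 0), cJ(0, cc))
  expect_equal(A$mJy1[1, 1], 0)
  expect_equal(A$Jx1[1, 1], -cc)
  expect_equal(A$mJy2[1, 1], -cc)
  expect_equal(A$det[1, 1], -cc^2)
  expect_true(all(A$reliable))

  # parallel currents: rank deficient everywhere, all flagged
  expect_warning(Ap <- build_a_matrix(cJ(-cc, 0), cJ(-cc, 0)),
                 class = "mreit_warning")
  expect_false(any(Ap$reliable))
})

test_that("the determinant matches recomputation from the stored currents", {
  case <- fixture_case(48, "default")
  A <- build_a_matrix(case$J[[1]], case$J[[2]])
  ok <- A$valid
  det_oracle <- case$J[[1]]$Jx * case$J[[2]]$Jy - case$J[[1]]$Jy * case$J[[2]]$Jx
  expect_equal(A$det[ok], det_oracle[ok], tolerance = 1e-12)
})

test_that("a zero right-hand side reconstructs sigma identically 1", {
  case <- fixture_case(32, "homog")
  A <- build_a_matrix(case$J[[1]], case$J[[2]])
  zero <- matrix(0, 32, 32)
  rec <- harmonic_bz_reconstruct(case$mesh, A, zero, zero)
  expect_equal(rec$sigma, rep(1, length(rec$sigma)), tolerance = 1e-12)
  expect_true(all(rec$log_sigma[mreit:::boundary_vertices(case$mesh)] == 0))
})

test_that("a homogeneous phantom reconstructs near unity", {
  case <- fixture_case(64, "homog")
  A <- build_a_matrix(case$J[[1]], case$J[[2]])
  rec <- harmonic_bz_reconstruct(case$mesh, A,
                                 laplacian_bz(case$bz_true, 1, 1),
                                 laplacian_bz(case$bz_true, 1, 2))
  expect_lt(max(abs(rec$sigma - 1)), 0.02)
})

test_that("reconstruction is invariant to an affine harmonic background", {
  case <- fixture_case(48, "homog")
  g <- case$phantom$grid
  A <- build_a_matrix(case$J[[1]], case$J[[2]])
  rec0 <- harmonic_bz_reconstruct(case$mesh, A,
                                  laplacian_bz(case$bz_true, 1, 1),
                                  laplacian_bz(case$bz_true, 1, 2))
  xy <- mreit:::grid_xy(g)
  aff <- 5e-8 + 3e-6 * xy$x - 2e-6 * xy$y
  shifted <- mk_volume(g, list(case$bz_true$bz[, , 1, 1] + aff),
                       valid = case$bz_true$valid[, , 1, 1])
  shifted2 <- mk_volume(g, list(case$bz_true$bz[, , 1, 2] + aff),
                        valid = case$bz_true$valid[, , 1, 2])
  rec1 <- harmonic_bz_reconstruct(case$mesh, A,
                                  laplacian_bz(shifted, 1, 1),
                                  laplacian_bz(shifted2, 1, 1))
  expect_lt(max(abs(rec1$log_sigma - rec0$log_sigma)), 1e-10)
})

test_that("symmetric rescaling of Bz and currents leaves sigma unchanged", {
  case <- fixture_case(48, "homog")
  g <- case$phantom$grid
  A <- build_a_matrix(case$J[[1]], case$J[[2]])
  l1 <- laplacian_bz(case$bz_true, 1, 1); l2 <- laplacian_bz(case$bz_true, 1, 2)
  rec0 <- harmonic_bz_reconstruct(case$mesh, A, l1, l2)
  cfac <- 3.7
  Js <- lapply(case$J, function(J) { J$Jx <- J$Jx * cfac; J$Jy <- J$Jy * cfac; J })
  A2 <- build_a_matrix(Js[[1]], Js[[2]])
  l1s <- l1; l1s$lap <- l1$lap * cfac
  l2s <- l2; l2s$lap <- l2$lap * cfac
  rec1 <- harmonic_bz_reconstruct(case$mesh, A2, l1s, l2s)
  expect_lt(max(abs(rec1$log_sigma - rec0$log_sigma)),
            1e-10 * max(abs(rec0$log_sigma), 1e-12))
})

test_that("recovery error improves under mesh refinement until data error dominates", {
  case <- fixture_case(48, "homog")
  g <- case$phantom$grid
  el <- case$electrodes
  l1 <- laplacian_bz(case$bz_true, 1, 1); l2 <- laplacian_bz(case$bz_true, 1, 2)
  errs <- vapply(c(1, 4, 16), function(div) {
    mesh <- mesh_from_mask(g, case$phantom$domain_mask, el,
                           max_area = g$dx * g$dy / 2 / div)
    pots <- lapply(1:2, function(j) solve_forward_2d(case$phantom, el, j, mesh = mesh))
    Js <- lapply(pots, function(p) current_density(case$phantom, p, el))
    A <- build_a_matrix(Js[[1]], Js[[2]])
    rec <- harmonic_bz_reconstruct(mesh, A, l1, l2)
    max(abs(rec$sigma - 1))
  }, 0)
  expect_lt(errs[2], errs[1])
  # the finest level saturates at the data-discretization floor
  expect_lte(errs[3], errs[1] * 1.05)
})

test_that("a local region equal to the whole domain matches the global solve", {
  case <- fixture_case(48, "lowcontrast")
  g <- case$phantom$grid
  A <- build_a_matrix(case$J[[1]], case$J[[2]])
  l1 <- laplacian_bz(case$bz_true, 1, 1); l2 <- laplacian_bz(case$bz_true, 1, 2)
  glob <- harmonic_bz_reconstruct(case$mesh, A, l1, l2)
  poly <- segment_domain(case$M, g)
  loc <- local_harmonic_bz(poly, A, l1, l2, g)
  both <- is.finite(glob$raster) & is.finite(loc$raster)
  # the segmented polygon's pixelation differs from the mask by at most a
  # boundary ring; away from it the two solves agree (differences decay
  # inward from the slightly different Dirichlet boundary)
  er <- erode_mask(both, 3)
  expect_gt(mean(both[case$phantom$domain_mask]), 0.95)
  expect_lt(max(abs(glob$raster[er] - loc$raster[er])), 1e-3)
})

test_that("local reconstruction on a homogeneous phantom stays near 1", {
  case <- fixture_case(48, "homog")
  g <- case$phantom$grid
  ctr <- mreit:::grid_center(g)
  half <- c((g$nx - 1) * g$dx / 2, (g$ny - 1) * g$dy / 2)
  s <- 0.3
  D <- rbind(c(ctr[1] - s * half[1], ctr[2] - s * half[2]),
             c(ctr[1] + s * half[1], ctr[2] - s * half[2]),
             c(ctr[1] + s * half[1], ctr[2] + s * half[2]),
             c(ctr[1] - s * half[1], ctr[2] + s * half[2]))
  A <- build_a_matrix(case$J[[1]], case$J[[2]])
  rec <- local_harmonic_bz(mreit:::new_domain_polygon(D), A,
                           laplacian_bz(case$bz_true, 1, 1),
                           laplacian_bz(case$bz_true, 1, 2), g)
  expect_lt(max(abs(rec$sigma - 1)), 0.02)
})
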