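# One-pass harmonic Bz reconstruction of scaled conductivity.
#
# The identity behind the method: with two independent injections,
#   [d(ln sigma)/dx; d(ln sigma)/dy] = (1/mu0) A^-1 [lap Bz1; lap Bz2],
# where A has rows (-Jy_j, Jx_j). Taking the 2D divergence gives a Poisson
# equation for ln sigma, solved with P1 finite elements, Dirichlet
# ln sigma = 0 on the region boundary (sigma = 1 there), and a weak-form
# right-hand side (the vector field F = A^-1 [lap Bz] is integrated against
# test-function gradients, avoiding yet another differentiation of noisy
# data). One pass with sigma0 = 1 yields the scaled conductivity image.

#' Laplacian of Bz on the pixel grid
#'
#' 2D mode: five-point stencil with physical spacings. 3D mode adds the
#' second difference across adjacent slices (requires at least 3 slices and a
#' passing continuity report; refuse otherwise unless `force`). The
#' evaluation mask excludes stencil-incomplete pixels.
#'
#' @param bz a `bz_volume`.
#' @param slice slice index at which to evaluate.
#' @param injection injection index.
#' @param mode `"2d"` or `"3d"`.
#' @param report a `continuity_report`, required for 3D mode.
#' @param force bypass the continuity gate.
#' @param margin extra erosion rings applied to the validity mask before the
#'   stencil requirement. Bz is only C^1 across the domain boundary (the
#'   tangential current jumps to zero there), so stencils reaching into the
#'   outermost ring pick up the boundary layer; one extra ring keeps the
#'   evaluation clear of it.
#' @return object of class `laplacian_field`: matrix `lap` (NA outside the
#'   evaluation mask), `mode`, spacings used.
#' @export
laplacian_bz <- function(bz, slice = 1L, injection = 1L,
                         mode = c("2d", "3d"), report = NULL, force = FALSE,
                         margin = 1L) {
  mode <- match.arg(mode)
  if (!inherits(bz, "bz_volume")) stop_validation("bz must be a bz_volume")
  m <- bz$bz[, , slice, injection]
  v <- bz$valid[, , slice, injection]
  if (margin > 0) for (i in seq_len(margin)) v <- v & !boundary_ring(v)
  lap <- laplacian5(m, bz$grid$dx, bz$grid$dy, v)
  if (mode == "3d") {
    if (bz$nz < 3 || slice == 1L || slice == bz$nz)
      stop_validation("3d Laplacian needs interior slices of a volume with nz >= 3")
    if (is.null(report) && !force)
      stop_quality("3d mode requires a continuity report (or force = TRUE)")
    if (!is.null(report) && report$recommended_mode != "3d" && !force)
      stop_quality("continuity verification recommends 2d mode; refusing 3d (use force to override)")
    up <- bz$bz[, , slice + 1, injection]
    dn <- bz$bz[, , slice - 1, injection]
    okz <- v & bz$valid[, , slice + 1, injection] & bz$valid[, , slice - 1, injection]
    zterm <- (up + dn - 2 * m) / bz$grid$dz^2
    lap <- lap + ifelse(okz, zterm, NA_real_)
  }
  structure(list(lap = lap, mode = mode, grid = bz$grid,
                 slice = slice, injection = injection),
            class = "laplacian_field")
}

#' Transverse-current matrix field from the two reference potentials
#'
#' Builds, per pixel, the 2x2 matrix with rows `(-Jy1, Jx1)` and
#' `(-Jy2, Jx2)` from the current densities of the two injections solved with
#' the reference conductivity (the one-pass initial guess sigma0 = 1), plus
#' its determinant and a reliability flag: points where `|det|` falls below
#' `det_fraction` times the median `|det|` are flagged unreliable.
#'
#' @param J1,J2 `current_density` objects for injections 1 and 2.
#' @param det_fraction reliability threshold fraction of the median `|det|`.
#' @return object of class `a_matrix_field`: matrices `mJy1`, `Jx1`, `mJy2`,
#'   `Jx2`, `det`, logical `reliable`, `valid`.
#' @export
build_a_matrix <- function(J1, J2, det_fraction = 1e-3) {
  if (!all(dim(J1$Jx) == dim(J2$Jx))) stop_validation("current grids differ")
  valid <- J1$valid & J2$valid
  det <- J1$Jx * J2$Jy - J1$Jy * J2$Jx   # det of [(-Jy1, Jx1); (-Jy2, Jx2)]
  det[!valid] <- NA_real_
  med <- stats::median(abs(det[valid]), na.rm = TRUE)
  reliable <- valid & is.finite(det) & abs(det) > 0 &
    is.finite(med) & med > 0 & abs(det) >= det_fraction * med
  frac_bad <- 1 - sum(reliable) / max(sum(valid), 1)
  if (frac_bad > 0.2)
    warn_mreit("%.0f%% of points have a near-singular current matrix", 100 * frac_bad)
  structure(list(mJy1 = -J1$Jy, Jx1 = J1$Jx, mJy2 = -J2$Jy, Jx2 = J2$Jx,
                 det = det, reliable = reliable, valid = valid,
                 grid = J1$grid),
            class = "a_matrix_field")
}

# Per-pixel F = A^-1 [L1; L2] (optionally / mu0); 0 where unreliable/invalid.
a_inverse_apply <- function(a_field, L1, L2, mu0_scaling = TRUE) {
  det <- a_field$det
  ok <- a_field$reliable & is.finite(L1) & is.finite(L2)
  # A = [(-Jy1, Jx1); (-Jy2, Jx2)]; A^-1 = (1/det) [(Jx2, -Jx1); (Jy2, -Jy1)]
  F1 <- (a_field$Jx2 * L1 - a_field$Jx1 * L2) / det
  F2 <- (-a_field$mJy2 * L1 + a_field$mJy1 * L2) / det
  F1[!ok] <- 0; F2[!ok] <- 0
  if (mu0_scaling) { F1 <- F1 / mu0; F2 <- F2 / mu0 }
  list(F1 = F1, F2 = F2, used = ok)
}

#' One-pass harmonic Bz reconstruction of scaled conductivity
#'
#' Solves the weak-form Poisson problem `lap(ln sigma) = div F` with
#' `F = (1/mu0) A^-1 [lap Bz1; lap Bz2]` sampled at element centroids and
#' integrated against test-function gradients, under the Dirichlet boundary
#' condition `ln sigma = 0` (sigma = 1) on the region boundary. A Neumann
#' variant (natural boundary condition `grad(ln sigma) . n = F . n`, with one
#' pinned vertex) is available via `boundary = "neumann"`.
#'
#' @param mesh `triangle_mesh` of the reconstruction region.
#' @param a_field an `a_matrix_field`.
#' @param lap1,lap2 `laplacian_field`s (or matrices) for the two injections.
#' @param mu0_scaling divide F by mu0 (appropriate when Bz and J carry
#'   physical units); a pure global scale in the log, so it cannot change the
#'   contrast image.
#' @param boundary `"dirichlet"` (default) or `"neumann"`.
#' @param tol CG tolerance.
#' @return object of class `scaled_conductivity`: vertex `log_sigma` and
#'   `sigma`, pixel `raster` (sigma, NA outside the region), `mesh`,
#'   `excluded` (count of RHS points zeroed as unreliable), CG diagnostics.
#' @export
harmonic_bz_reconstruct <- function(mesh, a_field, lap1, lap2,
                                    mu0_scaling = TRUE,
                                    boundary = c("dirichlet", "neumann"),
                                    tol = 1e-8) {
  boundary <- match.arg(boundary)
  L1 <- if (inherits(lap1, "laplacian_field")) lap1$lap else lap1
  L2 <- if (inherits(lap2, "laplacian_field")) lap2$lap else lap2
  grid <- a_field$grid
  FF <- a_inverse_apply(a_field, L1, L2, mu0_scaling)
  if (!any(FF$used)) stop_solver("no reliable points to build the right-hand side from")

  system <- assemble_p1(mesh, 1)
  cen <- mesh_centroids(mesh)
  F1c <- sample_bilinear(ifelse(FF$used, FF$F1, NA_real_), grid, cen[, 1], cen[, 2])
  F2c <- sample_bilinear(ifelse(FF$used, FF$F2, NA_real_), grid, cen[, 1], cen[, 2])
  miss <- !is.finite(F1c) | !is.finite(F2c)
  F1c[miss] <- 0; F2c[miss] <- 0

  # load_i = sum_e A_e F_e . grad(phi_i)
  v <- mesh$vertices; t <- mesh$triangles
  x1 <- v[t[, 1], 1]; y1 <- v[t[, 1], 2]
  x2 <- v[t[, 2], 1]; y2 <- v[t[, 2], 2]
  x3 <- v[t[, 3], 1]; y3 <- v[t[, 3], 2]
  area2 <- x2 * y3 - x3 * y2 - x1 * y3 + x3 * y1 + x1 * y2 - x2 * y1
  b <- cbind(y2 - y3, y3 - y1, y1 - y2)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1)
  load <- numeric(nrow(v))
  for (i in 1:3) {
    # A_e * F . grad(phi_i) with grad(phi_i) = (b_i, c_i) / (2 A_e)
    contrib <- (F1c * b[, i] + F2c * cc[, i]) / 2
    load <- load + accumulate_load(contrib, t[, i], nrow(v))
  }
  system$load <- load

  if (boundary == "dirichlet") {
    bv <- boundary_vertices(mesh)
    system <- set_dirichlet(system, bv, 0)
  } else {
    # natural condition is built into the weak form; pin one vertex
    system <- set_dirichlet(system, boundary_vertices(mesh)[1], 0)
  }
  sol <- solve_cg(system, tol = tol)
  log_sigma <- sol$u
  sigma <- exp(log_sigma)
  raster <- rasterize_mesh(mesh, sigma, grid)
  structure(list(log_sigma = log_sigma, sigma = sigma, raster = raster,
                 mesh = mesh, boundary = boundary,
                 excluded = sum(!FF$used & a_field$valid),
                 cg = sol[c("iterations", "relres")]),
            class = "scaled_conductivity")
}

accumulate_load <- function(values, index, n) {
  out <- numeric(n)
  s <- rowsum(values, index)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' @export
print.scaled_conductivity <- function(x, ...) {
  cat(sprintf("<scaled_conductivity> sigma in [%.3g, %.3g], %s boundary, %d RHS points excluded, CG %d iters\n",
              min(x$sigma), max(x$sigma), x$boundary, x$excluded, x$cg$iterations))
  invisible(x)
}

#' Local harmonic Bz reconstruction on a polygonal region
#'
#' Runs the identical Poisson solve restricted to a local region D with
#' `ln sigma = 0` on the boundary of D, isolating D from corrupted data
#' elsewhere in the domain.
#'
#' @param region a `domain_polygon` (e.g. from [clip_local_region()]).
#' @param a_field an `a_matrix_field`.
#' @param lap1,lap2 Laplacian fields for the two injections.
#' @param grid [slice_grid()] used to mesh the region.
#' @param max_area mesh area constraint; default half a pixel.
#' @param ... passed to [harmonic_bz_reconstruct()].
#' @return a `scaled_conductivity` on the local region.
#' @export
local_harmonic_bz <- function(region, a_field, lap1, lap2, grid,
                              max_area = NULL, ...) {
  mesh <- triangulate_domain(region, max_area = max_area, grid = grid)
  harmonic_bz_reconstruct(mesh, a_field, lap1, lap2, ...)
}
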