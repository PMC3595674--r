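#' Solve the simplified 2D forward problem for one injection
#'
#' Solves `div(sigma grad u) = 0` on the slice domain with Dirichlet data
#' `u = +1` on the positive electrode arc, `u = -1` on the negative arc, and a
#' natural (zero Neumann) condition elsewhere, using P1 finite elements and
#' conjugate gradients. The Dirichlet normalization makes the potential
#' dimensionless; physical current amplitude only rescales the simulated
#' fields and is applied downstream (see [current_density()]).
#'
#' @param phantom a `conductivity_phantom`.
#' @param electrodes an [electrode_config()].
#' @param j injection index, 1 or 2.
#' @param mesh optional precomputed `triangle_mesh` with electrode markers;
#'   built from the phantom's domain mask when omitted.
#' @param tol CG relative residual tolerance.
#' @return object of class `potential_field`: `mesh`, vertex values `u`,
#'   `injection`, electrode fluxes `flux_pos`/`flux_neg` (per unit z-length,
#'   in the dimensionless potential scale), CG diagnostics.
#' @export
solve_forward_2d <- function(phantom, electrodes, j, mesh = NULL, tol = 1e-10) {
  if (!j %in% c(1L, 2L)) stop_validation("injection index j must be 1 or 2")
  if (is.null(mesh))
    mesh <- mesh_from_mask(phantom$grid, phantom$domain_mask, electrodes)
  sig <- element_sigma(mesh, phantom)
  if (any(sig <= 0)) stop_validation("conductivity interpolated to elements must be positive")
  system <- assemble_p1(mesh, sig)

  vpos <- boundary_vertices(mesh, sprintf("E%d+", j))
  vneg <- boundary_vertices(mesh, sprintf("E%d-", j))
  if (length(vpos) == 0 || length(vneg) == 0)
    stop_validation("mesh has no boundary edges marked for injection %d", j)
  system <- set_dirichlet(system, c(vpos, vneg),
                          c(rep(1, length(vpos)), rep(-1, length(vneg))))
  sol <- solve_cg(system, tol = tol)
  # boundary flux = residual of the unconstrained system at constrained nodes
  resid <- as.numeric(system$stiffness %*% sol$u)
  structure(list(mesh = mesh, u = sol$u, injection = j,
                 sigma_element = sig,
                 flux_pos = sum(resid[vpos]), flux_neg = sum(resid[vneg]),
                 cg = sol[c("iterations", "relres")]),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field> injection %d, u in [%.3g, %.3g], flux %.4g / %.4g, CG %d iters (relres %.2g)\n",
              x$injection, min(x$u), max(x$u), x$flux_pos, x$flux_neg,
              x$cg$iterations, x$cg$relres))
  invisible(x)
}

# Element conductivity: the phantom's sigma is piecewise constant per pixel,
# so pixel-aligned elements take their own pixel's value exactly; meshes not
# aligned to the phantom grid fall back to bilinear centroid sampling.
element_sigma <- function(mesh, phantom) {
  grid <- phantom$grid
  if (!is.na(mesh$k) && !is.null(mesh$grid) &&
      identical(mesh$grid[c("nx", "ny", "dx", "dy")], grid[c("nx", "ny", "dx", "dy")])) {
    k <- mesh$k
    pr <- (mesh$tri_cell[, 1] - 1L) %/% k + 1L
    pc <- (mesh$tri_cell[, 2] - 1L) %/% k + 1L
    sig <- phantom$sigma[cbind(pr, pc)]
  } else {
    cen <- mesh_centroids(mesh)
    sig <- sample_bilinear(phantom$sigma, grid, cen[, 1], cen[, 2])
  }
  sig[!is.finite(sig)] <- 1  # centroids grazing the raster edge: background
  sig
}

# Per-element constant gradient of a P1 vertex field: m x 2 matrix.
element_gradient <- function(mesh, u) {
  v <- mesh$vertices; t <- mesh$triangles
  x1 <- v[t[, 1], 1]; y1 <- v[t[, 1], 2]
  x2 <- v[t[, 2], 1]; y2 <- v[t[, 2], 2]
  x3 <- v[t[, 3], 1]; y3 <- v[t[, 3], 2]
  area2 <- x2 * y3 - x3 * y2 - x1 * y3 + x3 * y1 + x1 * y2 - x2 * y1
  b1 <- y2 - y3; b2 <- y3 - y1; b3 <- y1 - y2
  c1 <- x3 - x2; c2 <- x1 - x3; c3 <- x2 - x1
  gx <- (u[t[, 1]] * b1 + u[t[, 2]] * b2 + u[t[, 3]] * b3) / area2
  gy <- (u[t[, 1]] * c1 + u[t[, 2]] * c2 + u[t[, 3]] * c3) / area2
  cbind(gx, gy)
}

# Physical scaling for simulated currents: the Dirichlet +-1 solve carries a
# boundary flux per unit z-length; scaling J by I / (flux * dz) makes a slab
# of thickness dz carry the configured current amplitude.
current_scale <- function(potential, electrodes, grid) {
  flux <- abs(potential$flux_pos)
  if (flux <= 0) stop_solver("forward solve produced zero electrode flux")
  electrodes$I / (flux * grid$dz)
}

#' In-plane current density from a solved potential
#'
#' Computes the element-wise current density `J = -sigma grad(u)` and
#' rasterizes it to pixel centers (average of the two triangles covering each
#' pixel). With `electrodes` supplied, J is rescaled so that a slab of
#' thickness `dz` carries the configured current amplitude `I`, giving J in
#' A/m^2; otherwise it stays in the dimensionless potential scale.
#'
#' @param phantom the `conductivity_phantom` the potential was solved on.
#' @param potential a `potential_field`.
#' @param electrodes optional [electrode_config()] for physical scaling.
#' @return object of class `current_density`: `grid`, matrices `Jx`, `Jy`,
#'   logical `valid` (pixels covered by the mesh), `scale` applied.
#' @export
current_density <- function(phantom, potential, electrodes = NULL) {
  mesh <- potential$mesh
  grid <- phantom$grid
  g <- element_gradient(mesh, potential$u)
  Jx_e <- -potential$sigma_element * g[, 1]
  Jy_e <- -potential$sigma_element * g[, 2]
  scale <- if (is.null(electrodes)) 1 else current_scale(potential, electrodes, grid)
  Jx_e <- Jx_e * scale; Jy_e <- Jy_e * scale

  # pixel value = mean over the triangles of the cells covering the pixel
  k <- mesh$k
  lo <- mesh$cell_tri_lo; hi <- mesh$cell_tri_hi
  cells <- which(!is.na(lo), arr.ind = TRUE)
  pr <- (cells[, 1] - 1L) %/% k + 1L
  pc <- (cells[, 2] - 1L) %/% k + 1L
  tl <- lo[cells]; th <- hi[cells]
  lin <- (pc - 1L) * grid$ny + pr
  idx2 <- c(lin, lin)
  sx <- rowsum(c(Jx_e[tl], Jx_e[th]), idx2)
  sy <- rowsum(c(Jy_e[tl], Jy_e[th]), idx2)
  cn <- rowsum(rep(1, length(idx2)), idx2)
  where <- as.integer(rownames(sx))
  Jx <- matrix(NA_real_, grid$ny, grid$nx); Jy <- Jx
  valid <- matrix(FALSE, grid$ny, grid$nx)
  Jx[where] <- sx[, 1] / cn[, 1]
  Jy[where] <- sy[, 1] / cn[, 1]
  valid[where] <- TRUE
  structure(list(grid = grid, Jx = Jx, Jy = Jy, valid = valid,
                 injection = potential$injection, scale = scale),
            class = "current_density")
}

#' @export
print.current_density <- function(x, ...) {
  cat(sprintf("<current_density> injection %d, |J| up to %.3g, %d valid pixels, scale %.3g\n",
              x$injection, max(sqrt(x$Jx^2 + x$Jy^2), na.rm = TRUE),
              sum(x$valid), x$scale))
  invisible(x)
}
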