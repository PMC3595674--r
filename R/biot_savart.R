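#' Magnetic flux density Bz from an in-plane current density
#'
#' Evaluates the z-component of the Biot-Savart integral at the pixel centers
#' of the slice, for a planar current density extruded along z. Two extrusion
#' models are available:
#'
#' * `"infinite"` (default): the current is translationally invariant in z,
#'   giving the 2D kernel `2 / rho^2`. Bz is then independent of z and the
#'   in-plane Laplacian identity `lap2 Bz = -mu0 (dJy/dx - dJx/dy)` holds
#'   exactly in the continuum — the model under which the harmonic Bz
#'   reconstruction with a 2D Laplacian is consistent.
#' * `"slab"`: the current occupies a slab of thickness `dz`, kernel
#'   `dz / (rho^2 sqrt(rho^2 + dz^2/4))`, evaluated on the slab midplane.
#'
#' The integral is computed as a discrete convolution over source pixels; in
#' the near field (offsets up to `near_radius` pixels) the kernel is averaged
#' over an `nsub x nsub` midpoint subdivision of the source pixel, which also
#' defines the singular self-pixel rule (its contribution vanishes by
#' antisymmetry of the midpoint subgrid). An optional additive background
#' field can be supplied as an affine (hence harmonic) function
#' `c(a0, ax, ay)`: `a0 + ax x + ay y` in Tesla.
#'
#' @param J a `current_density` (values in A/m^2 for physical output).
#' @param grid target [slice_grid()]; defaults to the grid of `J`.
#' @param thickness_model `"infinite"` or `"slab"`.
#' @param near_radius,nsub near-field quadrature controls.
#' @param background optional affine background coefficients `c(a0, ax, ay)`.
#' @return object of class `bz_slice`: `grid`, matrix `bz` (Tesla), logical
#'   `valid`.
#' @export
biot_savart_bz <- function(J, grid = J$grid, thickness_model = c("infinite", "slab"),
                           near_radius = 5L, nsub = 8L, background = NULL) {
  thickness_model <- match.arg(thickness_model)
  ny <- grid$ny; nx <- grid$nx
  if (ny < 1 || nx < 1) stop_validation("target point set is empty")
  Jx <- J$Jx; Jy <- J$Jy
  Jx[!J$valid] <- 0; Jy[!J$valid] <- 0

  kr <- kernel_tables(grid, thickness_model, near_radius, nsub)
  bz <- mu0 / (4 * pi) * grid$dx * grid$dy *
    (conv2_offsets(Jx, kr$ky) - conv2_offsets(Jy, kr$kx))
  if (!is.null(background)) {
    if (length(background) != 3) stop_validation("background must be c(a0, ax, ay)")
    xy <- grid_xy(grid)
    bz <- bz + background[1] + background[2] * xy$x + background[3] * xy$y
  }
  structure(list(grid = grid, bz = bz, valid = matrix(TRUE, ny, nx),
                 thickness_model = thickness_model),
            class = "bz_slice")
}

# Offset kernels kx(dx, dy) = dx * K(rho), ky = dy * K(rho) tabulated on the
# (2ny-1) x (2nx-1) offset lattice, with near-field midpoint subdivision.
kernel_tables <- function(grid, thickness_model, near_radius, nsub) {
  ny <- grid$ny; nx <- grid$nx
  ddx <- (-(nx - 1)):(nx - 1) * grid$dx
  ddy <- (-(ny - 1)):(ny - 1) * grid$dy
  DX <- matrix(ddx, 2 * ny - 1, 2 * nx - 1, byrow = TRUE)
  DY <- matrix(ddy, 2 * ny - 1, 2 * nx - 1)
  krho <- function(dx, dy) {
    r2 <- dx^2 + dy^2
    if (thickness_model == "infinite") 2 / r2
    else grid$dz / (r2 * sqrt(r2 + grid$dz^2 / 4))
  }
  kx <- DX * krho(DX, DY)
  ky <- DY * krho(DX, DY)
  # near field: average the kernel over each source pixel
  nearc <- abs(DX) <= near_radius * grid$dx + 1e-15 &
           abs(DY) <= near_radius * grid$dy + 1e-15
  sub <- (seq_len(nsub) - 0.5) / nsub - 0.5
  off <- which(nearc)
  accx <- numeric(length(off)); accy <- numeric(length(off))
  for (u in sub) for (v in sub) {
    ddx2 <- DX[off] - u * grid$dx
    ddy2 <- DY[off] - v * grid$dy
    kk <- krho(ddx2, ddy2)
    accx <- accx + ddx2 * kk
    accy <- accy + ddy2 * kk
  }
  kx[off] <- accx / nsub^2
  ky[off] <- accy / nsub^2
  # the exact singular point never coincides with a midpoint, and the
  # self-pixel sum cancels by antisymmetry; enforce it exactly
  kx[ny, nx] <- 0
  ky[ny, nx] <- 0
  list(kx = kx, ky = ky)
}

# Correlation-style convolution: out[r, c] = sum_{r', c'} f[r', c'] *
# ker[r - r' + ny, c - c' + nx], with ker on the full offset lattice, via FFT.
conv2_offsets <- function(f, ker) {
  ny <- nrow(f); nx <- ncol(f)
  pr <- stats::nextn(3 * ny - 2, c(2, 3, 5))
  pc <- stats::nextn(3 * nx - 2, c(2, 3, 5))
  fp <- matrix(0, pr, pc); fp[1:ny, 1:nx] <- f
  kp <- matrix(0, pr, pc); kp[1:(2 * ny - 1), 1:(2 * nx - 1)] <- ker
  conv <- Re(stats::fft(stats::fft(fp) * stats::fft(kp), inverse = TRUE)) / (pr * pc)
  conv[(ny:(2 * ny - 1)), (nx:(2 * nx - 1))]
}

#' Stack Bz slices into a volume
#'
#' @param slices list (per slice) of lists (per injection) of `bz_slice`
#'   objects, or a single `bz_slice` for a one-slice, one-injection volume.
#' @param grid the shared [slice_grid()].
#' @return object of class `bz_volume`: `grid`, `nz`, `bz` array
#'   `[ny, nx, nz, n_injection]`, `valid` array of the same shape.
#' @export
bz_volume <- function(slices, grid = NULL) {
  if (inherits(slices, "bz_slice")) slices <- list(list(slices))
  nz <- length(slices)
  nj <- length(slices[[1]])
  if (is.null(grid)) grid <- slices[[1]][[1]]$grid
  bz <- array(NA_real_, c(grid$ny, grid$nx, nz, nj))
  valid <- array(FALSE, c(grid$ny, grid$nx, nz, nj))
  for (s in seq_len(nz)) for (j in seq_len(nj)) {
    sl <- slices[[s]][[j]]
    m <- if (inherits(sl, "bz_slice")) sl$bz else sl
    v <- if (inherits(sl, "bz_slice")) sl$valid else is.finite(m)
    bz[, , s, j] <- m
    valid[, , s, j] <- v
  }
  if (!all(is.finite(bz[valid]))) stop_validation("Bz must be finite wherever valid")
  structure(list(grid = grid, nz = nz, bz = bz, valid = valid),
            class = "bz_volume")
}
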