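#' Default modified Shepp-Logan conductivity ellipses
#'
#' Ellipse parameters in normalized coordinates: centers and semi-axes are
#' fractions of half the field of view, angles in degrees (counterclockwise
#' from the x axis). The first row is the outer ellipse defining the imaging
#' domain; its value is the background conductivity (1 S/m). Later rows
#' overwrite earlier ones where they overlap. Values are conductivities in
#' S/m, so all must be positive; the classic attenuation values of the
#' Shepp-Logan head are replaced by conductivity contrasts around 1 S/m.
#'
#' @param contrast multiplicative strength of the anomalies: each ellipse
#'   value v becomes `exp(contrast * log(v))`, so `contrast = 0` yields a
#'   homogeneous phantom and `contrast = 1` the default.
#' @return data.frame with columns cx, cy, a, b, angle, value.
#' @export
shepp_logan_ellipses <- function(contrast = 1) {
  e <- data.frame(
    cx    = c( 0.00,  0.00, -0.22,  0.22,  0.00,  0.00),
    cy    = c( 0.00,  0.02,  0.00,  0.00,  0.35, -0.35),
    a     = c( 0.78,  0.72,  0.11,  0.16,  0.12,  0.09),
    b     = c( 0.92,  0.85,  0.31,  0.41,  0.12,  0.09),
    angle = c( 0,     0,    -18,    18,    0,     0),
    value = c( 1.0,   1.1,   0.80,  1.25,  1.4,   0.7)
  )
  e$value <- exp(contrast * log(e$value))
  e
}

#' Generate a pixel-grid conductivity phantom from ellipses
#'
#' Rasterizes a list of ellipses onto a slice grid. The first ellipse is the
#' outer boundary of the imaging domain: pixels outside it are flagged outside
#' the domain and carry the background conductivity 1 S/m for interpolation
#' convenience. Later ellipses overwrite earlier ones. The domain boundary
#' ring is required to stay at the background value (homogeneous-boundary
#' assumption of the reconstruction algorithm), so interior ellipses must not
#' touch the outer rim.
#'
#' @param grid a [slice_grid()].
#' @param ellipses data.frame as [shepp_logan_ellipses()]: normalized centers
#'   `cx, cy`, semi-axes `a, b` (fractions of half the field of view), `angle`
#'   degrees, conductivity `value` in S/m.
#' @return object of class `conductivity_phantom` with elements `grid`,
#'   `sigma` (ny x nx, S/m) and `domain_mask`.
#' @export
make_shepp_logan <- function(grid, ellipses = shepp_logan_ellipses()) {
  need <- c("cx", "cy", "a", "b", "angle", "value")
  if (!all(need %in% names(ellipses)) || nrow(ellipses) < 1)
    stop_validation("ellipses must have columns %s and at least one row", paste(need, collapse = ", "))
  if (any(ellipses$value <= 0))
    stop_validation("conductivity values must be positive (got min %g)", min(ellipses$value))
  if (any(ellipses$a <= 0 | ellipses$b <= 0))
    stop_validation("ellipse semi-axes must be positive")
  if (any(abs(ellipses$cx) + pmax(ellipses$a, ellipses$b) > 1 + 1e-12) ||
      any(abs(ellipses$cy) + pmax(ellipses$a, ellipses$b) > 1 + 1e-12))
    stop_validation("an ellipse exceeds the grid's normalized [-1, 1] extent")

  xy <- grid_xy(grid)
  ctr <- grid_center(grid)
  half <- c((grid$nx - 1) * grid$dx / 2, (grid$ny - 1) * grid$dy / 2)
  # normalized coordinates in [-1, 1]
  xn <- (xy$x - ctr[1]) / half[1]
  yn <- (xy$y - ctr[2]) / half[2]

  sigma <- matrix(1, grid$ny, grid$nx)
  domain_mask <- in_ellipse(xn, yn, ellipses[1, ])
  sigma[domain_mask] <- ellipses$value[1]
  if (nrow(ellipses) > 1) {
    for (i in 2:nrow(ellipses)) {
      inside <- in_ellipse(xn, yn, ellipses[i, ]) & domain_mask
      sigma[inside] <- ellipses$value[i]
    }
  }
  ring <- boundary_ring(domain_mask)
  bg <- ellipses$value[1]
  if (any(abs(sigma[ring] - bg) > 1e-12))
    stop_validation("conductivity must equal the background value on the domain boundary ring")
  structure(list(grid = grid, sigma = sigma, domain_mask = domain_mask,
                 ellipses = ellipses),
            class = "conductivity_phantom")
}

# Point-in-ellipse membership in normalized coordinates.
in_ellipse <- function(xn, yn, e) {
  th <- e$angle * pi / 180
  u <- (xn - e$cx) * cos(th) + (yn - e$cy) * sin(th)
  v <- -(xn - e$cx) * sin(th) + (yn - e$cy) * cos(th)
  (u / e$a)^2 + (v / e$b)^2 <= 1
}

#' @export
print.conductivity_phantom <- function(x, ...) {
  cat(sprintf("<conductivity_phantom> %d x %d, sigma in [%.3g, %.3g] S/m, %d domain pixels\n",
              x$grid$ny, x$grid$nx, min(x$sigma[x$domain_mask]),
              max(x$sigma[x$domain_mask]), sum(x$domain_mask)))
  invisible(x)
}

#' Electrode configuration for two current injections
#'
#' Each injection uses one pair of boundary arcs, described by the angular
#' position of the arc center as seen from the domain centroid and the arc's
#' angular width. The defaults give a horizontal pair (injection 1, arcs at
#' angles 0 and pi) and a vertical pair (injection 2, at pi/2 and 3 pi/2),
#' the usual non-parallel two-injection layout.
#'
#' @param I injected current amplitude in amperes.
#' @param Tc current pulse width in seconds.
#' @param width angular width of every electrode arc (radians).
#' @param angles named list with entries `E1p, E1m, E2p, E2m`: arc-center
#'   angles in radians.
#' @return object of class `electrode_config` with an `arcs` data.frame
#'   (columns injection, polarity, angle0, angle1).
#' @export
electrode_config <- function(I = 1e-3, Tc = 30e-3, width = pi / 4,
                             angles = list(E1p = 0, E1m = pi,
                                           E2p = pi / 2, E2m = 3 * pi / 2)) {
  if (I <= 0) stop_validation("current amplitude I must be positive")
  if (Tc <= 0) stop_validation("pulse width Tc must be positive")
  if (width <= 0 || width >= pi / 2)
    stop_validation("arc width must lie in (0, pi/2) so arcs stay disjoint")
  a <- unlist(angles[c("E1p", "E1m", "E2p", "E2m")])
  arcs <- data.frame(
    injection = c(1L, 1L, 2L, 2L),
    polarity  = c(1L, -1L, 1L, -1L),
    angle0 = a - width / 2,
    angle1 = a + width / 2,
    row.names = NULL
  )
  # pairwise disjointness on the circle
  mids <- wrap_phase(a)
  for (i in 1:3) for (j in (i + 1):4) {
    sep <- abs(wrap_phase(mids[i] - mids[j]))
    if (sep < width) stop_validation("electrode arcs overlap (angular separation %.3g < width %.3g)", sep, width)
  }
  structure(list(I = I, Tc = Tc, width = width, arcs = arcs),
            class = "electrode_config")
}

# TRUE where angle th (radians) lies inside arc [angle0, angle1] on the circle.
angle_in_arc <- function(th, angle0, angle1) {
  half <- (angle1 - angle0) / 2
  mid <- (angle0 + angle1) / 2
  abs(wrap_phase(th - mid)) <= half + 1e-12
}
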