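#' Pixel grid for one imaging slice
#'
#' Describes the raster on which all per-slice fields (conductivity, current
#' density, Bz, MR images) live. Fields are stored as `ny x nx` matrices with
#' rows indexing y (increasing upward in physical space) and columns indexing
#' x. Pixel `(r, c)` has its center at
#' `origin + ((c - 1) * dx, (r - 1) * dy)`; all physical lengths are meters.
#'
#' @param nx,ny pixel counts (at least 8 each).
#' @param dx,dy pixel spacing in meters.
#' @param dz slice thickness in meters.
#' @param origin physical coordinates (x, y) of the center of pixel (1, 1).
#' @return An object of class `slice_grid`.
#' @export
slice_grid <- function(nx, ny, dx = 1.4e-3, dy = dx, dz = 3e-3,
                       origin = c(0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 8L || ny < 8L) stop_validation("grid must be at least 8 x 8 pixels (got %d x %d)", nx, ny)
  if (dx <= 0 || dy <= 0 || dz <= 0) stop_validation("pixel spacings and slice thickness must be positive")
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy, dz = dz,
                 origin = as.numeric(origin)),
            class = "slice_grid")
}

#' @export
print.slice_grid <- function(x, ...) {
  cat(sprintf("<slice_grid> %d x %d pixels, dx=%.3g m dy=%.3g m dz=%.3g m, origin=(%.3g, %.3g)\n",
              x$nx, x$ny, x$dx, x$dy, x$dz, x$origin[1], x$origin[2]))
  invisible(x)
}

# Physical coordinates of pixel centers.
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx,
       y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dy)
}

# ny x nx matrices of pixel-center coordinates.
grid_xy <- function(grid) {
  ax <- grid_axes(grid)
  list(x = matrix(ax$x, grid$ny, grid$nx, byrow = TRUE),
       y = matrix(ax$y, grid$ny, grid$nx))
}

# Center of the grid's field of view.
grid_center <- function(grid) {
  c(grid$origin[1] + (grid$nx - 1) * grid$dx / 2,
    grid$origin[2] + (grid$ny - 1) * grid$dy / 2)
}

check_field <- function(f, grid, name = "field") {
  if (!is.matrix(f) || nrow(f) != grid$ny || ncol(f) != grid$nx)
    stop_validation("%s must be a %d x %d matrix", name, grid$ny, grid$nx)
  invisible(f)
}
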