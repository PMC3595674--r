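# Structured triangulations of rasterized domains.
#
# All FEM work in this package happens on meshes built from a rectangular cell
# lattice: every kept cell is split into two positively oriented triangles.
# For imaging data the lattice is the pixel grid itself (optionally k x k
# subdivided so triangle areas satisfy a max_area constraint), which makes the
# mesh conform exactly to the pixel raster that carries sigma, J and Bz and
# makes pixel <-> mesh transfer trivial and deterministic.

# Build a triangle_mesh from a cell lattice.
# lattice: list(x0, y0, hx, hy, ncx, ncy) where (x0, y0) is corner (1,1).
# cellmask: ncy x ncx logical. marker_fun(mx, my): character markers for
# boundary-edge midpoints.
build_lattice_mesh <- function(lattice, cellmask, marker_fun = NULL,
                               grid = NULL, k = NA_integer_) {
  ncx <- lattice$ncx; ncy <- lattice$ncy
  if (!any(cellmask)) stop_validation("mesh region is empty")
  corner <- matrix(FALSE, ncy + 1, ncx + 1)
  idx <- which(cellmask, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  corner[cbind(r, c)] <- TRUE; corner[cbind(r, c + 1)] <- TRUE
  corner[cbind(r + 1, c)] <- TRUE; corner[cbind(r + 1, c + 1)] <- TRUE
  vid <- matrix(0L, ncy + 1, ncx + 1)
  vid[corner] <- seq_len(sum(corner))
  cr <- which(corner, arr.ind = TRUE)
  vx <- lattice$x0 + (cr[, 2] - 1) * lattice$hx
  vy <- lattice$y0 + (cr[, 1] - 1) * lattice$hy
  ord <- order(vid[corner])
  vertices <- cbind(x = vx[ord], y = vy[ord])

  v00 <- vid[cbind(r, c)]; v10 <- vid[cbind(r, c + 1)]
  v11 <- vid[cbind(r + 1, c + 1)]; v01 <- vid[cbind(r + 1, c)]
  m <- length(r)
  triangles <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  tri_cell <- rbind(cbind(r, c), cbind(r, c))      # lattice cell per triangle
  # triangle lookup per cell: lower (below diagonal) then upper
  cell_tri_lo <- matrix(NA_integer_, ncy, ncx)
  cell_tri_hi <- matrix(NA_integer_, ncy, ncx)
  cell_tri_lo[cbind(r, c)] <- seq_len(m)
  cell_tri_hi[cbind(r, c)] <- m + seq_len(m)
  area <- rep(lattice$hx * lattice$hy / 2, 2 * m)

  # boundary edges: cell faces whose neighboring cell is absent
  pad <- function(dr, dc) {
    out <- matrix(FALSE, ncy, ncx)
    rs <- seq_len(ncy) - dr; cs <- seq_len(ncx) - dc
    rok <- rs >= 1 & rs <= ncy; cok <- cs >= 1 & cs <= ncx
    out[rok, cok] <- cellmask[rs[rok], cs[cok]]
    out
  }
  be <- list()
  add_edges <- function(sel, va, vb) {
    if (!any(sel)) return(NULL)
    cbind(va[sel], vb[sel])
  }
  bottom <- cellmask & !pad(1, 0)   # neighbor below absent
  top    <- cellmask & !pad(-1, 0)
  left   <- cellmask & !pad(0, 1)
  right  <- cellmask & !pad(0, -1)
  sel_cells <- function(sidemask) {
    w <- which(sidemask, arr.ind = TRUE)
    list(r = w[, 1], c = w[, 2])
  }
  edges <- NULL
  for (side in c("bottom", "top", "left", "right")) {
    sm <- switch(side, bottom = bottom, top = top, left = left, right = right)
    w <- sel_cells(sm)
    if (!length(w$r)) next
    e <- switch(side,
      bottom = cbind(vid[cbind(w$r, w$c)],     vid[cbind(w$r, w$c + 1)]),
      top    = cbind(vid[cbind(w$r + 1, w$c)], vid[cbind(w$r + 1, w$c + 1)]),
      left   = cbind(vid[cbind(w$r, w$c)],     vid[cbind(w$r + 1, w$c)]),
      right  = cbind(vid[cbind(w$r, w$c + 1)], vid[cbind(w$r + 1, w$c + 1)]))
    edges <- rbind(edges, e)
  }
  mx <- (vertices[edges[, 1], 1] + vertices[edges[, 2], 1]) / 2
  my <- (vertices[edges[, 1], 2] + vertices[edges[, 2], 2]) / 2
  marker <- if (is.null(marker_fun)) rep("boundary", nrow(edges)) else marker_fun(mx, my)
  boundary_edges <- data.frame(v1 = edges[, 1], v2 = edges[, 2],
                               marker = marker, mx = mx, my = my,
                               stringsAsFactors = FALSE)

  structure(list(vertices = vertices, triangles = triangles,
                 area = area, tri_cell = tri_cell,
                 cell_tri_lo = cell_tri_lo, cell_tri_hi = cell_tri_hi,
                 lattice = lattice, boundary_edges = boundary_edges,
                 grid = grid, k = k),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles, max area %.3g, %d boundary edges\n",
              nrow(x$vertices), nrow(x$triangles), max(x$area), nrow(x$boundary_edges)))
  invisible(x)
}

#' Triangulate the pixels of a slice-domain mask
#'
#' Builds a conforming triangulation of the union of pixels where `mask` is
#' TRUE, splitting each pixel (or each of its k x k subcells when `max_area`
#' demands sub-pixel triangles) into two positively oriented triangles.
#' Electrode boundary markers are assigned from the angular arcs of an
#' [electrode_config()] measured about the mask centroid; unmarked boundary
#' edges carry marker `"boundary"`.
#'
#' @param grid [slice_grid()] the mask lives on.
#' @param mask logical ny x nx pixel mask.
#' @param electrodes optional [electrode_config()] for boundary markers.
#' @param max_area maximal triangle area (m^2); default half a pixel.
#' @param marker_fun optional function(mx, my) -> character markers for
#'   boundary-edge midpoints, overriding the angular electrode marking (e.g.
#'   to realize full-edge electrodes on a rectangular domain).
#' @return a `triangle_mesh`.
#' @export
mesh_from_mask <- function(grid, mask, electrodes = NULL, max_area = NULL,
                           marker_fun = NULL) {
  check_field(mask, grid, "mask")
  if (is.null(max_area)) max_area <- grid$dx * grid$dy / 2
  if (max_area <= 0) stop_validation("max_area must be positive")
  k <- max(1L, ceiling(sqrt(grid$dx * grid$dy / (2 * max_area))))
  lattice <- list(x0 = grid$origin[1] - grid$dx / 2,
                  y0 = grid$origin[2] - grid$dy / 2,
                  hx = grid$dx / k, hy = grid$dy / k,
                  ncx = grid$nx * k, ncy = grid$ny * k)
  cellmask <- mask[rep(seq_len(grid$ny), each = k), rep(seq_len(grid$nx), each = k)]
  if (is.null(marker_fun) && !is.null(electrodes)) {
    ctr <- mask_centroid(grid, mask)
    arcs <- electrodes$arcs
    marker_fun <- function(mx, my) {
      th <- atan2(my - ctr[2], mx - ctr[1])
      out <- rep("boundary", length(mx))
      for (i in seq_len(nrow(arcs))) {
        hit <- angle_in_arc(th, arcs$angle0[i], arcs$angle1[i])
        out[hit] <- sprintf("E%d%s", arcs$injection[i], if (arcs$polarity[i] > 0) "+" else "-")
      }
      out
    }
  }
  mesh <- build_lattice_mesh(lattice, cellmask, marker_fun, grid = grid, k = k)
  mesh$domain_mask <- mask
  mesh
}

mask_centroid <- function(grid, mask) {
  xy <- grid_xy(grid)
  c(mean(xy$x[mask]), mean(xy$y[mask]))
}

# Triangle centroids, n x 2.
mesh_centroids <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  cbind((v[t[, 1], 1] + v[t[, 2], 1] + v[t[, 3], 1]) / 3,
        (v[t[, 1], 2] + v[t[, 2], 2] + v[t[, 3], 2]) / 3)
}

# Vertices lying on boundary edges, optionally restricted to a marker set.
boundary_vertices <- function(mesh, markers = NULL) {
  be <- mesh$boundary_edges
  if (!is.null(markers)) be <- be[be$marker %in% markers, , drop = FALSE]
  sort(unique(c(be$v1, be$v2)))
}

# Evaluate a P1 vertex field at arbitrary physical points by barycentric
# interpolation on the lattice mesh. Points outside the mesh give NA.
eval_mesh <- function(mesh, u, x, y) {
  lat <- mesh$lattice
  fx <- (x - lat$x0) / lat$hx
  fy <- (y - lat$y0) / lat$hy
  c0 <- pmin(pmax(floor(fx), 0), lat$ncx - 1)
  r0 <- pmin(pmax(floor(fy), 0), lat$ncy - 1)
  tx <- fx - c0; ty <- fy - r0
  ok <- tx > -1e-9 & tx < 1 + 1e-9 & ty > -1e-9 & ty < 1 + 1e-9
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  ci <- cbind(r0 + 1, c0 + 1)
  lo <- mesh$cell_tri_lo[ci]; hi <- mesh$cell_tri_hi[ci]
  ok <- ok & !is.na(lo)
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  tri <- mesh$triangles
  lower <- tx >= ty
  # lower triangle (v00, v10, v11): u = u00 (1-tx) + u10 (tx-ty) + u11 ty
  il <- which(ok & lower)
  if (length(il)) {
    t1 <- tri[lo[il], , drop = FALSE]
    out[il] <- u[t1[, 1]] * (1 - tx[il]) + u[t1[, 2]] * (tx[il] - ty[il]) + u[t1[, 3]] * ty[il]
  }
  # upper triangle (v00, v11, v01): u = u00 (1-ty) + u11 tx + u01 (ty-tx)
  iu <- which(ok & !lower)
  if (length(iu)) {
    t2 <- tri[hi[iu], , drop = FALSE]
    out[iu] <- u[t2[, 1]] * (1 - ty[iu]) + u[t2[, 2]] * tx[iu] + u[t2[, 3]] * (ty[iu] - tx[iu])
  }
  out
}

# Rasterize a vertex field back to pixel centers of `grid`.
rasterize_mesh <- function(mesh, u, grid = mesh$grid) {
  if (is.null(grid)) stop_validation("rasterize_mesh needs a target slice_grid")
  xy <- grid_xy(grid)
  matrix(eval_mesh(mesh, u, as.numeric(xy$x), as.numeric(xy$y)), grid$ny, grid$nx)
}

# Coverage mask: pixels of `grid` whose centers fall in a mesh cell.
mesh_pixel_mask <- function(mesh, grid = mesh$grid) {
  xy <- grid_xy(grid)
  v <- eval_mesh(mesh, rep(1, nrow(mesh$vertices)), as.numeric(xy$x), as.numeric(xy$y))
  matrix(is.finite(v), grid$ny, grid$nx)
}
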