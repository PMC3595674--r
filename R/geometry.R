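# Domain geometry: segmentation of the imaging domain from MR magnitude,
# electrode arc placement on the boundary polyline, polygon triangulation and
# local-region handling.

#' Segment the imaging domain from an MR magnitude image
#'
#' Thresholds the magnitude at `level_fraction * max(M)`, extracts the largest
#' closed iso-contour at that level (sub-pixel marching-squares contour via
#' [grDevices::contourLines()]), and simplifies it with a Douglas-Peucker
#' tolerance of half a pixel. A frame-filling constant image (no contour
#' crossings) yields the frame rectangle. Ties between equal-area contours are
#' broken by the smaller centroid y, then x.
#'
#' @param M nonnegative magnitude matrix.
#' @param grid [slice_grid()] giving physical coordinates.
#' @param level_fraction threshold fraction of `max(M)`; default reuses the
#'   defect-detection convention 0.10.
#' @return object of class `domain_polygon`: `vertices` (closed polyline
#'   without repeated endpoint, counterclockwise), `arcs` (empty until
#'   [attach_electrodes()]), `perimeter`.
#' @export
segment_domain <- function(M, grid, level_fraction = 0.10) {
  if (any(M < 0)) stop_validation("magnitude must be nonnegative")
  level <- level_fraction * max(M)
  ax <- grid_axes(grid)
  cl <- grDevices::contourLines(x = ax$x, y = ax$y, z = t(M), levels = level)
  if (length(cl) == 0) {
    if (all(M >= level)) {
      v <- rbind(c(ax$x[1], ax$y[1]), c(ax$x[grid$nx], ax$y[1]),
                 c(ax$x[grid$nx], ax$y[grid$ny]), c(ax$x[1], ax$y[grid$ny]))
      return(new_domain_polygon(v))
    }
    stop_validation("no super-threshold component found")
  }
  areas <- vapply(cl, function(p) abs(shoelace_area(cbind(p$x, p$y))), 0)
  cy <- vapply(cl, function(p) mean(p$y), 0)
  cx <- vapply(cl, function(p) mean(p$x), 0)
  ord <- order(-areas, cy, cx)
  best <- cl[[ord[1]]]
  v <- cbind(best$x, best$y)
  if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  v <- simplify_polyline_closed(v, tol = 0.5 * min(grid$dx, grid$dy))
  if (shoelace_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  new_domain_polygon(v)
}

new_domain_polygon <- function(vertices, arcs = NULL) {
  if (shoelace_area(vertices) < 0)
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  if (is.null(arcs))
    arcs <- data.frame(injection = integer(0), polarity = integer(0),
                       t0 = numeric(0), t1 = numeric(0),
                       i0 = integer(0), i1 = integer(0))
  structure(list(vertices = vertices, arcs = arcs,
                 perimeter = polyline_perimeter(vertices)),
            class = "domain_polygon")
}

#' @export
print.domain_polygon <- function(x, ...) {
  cat(sprintf("<domain_polygon> %d vertices, area %.4g m^2, perimeter %.4g m, %d electrode arcs\n",
              nrow(x$vertices), polygon_area(x), x$perimeter, nrow(x$arcs)))
  invisible(x)
}

#' Area of a domain polygon
#' @param poly a `domain_polygon`.
#' @return signed area (positive, counterclockwise), m^2.
#' @export
polygon_area <- function(poly) shoelace_area(poly$vertices)

shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

polyline_perimeter <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(sqrt(rowSums((v[j, ] - v)^2)))
}

# Douglas-Peucker simplification of a closed polyline; the two anchor points
# are the extremes of the x coordinate so the loop splits into two open runs.
simplify_polyline_closed <- function(v, tol) {
  n <- nrow(v)
  if (n <= 4) return(v)
  a <- which.min(v[, 1]); b <- which.max(v[, 1])
  lo <- min(a, b); hi <- max(a, b)
  run1 <- v[lo:hi, , drop = FALSE]
  run2 <- v[c(hi:n, 1:lo), , drop = FALSE]
  s1 <- dp_simplify(run1, tol)
  s2 <- dp_simplify(run2, tol)
  out <- rbind(s1[-nrow(s1), , drop = FALSE], s2[-nrow(s2), , drop = FALSE])
  if (nrow(out) < 3) v else out
}

dp_simplify <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  a <- pts[1, ]; b <- pts[n, ]
  ab <- b - a
  L2 <- sum(ab^2)
  d <- if (L2 == 0) sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
       else abs(ab[1] * (pts[, 2] - a[2]) - ab[2] * (pts[, 1] - a[1])) / sqrt(L2)
  k <- which.max(d)
  if (d[k] <= tol) return(pts[c(1, n), , drop = FALSE])
  left <- dp_simplify(pts[1:k, , drop = FALSE], tol)
  right <- dp_simplify(pts[k:n, , drop = FALSE], tol)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

#' Attach electrode arcs to a domain polygon
#'
#' Places four boundary arcs (two injections, two polarities) on the polygon's
#' perimeter. Each arc is specified by an anchor — an angle about the polygon
#' centroid or an explicit boundary point — and an arc length along the
#' polyline; the polyline is resampled so the arc endpoints become vertices
#' and the covered vertex index ranges are recorded.
#'
#' @param poly a `domain_polygon`.
#' @param spec data.frame with columns `injection` (1/2), `polarity` (+1/-1)
#'   and `length` (arc length, meters), plus either `angle` (radians, about
#'   the centroid) or `x`,`y` (anchor point projected to the boundary).
#'   Alternatively an [electrode_config()], whose angular arcs are converted
#'   using the polygon perimeter (arc length = angular width / 2 pi *
#'   perimeter).
#' @return the polygon with resampled vertices and a populated `arcs` table.
#' @export
attach_electrodes <- function(poly, spec) {
  if (inherits(spec, "electrode_config")) {
    a <- spec$arcs
    spec <- data.frame(injection = a$injection, polarity = a$polarity,
                       angle = (a$angle0 + a$angle1) / 2,
                       length = (a$angle1 - a$angle0) / (2 * pi) * poly$perimeter)
  }
  if (any(spec$length <= 0)) stop_validation("electrode arc length must be positive")
  v <- poly$vertices
  ctr <- c(mean(v[, 1]), mean(v[, 2]))
  anchors_t <- numeric(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    if (!is.null(spec$angle) && !is.na(spec$angle[i])) {
      th <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
      k <- which.min(abs(wrap_phase(th - spec$angle[i])))
      anchors_t[i] <- polyline_param(v, k)
    } else {
      np <- nearest_on_polyline(v, spec$x[i], spec$y[i])
      anchors_t[i] <- np$t
    }
  }
  P <- poly$perimeter
  t0 <- (anchors_t - spec$length / 2) %% P
  t1 <- (anchors_t + spec$length / 2) %% P
  # overlap check on the circle of perimeter parameters
  covers <- function(a0, a1, t) if (a0 <= a1) t >= a0 & t <= a1 else t >= a0 | t <= a1
  for (i in seq_len(nrow(spec))) for (j in seq_len(nrow(spec))) {
    if (i == j) next
    if (covers(t0[i], t1[i], t0[j]) || covers(t0[i], t1[i], t1[j]))
      stop_validation("electrode arcs overlap on the boundary polyline")
  }
  # resample: insert arc endpoints as vertices
  cuts <- sort(unique(c(t0, t1) %% P))
  v2 <- insert_polyline_points(v, cuts)
  tv <- polyline_params(v2)
  arcs <- data.frame(injection = spec$injection, polarity = spec$polarity,
                     t0 = t0, t1 = t1, i0 = NA_integer_, i1 = NA_integer_)
  for (i in seq_len(nrow(arcs))) {
    inarc <- covers(t0[i], t1[i], tv)
    idx <- which(inarc)
    arcs$i0[i] <- min(idx); arcs$i1[i] <- max(idx)
  }
  out <- new_domain_polygon(v2, arcs)
  out
}

# Cumulative perimeter parameter of vertex k (first vertex has t = 0).
polyline_param <- function(v, k) polyline_params(v)[k]

polyline_params <- function(v) {
  n <- nrow(v)
  seg <- sqrt(rowSums((v[c(2:n, 1), ] - v)^2))
  c(0, cumsum(seg))[seq_len(n)]
}

# Nearest point on the closed polyline to (x, y); returns the perimeter
# parameter t and the distance.
nearest_on_polyline <- function(v, x, y) {
  n <- nrow(v)
  j <- c(2:n, 1)
  ax <- v[, 1]; ay <- v[, 2]
  bx <- v[j, 1]; by <- v[j, 2]
  dx <- bx - ax; dy <- by - ay
  L2 <- dx^2 + dy^2
  tt <- pmin(pmax(((x - ax) * dx + (y - ay) * dy) / pmax(L2, 1e-300), 0), 1)
  px <- ax + tt * dx; py <- ay + tt * dy
  d2 <- (px - x)^2 + (py - y)^2
  k <- which.min(d2)
  t_start <- polyline_params(v)
  list(t = t_start[k] + tt[k] * sqrt(L2[k]), dist = sqrt(d2[k]), segment = k)
}

# Insert points at perimeter parameters `ts` into the closed polyline.
insert_polyline_points <- function(v, ts) {
  n <- nrow(v)
  t_start <- polyline_params(v)
  seg_len <- sqrt(rowSums((v[c(2:n, 1), ] - v)^2))
  pieces <- list()
  for (k in seq_len(n)) {
    pieces[[k]] <- v[k, , drop = FALSE]
    in_seg <- ts[ts > t_start[k] + 1e-12 & ts < t_start[k] + seg_len[k] - 1e-12]
    if (length(in_seg)) {
      frac <- (in_seg - t_start[k]) / seg_len[k]
      nxt <- v[if (k == n) 1 else k + 1, ]
      pts <- cbind(v[k, 1] + frac * (nxt[1] - v[k, 1]),
                   v[k, 2] + frac * (nxt[2] - v[k, 2]))
      pieces[[k]] <- rbind(pieces[[k]], pts)
    }
  }
  do.call(rbind, pieces)
}

#' Triangulate a domain polygon
#'
#' Produces a conforming triangulation whose elements tile the polygon's
#' rasterization: a cell lattice spans the polygon's bounding box with cell
#' size chosen so every triangle area is at most `max_area` (and cells tile
#' the box exactly); cells whose centers fall inside the polygon are kept and
#' split in two. When `grid` is supplied the lattice is aligned to the pixel
#' raster (pixel cells, subdivided as needed), so the mesh matches the imaging
#' data exactly. Electrode markers recorded on the polygon propagate to
#' boundary edges by nearest-boundary-point perimeter parameter.
#'
#' @param poly a `domain_polygon` (with arcs if markers are wanted).
#' @param max_area maximal triangle area, m^2. Default: half a pixel when
#'   `grid` is given, else 1/2000 of the polygon's bounding-box area.
#' @param grid optional [slice_grid()] for pixel alignment.
#' @return a `triangle_mesh`.
#' @export
triangulate_domain <- function(poly, max_area = NULL, grid = NULL) {
  v <- poly$vertices
  if (nrow(v) < 3 || abs(shoelace_area(v)) < 1e-300)
    stop_validation("degenerate polygon")
  marker_fun <- NULL
  if (nrow(poly$arcs) > 0) {
    arcs <- poly$arcs
    P <- poly$perimeter
    covers <- function(a0, a1, t) if (a0 <= a1) t >= a0 & t <= a1 else t >= a0 | t <= a1
    marker_fun <- function(mx, my) {
      out <- rep("boundary", length(mx))
      for (p in seq_along(mx)) {
        np <- nearest_on_polyline(v, mx[p], my[p])
        for (i in seq_len(nrow(arcs))) {
          if (covers(arcs$t0[i] %% P, arcs$t1[i] %% P, np$t)) {
            out[p] <- sprintf("E%d%s", arcs$injection[i],
                              if (arcs$polarity[i] > 0) "+" else "-")
            break
          }
        }
      }
      out
    }
  }
  if (!is.null(grid)) {
    if (is.null(max_area)) max_area <- grid$dx * grid$dy / 2
    k <- max(1L, ceiling(sqrt(grid$dx * grid$dy / (2 * max_area))))
    lattice <- list(x0 = grid$origin[1] - grid$dx / 2,
                    y0 = grid$origin[2] - grid$dy / 2,
                    hx = grid$dx / k, hy = grid$dy / k,
                    ncx = grid$nx * k, ncy = grid$ny * k)
    kk <- k
  } else {
    bb <- apply(v, 2, range)
    w <- bb[2, 1] - bb[1, 1]; h <- bb[2, 2] - bb[1, 2]
    if (is.null(max_area)) max_area <- w * h / 2000
    h0 <- sqrt(2 * max_area)
    ncx <- max(2L, ceiling(w / h0)); ncy <- max(2L, ceiling(h / h0))
    lattice <- list(x0 = bb[1, 1], y0 = bb[1, 2],
                    hx = w / ncx, hy = h / ncy, ncx = ncx, ncy = ncy)
    kk <- NA_integer_
  }
  cx <- lattice$x0 + (seq_len(lattice$ncx) - 0.5) * lattice$hx
  cy <- lattice$y0 + (seq_len(lattice$ncy) - 0.5) * lattice$hy
  CX <- matrix(cx, lattice$ncy, lattice$ncx, byrow = TRUE)
  CY <- matrix(cy, lattice$ncy, lattice$ncx)
  inside <- pracma::inpolygon(as.numeric(CX), as.numeric(CY),
                              v[, 1], v[, 2], boundary = TRUE)
  cellmask <- matrix(inside, lattice$ncy, lattice$ncx)
  mesh <- build_lattice_mesh(lattice, cellmask, marker_fun, grid = grid, k = kk)
  mesh$polygon <- poly
  mesh
}

#' Clip a local region polygon to the imaging domain
#'
#' Intersects a user-specified polygonal local region with the imaging domain
#' polygon (Sutherland-Hodgman clipping; exact for the convex-ish domains
#' produced by segmentation) and warns when the region overlaps the defected
#' mask — the local reconstruction assumes a defect-free region.
#'
#' @param region matrix of polygon vertices (or a `domain_polygon`).
#' @param poly the imaging-domain `domain_polygon`.
#' @param defect optional `defect_mask` plus `grid` to quantify overlap.
#' @param grid [slice_grid()] for the overlap check.
#' @return a `domain_polygon` for the clipped region.
#' @export
clip_local_region <- function(region, poly, defect = NULL, grid = NULL) {
  rv <- if (inherits(region, "domain_polygon")) region$vertices else region
  if (nrow(rv) < 3) stop_validation("local region polygon needs at least 3 vertices")
  dv <- poly$vertices
  inside <- pracma::inpolygon(rv[, 1], rv[, 2], dv[, 1], dv[, 2], boundary = TRUE)
  out_v <- if (all(inside)) rv else {
    cl <- sutherland_hodgman(rv, dv)
    if (is.null(cl) || nrow(cl) < 3) stop_validation("local region does not intersect the imaging domain")
    cl
  }
  res <- new_domain_polygon(out_v)
  if (!is.null(defect) && !is.null(grid)) {
    dm <- if (inherits(defect, "defect_mask")) defect$mask else defect
    xy <- grid_xy(grid)
    inreg <- matrix(pracma::inpolygon(as.numeric(xy$x), as.numeric(xy$y),
                                      out_v[, 1], out_v[, 2], boundary = TRUE),
                    grid$ny, grid$nx)
    overlap <- sum(inreg & dm)
    if (overlap > 0)
      warn_mreit("local region overlaps the defected mask on %d pixels (%.3g m^2); the local reconstruction assumes a defect-free region",
                 overlap, overlap * grid$dx * grid$dy)
    res$defect_overlap_pixels <- overlap
  }
  res
}

# Clip subject polygon by (convex) clip polygon.
sutherland_hodgman <- function(subject, clip) {
  if (shoelace_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    a <- clip[i, ]; b <- clip[if (i == n) 1 else i + 1, ]
    if (nrow(out) == 0) return(NULL)
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    m <- nrow(inp)
    side <- (b[1] - a[1]) * (inp[, 2] - a[2]) - (b[2] - a[2]) * (inp[, 1] - a[1]) >= -1e-12
    for (k in seq_len(m)) {
      cur <- inp[k, ]; prv <- inp[if (k == 1) m else k - 1, ]
      cs <- side[k]; ps <- side[if (k == 1) m else k - 1]
      if (cs) {
        if (!ps) out <- rbind(out, line_intersect(prv, cur, a, b))
        out <- rbind(out, cur)
      } else if (ps) {
        out <- rbind(out, line_intersect(prv, cur, a, b))
      }
    }
  }
  if (nrow(out) < 3) return(out)
  # drop consecutive duplicates
  keep <- c(TRUE, rowSums(abs(diff(out)))[seq_len(nrow(out) - 1)] > 1e-12)
  out[keep, , drop = FALSE]
}

line_intersect <- function(p1, p2, a, b) {
  d1 <- p2 - p1; d2 <- b - a
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  t <- ((a[1] - p1[1]) * d2[2] - (a[2] - p1[2]) * d2[1]) / den
  p1 + t * d1
}
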