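smooth_ellipse_magnitude <- function(g, a_frac = 0.6, b_frac = 0.4) {
  xy <- mreit:::grid_xy(g)
  ctr <- mreit:::grid_center(g)
  half <- c((g$nx - 1) * g$dx / 2, (g$ny - 1) * g$dy / 2)
  a <- a_frac * half[1]; b <- b_frac * half[2]
  rho2 <- ((xy$x - ctr[1]) / a)^2 + ((xy$y - ctr[2]) / b)^2
  list(M = 100 * exp(-rho2 * log(10)), a = a, b = b)  # 10% of max on the ellipse
}

test_that("segmentation recovers an elliptical support to within 2% area", {
  g <- slice_grid(128, 128, dx = 1.4e-3)
  fx <- smooth_ellipse_magnitude(g)
  poly <- segment_domain(fx$M, g)
  expect_lt(abs(polygon_area(poly) - pi * fx$a * fx$b) / (pi * fx$a * fx$b), 0.02)
})

test_that("a frame-filling constant magnitude yields the frame rectangle", {
  g <- slice_grid(16, 16, dx = 1e-3)
  expect_warning(poly <- segment_domain(matrix(7, 16, 16), g), "equal")
  expect_identical(nrow(poly$vertices), 4L)
  ax <- mreit:::grid_axes(g)
  expect_equal(polygon_area(poly), diff(range(ax$x)) * diff(range(ax$y)),
               tolerance = 1e-12)
})

test_that("the larger of two components is segmented", {
  g <- slice_grid(64, 64, dx = 1e-3)
  xy <- mreit:::grid_xy(g)
  ctr <- mreit:::grid_center(g)
  M <- matrix(0, 64, 64)
  M[(xy$x - ctr[1])^2 + (xy$y - ctr[2] + 0.015)^2 < 0.012^2] <- 100   # big, low
  M[(xy$x - ctr[1])^2 + (xy$y - ctr[2] - 0.02)^2 < 0.005^2] <- 100    # small, high
  poly <- segment_domain(M, g)
  expect_lt(abs(polygon_area(poly) - pi * 0.012^2) / (pi * 0.012^2), 0.25)
  expect_lt(mean(poly$vertices[, 2]), ctr[2])  # it picked the lower, bigger disk
})

test_that("electrode arcs are resampled onto the polyline with correct lengths", {
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  circ <- mreit:::new_domain_polygon(cbind(cos(th), sin(th)))
  quarter <- circ$perimeter / 4
  spec <- data.frame(injection = c(1, 1, 2, 2), polarity = c(1, -1, 1, -1),
                     angle = c(0, pi, pi / 2, 3 * pi / 2),
                     length = rep(quarter * 0.95, 4))
  pe <- attach_electrodes(circ, spec)
  seg <- circ$perimeter / 128
  for (i in 1:4) {
    len <- (pe$arcs$t1[i] - pe$arcs$t0[i]) %% pe$perimeter
    expect_lt(abs(len - quarter * 0.95), seg + 1e-12)
  }
  # arcs are disjoint and each covers ~1/4 of the perimeter
  expect_error(attach_electrodes(circ, transform(spec, length = quarter * 1.2)),
               class = "mreit_validation_error")
  expect_error(attach_electrodes(circ, transform(spec, length = 0)),
               class = "mreit_validation_error")
})

test_that("random anchors give recorded arc lengths within one segment", {
  set.seed(23)
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- mreit:::new_domain_polygon(cbind(2 * cos(th), 2 * sin(th)))
  seg <- circ$perimeter / 64
  ang <- sort(runif(4, 0, 2 * pi))
  # keep arcs short so random anchors cannot overlap
  spec <- data.frame(injection = c(1, 1, 2, 2), polarity = c(1, -1, 1, -1),
                     angle = ang, length = rep(circ$perimeter / 40, 4))
  pe <- attach_electrodes(circ, spec)
  for (i in 1:4) {
    len <- (pe$arcs$t1[i] - pe$arcs$t0[i]) %% pe$perimeter
    expect_lt(abs(len - circ$perimeter / 40), seg + 1e-12)
  }
})

test_that("triangulation satisfies the area constraint and orientation", {
  sq <- mreit:::new_domain_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  mesh <- triangulate_domain(sq, max_area = 0.005)
  expect_true(all(mesh$area <= 0.005 + 1e-15))
  expect_equal(sum(mesh$area), 1, tolerance = 1e-9)
  v <- mesh$vertices; t <- mesh$triangles
  signed2 <- (v[t[, 2], 1] - v[t[, 1], 1]) * (v[t[, 3], 2] - v[t[, 1], 2]) -
             (v[t[, 3], 1] - v[t[, 1], 1]) * (v[t[, 2], 2] - v[t[, 1], 2])
  expect_true(all(signed2 > 0))
  expect_error(triangulate_domain(mreit:::new_domain_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))),
                                  max_area = 0.1),
               class = "mreit_validation_error")
})

test_that("electrode markers propagate to exactly the in-arc boundary edges", {
  g <- slice_grid(48, 48, dx = 1e-3)
  fx <- smooth_ellipse_magnitude(g, 0.8, 0.8)
  poly <- segment_domain(fx$M, g)
  poly <- attach_electrodes(poly, electrode_config())
  mesh <- triangulate_domain(poly, grid = g)
  be <- mesh$boundary_edges
  # exhaustive edge walk with an independently coded membership rule
  P <- poly$perimeter
  for (i in seq_len(nrow(be))) {
    np <- mreit:::nearest_on_polyline(poly$vertices, be$mx[i], be$my[i])
    expected <- "boundary"
    for (k in seq_len(nrow(poly$arcs))) {
      t0 <- poly$arcs$t0[k] %% P; t1 <- poly$arcs$t1[k] %% P
      inarc <- if (t0 <= t1) np$t >= t0 && np$t <= t1 else np$t >= t0 || np$t <= t1
      if (inarc) {
        expected <- sprintf("E%d%s", poly$arcs$injection[k],
                            if (poly$arcs$polarity[k] > 0) "+" else "-")
        break
      }
    }
    expect_identical(be$marker[i], expected)
  }
  # all four electrodes are present
  expect_setequal(unique(be$marker), c("boundary", "E1+", "E1-", "E2+", "E2-"))
})

test_that("rasterizing the mesh reproduces the pixel domain mask", {
  case <- fixture_case(64, "contrast")
  mesh <- case$mesh
  cover <- mreit:::mesh_pixel_mask(mesh)
  agree <- mean(cover == case$phantom$domain_mask)
  expect_gte(agree, 0.98)
  # determinism: identical inputs give identical meshes
  mesh2 <- mesh_from_mask(case$phantom$grid, case$phantom$domain_mask,
                          case$electrodes)
  expect_identical(mesh[c("vertices", "triangles", "boundary_edges")],
                   mesh2[c("vertices", "triangles", "boundary_edges")])
})

test_that("local regions are clipped to the domain and checked against defects", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  dom <- mreit:::new_domain_polygon(cbind(0.05 * cos(th), 0.05 * sin(th)))
  # fully inside: unchanged
  sq <- rbind(c(-0.01, -0.01), c(0.01, -0.01), c(0.01, 0.01), c(-0.01, 0.01))
  r1 <- clip_local_region(sq, dom)
  expect_equal(r1$vertices, sq, tolerance = 1e-12)
  # region = domain: identity (local = global)
  r2 <- clip_local_region(dom$vertices, dom)
  expect_equal(polygon_area(r2), polygon_area(dom), tolerance = 1e-9)
  # protruding region is clipped
  sq2 <- rbind(c(0, -0.01), c(0.2, -0.01), c(0.2, 0.01), c(0, 0.01))
  r3 <- clip_local_region(sq2, dom)
  expect_lt(polygon_area(r3), polygon_area(mreit:::new_domain_polygon(sq2)))
  # no intersection errors
  far <- sq + 1
  expect_error(clip_local_region(far, dom), class = "mreit_validation_error")
})

test_that("defect overlap is reported with a rasterization-consistent area", {
  g <- slice_grid(64, 64, dx = 1e-3)
  fx <- smooth_ellipse_magnitude(g, 0.8, 0.8)
  dom <- segment_domain(fx$M, g)
  xy <- mreit:::grid_xy(g)
  ctr <- mreit:::grid_center(g)
  defect <- (xy$x - ctr[1])^2 + (xy$y - ctr[2])^2 < 0.008^2
  sq <- rbind(c(ctr[1] - 0.01, ctr[2] - 0.01), c(ctr[1] + 0.01, ctr[2] - 0.01),
              c(ctr[1] + 0.01, ctr[2] + 0.01), c(ctr[1] - 0.01, ctr[2] + 0.01))
  expect_warning(r <- clip_local_region(sq, dom, defect = defect, grid = g),
                 class = "mreit_warning")
  # oracle: rasterized overlap count of square and disk
  inreg <- xy$x >= ctr[1] - 0.01 & xy$x <= ctr[1] + 0.01 &
           xy$y >= ctr[2] - 0.01 & xy$y <= ctr[2] + 0.01
  expect_equal(r$defect_overlap_pixels, sum(inreg & defect))
})
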