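# Shared fixtures and independent oracles for the test suite. Oracles here
# are deliberately written as plain loops / dense linear algebra, independent
# of the package's vectorized implementations.

# Brute-force point-in-ellipse membership count per conductivity level.
oracle_ellipse_counts <- function(grid, ellipses) {
  ax <- mreit:::grid_axes(grid)
  ctr <- mreit:::grid_center(grid)
  half <- c((grid$nx - 1) * grid$dx / 2, (grid$ny - 1) * grid$dy / 2)
  sigma <- matrix(NA_real_, grid$ny, grid$nx)
  for (r in seq_len(grid$ny)) for (c in seq_len(grid$nx)) {
    xn <- (ax$x[c] - ctr[1]) / half[1]
    yn <- (ax$y[r] - ctr[2]) / half[2]
    val <- NA_real_
    for (i in seq_len(nrow(ellipses))) {
      e <- ellipses[i, ]
      th <- e$angle * pi / 180
      u <- (xn - e$cx) * cos(th) + (yn - e$cy) * sin(th)
      v <- -(xn - e$cx) * sin(th) + (yn - e$cy) * cos(th)
      inside <- (u / e$a)^2 + (v / e$b)^2 <= 1
      if (i == 1 && !inside) break
      if (inside) val <- e$value
    }
    sigma[r, c] <- val
  }
  table(sigma, useNA = "always")
}

# Exhaustive 2x2 loop-sum residue detector (plain double loop).
oracle_residues <- function(phi) {
  ny <- nrow(phi); nx <- ncol(phi)
  w <- function(x) x - 2 * pi * ceiling(x / (2 * pi) - 0.5)
  out <- NULL
  for (r in 1:(ny - 1)) for (c in 1:(nx - 1)) {
    s <- w(phi[r, c + 1] - phi[r, c]) + w(phi[r + 1, c + 1] - phi[r, c + 1]) +
         w(phi[r + 1, c] - phi[r + 1, c + 1]) + w(phi[r, c] - phi[r + 1, c])
    q <- round(s / (2 * pi))
    if (q != 0) out <- rbind(out, c(r, c, q))
  }
  out
}

# Dense direct solve of the masked 5-point Laplace problem (Dirichlet ring).
oracle_dense_inpaint <- function(f, unknown) {
  ny <- nrow(f); nx <- ncol(f)
  un <- which(unknown)
  idx <- matrix(0L, ny, nx); idx[un] <- seq_along(un)
  n <- length(un)
  A <- matrix(0, n, n); b <- numeric(n)
  for (m in seq_len(n)) {
    p <- un[m]
    r <- ((p - 1) %% ny) + 1; c <- ((p - 1) %/% ny) + 1
    cnt <- 0
    for (k in 1:4) {
      rr <- r + c(-1, 1, 0, 0)[k]; cc <- c + c(0, 0, -1, 1)[k]
      if (rr < 1 || rr > ny || cc < 1 || cc > nx) next
      cnt <- cnt + 1
      if (unknown[rr, cc]) A[m, idx[rr, cc]] <- -1
      else b[m] <- b[m] + f[rr, cc]
    }
    A[m, m] <- cnt
  }
  x <- solve(A, b)
  out <- f; out[un] <- x
  out
}

# Five-point variable-coefficient finite-difference forward solver with
# Dirichlet electrode data imposed on boundary faces (half-cell ghost links),
# the same staircase electrode geometry the mesh uses.
oracle_fd_forward <- function(sigma, mask, grid, arcs, injection) {
  ny <- nrow(mask); nx <- ncol(mask)
  ctr <- mreit:::mask_centroid(grid, mask)
  ax <- mreit:::grid_axes(grid)
  idx <- matrix(0L, ny, nx); un <- which(mask); idx[un] <- seq_along(un)
  n <- length(un)
  ii <- jj <- integer(0); vv <- numeric(0); b <- numeric(n); dg <- numeric(n)
  r <- ((un - 1) %% ny) + 1; c <- ((un - 1) %/% ny) + 1
  px <- ax$x[c]; py <- ax$y[r]
  arcs <- arcs[arcs$injection == injection, ]
  for (k in 1:4) {
    dr <- c(-1, 1, 0, 0)[k]; dc <- c(0, 0, -1, 1)[k]
    rr <- r + dr; cc <- c + dc
    inb <- rr >= 1 & rr <= ny & cc >= 1 & cc <= nx
    q <- ifelse(inb, (cc - 1) * ny + rr, 1L)
    act <- inb & mask[q]
    w <- numeric(n)
    w[act] <- 2 / (1 / sigma[un[act]] + 1 / sigma[q[act]])
    dg <- dg + w
    wme <- which(act)
    ii <- c(ii, wme); jj <- c(jj, idx[q[wme]]); vv <- c(vv, -w[wme])
    bd <- which(!act)
    if (length(bd)) {
      mx <- px[bd] + dc * grid$dx / 2; my <- py[bd] + dr * grid$dy / 2
      th <- atan2(my - ctr[2], mx - ctr[1])
      for (i in seq_len(nrow(arcs))) {
        hit <- mreit:::angle_in_arc(th, arcs$angle0[i], arcs$angle1[i])
        wh <- bd[hit]
        if (length(wh)) {
          wgt <- 2 * sigma[un[wh]]
          dg[wh] <- dg[wh] + wgt
          b[wh] <- b[wh] + wgt * ifelse(arcs$polarity[i] > 0, 1, -1)
        }
      }
    }
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                            x = c(dg, vv), dims = c(n, n))
  x <- as.numeric(Matrix::solve(A, b))
  out <- matrix(NA_real_, ny, nx); out[un] <- x
  out
}

# Piecewise-ramp 1D profile extruded in y: the clean structure denoising must
# preserve.
ramp_fixture <- function(nx = 128, ny = 64) {
  n3 <- c(round(0.3 * nx), round(0.4 * nx), nx - round(0.3 * nx) - round(0.4 * nx))
  prof <- c(seq(0, 1, length.out = n3[1]),
            seq(1, 0.4, length.out = n3[2]),
            seq(0.4, 0.9, length.out = n3[3]))
  matrix(rep(prof, each = ny), ny, nx)
}

# Small standard simulation fixtures (cached per session: forward solves are
# the slow part of the suite).
.fixture_env <- new.env()

fixture_case <- function(n = 64, which = c("homog", "contrast", "lowcontrast", "default"),
                         ...) {
  which <- match.arg(which)
  extra <- list(...)
  key <- paste0(which, "_", n)
  if (length(extra) == 0 && !is.null(.fixture_env[[key]]))
    return(.fixture_env[[key]])
  ell <- switch(which,
    homog = data.frame(cx = 0, cy = 0, a = 0.8, b = 0.9, angle = 0, value = 1),
    contrast = data.frame(cx = c(0, -0.15, 0.2), cy = c(0, 0.1, -0.2),
                          a = c(0.8, 0.25, 0.2), b = c(0.9, 0.3, 0.25),
                          angle = c(0, 0, 0), value = c(1, 1.3, 0.75)),
    lowcontrast = data.frame(cx = c(0, -0.25, 0.25), cy = c(0, 0.05, -0.05),
                             a = c(0.78, 0.2, 0.25), b = c(0.92, 0.35, 0.3),
                             angle = c(0, -15, 15), value = c(1, 0.8, 1.2)),
    default = shepp_logan_ellipses())
  g <- slice_grid(n, n, dx = 0.18 / n)
  case <- simulate_mreit(g, ellipses = ell, ...)
  if (length(extra) == 0) .fixture_env[[key]] <- case
  case
}

erode_mask <- function(m, k) {
  for (i in seq_len(k)) m <- m & !mreit:::boundary_ring(m)
  m
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

rmse_on <- function(a, b, mask) {
  d <- (a - b)[mask]
  sqrt(mean(d[is.finite(d)]^2))
}
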