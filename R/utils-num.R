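# Shared numeric helpers: phase wrapping, shifts, masked derivatives,
# Gaussian smoothing, connected components, bilinear sampling.

#' Wrap angles to the principal branch
#'
#' Maps values to the half-open interval (-pi, pi], the branch on which
#' wrapped phase data and wrapped phase differences live.
#'
#' @param x numeric vector/matrix of angles (radians).
#' @return wrapped values, same shape as `x`.
#' @export
wrap_phase <- function(x) x - 2 * pi * ceiling(x / (2 * pi) - 0.5)

# Shift a matrix by (dr, dc), filling vacated entries.
shift_mat <- function(m, dr, dc, fill = 0) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  rs <- seq_len(ny) - dr; cs <- seq_len(nx) - dc
  rok <- rs >= 1 & rs <= ny; cok <- cs >= 1 & cs <= nx
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Masked central differences. Where only one neighbor is inside the mask a
# one-sided difference is used; isolated pixels get 0. Returns per-pixel
# gradient components and the pixels where any estimate exists.
masked_gradient <- function(f, dx = 1, dy = 1, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(f)
  f0 <- f; f0[!mask] <- 0
  mp <- shift_mat(mask, 0, -1); mm <- shift_mat(mask, 0, 1)   # x+1, x-1 neighbors
  fp <- shift_mat(f0, 0, -1);   fm <- shift_mat(f0, 0, 1)
  gx <- matrix(0, nrow(f), ncol(f))
  both <- mask & mp & mm
  gx[both] <- (fp[both] - fm[both]) / (2 * dx)
  fwd <- mask & mp & !mm; gx[fwd] <- (fp[fwd] - f0[fwd]) / dx
  bwd <- mask & !mp & mm; gx[bwd] <- (f0[bwd] - fm[bwd]) / dx

  mp <- shift_mat(mask, -1, 0); mm <- shift_mat(mask, 1, 0)   # y+1, y-1 neighbors
  fp <- shift_mat(f0, -1, 0);   fm <- shift_mat(f0, 1, 0)
  gy <- matrix(0, nrow(f), ncol(f))
  both <- mask & mp & mm
  gy[both] <- (fp[both] - fm[both]) / (2 * dy)
  fwd <- mask & mp & !mm; gy[fwd] <- (fp[fwd] - f0[fwd]) / dy
  bwd <- mask & !mp & mm; gy[bwd] <- (f0[bwd] - fm[bwd]) / dy

  gx[!mask] <- NA_real_; gy[!mask] <- NA_real_
  list(gx = gx, gy = gy, valid = mask)
}

# Five-point Laplacian with physical spacings; NA where the stencil leaves the
# mask. `mask` defaults to finite entries.
laplacian5 <- function(f, dx = 1, dy = 1, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(f)
  f0 <- f; f0[!mask] <- 0
  ok <- mask &
    shift_mat(mask, 0, -1) & shift_mat(mask, 0, 1) &
    shift_mat(mask, -1, 0) & shift_mat(mask, 1, 0)
  lap <- (shift_mat(f0, 0, -1) + shift_mat(f0, 0, 1) - 2 * f0) / dx^2 +
         (shift_mat(f0, -1, 0) + shift_mat(f0, 1, 0) - 2 * f0) / dy^2
  lap[!ok] <- NA_real_
  lap
}

# Mask-normalized separable Gaussian smoothing, kernel truncated at 4*s.
# Outside the mask the output is NA; inside, weights renormalize so the mask
# boundary does not bleed zeros in.
gaussian_smooth <- function(f, s, mask = NULL) {
  if (s <= 0) return(f)
  if (is.null(mask)) mask <- is.finite(f)
  r <- max(1L, ceiling(4 * s))
  k <- exp(-(seq(-r, r))^2 / (2 * s^2)); k <- k / sum(k)
  f0 <- f; f0[!mask] <- 0
  m0 <- mask * 1
  num <- f0; den <- m0
  conv1 <- function(m, along, kk, rr) {
    acc <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(kk)) {
      off <- i - rr - 1L
      acc <- acc + kk[i] * if (along == "x") shift_mat(m, 0, off) else shift_mat(m, off, 0)
    }
    acc
  }
  num <- conv1(num, "x", k, r); den <- conv1(den, "x", k, r)
  num <- conv1(num, "y", k, r); den <- conv1(den, "y", k, r)
  out <- num / pmax(den, .Machine$double.eps)
  out[!mask] <- NA_real_
  out
}

# 4- (or 8-) connected component labeling by breadth-first search.
label_components <- function(mask, connectivity = 4) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  if (connectivity == 4) {
    nbr_dr <- c(-1L, 1L, 0L, 0L); nbr_dc <- c(0L, 0L, -1L, 1L)
  } else {
    nbr_dr <- rep(c(-1L, 0L, 1L), 3L); nbr_dc <- rep(c(-1L, 0L, 1L), each = 3L)
    keep <- !(nbr_dr == 0L & nbr_dc == 0L); nbr_dr <- nbr_dr[keep]; nbr_dc <- nbr_dc[keep]
  }
  cur <- 0L
  queue <- integer(sum(mask))
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    head <- 1L; tail <- 1L
    queue[1L] <- start; lab[start] <- cur
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% ny) + 1L; c <- ((p - 1L) %/% ny) + 1L
      for (k in seq_along(nbr_dr)) {
        rr <- r + nbr_dr[k]; cc <- c + nbr_dc[k]
        if (rr >= 1L && rr <= ny && cc >= 1L && cc <= nx) {
          q <- (cc - 1L) * ny + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur; tail <- tail + 1L; queue[tail] <- q
          }
        }
      }
    }
  }
  lab
}

# One-pixel 4-neighborhood dilation.
dilate4 <- function(mask) {
  mask | shift_mat(mask, 1, 0) | shift_mat(mask, -1, 0) |
    shift_mat(mask, 0, 1) | shift_mat(mask, 0, -1)
}

# Pixels of `mask` adjacent (4-connectivity) to the outside of `mask`.
boundary_ring <- function(mask) {
  inner <- shift_mat(mask, 1, 0, fill = FALSE) & shift_mat(mask, -1, 0, fill = FALSE) &
    shift_mat(mask, 0, 1, fill = FALSE) & shift_mat(mask, 0, -1, fill = FALSE)
  mask & !inner
}

# Bilinear sampling of a grid field at physical points (x, y). Points outside
# the pixel-center lattice, or touching NA samples, yield NA.
sample_bilinear <- function(f, grid, x, y) {
  ax <- grid_axes(grid)
  fx <- (x - ax$x[1]) / grid$dx
  fy <- (y - ax$y[1]) / grid$dy
  eps <- 1e-9
  inside <- fx >= -eps & fx <= grid$nx - 1 + eps & fy >= -eps & fy <= grid$ny - 1 + eps
  c0 <- pmin(pmax(floor(fx), 0), grid$nx - 2)
  r0 <- pmin(pmax(floor(fy), 0), grid$ny - 2)
  tx <- fx - c0; ty <- fy - r0
  c0 <- c0 + 1; r0 <- r0 + 1
  out <- rep(NA_real_, length(x))
  idx <- which(inside)
  if (length(idx)) {
    ny <- grid$ny
    i00 <- (c0[idx] - 1) * ny + r0[idx]
    i01 <- i00 + ny
    i10 <- i00 + 1
    i11 <- i01 + 1
    out[idx] <- (1 - tx[idx]) * (1 - ty[idx]) * f[i00] +
      tx[idx] * (1 - ty[idx]) * f[i01] +
      (1 - tx[idx]) * ty[idx] * f[i10] +
      tx[idx] * ty[idx] * f[i11]
  }
  out
}

# Root mean square over finite entries.
rmse <- function(a, b) {
  d <- a - b
  sqrt(mean(d[is.finite(d)]^2))
}

mu0 <- 4e-7 * pi
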