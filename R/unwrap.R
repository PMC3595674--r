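# Goldstein branch-cut phase unwrapping.
#
# Residues are the 2x2 loops whose wrapped phase differences fail to close;
# branch cuts pair each residue with its nearest opposite-charge partner (or
# with the mask border when that is nearer), and integration is a breadth
# first flood fill that never crosses a cut. The variant is deterministic:
# greedy pairing in scan order, ties broken by scan order.

#' Detect phase residues
#'
#' A residue sits at the 2x2 loop with top-left pixel (r, c) when the four
#' wrapped differences around the loop sum to a nonzero multiple of 2 pi.
#'
#' @param phi wrapped phase matrix.
#' @param mask logical mask of usable pixels (all four loop pixels must be in
#'   the mask).
#' @return data.frame with columns `r`, `c`, `charge` (+1 / -1).
#' @export
phase_residues <- function(phi, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(phi)
  ny <- nrow(phi); nx <- ncol(phi)
  p <- phi; p[!mask] <- 0
  p00 <- p[-ny, -nx]; p01 <- p[-ny, -1]; p11 <- p[-1, -1]; p10 <- p[-1, -nx]
  ok <- mask[-ny, -nx] & mask[-ny, -1] & mask[-1, -1] & mask[-1, -nx]
  s <- wrap_phase(p01 - p00) + wrap_phase(p11 - p01) +
       wrap_phase(p10 - p11) + wrap_phase(p00 - p10)
  q <- round(s / (2 * pi))
  q[!ok] <- 0L
  idx <- which(q != 0, arr.ind = TRUE)
  data.frame(r = idx[, 1], c = idx[, 2],
             charge = as.integer(q[idx]))
}

#' Goldstein branch-cut unwrapping of one slice
#'
#' @param wp a `wrapped_phase` (or a wrapped phase matrix).
#' @param mask mask when `wp` is a bare matrix.
#' @param max_residue_density abort threshold: residues per mask pixel above
#'   which the data are considered too noisy to unwrap (denoise first).
#' @return list with `phi` (unwrapped, NA off mask), `residue_count`,
#'   `cut_pixels` (logical matrix of branch-cut barrier pixels).
#' @export
goldstein_unwrap <- function(wp, mask = NULL, max_residue_density = 0.10) {
  if (inherits(wp, "wrapped_phase")) {
    mask <- wp$mask
    phi <- wp$phi
  } else {
    phi <- wp
    if (is.null(mask)) mask <- is.finite(phi)
  }
  ny <- nrow(phi); nx <- ncol(phi)
  res <- phase_residues(phi, mask)
  n_mask <- sum(mask)
  if (n_mask == 0) stop_validation("mask is empty")
  if (nrow(res) > max_residue_density * n_mask)
    stop_quality("residue density %.3f exceeds %.2f; denoise the phase before unwrapping",
                 nrow(res) / n_mask, max_residue_density)

  cut <- matrix(FALSE, ny, nx)
  if (nrow(res) > 0) cut <- place_branch_cuts(res, mask)

  unwrapped <- integrate_phase(phi, mask, cut)
  list(phi = unwrapped, residue_count = nrow(res), cut_pixels = cut)
}

# Greedy nearest-opposite pairing with dipole cuts; a residue closer to the
# mask border than to any opposite partner is grounded to the border.
place_branch_cuts <- function(res, mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  cut <- matrix(FALSE, ny, nx)
  ring <- which(boundary_ring(mask), arr.ind = TRUE)
  unpaired <- rep(TRUE, nrow(res))
  ord <- order(res$r, res$c)  # scan order
  for (i in ord) {
    if (!unpaired[i]) next
    # nearest opposite-charge unpaired residue
    cand <- which(unpaired & res$charge == -res$charge[i])
    best_j <- NA_integer_; best_d <- Inf
    if (length(cand)) {
      d <- (res$r[cand] - res$r[i])^2 + (res$c[cand] - res$c[i])^2
      k <- which.min(d)  # which.min is scan-order deterministic on ties
      best_j <- cand[k]; best_d <- d[k]
    }
    # distance to mask border
    db <- Inf; bidx <- NA_integer_
    if (nrow(ring)) {
      d2 <- (ring[, 1] - res$r[i])^2 + (ring[, 2] - res$c[i])^2
      bk <- which.min(d2)
      db <- d2[bk]; bidx <- bk
    }
    if (is.finite(best_d) && best_d <= db) {
      cut <- mark_cut(cut, res$r[i], res$c[i], res$r[best_j], res$c[best_j])
      unpaired[i] <- FALSE; unpaired[best_j] <- FALSE
    } else {
      cut <- mark_cut(cut, res$r[i], res$c[i], ring[bidx, 1], ring[bidx, 2])
      unpaired[i] <- FALSE
    }
  }
  cut & mask
}

# Rasterize the cut between two lattice points as an 8-connected pixel line
# (Bresenham), which a 4-connected flood fill cannot cross.
mark_cut <- function(cut, r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  r <- r0; c <- c0
  repeat {
    cut[r, c] <- TRUE
    if (r == r1 && c == c1) break
    e2 <- 2 * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  cut
}

# Flood-fill integration of wrapped differences over the mask, avoiding cut
# pixels; cut pixels are unwrapped afterwards from any unwrapped neighbor.
integrate_phase <- function(phi, mask, cut) {
  ny <- nrow(phi); nx <- ncol(phi)
  u <- matrix(NA_real_, ny, nx)
  visited <- matrix(FALSE, ny, nx)
  passable <- mask & !cut
  queue <- integer(sum(mask))
  for (start in which(passable & !visited)) {
    if (visited[start]) next
    u[start] <- phi[start]
    visited[start] <- TRUE
    head <- 1L; tail <- 1L; queue[1L] <- start
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% ny) + 1L; c <- ((p - 1L) %/% ny) + 1L
      for (k in 1:4) {
        rr <- r + c(-1L, 1L, 0L, 0L)[k]
        cc <- c + c(0L, 0L, -1L, 1L)[k]
        if (rr < 1L || rr > ny || cc < 1L || cc > nx) next
        q <- (cc - 1L) * ny + rr
        if (passable[q] && !visited[q]) {
          u[q] <- u[p] + wrap_phase(phi[q] - phi[p])
          visited[q] <- TRUE
          tail <- tail + 1L; queue[tail] <- q
        }
      }
    }
  }
  # fill cut pixels from unwrapped neighbors (repeat for cut chains)
  todo <- which(mask & !visited)
  while (length(todo)) {
    progressed <- FALSE
    for (p in todo) {
      r <- ((p - 1L) %% ny) + 1L; c <- ((p - 1L) %/% ny) + 1L
      for (k in 1:4) {
        rr <- r + c(-1L, 1L, 0L, 0L)[k]
        cc <- c + c(0L, 0L, -1L, 1L)[k]
        if (rr < 1L || rr > ny || cc < 1L || cc > nx) next
        q <- (cc - 1L) * ny + rr
        if (visited[q]) {
          u[p] <- u[q] + wrap_phase(phi[p] - phi[q])
          visited[p] <- TRUE
          progressed <- TRUE
          break
        }
      }
    }
    todo <- which(mask & !visited)
    if (!progressed) break  # isolated pixels: leave wrapped values
  }
  if (length(todo)) u[todo] <- phi[todo]
  u
}
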