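# Detection and repair of MR signal-void ("defected") regions. Where the MR
# magnitude is near zero the phase division amplifies noise arbitrarily; those
# pixels are assumed conductivity-homogeneous (so Laplace's equation holds for
# Bz) and refilled from their rim.

#' Detect defected pixels by magnitude thresholding
#'
#' Flags pixels in the domain whose MR magnitude falls below
#' `fraction * max(M)` (maximum over the domain of this slice). The default
#' fraction is 0.10 — ten percent of the maximum magnitude.
#'
#' @param M nonnegative MR magnitude matrix.
#' @param domain_mask logical domain mask.
#' @param fraction threshold fraction of the maximum magnitude.
#' @return object of class `defect_mask`: logical `mask`, `threshold_used`,
#'   `fraction`.
#' @export
detect_defected_region <- function(M, domain_mask = NULL, fraction = 0.10) {
  if (is.null(domain_mask)) domain_mask <- matrix(TRUE, nrow(M), ncol(M))
  if (any(M[domain_mask] < 0)) stop_validation("magnitude must be nonnegative")
  if (!any(domain_mask)) stop_validation("domain mask is empty")
  if (fraction <= 0 || fraction >= 1) stop_validation("fraction must be in (0, 1)")
  thr <- fraction * max(M[domain_mask])
  mask <- domain_mask & (M < thr)
  n_dom <- sum(domain_mask)
  if (sum(mask) == n_dom)
    stop_validation("every domain pixel is defected; nothing to reconstruct from")
  if (sum(mask) > 0.5 * n_dom)
    warn_mreit("defected region covers %.0f%% of the domain; reconstruction reliability is doubtful",
               100 * sum(mask) / n_dom)
  structure(list(mask = mask, threshold_used = thr, fraction = fraction),
            class = "defect_mask")
}

#' @export
print.defect_mask <- function(x, ...) {
  cat(sprintf("<defect_mask> %d defected pixels, threshold %.4g (fraction %.2f)\n",
              sum(x$mask), x$threshold_used, x$fraction))
  invisible(x)
}

#' Harmonic inpainting of Bz over defected pixels
#'
#' Replaces Bz on the defect mask by the solution of the discrete (5-point)
#' Laplace equation with Dirichlet data taken from the surrounding valid
#' pixels; everything outside the mask is untouched. Defect pixels whose
#' entire neighborhood is defected are simply part of the joint linear system
#' (an island inside another defect is absorbed into the enclosing solve).
#'
#' @param bz_slice numeric matrix with valid Bz outside the defect.
#' @param defect a `defect_mask` (or logical matrix).
#' @param domain_mask optional domain restriction; pixels outside the domain
#'   are ignored entirely.
#' @param tol CG relative residual tolerance.
#' @return repaired matrix.
#' @export
harmonic_inpaint <- function(bz_slice, defect, domain_mask = NULL, tol = 1e-10) {
  mask <- if (inherits(defect, "defect_mask")) defect$mask else defect
  if (is.null(domain_mask)) domain_mask <- matrix(TRUE, nrow(bz_slice), ncol(bz_slice))
  mask <- mask & domain_mask
  if (!any(mask)) return(bz_slice)
  ring_ok <- domain_mask & !mask & is.finite(bz_slice)
  sol <- solve_masked_laplace(bz_slice, mask, ring_ok, tol = tol)
  out <- bz_slice
  out[mask] <- sol[mask]
  out
}

# Solve the 5-point Laplace system on `unknown` with Dirichlet data from
# `known` (values of f there); faces leading outside known+unknown are
# treated as no-flux (mirror) so boundary-touching defects remain solvable.
solve_masked_laplace <- function(f, unknown, known, tol = 1e-10) {
  ny <- nrow(f); nx <- ncol(f)
  idx <- matrix(0L, ny, nx)
  un <- which(unknown)
  if (!length(un)) return(f)
  idx[un] <- seq_along(un)
  nun <- length(un)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  b <- numeric(nun)
  diag_cnt <- numeric(nun)
  has_known <- FALSE
  r <- ((un - 1L) %% ny) + 1L; c <- ((un - 1L) %/% ny) + 1L
  for (k in 1:4) {
    rr <- r + c(-1L, 1L, 0L, 0L)[k]
    cc <- c + c(0L, 0L, -1L, 1L)[k]
    inb <- rr >= 1L & rr <= ny & cc >= 1L & cc <= nx
    q <- ifelse(inb, (cc - 1L) * ny + rr, NA_integer_)
    is_un <- inb & unknown[ifelse(inb, q, 1L)]
    is_kn <- inb & !is_un & known[ifelse(inb, q, 1L)]
    # neighbors outside known+unknown contribute nothing (no-flux)
    diag_cnt <- diag_cnt + as.numeric(is_un | is_kn)
    w <- which(is_un)
    if (length(w)) {
      ii <- c(ii, w); jj <- c(jj, idx[q[w]]); xx <- c(xx, rep(-1, length(w)))
    }
    wk <- which(is_kn)
    if (length(wk)) {
      b[wk] <- b[wk] + f[q[wk]]
      has_known <- TRUE
    }
  }
  if (!has_known)
    stop_validation("defected region has no valid neighbors anywhere")
  A <- Matrix::sparseMatrix(i = c(seq_len(nun), ii), j = c(seq_len(nun), jj),
                            x = c(pmax(diag_cnt, 1), xx), dims = c(nun, nun))
  sol <- cg_core(A, b, tol = tol, maxit = max(10L * nun, 100L))
  out <- f
  out[un] <- sol$x
  out
}

#' Isotropic seam smoothing after inpainting
#'
#' Runs the heat equation (unit diffusivity) on the defect mask dilated by one
#' pixel, clamping values outside the dilated region (Dirichlet), for
#' `duration` time units. This smooths the seam between inpainted and measured
#' pixels; an exactly harmonic patch with consistent rim data is a steady
#' state and passes through unchanged.
#'
#' @param bz_slice matrix after [harmonic_inpaint()].
#' @param defect `defect_mask` or logical matrix.
#' @param duration diffusion duration (pixel units); default 2.
#' @param dt explicit step, stability-capped at 0.25.
#' @param domain_mask optional domain restriction.
#' @return smoothed matrix.
#' @export
isotropic_smooth_defect <- function(bz_slice, defect, duration = 2.0,
                                    dt = 0.2, domain_mask = NULL) {
  mask <- if (inherits(defect, "defect_mask")) defect$mask else defect
  if (is.null(domain_mask)) domain_mask <- matrix(TRUE, nrow(bz_slice), ncol(bz_slice))
  if (duration <= 0 || !any(mask)) return(bz_slice)
  region <- dilate4(mask) & domain_mask & is.finite(bz_slice)
  dt <- min(dt, 0.25)
  u <- bz_slice
  t <- 0
  while (t < duration - 1e-12) {
    step <- min(dt, duration - t)
    u0 <- u; u0[!domain_mask | !is.finite(u0)] <- 0
    ok <- domain_mask & is.finite(u)
    lap <- matrix(0, nrow(u), ncol(u))
    for (k in 1:4) {
      nb <- shift_mat(u0, c(-1, 1, 0, 0)[k], c(0, 0, -1, 1)[k])
      nb_ok <- shift_mat(ok, c(-1, 1, 0, 0)[k], c(0, 0, -1, 1)[k], fill = FALSE)
      lap <- lap + ifelse(nb_ok, nb - u0, 0)  # mirror at region border
    }
    u[region] <- u[region] + step * lap[region]
    t <- t + step
  }
  u
}
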