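#' Inverse DFT of k-space data to a complex image
#'
#' Applies the inverse transform under the convention recorded in the
#' `kspace_data` object (DC-centered storage, `1/(nx ny)`-normalized
#' inverse). Data without convention metadata are refused rather than decoded
#' with a silent default.
#'
#' @param s a `kspace_data` object, or a complex matrix together with an
#'   explicit `convention` string.
#' @param convention required when `s` is a bare matrix.
#' @return complex image matrix, or a list `plus`/`minus` when the k-space
#'   object holds a polarity pair.
#' @export
kspace_to_image <- function(s, convention = NULL) {
  if (inherits(s, "kspace_data")) {
    convention <- s$convention
    s <- s$s
  }
  if (is.null(convention))
    stop_validation("k-space data has no storage convention metadata; refusing to guess")
  if (convention != "dc-centered/unnormalized-forward")
    stop_validation("unsupported k-space convention '%s'", convention)
  inv <- function(m) {
    if (any(!is.finite(Re(m))) || any(!is.finite(Im(m))))
      stop_validation("k-space array contains non-finite values")
    stats::fft(ifftshift2(m), inverse = TRUE) / length(m)
  }
  if (is.list(s)) lapply(s, inv) else inv(s)
}

#' Wrapped current-induced phase from a complex image pair
#'
#' Computes `phi = arg(m_plus * conj(m_minus))`, the wrapped version of
#' `2 gamma Tc Bz`. The systematic phase artifact common to both images
#' cancels exactly in the product. Pixels whose magnitude product falls below
#' `magnitude_floor` are masked out (they belong to the defect-repair path).
#'
#' @param m_plus,m_minus complex matrices of equal shape (or a
#'   `complex_image_pair`, in which case `m_minus` is ignored).
#' @param magnitude_floor threshold on `|m_plus| * |m_minus|`.
#' @return object of class `wrapped_phase`: `phi` in (-pi, pi], logical
#'   `mask`.
#' @export
extract_wrapped_bz <- function(m_plus, m_minus = NULL, magnitude_floor = 0) {
  if (inherits(m_plus, "complex_image_pair")) {
    m_minus <- m_plus$m_minus
    m_plus <- m_plus$m_plus
  }
  if (!all(dim(m_plus) == dim(m_minus)))
    stop_validation("m_plus and m_minus must have the same shape")
  prod <- m_plus * Conj(m_minus)
  phi <- Arg(prod)
  phi <- wrap_phase(phi)  # Arg returns (-pi, pi]; enforce the invariant
  mask <- Mod(prod) >= magnitude_floor & is.finite(phi)
  if (!any(mask)) warn_mreit("all pixels fall below the magnitude floor")
  phi[!mask] <- NA_real_
  structure(list(phi = phi, mask = mask), class = "wrapped_phase")
}

#' Scale unwrapped phase to Bz
#'
#' `Bz = phase / (2 gamma Tc)`, Tesla.
#'
#' @param unwrapped unwrapped phase matrix (radians).
#' @param Tc current pulse width, seconds.
#' @param gamma gyromagnetic ratio, rad/(T s).
#' @return Bz matrix in Tesla.
#' @export
phase_to_bz <- function(unwrapped, Tc, gamma = GAMMA_HYDROGEN) {
  if (Tc <= 0 || gamma <= 0) stop_validation("Tc and gamma must be positive")
  unwrapped / (2 * gamma * Tc)
}

#' Full measured-phase-to-Bz chain for one slice
#'
#' Phase division, Goldstein unwrapping, per-slice constant fixing (the
#' additive 2 pi k ambiguity is resolved by moving the median phase over the
#' mask's boundary ring to the multiple of 2 pi nearest zero — Bz is
#' physically near zero at the domain rim), and scaling by `1/(2 gamma Tc)`.
#'
#' @inheritParams extract_wrapped_bz
#' @inheritParams phase_to_bz
#' @return list with `bz` (Tesla, NA off the mask), `mask`, `unwrapped`,
#'   `residue_count`.
#' @export
bz_from_pair <- function(m_plus, m_minus = NULL, Tc = NULL,
                         gamma = GAMMA_HYDROGEN, magnitude_floor = 0) {
  if (inherits(m_plus, "complex_image_pair")) {
    if (is.null(Tc)) Tc <- m_plus$Tc
    gamma <- m_plus$gamma
  }
  if (is.null(Tc)) stop_validation("Tc is required")
  wp <- extract_wrapped_bz(m_plus, m_minus, magnitude_floor)
  uw <- goldstein_unwrap(wp)
  phi <- normalize_phase_offset(uw$phi, wp$mask)
  list(bz = phase_to_bz(phi, Tc, gamma), mask = wp$mask,
       unwrapped = phi, residue_count = uw$residue_count)
}

# Remove the global 2*pi*k so the boundary-ring median lands nearest zero.
normalize_phase_offset <- function(phi, mask) {
  ring <- boundary_ring(mask)
  if (!any(ring)) ring <- mask
  med <- stats::median(phi[ring], na.rm = TRUE)
  phi - 2 * pi * round(med / (2 * pi))
}

#' Verify Bz continuity across slices
#'
#' For each adjacent slice pair the statistic is the median absolute
#' inter-slice difference divided by the median in-plane gradient magnitude
#' (averaged over the two slices). A pair fails when the ratio exceeds
#' `threshold`; any failing pair makes the recommended Laplacian mode "2d"
#' (drop the d2/dz2 term rather than risk an artifact from a z-discontinuity,
#' e.g. a per-slice unwrapping offset).
#'
#' @param bz a `bz_volume`.
#' @param injection which injection's slices to check.
#' @param threshold failure threshold for the ratio statistic.
#' @return object of class `continuity_report`: data.frame `pairs`
#'   (slice_a, slice_b, statistic, pass), `recommended_mode`.
#' @export
verify_z_continuity <- function(bz, injection = 1L, threshold = 5.0) {
  if (!inherits(bz, "bz_volume")) stop_validation("bz must be a bz_volume")
  if (bz$nz < 2) {
    return(structure(list(pairs = data.frame(slice_a = integer(0), slice_b = integer(0),
                                             statistic = numeric(0), pass = logical(0)),
                          recommended_mode = "2d", threshold = threshold),
                     class = "continuity_report"))
  }
  st <- numeric(bz$nz - 1); ok <- logical(bz$nz - 1)
  for (s in seq_len(bz$nz - 1)) {
    a <- bz$bz[, , s, injection]; b <- bz$bz[, , s + 1, injection]
    va <- bz$valid[, , s, injection] & bz$valid[, , s + 1, injection]
    dif <- stats::median(abs(b - a)[va], na.rm = TRUE)
    gmag <- function(m, v) {
      g <- masked_gradient(m, bz$grid$dx, bz$grid$dy, v)
      stats::median(sqrt(g$gx^2 + g$gy^2)[v], na.rm = TRUE)
    }
    gref <- (gmag(a, va) + gmag(b, va)) / 2 * min(bz$grid$dx, bz$grid$dy)
    # gref is the median per-pixel in-plane increment; guard flat slices
    st[s] <- dif / max(gref, .Machine$double.eps)
    ok[s] <- st[s] <= threshold
  }
  structure(list(pairs = data.frame(slice_a = seq_len(bz$nz - 1),
                                    slice_b = 2:bz$nz,
                                    statistic = st, pass = ok),
                 recommended_mode = if (all(ok)) "3d" else "2d",
                 threshold = threshold),
            class = "continuity_report")
}

#' @export
print.continuity_report <- function(x, ...) {
  cat(sprintf("<continuity_report> %d slice pairs, recommended Laplacian mode: %s\n",
              nrow(x$pairs), x$recommended_mode))
  if (nrow(x$pairs)) print(x$pairs)
  invisible(x)
}
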