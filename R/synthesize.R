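# Gyromagnetic ratio of hydrogen, rad / (T s).
GAMMA_HYDROGEN <- 26.75e7

#' Synthesize a complex MR image pair for one injection
#'
#' Builds the complex images acquired with positive and counter-directional
#' current injection:
#' `m_plus = M exp(i delta) exp(+i gamma Bz Tc)` and
#' `m_minus = M exp(i delta) exp(-i gamma Bz Tc)`,
#' where `M` is the MR magnitude, `delta` any systematic phase artifact
#' (common to both polarities, so it cancels in the phase division), `gamma`
#' the gyromagnetic ratio of hydrogen and `Tc` the current pulse width.
#' Optional i.i.d. circular complex Gaussian noise of standard deviation
#' `noise_sd` (per real/imaginary channel) is added independently to each
#' image, reproducibly from `seed`.
#'
#' @param M nonnegative magnitude matrix.
#' @param delta systematic phase matrix (radians); scalar 0 allowed.
#' @param bz_slice Bz matrix in Tesla (or a `bz_slice`).
#' @param Tc current pulse width, seconds.
#' @param gamma gyromagnetic ratio, rad/(T s).
#' @param noise_sd complex-Gaussian noise standard deviation (magnitude units).
#' @param seed integer seed used when `noise_sd > 0`.
#' @return object of class `complex_image_pair` with `m_plus`, `m_minus`,
#'   `magnitude`, `phase_artifact`, `Tc`, `gamma`, `noise_sd`, `seed`.
#' @export
synthesize_complex_pair <- function(M, delta = 0, bz_slice, Tc,
                                    gamma = GAMMA_HYDROGEN,
                                    noise_sd = 0, seed = 1L) {
  if (inherits(bz_slice, "bz_slice")) bz_slice <- bz_slice$bz
  if (any(M < 0)) stop_validation("magnitude M must be nonnegative")
  if (Tc <= 0) stop_validation("pulse width Tc must be positive")
  if (gamma <= 0) stop_validation("gamma must be positive")
  if (noise_sd < 0) stop_validation("noise_sd must be nonnegative")
  if (length(delta) == 1) delta <- matrix(delta, nrow(M), ncol(M))
  base <- M * exp(1i * delta)
  phase <- gamma * bz_slice * Tc
  m_plus <- base * exp(1i * phase)
  m_minus <- base * exp(-1i * phase)
  if (noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    n <- length(M)
    m_plus <- m_plus + matrix(complex(real = stats::rnorm(n, sd = noise_sd),
                                      imaginary = stats::rnorm(n, sd = noise_sd)),
                              nrow(M), ncol(M))
    m_minus <- m_minus + matrix(complex(real = stats::rnorm(n, sd = noise_sd),
                                        imaginary = stats::rnorm(n, sd = noise_sd)),
                                nrow(M), ncol(M))
  }
  structure(list(m_plus = m_plus, m_minus = m_minus,
                 magnitude = M, phase_artifact = delta,
                 Tc = Tc, gamma = gamma, noise_sd = noise_sd, seed = seed),
            class = "complex_image_pair")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Forward DFT of complex images to k-space
#'
#' Storage convention: DC-centered ("fftshift" layout), unnormalized forward
#' transform; the matching inverse divides by `nx * ny`. The convention is
#' recorded in the returned object so readers never have to guess.
#'
#' @param pair a `complex_image_pair`, or a single complex matrix.
#' @return object of class `kspace_data`: `s` (list with `plus`/`minus`, or a
#'   single matrix), `convention = "dc-centered/unnormalized-forward"`,
#'   `dkx`, `dky` (cycles/m) when a grid is supplied.
#' @param grid optional [slice_grid()] for the frequency spacings.
#' @export
synthesize_kspace <- function(pair, grid = NULL) {
  fw <- function(m) {
    if (any(!is.finite(Re(m))) || any(!is.finite(Im(m))))
      stop_validation("complex image contains non-finite values")
    fftshift2(stats::fft(m))
  }
  s <- if (inherits(pair, "complex_image_pair"))
    list(plus = fw(pair$m_plus), minus = fw(pair$m_minus))
  else fw(pair)
  dk <- if (is.null(grid)) c(NA_real_, NA_real_)
        else c(1 / (grid$nx * grid$dx), 1 / (grid$ny * grid$dy))
  structure(list(s = s, convention = "dc-centered/unnormalized-forward",
                 dkx = dk[1], dky = dk[2]),
            class = "kspace_data")
}

# Swap quadrants so DC sits at index floor(n/2) + 1 on each axis.
fftshift2 <- function(m) {
  idx <- function(n) ((seq_len(n) - 1 - floor(n / 2)) %% n) + 1
  m[idx(nrow(m)), idx(ncol(m))]
}

ifftshift2 <- function(m) {
  idx <- function(n) ((seq_len(n) - 1 + floor(n / 2)) %% n) + 1
  m[idx(nrow(m)), idx(ncol(m))]
}
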