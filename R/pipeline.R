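# Pipeline orchestration: one configuration drives the full
# simulate -> phase -> denoise -> inpaint -> mesh -> reconstruct chain, with a
# strict parameter schema, a single accumulating container, and a JSON run
# manifest (per-stage parameter snapshots + output hashes).

PIPELINE_SCHEMA <- list(
  simulate = c("nx", "ny", "dx", "dz", "contrast", "I", "Tc", "arc_width",
               "noise_sd", "thickness_model", "magnitude"),
  phase = c("magnitude_floor"),
  denoise = c("t1", "t2", "dt", "s"),
  inpaint = c("fraction", "duration"),
  mesh = c("max_area"),
  reconstruct = c("mode", "boundary", "local_region", "det_fraction")
)

validate_config <- function(config) {
  if (is.null(config$stages) || !is.list(config$stages))
    stop_validation("config must contain a 'stages' list")
  top_ok <- c("seed", "stages", "out")
  bad <- setdiff(names(config), top_ok)
  if (length(bad)) stop_validation("unknown config key: '%s'", bad[1])
  known <- names(PIPELINE_SCHEMA)
  for (st in names(config$stages)) {
    if (!st %in% known) stop_validation("unknown stage: '%s'", st)
    bad <- setdiff(names(config$stages[[st]]), PIPELINE_SCHEMA[[st]])
    if (length(bad)) stop_validation("unknown key '%s' in stage '%s'", bad[1], st)
  }
  # stages must appear in topological order
  ord <- match(names(config$stages), known)
  if (is.unsorted(ord)) stop_validation("stages are out of order; expected order %s",
                                        paste(known, collapse = " -> "))
  invisible(config)
}

#' Run the MREIT pipeline from a configuration
#'
#' Executes the configured stages in order, accumulating results in a single
#' container file, and writes a JSON manifest with parameter snapshots and an
#' MD5 hash of the container after every stage. Every stage is a pure
#' function of (inputs, parameters, seed), so re-running an identical
#' configuration reproduces identical container bytes.
#'
#' @param config nested list (or path to a YAML file): optional `seed`,
#'   mandatory `stages` with per-stage parameter blocks. Unknown keys are
#'   rejected.
#' @param out path of the container file to create/update (`.rds`).
#' @param manifest_path optional path for the JSON manifest.
#' @return the manifest (list), invisibly; the container lives at `out`.
#' @export
run_pipeline <- function(config, out, manifest_path = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  container <- NULL
  manifest <- list(seed = seed, stages = list())
  for (st in names(stages)) {
    p <- stages[[st]]
    started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    warnings_seen <- character(0)
    res <- withCallingHandlers(
      switch(st,
        simulate = stage_simulate(p, seed),
        phase = stage_phase(container, p),
        denoise = stage_denoise(container, p),
        inpaint = stage_inpaint(container, p),
        mesh = stage_mesh(container, p),
        reconstruct = stage_reconstruct(container, p)
      ),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    container <- res
    container$meta$dirty <- NULL
    write_container(container, out)
    manifest$stages[[st]] <- list(
      params = if (length(p)) p else NULL,
      container_md5 = unname(tools::md5sum(out)),
      warnings = if (length(warnings_seen)) warnings_seen else NULL,
      started = started
    )
  }
  if (!is.null(manifest_path))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

stage_simulate <- function(p, seed) {
  nx <- p$nx %||% 128L; ny <- p$ny %||% nx
  grid <- slice_grid(nx, ny, dx = p$dx %||% 1.4e-3, dz = p$dz %||% 3e-3)
  electrodes <- electrode_config(I = p$I %||% 1e-3, Tc = p$Tc %||% 30e-3,
                                 width = p$arc_width %||% (pi / 4))
  case <- simulate_mreit(grid,
                         ellipses = shepp_logan_ellipses(p$contrast %||% 1),
                         electrodes = electrodes,
                         noise_sd = p$noise_sd %||% 0, seed = seed,
                         thickness_model = p$thickness_model %||% "infinite")
  cont <- new_container(grid, meta = list(Tc = electrodes$Tc,
                                          gamma = case$pairs[[1]]$gamma,
                                          I = electrodes$I, seed = seed))
  cont$sigma_true <- case$phantom$sigma
  cont$domain_mask <- case$phantom$domain_mask
  cont$M <- case$M
  cont$electrodes <- electrodes
  cont$phantom <- case$phantom
  cont$pairs <- case$pairs
  cont$bz_true <- case$bz_true
  cont$J_sim <- case$J
  cont
}

stage_phase <- function(cont, p) {
  if (is.null(cont$pairs)) stop_validation("phase stage needs simulated (or imported) image pairs")
  # default floor: the 10%-of-max magnitude convention applied to each factor
  # of |m_plus| |m_minus|, so defect-bound pixels are masked out here too
  floor_ <- p$magnitude_floor %||%
    (0.10 * max(Mod(cont$pairs[[1]]$m_plus)))^2
  slices <- lapply(1:2, function(j) {
    out <- bz_from_pair(cont$pairs[[j]], magnitude_floor = floor_)
    structure(list(grid = cont$grid, bz = ifelse(out$mask, out$bz, NA_real_),
                   valid = out$mask), class = "bz_slice")
  })
  cont$bz_meas <- bz_volume(list(slices), cont$grid)
  rep1 <- verify_z_continuity(cont$bz_meas)
  cont$continuity <- list(recommended_mode = rep1$recommended_mode,
                          pairs = rep1$pairs)
  cont
}

stage_denoise <- function(cont, p) {
  if (is.null(cont$bz_meas)) stop_validation("denoise stage needs measured Bz")
  settings <- diffusion_settings(T1 = p$t1 %||% 1, T2 = p$t2 %||% 2,
                                 dt = p$dt %||% 0.2, s = p$s %||% 1)
  defect <- detect_defected_region(cont$M, cont$domain_mask,
                                   fraction = 0.10)
  mask <- cont$domain_mask & !defect$mask
  bz <- cont$bz_meas
  for (j in 1:2) {
    sl <- bz$bz[, , 1, j]
    sl[!bz$valid[, , 1, j]] <- NA_real_
    den <- ramp_preserving_denoise(sl, settings, mask = mask & bz$valid[, , 1, j])
    bz$bz[, , 1, j] <- den
  }
  cont$bz_denoised <- bz
  cont$denoise_settings <- settings
  cont
}

stage_inpaint <- function(cont, p) {
  src <- cont$bz_denoised %||% cont$bz_meas
  if (is.null(src)) stop_validation("inpaint stage needs Bz data")
  defect <- detect_defected_region(cont$M, cont$domain_mask,
                                   fraction = p$fraction %||% 0.10)
  bz <- src
  for (j in 1:2) {
    sl <- bz$bz[, , 1, j]
    sl <- harmonic_inpaint(sl, defect, domain_mask = cont$domain_mask)
    sl <- isotropic_smooth_defect(sl, defect, duration = p$duration %||% 2,
                                  domain_mask = cont$domain_mask)
    bz$bz[, , 1, j] <- sl
    bz$valid[, , 1, j] <- bz$valid[, , 1, j] | (defect$mask & cont$domain_mask)
  }
  cont$defect_mask <- defect
  cont$bz_repaired <- bz
  cont
}

stage_mesh <- function(cont, p) {
  if (is.null(cont$domain_mask)) stop_validation("mesh stage needs a domain mask")
  cont$recon_mesh <- mesh_from_mask(cont$grid, cont$domain_mask,
                                    electrodes = cont$electrodes,
                                    max_area = p$max_area)
  cont
}

stage_reconstruct <- function(cont, p) {
  bzv <- cont$bz_repaired %||% cont$bz_denoised %||% cont$bz_meas
  if (is.null(bzv)) stop_validation("reconstruct stage needs Bz data")
  if (is.null(cont$recon_mesh)) stop_validation("reconstruct stage needs a mesh (run the mesh stage)")
  mode <- p$mode %||% "2d"
  phantom <- cont$phantom
  electrodes <- cont$electrodes
  pots <- lapply(1:2, function(j) {
    ph0 <- phantom; ph0$sigma <- matrix(1, cont$grid$ny, cont$grid$nx)
    solve_forward_2d(ph0, electrodes, j, mesh = cont$recon_mesh)
  })
  ph0 <- phantom; ph0$sigma <- matrix(1, cont$grid$ny, cont$grid$nx)
  Js <- lapply(pots, function(pt) current_density(ph0, pt, electrodes))
  a_field <- build_a_matrix(Js[[1]], Js[[2]],
                            det_fraction = p$det_fraction %||% 1e-3)
  lap1 <- laplacian_bz(bzv, 1, 1, mode = mode, force = TRUE)
  lap2 <- laplacian_bz(bzv, 1, 2, mode = mode, force = TRUE)
  if (!is.null(p$local_region)) {
    rv <- matrix(unlist(p$local_region), ncol = 2, byrow = TRUE)
    poly <- segment_domain(cont$M, cont$grid)
    region <- clip_local_region(rv, poly, defect = cont$defect_mask,
                                grid = cont$grid)
    rec <- local_harmonic_bz(region, a_field, lap1, lap2, cont$grid,
                             boundary = p$boundary %||% "dirichlet")
  } else {
    rec <- harmonic_bz_reconstruct(cont$recon_mesh, a_field, lap1, lap2,
                                   boundary = p$boundary %||% "dirichlet")
  }
  cont$sigma_recon <- rec$raster
  cont$recon <- list(boundary = rec$boundary, excluded = rec$excluded,
                     cg = rec$cg, mode = mode,
                     local = !is.null(p$local_region))
  cont
}

`%||%` <- function(a, b) if (is.null(a)) b else a
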