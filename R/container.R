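# Named-array container for the pipeline's dataflow: one file accumulates the
# outputs of every stage (arrays + metadata + schema version), serialized in
# R's native RDS format. NIfTI import/export is provided for magnitude and
# raster volumes.

CONTAINER_SCHEMA <- "mreit-container/1.1"

# Migrations from older minor schemas: old field name -> new field name.
CONTAINER_MIGRATIONS <- list(
  "mreit-container/1.0" = list(rename = c(mask = "domain_mask", bz = "bz_meas"))
)

#' Create an empty pipeline container
#'
#' @param grid a [slice_grid()].
#' @param meta named list of metadata (spacings, Tc, gamma, I, seed are
#'   filled in by the stages that know them).
#' @return object of class `mreit_container`.
#' @export
new_container <- function(grid, meta = list()) {
  meta <- utils::modifyList(list(dx = grid$dx, dy = grid$dy, dz = grid$dz,
                                 nx = grid$nx, ny = grid$ny,
                                 origin = grid$origin), meta)
  structure(list(schema = CONTAINER_SCHEMA, grid = grid, meta = meta),
            class = "mreit_container")
}

#' Write a container to disk
#' @param container an `mreit_container`.
#' @param path output file path (`.rds`).
#' @export
write_container <- function(container, path) {
  if (!inherits(container, "mreit_container"))
    stop_validation("not an mreit_container")
  saveRDS(container, path)
  invisible(path)
}

#' Read a container, migrating older minor schemas
#' @param path file path written by [write_container()].
#' @return an `mreit_container`.
#' @export
read_container <- function(path) {
  x <- readRDS(path)
  if (is.null(x$schema))
    stop_validation("file has no container schema field; cannot migrate")
  if (!identical(x$schema, CONTAINER_SCHEMA)) {
    mig <- CONTAINER_MIGRATIONS[[x$schema]]
    if (is.null(mig))
      stop_validation("container schema '%s' is not supported (current: %s)",
                      x$schema, CONTAINER_SCHEMA)
    for (old in names(mig$rename)) {
      if (!is.null(x[[old]])) {
        x[[mig$rename[[old]]]] <- x[[old]]
        x[[old]] <- NULL
      }
    }
    message(sprintf("migrated container from schema %s to %s", x$schema, CONTAINER_SCHEMA))
    x$schema <- CONTAINER_SCHEMA
  }
  if (!inherits(x, "mreit_container")) class(x) <- "mreit_container"
  x
}

#' @export
print.mreit_container <- function(x, ...) {
  keys <- setdiff(names(x), c("schema", "meta"))
  cat(sprintf("<mreit_container> schema %s\n  fields: %s\n", x$schema,
              paste(keys, collapse = ", ")))
  invisible(x)
}

#' Export a volume to NIfTI
#'
#' Writes a matrix (or ny x nx x nz array) as a NIfTI file with voxel
#' dimensions taken from the grid.
#'
#' @param vol matrix or 3D array.
#' @param grid a [slice_grid()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_nifti_volume <- function(vol, grid, path) {
  # NIfTI x fastest: store as [nx, ny(, nz)]; single slices stay 2D (the
  # NIfTI writer squeezes trailing singleton dimensions anyway)
  if (is.matrix(vol)) {
    a <- t(vol)
    pd <- c(grid$dx, grid$dy)
  } else {
    a <- aperm(vol, c(2, 1, 3))
    pd <- c(grid$dx, grid$dy, grid$dz)
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Import a NIfTI volume written by [write_nifti_volume()]
#' @param path NIfTI file path.
#' @return list with `vol` (ny x nx x nz array) and `pixdim`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  pd <- RNifti::pixdim(img)
  if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1))
  list(vol = aperm(a, c(2, 1, 3)),
       pixdim = c(pd, rep(NA_real_, max(0, 3 - length(pd))))[1:3])
}
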