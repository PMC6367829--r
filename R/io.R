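#' Write a voxel grid to a NIfTI file
#'
#' Volumes (CT, dose, masks) are written as `.nii.gz` with the grid spacing
#' in the header; deformation fields are written as 4D volumes with the
#' vector component as the fourth dimension.
#'
#' @param x a `voxel_grid` or `deformation_field`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI volumes requires the RNifti package", call. = FALSE)
  }
  arr <- if (inherits(x, "deformation_field")) x$u else x$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(x$spacing, 1)[seq_len(length(dim(arr)))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel grid from a NIfTI file
#' @param path a `.nii`/`.nii.gz` file.
#' @param origin world origin; grid-centred when NULL.
#' @return a `voxel_grid` (3D) or `deformation_field` (4D, 3 components).
#' @export
read_volume <- function(path, origin = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")[1:3]
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 3L) {
    deformation_field(arr, spacing, origin)
  } else {
    voxel_grid(arr, spacing, origin)
  }
}

#' Serialize a spot plan to JSON
#'
#' Writes the plan as field -> energy layers -> spots (energy, lateral
#' position, weight, timestamp), with the machine model, prescription and
#' calibration alongside.
#'
#' @param plan a `spot_plan`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  fields <- lapply(0:1, function(f) {
    sf <- plan$spots[plan$spots$field == f, ]
    layers <- lapply(unique(sf$energy_mev), function(E) {
      sl <- sf[sf$energy_mev == E, ]
      list(energy_mev = E,
           spots = lapply(seq_len(nrow(sl)), function(r) {
             list(u_mm = sl$u[r], v_mm = sl$v[r], weight = sl$weight[r],
                  timestamp_s = sl$timestamp_s[r])
           }))
    })
    list(field = f, angle_deg = plan$fields[[f + 1]]$angle_deg,
         layers = layers)
  })
  obj <- list(fields = fields, calibration = plan$calibration,
              prescription = plan$prescription,
              machine = unclass(plan$machine),
              isocentre_mm = plan$iso)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# CSV writer: readr when present, base otherwise
write_table_csv <- function(x, path) {
  if (requireNamespace("readr", quietly = TRUE)) {
    readr::write_csv(x, path)
  } else {
    utils::write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}
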