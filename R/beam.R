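#' Beam coordinate frame for a gantry angle
#'
#' The gantry rotates in the axial (LR-AP) plane about the isocentre; the
#' couch is fixed. At 0 degrees the beam enters from anterior and travels
#' posterior; angles increase toward the patient's left. Beam's-eye-view
#' (BEV) axes are right-handed: `u` lateral in the axial plane, `v` along
#' IS, `t` the beam travel direction.
#'
#' @param angle_deg gantry angle in degrees, `[0, 360)`.
#' @param iso isocentre in world mm (length 3).
#' @return list with unit vectors `t`, `e_u`, `e_v` and the isocentre.
#' @export
beam_frame <- function(angle_deg, iso = c(0, 0, 0)) {
  th <- angle_deg * pi / 180
  t <- c(-sin(th), -cos(th), 0)
  e_u <- c(-t[2], t[1], 0) # z x t
  e_v <- c(0, 0, 1)
  list(angle_deg = angle_deg, t = t, e_u = e_u, e_v = e_v, iso = as.numeric(iso))
}

# BEV grid specification covering the whole patient grid
bev_grid_spec <- function(reference, frame, spacing = NULL) {
  if (is.null(spacing)) spacing <- min(reference$spacing)
  d <- grid_shape(reference)
  corners <- as.matrix(expand.grid(
    x = c(reference$origin[1], reference$origin[1] + (d[1] - 1) * reference$spacing[1]),
    y = c(reference$origin[2], reference$origin[2] + (d[2] - 1) * reference$spacing[2]),
    z = c(reference$origin[3], reference$origin[3] + (d[3] - 1) * reference$spacing[3])
  ))
  rel <- sweep(corners, 2, frame$iso, `-`)
  u <- rel %*% frame$e_u; v <- rel %*% frame$e_v; dd <- rel %*% frame$t
  pad <- 2 * spacing
  lo <- c(min(u) - pad, min(v) - pad, min(dd) - pad)
  hi <- c(max(u) + pad, max(v) + pad, max(dd) + pad)
  n <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  list(frame = frame, spacing = spacing, lo = lo, n = n)
}

# world positions (n x 3) of all BEV voxel centres
bev_centers_patient <- function(spec) {
  f <- spec$frame
  ax <- lapply(1:3, function(a) spec$lo[a] + (seq_len(spec$n[a]) - 1) * spec$spacing)
  uu <- rep(ax[[1]], times = spec$n[2] * spec$n[3])
  vv <- rep(rep(ax[[2]], each = spec$n[1]), times = spec$n[3])
  dd <- rep(ax[[3]], each = spec$n[1] * spec$n[2])
  cbind(f$iso[1] + uu * f$e_u[1] + vv * f$e_v[1] + dd * f$t[1],
        f$iso[2] + uu * f$e_u[2] + vv * f$e_v[2] + dd * f$t[2],
        f$iso[3] + uu * f$e_u[3] + vv * f$e_v[3] + dd * f$t[3])
}

# world points -> BEV coordinates (u, v, d) in mm
patient_to_bev <- function(spec, pts) {
  rel <- sweep(pts, 2, spec$frame$iso, `-`)
  cbind(rel %*% spec$frame$e_u, rel %*% spec$frame$e_v, rel %*% spec$frame$t)
}

# BEV mm coords -> fractional 1-based BEV indices
bev_coord_to_index <- function(spec, bev) {
  sweep(bev, 2, spec$lo, `-`) / spec$spacing + 1
}

# Radiological depth on the BEV grid from a density vector sampled at the
# BEV voxel centres: midpoint cumulative sum along the beam axis.
bev_wepl_from_density <- function(spec, rho) {
  dim(rho) <- spec$n
  nd <- spec$n[3]
  wepl <- array(0, spec$n)
  acc <- matrix(0, spec$n[1], spec$n[2])
  for (k in seq_len(nd)) {
    slab <- rho[, , k]
    wepl[, , k] <- (acc + slab / 2) * spec$spacing
    acc <- acc + slab
  }
  wepl
}

# density at BEV centres for a (possibly deformed) CT: the reference CT is
# sampled at (bev centre position + shift), where `shift` is an optional
# n x 3 displacement (pull-back composition with a phase field)
bev_density <- function(ct, spec, table, centers = NULL, shift = NULL) {
  if (is.null(centers)) centers <- bev_centers_patient(spec)
  pts <- if (is.null(shift)) centers else centers + shift
  hu <- sample_grid(ct, pts, fill = -1000, method = "linear")
  hu_to_density(hu, table)
}

#' Water-equivalent path length grid for a field
#'
#' Traces radiological depth through the CT for the given gantry angle:
#' the CT is resampled onto a beam-aligned (BEV) grid, relative stopping
#' power is approximated by physical density from the HU-density table, and
#' depth is integrated along the beam axis. The result is mapped back to the
#' patient grid.
#'
#' @param ct a `voxel_grid` of HU.
#' @param angle_deg gantry angle in degrees.
#' @param table a `hu_density_table`.
#' @param iso isocentre (world mm); grid centre by default.
#' @return a `voxel_grid` of WEPL in mm on the patient grid.
#' @export
trace_wepl <- function(ct, angle_deg, table = hu_density_table(),
                       iso = NULL) {
  if (is.null(iso)) {
    iso <- ct$origin + (grid_shape(ct) - 1) / 2 * ct$spacing
  }
  frame <- beam_frame(angle_deg, iso)
  spec <- bev_grid_spec(ct, frame)
  rho <- bev_density(ct, spec, table)
  wepl <- bev_wepl_from_density(spec, rho)
  pts <- grid_points(ct)
  bevc <- patient_to_bev(spec, pts)
  vals <- interp_trilinear_idx(wepl, bev_coord_to_index(spec, bevc), fill = 0)
  dim(vals) <- grid_shape(ct)
  voxel_grid(vals, ct$spacing, ct$origin)
}
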