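#' Default phantom configuration
#'
#' Parameters of the synthetic abdominal phantom: grid geometry, tissue
#' Hounsfield units and the geometric primitives (ellipsoids/cylinders, in
#' mm) that define the target and the organs at risk. The layout follows
#' abdominal anatomy at the pancreatic level: spinal cord posterior inside a
#' vertebral body, kidneys lateral-posterior, liver right-superior, bowel
#' anterior, CTV (pancreas) central, anterior to the vertebra.
#'
#' All organ positions scale with `fov_mm` so the same anatomy can be run at
#' reduced grid sizes. The default is a 96^3 grid at 2.5 mm (240 mm
#' field of view).
#'
#' @param n voxels per axis (scalar or length 3).
#' @param spacing_mm voxel spacing in mm (scalar or length 3).
#' @param ctv_volume_cc target CTV volume in cc.
#' @return named list of phantom parameters.
#' @export
phantom_config <- function(n = 96, spacing_mm = 2.5, ctv_volume_cc = 51.9) {
  n <- rep_len(as.integer(n), 3L)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  fov <- n * spacing_mm
  s <- fov[1] / 240 # anatomical scale factor relative to the default FOV
  list(
    n = n,
    spacing_mm = spacing_mm,
    hu = c(air = -1000, soft = 40, fat = -90, bone = 700,
           liver = 60, kidney = 30, bowel = 20, cord = 35),
    body = list(center = c(0, 0, 0), semiaxes = c(110, 92, fov[3]) * s),
    ctv = list(center = c(0, 20, 0) * s, volume_cc = ctv_volume_cc,
               aspect = c(1.35, 1.0, 0.9)),
    gtv_scale = 0.6,
    vertebra = list(center_xy = c(0, -62) * s, radius = 16 * s),
    cord = list(center_xy = c(0, -62) * s, radius = 5.5 * s),
    liver = list(center = c(-52, 18, 38) * s, semiaxes = c(44, 52, 62) * s),
    kidney_L = list(center = c(56, -34, -22) * s, semiaxes = c(20, 27, 38) * s),
    kidney_R = list(center = c(-56, -34, -22) * s, semiaxes = c(20, 27, 38) * s),
    bowel = list(center = c(12, 68, -12) * s, semiaxes = c(52, 24, 58) * s)
  )
}

#' Build the synthetic HU phantom and its structure set
#'
#' Voxelizes the configured geometric primitives into a Hounsfield-unit
#' volume and a `structure_set`. The CTV is an ellipsoid whose semi-axes are
#' solved from the requested volume at the configured aspect ratio; its
#' voxelized volume is required to be within 5% of the request. ITV and PTV
#' are initialised to the CTV (they are motion-derived; see
#' [derive_itv_ptv()]).
#'
#' @param config a list from [phantom_config()].
#' @return list with elements `ct` (a `voxel_grid` of HU) and `structures`
#'   (a `structure_set`).
#' @export
build_phantom <- function(config = phantom_config()) {
  if (any(config$spacing_mm <= 0)) stop("non-positive voxel spacing", call. = FALSE)
  g <- voxel_grid(array(config$hu[["air"]], config$n), config$spacing_mm)

  body <- ellipsoid_mask(g, config$body$center, config$body$semiaxes)
  hu <- array(config$hu[["air"]], config$n)
  hu[body] <- config$hu[["soft"]]

  # CTV ellipsoid from volume + aspect ratio: V = 4/3 pi (a1 s)(a2 s)(a3 s)
  asp <- config$ctv$aspect
  s3 <- config$ctv$volume_cc * 1000 * 3 / (4 * pi * prod(asp))
  semi <- asp * s3^(1 / 3)
  ctv <- ellipsoid_mask(g, config$ctv$center, semi)
  gtv <- ellipsoid_mask(g, config$ctv$center, semi * config$gtv_scale)

  vert <- cylinder_mask(g, config$vertebra$center_xy, config$vertebra$radius)
  cord <- cylinder_mask(g, config$cord$center_xy, config$cord$radius)
  # at coarse spacing a thin cylinder can miss every voxel centre; keep the
  # column nearest the axis so the structure never vanishes
  if (!any(cord)) {
    d <- grid_shape(g)
    ii <- which.min(abs(g$origin[1] + (seq_len(d[1]) - 1) * g$spacing[1] -
                          config$cord$center_xy[1]))
    jj <- which.min(abs(g$origin[2] + (seq_len(d[2]) - 1) * g$spacing[2] -
                          config$cord$center_xy[2]))
    cord[ii, jj, ] <- TRUE
  }
  vert <- (vert | cord) & body
  cord <- cord & body
  if (any(ctv & cord)) {
    stop("invalid phantom config: CTV overlaps the spinal cord", call. = FALSE)
  }
  liver <- ellipsoid_mask(g, config$liver$center, config$liver$semiaxes) & body
  kid_l <- ellipsoid_mask(g, config$kidney_L$center, config$kidney_L$semiaxes) & body
  kid_r <- ellipsoid_mask(g, config$kidney_R$center, config$kidney_R$semiaxes) & body
  bowel <- ellipsoid_mask(g, config$bowel$center, config$bowel$semiaxes) & body
  bowel <- bowel & !ctv

  hu[liver] <- config$hu[["liver"]]
  hu[kid_l | kid_r] <- config$hu[["kidney"]]
  hu[bowel] <- config$hu[["bowel"]]
  hu[vert] <- config$hu[["bone"]]
  hu[cord] <- config$hu[["cord"]]

  ct <- voxel_grid(hu, config$spacing_mm, g$origin)
  vol <- mask_volume_cc(ctv, config$spacing_mm)
  if (abs(vol - config$ctv$volume_cc) / config$ctv$volume_cc > 0.05) {
    stop(sprintf(
      "voxelized CTV volume %.1f cc deviates > 5%% from requested %.1f cc (grid too coarse)",
      vol, config$ctv$volume_cc), call. = FALSE)
  }
  ss <- structure_set(
    list(GTV = gtv, CTV = ctv, ITV = ctv, PTV = ctv,
         liver = liver, kidney_L = kid_l, kidney_R = kid_r,
         spinal_cord = cord, bowel = bowel),
    reference = ct
  )
  list(ct = ct, structures = ss)
}
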