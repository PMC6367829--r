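#' Voxel grid container
#'
#' A `voxel_grid` holds one scalar value per voxel of a regular 3D grid:
#' Hounsfield units for CT images, dose in % of prescription for dose grids,
#' or 0/1 for binary masks. The fixed axis order is (LR, AP, IS) — x toward
#' patient left, y toward anterior, z toward superior — with world
#' coordinates in millimetres at voxel centres. All grids of one study share
#' shape, spacing and origin.
#'
#' @param values numeric 3D array (LR, AP, IS).
#' @param spacing numeric length-3, voxel spacing in mm per axis (> 0).
#' @param origin numeric length-3, world position (mm) of voxel (1,1,1).
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(values, spacing, origin = NULL) {
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3D array (LR, AP, IS)", call. = FALSE)
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be positive and finite on all axes", call. = FALSE)
  }
  if (is.null(origin)) {
    # centre the grid on the world origin
    origin <- -(dim(values) - 1) / 2 * spacing
  }
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, spacing %s mm, range [%.6g, %.6g]\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

grid_shape <- function(g) dim(g$values)

#' Voxel volume in cubic millimetres
#' @param g a `voxel_grid`.
#' @return scalar, mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(g) prod(g$spacing)

#' World coordinates of every voxel centre
#'
#' @param g a `voxel_grid`.
#' @param subset optional logical array or integer vector of voxel indices.
#' @return n x 3 matrix of (x, y, z) positions in mm.
#' @export
grid_points <- function(g, subset = NULL) {
  d <- grid_shape(g)
  if (is.null(subset)) {
    idx <- seq_len(prod(d))
  } else if (is.logical(subset) || is.array(subset)) {
    idx <- which(as.logical(subset))
  } else {
    idx <- as.integer(subset)
  }
  ijk <- arrayInd(idx, d)
  sweep(sweep(ijk - 1, 2, g$spacing, `*`), 2, g$origin, `+`)
}

# world (mm) -> fractional 1-based voxel index, per column
world_to_index <- function(g, pts) {
  sweep(sweep(pts, 2, g$origin, `-`), 2, g$spacing, `/`) + 1
}

index_to_world <- function(g, ijk) {
  sweep(sweep(ijk - 1, 2, g$spacing, `*`), 2, g$origin, `+`)
}

# Trilinear interpolation of a 3D array at fractional 1-based indices.
# `ijk` is an n x 3 matrix; out-of-grid samples return `fill`.
interp_trilinear_idx <- function(arr, ijk, fill = 0) {
  d <- dim(arr)
  x <- ijk[, 1L]; y <- ijk[, 2L]; z <- ijk[, 3L]
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep.int(as.numeric(fill), length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  i0 <- pmin(pmax(floor(x), 1), d[1] - 1L); fx <- x - i0
  j0 <- pmin(pmax(floor(y), 1), d[2] - 1L); fy <- y - j0
  k0 <- pmin(pmax(floor(z), 1), d[3] - 1L); fz <- z - k0
  if (d[1] == 1L) { i0 <- rep.int(1, length(x)); fx <- fx * 0 }
  if (d[2] == 1L) { j0 <- rep.int(1, length(y)); fy <- fy * 0 }
  if (d[3] == 1L) { k0 <- rep.int(1, length(z)); fz <- fz * 0 }
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- (i0 - 1) + (j0 - 1) * nx + (k0 - 1) * nxy + 1
  sx <- if (d[1] > 1L) 1 else 0
  sy <- if (d[2] > 1L) nx else 0
  sz <- if (d[3] > 1L) nxy else 0
  v000 <- arr[base]
  v100 <- arr[base + sx]
  v010 <- arr[base + sy]
  v110 <- arr[base + sx + sy]
  v001 <- arr[base + sz]
  v101 <- arr[base + sx + sz]
  v011 <- arr[base + sy + sz]
  v111 <- arr[base + sx + sy + sz]
  c00 <- v000 + fx * (v100 - v000)
  c10 <- v010 + fx * (v110 - v010)
  c01 <- v001 + fx * (v101 - v001)
  c11 <- v011 + fx * (v111 - v011)
  c0 <- c00 + fy * (c10 - c00)
  c1 <- c01 + fy * (c11 - c01)
  out[inside] <- c0 + fz * (c1 - c0)
  out
}

# Nearest-neighbour sampling at fractional 1-based indices; ties at 0.5 round
# toward inclusion (round half up -> the larger index, i.e. floor(x + 0.5)).
interp_nearest_idx <- function(arr, ijk, fill = 0) {
  d <- dim(arr)
  i <- floor(ijk[, 1L] + 0.5); j <- floor(ijk[, 2L] + 0.5); k <- floor(ijk[, 3L] + 0.5)
  inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep.int(as.numeric(fill), nrow(ijk))
  lin <- (i[inside] - 1) + (j[inside] - 1) * d[1] + (k[inside] - 1) * d[1] * d[2] + 1
  out[inside] <- arr[lin]
  out
}

#' Sample a voxel grid at world positions
#'
#' @param g a `voxel_grid`.
#' @param pts n x 3 matrix of world positions (mm).
#' @param fill value for samples outside the grid.
#' @param method "linear" (trilinear) or "nearest".
#' @return numeric vector of sampled values.
#' @export
sample_grid <- function(g, pts, fill = 0, method = c("linear", "nearest")) {
  method <- match.arg(method)
  ijk <- world_to_index(g, pts)
  if (method == "linear") {
    interp_trilinear_idx(g$values, ijk, fill = fill)
  } else {
    interp_nearest_idx(g$values, ijk, fill = fill)
  }
}

stopifnot_same_grid <- function(a, b, what = "grids") {
  shape <- function(g) if (!is.null(g$values)) dim(g$values) else dim(g$u)[1:3]
  if (!identical(shape(a), shape(b)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6) {
    stop(sprintf("%s must share shape, spacing and origin", what), call. = FALSE)
  }
  invisible(TRUE)
}
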