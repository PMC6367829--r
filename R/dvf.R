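#' Deformation vector field
#'
#' Per-voxel 3-vector displacement in mm on the reference grid. The field
#' follows pull-back semantics: it maps reference (end-exhalation, EEX)
#' voxel positions to the corresponding sampling position in a breathing
#' phase, i.e. the phase image is obtained by sampling the reference image
#' at `x + u(x)` (see [warp_image()]). Phase 0 is EEX and carries a zero
#' field.
#'
#' @param u numeric 4D array `(nx, ny, nz, 3)` of displacements in mm,
#'   component order (LR, AP, IS).
#' @param spacing mm per axis.
#' @param origin world position (mm) of voxel (1,1,1); grid-centred default.
#' @return A `deformation_field` object.
#' @export
deformation_field <- function(u, spacing, origin = NULL) {
  d <- dim(u)
  if (length(d) != 4L || d[4] != 3L) {
    stop("`u` must be a (nx, ny, nz, 3) array of mm displacements", call. = FALSE)
  }
  if (any(!is.finite(u))) stop("displacements must be finite", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(origin)) origin <- -(d[1:3] - 1) / 2 * spacing
  structure(list(u = u, spacing = spacing, origin = as.numeric(origin)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x$u)
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<deformation_field> %d x %d x %d voxels, |u| max %.2f mm\n",
              d[1], d[2], d[3], max(mag)))
  invisible(x)
}

zero_field <- function(g) {
  deformation_field(array(0, c(grid_shape(g), 3)), g$spacing, g$origin)
}

# displacement matrix (n x 3) at world points, trilinear per component
sample_dvf <- function(dvf, pts) {
  ijk <- sweep(sweep(pts, 2, dvf$origin, `-`), 2, dvf$spacing, `/`) + 1
  vapply(1:3, function(c) interp_trilinear_idx(dvf$u[, , , c], ijk, fill = 0),
         numeric(nrow(pts)))
}

#' Warp an image with a deformation field
#'
#' Computes `out(x) = image(x + u(x))` by trilinear (images/dose) or
#' nearest-neighbour (masks) interpolation; samples falling outside the grid
#' take `fill` (air, -1000 HU, by default).
#'
#' @param image a `voxel_grid`.
#' @param dvf a `deformation_field` on the same grid.
#' @param fill out-of-grid fill value.
#' @param method "linear" or "nearest".
#' @return a `voxel_grid` with the warped values.
#' @export
warp_image <- function(image, dvf, fill = -1000, method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot_same_grid(image, dvf, "image and deformation field")
  d <- grid_shape(image)
  pts <- grid_points(image)
  pts <- pts + matrix(dvf$u, ncol = 3L)
  vals <- sample_grid(image, pts, fill = fill, method = method)
  dim(vals) <- d
  voxel_grid(vals, image$spacing, image$origin)
}

#' Warp a binary mask with a deformation field
#'
#' Nearest-neighbour sampling of the mask at `x + u(x)`; out-of-grid samples
#' are outside the mask.
#'
#' @param mask logical 3D array on the field's grid.
#' @param dvf a `deformation_field`.
#' @return logical array of the same shape.
#' @export
warp_mask <- function(mask, dvf) {
  g <- voxel_grid(array(as.numeric(mask), dim(mask)), dvf$spacing, dvf$origin)
  w <- warp_image(g, dvf, fill = 0, method = "nearest")
  m <- w$values > 0.5
  dim(m) <- dim(mask)
  m
}

# finite-difference gradient of a 3D array along `axis`, step h (mm);
# central differences in the interior, one-sided at the boundary slices
fd_gradient <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  g <- array(0, d)
  if (n == 1L) return(g)
  idx <- function(r) {
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ix[[axis]] <- r
    ix
  }
  `%slice%` <- function(a, ix) do.call(`[`, c(list(a), ix, list(drop = FALSE)))
  if (n > 2L) {
    interior <- idx(2:(n - 1))
    g[interior[[1]], interior[[2]], interior[[3]]] <-
      ((arr %slice% idx(3:n)) - (arr %slice% idx(1:(n - 2)))) / (2 * h)
  }
  first <- idx(1L); second <- idx(2L); last <- idx(n); prev <- idx(n - 1L)
  g[first[[1]], first[[2]], first[[3]]] <-
    ((arr %slice% second) - (arr %slice% first)) / h
  g[last[[1]], last[[2]], last[[3]]] <-
    ((arr %slice% last) - (arr %slice% prev)) / h
  g
}

#' Jacobian determinant map of a deformation field
#'
#' Per-voxel determinant of `I + grad(u)` with displacement gradients taken
#' by finite differences in physical mm (central in the interior, one-sided
#' at grid boundaries). Values of 1 indicate local volume preservation;
#' values <= 0 indicate folding.
#'
#' @param dvf a `deformation_field`.
#' @return a `voxel_grid` of Jacobian determinants.
#' @export
jacobian_determinant_map <- function(dvf) {
  J <- vector("list", 9)
  for (c in 1:3) {
    for (a in 1:3) {
      J[[(c - 1) * 3 + a]] <- fd_gradient(dvf$u[, , , c], a, dvf$spacing[a])
    }
  }
  # rows: displacement component, cols: derivative axis; F = I + J
  f11 <- 1 + J[[1]]; f12 <- J[[2]]; f13 <- J[[3]]
  f21 <- J[[4]]; f22 <- 1 + J[[5]]; f23 <- J[[6]]
  f31 <- J[[7]]; f32 <- J[[8]]; f33 <- 1 + J[[9]]
  det <- f11 * (f22 * f33 - f23 * f32) -
    f12 * (f21 * f33 - f23 * f31) +
    f13 * (f21 * f32 - f22 * f31)
  voxel_grid(det, dvf$spacing, dvf$origin)
}
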