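#' Structure set
#'
#' Named binary masks on the reference grid: nested target volumes
#' (GTV ⊆ CTV ⊆ ITV ⊆ PTV) and organs at risk (liver, kidney_L, kidney_R,
#' spinal_cord, bowel). Masks are logical arrays with the reference grid's
#' shape.
#'
#' @param masks named list of logical 3D arrays.
#' @param reference the reference `voxel_grid` (for shape/spacing checks).
#' @param require_all if TRUE, demand the full standard structure list.
#' @return A `structure_set` object (named list of logical arrays with
#'   spacing/origin attributes).
#' @export
structure_set <- function(masks, reference, require_all = TRUE) {
  standard <- c("GTV", "CTV", "ITV", "PTV",
                "liver", "kidney_L", "kidney_R", "spinal_cord", "bowel")
  if (require_all && !all(standard %in% names(masks))) {
    stop("structure set is missing: ",
         paste(setdiff(standard, names(masks)), collapse = ", "), call. = FALSE)
  }
  d <- grid_shape(reference)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), d)) {
      stop(sprintf("mask '%s' does not match the reference grid shape", nm),
           call. = FALSE)
    }
    if (!any(m)) stop(sprintf("mask '%s' is empty", nm), call. = FALSE)
    masks[[nm]] <- as.logical(m)
    dim(masks[[nm]]) <- d
  }
  check_nesting <- function(inner, outer) {
    if (all(c(inner, outer) %in% names(masks)) &&
        any(masks[[inner]] & !masks[[outer]])) {
      stop(sprintf("nesting violated: %s must lie inside %s", inner, outer),
           call. = FALSE)
    }
  }
  check_nesting("GTV", "CTV"); check_nesting("CTV", "ITV"); check_nesting("ITV", "PTV")
  structure(masks,
            spacing = reference$spacing, origin = reference$origin,
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  vol <- vapply(x, sum, numeric(1)) * prod(attr(x, "spacing")) / 1000
  cat("<structure_set>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %8.1f cc\n", nm, vol[[nm]]))
  invisible(x)
}

#' Structure volumes as a tibble
#' @param ss a `structure_set`.
#' @return tibble with columns `structure`, `n_voxels`, `volume_cc`.
#' @export
structure_volumes <- function(ss) {
  vv <- prod(attr(ss, "spacing"))
  tibble::tibble(
    structure = names(ss),
    n_voxels = vapply(ss, function(m) sum(m), numeric(1)),
    volume_cc = vapply(ss, function(m) sum(m) * vv / 1000, numeric(1))
  )
}

#' Volume of a binary mask in cc
#' @param mask logical array.
#' @param spacing mm per axis.
#' @return scalar volume in cubic centimetres.
#' @export
mask_volume_cc <- function(mask, spacing) sum(mask) * prod(spacing) / 1000

# centroid (world mm) of a mask on grid g
mask_centroid <- function(g, mask) {
  colMeans(grid_points(g, mask))
}

# Ellipsoid mask: centre (mm world), semi-axes (mm)
ellipsoid_mask <- function(g, center, semiaxes) {
  d <- grid_shape(g)
  ax <- lapply(1:3, function(a) {
    ((g$origin[a] + (seq_len(d[a]) - 1) * g$spacing[a]) - center[a]) / semiaxes[a]
  })
  X2 <- ax[[1]]^2
  Y2 <- ax[[2]]^2
  Z2 <- ax[[3]]^2
  m <- outer(outer(X2, Y2, `+`), Z2, `+`) <= 1
  dim(m) <- d
  m
}

# Cylinder along IS: centre (x, y) in mm, radius mm, z range (mm, world)
cylinder_mask <- function(g, center_xy, radius, z_range = c(-Inf, Inf)) {
  d <- grid_shape(g)
  x <- g$origin[1] + (seq_len(d[1]) - 1) * g$spacing[1] - center_xy[1]
  y <- g$origin[2] + (seq_len(d[2]) - 1) * g$spacing[2] - center_xy[2]
  z <- g$origin[3] + (seq_len(d[3]) - 1) * g$spacing[3]
  axial <- outer(x^2, y^2, `+`) <= radius^2
  inz <- z >= z_range[1] & z <= z_range[2]
  m <- array(FALSE, d)
  m[, , inz] <- axial
  m
}

#' Dilate a binary mask isotropically by a margin in millimetres
#'
#' Uses a Euclidean ball structuring element defined in mm (not voxels), so
#' anisotropic spacing is handled correctly.
#'
#' @param mask logical 3D array.
#' @param spacing mm per axis.
#' @param margin_mm isotropic margin in mm (0 returns the mask unchanged).
#' @return logical array of the same shape.
#' @export
dilate_mask_mm <- function(mask, spacing, margin_mm) {
  if (margin_mm <= 0) return(mask)
  d <- dim(mask)
  r <- floor(margin_mm / spacing)
  off <- expand.grid(
    i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3]
  )
  dist2 <- (off$i * spacing[1])^2 + (off$j * spacing[2])^2 + (off$k * spacing[3])^2
  off <- off[dist2 <= margin_mm^2, , drop = FALSE]
  out <- array(FALSE, d)
  for (n in seq_len(nrow(off))) {
    i <- off$i[n]; j <- off$j[n]; k <- off$k[n]
    src_i <- max(1, 1 - i):min(d[1], d[1] - i)
    src_j <- max(1, 1 - j):min(d[2], d[2] - j)
    src_k <- max(1, 1 - k):min(d[3], d[3] - k)
    out[src_i + i, src_j + j, src_k + k] <-
      out[src_i + i, src_j + j, src_k + k] | mask[src_i, src_j, src_k]
  }
  out
}
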