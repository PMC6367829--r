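#' Generic HU-to-density lookup table
#'
#' Piecewise-linear map from Hounsfield units to physical density in g/cm^3,
#' used both by the deformation QA (mass estimates) and by the dose engine
#' (density as a surrogate for relative stopping power). The default nodes
#' are a generic abdominal calibration: (-1000, 0.001), (-100, 0.93),
#' (0, 1.0), (100, 1.09), (1000, 1.6); HU outside the node range clamp to
#' the end densities.
#'
#' @param nodes two-column matrix or data frame `(hu, density)` with
#'   non-decreasing density.
#' @return a `hu_density_table` object.
#' @export
hu_density_table <- function(nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- data.frame(
      hu = c(-1000, -100, 0, 100, 1000),
      density = c(0.001, 0.93, 1.0, 1.09, 1.6)
    )
  }
  nodes <- as.data.frame(nodes)
  names(nodes) <- c("hu", "density")
  if (is.unsorted(nodes$hu, strictly = TRUE)) {
    stop("HU nodes must be strictly increasing", call. = FALSE)
  }
  if (is.unsorted(nodes$density)) {
    stop("density must be monotonically non-decreasing in HU", call. = FALSE)
  }
  structure(list(nodes = nodes), class = "hu_density_table")
}

#' Convert HU values to density
#' @param hu numeric vector or array of Hounsfield units.
#' @param table a `hu_density_table`.
#' @return densities in g/cm^3, same shape as `hu`.
#' @export
hu_to_density <- function(hu, table = hu_density_table()) {
  d <- dim(hu)
  rho <- stats::approx(table$nodes$hu, table$nodes$density, xout = as.numeric(hu),
                       rule = 2)$y
  if (!is.null(d)) dim(rho) <- d
  rho
}

#' Mass-conservation ratio of a warp
#'
#' Estimates how well a deformation conserves the mass of a delineated organ
#' when the image is warped by pure intensity resampling. The reference mass
#' is `m_EEX = sum over the mask of voxel_volume * rho(HU_EEX)`; the
#' end-inhalation mass `m_EIN` sums `voxel_volume * rho(HU_EIN)` over the
#' delineation warped from EEX to EIN (nearest-neighbour), with `HU_EIN` the
#' warped image. A ratio of 1 indicates conserved mass; intensity warping
#' with a non-unit Jacobian generally does not conserve it.
#'
#' @param ct_eex reference CT (`voxel_grid`, HU).
#' @param dvf the EEX-to-EIN `deformation_field`.
#' @param mask logical organ mask on the reference grid (non-empty).
#' @param table a `hu_density_table`.
#' @return list with `ratio` (m_EEX/m_EIN), `m_eex_g`, `m_ein_g`,
#'   `v_eex_cc`, `v_ein_cc`.
#' @export
mass_conservation_ratio <- function(ct_eex, dvf, mask, table = hu_density_table()) {
  if (!any(mask)) stop("organ mask is empty", call. = FALSE)
  vv_cc <- prod(ct_eex$spacing) / 1000 # mm^3 -> cm^3
  rho_eex <- hu_to_density(ct_eex$values[mask], table)
  m_eex <- sum(rho_eex) * vv_cc
  mask_ein <- warp_mask(mask, dvf)
  if (!any(mask_ein)) stop("warped mask is empty", call. = FALSE)
  ct_ein <- warp_image(ct_eex, dvf, fill = -1000, method = "linear")
  rho_ein <- hu_to_density(ct_ein$values[mask_ein], table)
  m_ein <- sum(rho_ein) * vv_cc
  list(ratio = m_eex / m_ein,
       m_eex_g = m_eex, m_ein_g = m_ein,
       v_eex_cc = sum(mask) * vv_cc, v_ein_cc = sum(mask_ein) * vv_cc)
}

#' Deformation-field QA report
#'
#' For every motion input of a scenario and every QA organ (liver, both
#' kidneys, bowel), evaluates the Jacobian determinant map of the
#' EEX-to-EIN field inside the organ delineation (mean, SD, folding count)
#' and the mass-conservation ratio `m_EEX / m_EIN`.
#'
#' @param scenario a `patient_scenario`.
#' @param organs character vector of structure names to QA.
#' @param table a `hu_density_table`.
#' @return tibble with columns `motion`, `organ`, `mean_jacobian`,
#'   `sd_jacobian`, `n_folding`, `mass_ratio`, `v_eex_cc`, `v_ein_cc`.
#' @export
qa_report <- function(scenario,
                      organs = c("liver", "kidney_L", "kidney_R", "bowel"),
                      table = hu_density_table()) {
  organs <- intersect(organs, names(scenario$structures))
  purrr::map_dfr(scenario$motions, function(m) {
    dvf <- phase_field(m, ein_phase(m))
    jmap <- jacobian_determinant_map(dvf)$values
    purrr::map_dfr(organs, function(org) {
      msk <- scenario$structures[[org]]
      jv <- jmap[msk]
      mc <- mass_conservation_ratio(scenario$ct, dvf, msk, table)
      tibble::tibble(
        motion = m$id, organ = org,
        mean_jacobian = mean(jv), sd_jacobian = stats::sd(jv),
        n_folding = sum(jv <= 0),
        mass_ratio = mc$ratio, v_eex_cc = mc$v_eex_cc, v_ein_cc = mc$v_ein_cc
      )
    })
  })
}
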