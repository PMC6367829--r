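#' Parameterized PBS machine model
#'
#' A self-contained stand-in for a scanned-proton gantry: a power-law
#' range-energy relation `R[cm] = alpha * E^p`, a linear lateral-sigma
#' model `sigma(wepl) = sigma0 + k * wepl`, an analytic Bragg depth-dose
#' shape, and delivery dynamics (spot dwell per unit weight, lateral move
#' time, energy-layer switch time). The timing constants are of the same
#' order as clinical scanned gantries so that the spill structure interacts
#' with 2.8-10 s breathing periods.
#'
#' @param energy_range_mev deliverable energy interval (MeV).
#' @param range_alpha,range_p power-law range-energy fit (`R[cm] = alpha E^p`).
#' @param sigma0_mm lateral spot sigma at the surface (mm).
#' @param sigma_k lateral sigma growth per mm of radiological depth.
#' @param plateau entrance plateau level relative to the Bragg peak.
#' @param straggling_frac Bragg-peak Gaussian width as a fraction of range.
#' @param spot_spacing_mm lateral spot grid spacing (mm).
#' @param layer_spacing_mm energy-layer spacing in mm WEPL.
#' @param dwell_s_typical typical spot dwell time (s); the per-weight dose
#'   rate is calibrated so the mean spot dwell of a field equals this.
#' @param move_s lateral magnet move time between consecutive spots (s).
#' @param layer_switch_s energy-layer switch time (s).
#' @return a `machine_model` object.
#' @export
machine_model <- function(energy_range_mev = c(70, 230),
                          range_alpha = 0.0022, range_p = 1.77,
                          sigma0_mm = 3, sigma_k = 0.025,
                          plateau = 0.32, straggling_frac = 0.025,
                          spot_spacing_mm = 5, layer_spacing_mm = 5,
                          dwell_s_typical = 0.005, move_s = 0.003,
                          layer_switch_s = 1.0) {
  stopifnot(dwell_s_typical > 0, move_s > 0, layer_switch_s > 0,
            range_alpha > 0, range_p > 0)
  structure(
    list(energy_range_mev = energy_range_mev,
         range_alpha = range_alpha, range_p = range_p,
         sigma0_mm = sigma0_mm, sigma_k = sigma_k,
         plateau = plateau, straggling_frac = straggling_frac,
         spot_spacing_mm = spot_spacing_mm, layer_spacing_mm = layer_spacing_mm,
         dwell_s_typical = dwell_s_typical, move_s = move_s,
         layer_switch_s = layer_switch_s),
    class = "machine_model"
  )
}

#' Proton range in water from beam energy
#' @param energy_mev beam energy (MeV).
#' @param machine a `machine_model`.
#' @return range in mm WEPL.
#' @export
proton_range_mm <- function(energy_mev, machine = machine_model()) {
  10 * machine$range_alpha * energy_mev^machine$range_p
}

#' Beam energy for a requested range
#' @param range_mm range in mm WEPL.
#' @param machine a `machine_model`.
#' @return energy in MeV (unclamped; see [machine_model()] for limits).
#' @export
energy_for_range <- function(range_mm, machine = machine_model()) {
  (range_mm / 10 / machine$range_alpha)^(1 / machine$range_p)
}

#' Analytic Bragg depth-dose curve
#'
#' Relative depth dose of a single pencil beam as a function of radiological
#' depth: a flat entrance plateau plus a Gaussian-capped Bragg peak at the
#' range `R(E)`, a steeper Gaussian distal falloff, and exactly zero beyond
#' the distal tail. Normalized to 1 at the peak.
#'
#' @param energy_mev beam energy (MeV).
#' @param wepl_mm radiological depth(s) in mm (vector or array).
#' @param machine a `machine_model`.
#' @return relative dose, same shape as `wepl_mm`.
#' @export
bragg_depth_dose <- function(energy_mev, wepl_mm, machine = machine_model()) {
  R <- proton_range_mm(energy_mev, machine)
  sig_p <- pmax(1, machine$straggling_frac * R)
  sig_d <- 0.35 * sig_p + 0.7
  z <- wepl_mm
  p <- machine$plateau
  dose <- ifelse(
    z <= R,
    p + (1 - p) * exp(-0.5 * ((z - R) / sig_p)^2),
    exp(-0.5 * ((z - R) / sig_d)^2)
  )
  dose[z > R + 4 * sig_d] <- 0
  dose[z < 0] <- 0
  dose
}

#' Lateral spot sigma at radiological depth
#' @param wepl_mm radiological depth (mm).
#' @param machine a `machine_model`.
#' @return sigma in mm.
#' @export
lateral_sigma_mm <- function(wepl_mm, machine = machine_model()) {
  machine$sigma0_mm + machine$sigma_k * wepl_mm
}
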