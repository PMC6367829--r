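#' Breathing motion input (one "measurement")
#'
#' One motion input corresponds to one repeated 4D acquisition: a breathing
#' period `T` and 20 per-phase deformation fields with respect to the
#' end-exhalation reference (phase 0, zero field). The generated fields are
#' separable, `u_j(x) = s_j * U(x)`, the product of a smooth spatial
#' displacement field `U` (the end-inhalation field) and a periodic temporal
#' factor `s_j` sampled at 20 uniform time points of one cycle, with
#' `s_0 = 0`.
#'
#' @param spatial a `deformation_field`: the peak (EIN) displacement field.
#' @param temporal numeric length `n_phases`, the per-phase scaling; the
#'   first entry must be 0 (EEX) and the maximum defines EIN.
#' @param period_s breathing period in seconds, in `[2.8, 10]`.
#' @param id label (the study's m1, m2, ...).
#' @param provenance "measured" for an independently generated pattern,
#'   "period-rescaled" for a copy that only changes the period.
#' @return a `motion_input` object.
#' @export
motion_input <- function(spatial, temporal, period_s, id = "m1",
                         provenance = c("measured", "period-rescaled")) {
  provenance <- match.arg(provenance)
  if (period_s < 2.8 || period_s > 10) {
    stop("breathing period must lie in [2.8, 10] s", call. = FALSE)
  }
  if (abs(temporal[1]) > 1e-12) {
    stop("phase 0 is the EEX reference and must have zero displacement",
         call. = FALSE)
  }
  structure(
    list(spatial = spatial, temporal = as.numeric(temporal),
         period_s = period_s, id = id, provenance = provenance),
    class = "motion_input"
  )
}

#' @export
print.motion_input <- function(x, ...) {
  cat(sprintf("<motion_input> %s: T = %.1f s, %d phases, EIN phase %d (%s)\n",
              x$id, x$period_s, n_phases(x), ein_phase(x), x$provenance))
  invisible(x)
}

#' Number of breathing phases of a motion input
#' @param m a `motion_input`.
#' @return integer phase count (20 by default).
#' @export
n_phases <- function(m) length(m$temporal)

#' End-inhalation phase index
#'
#' EIN is the phase with maximal CTV-centroid displacement; for separable
#' fields this is the phase with the largest |temporal factor|.
#'
#' @param m a `motion_input`.
#' @return integer phase index in `0..(n_phases-1)`.
#' @export
ein_phase <- function(m) which.max(abs(m$temporal)) - 1L

#' Deformation field of one breathing phase
#' @param m a `motion_input`.
#' @param phase phase index in `0..(n_phases-1)`; 0 is EEX.
#' @return a `deformation_field`.
#' @export
phase_field <- function(m, phase) {
  stopifnot(phase >= 0, phase < n_phases(m))
  s <- m$temporal[phase + 1L]
  deformation_field(m$spatial$u * s, m$spatial$spacing, m$spatial$origin)
}

# smoothstep ramp: 0 below a, 1 above b
smoothstep <- function(t, a, b) {
  s <- pmin(pmax((t - a) / (b - a), 0), 1)
  s * s * (3 - 2 * s)
}

# Smooth spatial envelope: ~1 around the CTV, falling to 0 toward the
# posterior (spine) and toward every grid face. Returned as a 3D array.
motion_envelope <- function(g, taper_mm = c(35, 30, 45), posterior_ramp = NULL) {
  d <- grid_shape(g)
  ax <- lapply(1:3, function(a) g$origin[a] + (seq_len(d[a]) - 1) * g$spacing[a])
  lo <- g$origin
  hi <- g$origin + (d - 1) * g$spacing
  ramp <- function(x, a, m) smoothstep(x, lo[a], lo[a] + m) *
    smoothstep(-x, -hi[a], -hi[a] + m)
  wx <- ramp(ax[[1]], 1, taper_mm[1])
  wz <- ramp(ax[[3]], 3, taper_mm[3])
  if (is.null(posterior_ramp)) {
    ext <- hi[2] - lo[2]
    posterior_ramp <- c(lo[2] + 0.18 * ext, lo[2] + 0.45 * ext)
  }
  wy <- smoothstep(ax[[2]], posterior_ramp[1], posterior_ramp[2]) *
    smoothstep(-ax[[2]], -hi[2], -hi[2] + taper_mm[2])
  env <- outer(outer(wx, wy), wz)
  dim(env) <- d
  env
}

#' Generate a synthetic breathing motion input
#'
#' Builds 20-phase periodic deformation fields as a smooth spatial envelope
#' (maximal near the target, vanishing at the posterior spine region and at
#' the grid boundary) times a periodic temporal factor, scaled so that the
#' CTV-centroid displacement between end-exhalation and end-inhalation
#' equals the requested per-axis amplitudes. The default temporal waveform
#' is `sin^2(pi * j / n_phases)` (regular breathing; EEX at phase 0, EIN at
#' phase `n_phases/2`).
#'
#' An optional seeded jitter perturbs the per-phase temporal factors
#' multiplicatively (EEX stays exactly zero) to emulate mild cycle-shape
#' variation between measurements.
#'
#' @param reference the reference `voxel_grid`.
#' @param ctv CTV mask (logical array) used to anchor the amplitude.
#' @param amplitude_mm length-3 numeric `(LR, AP, IS)` peak CTV-centroid
#'   displacement in mm (non-negative; signs follow the axis convention:
#'   superior, anterior, left positive).
#' @param period_s breathing period in seconds, `[2.8, 10]`.
#' @param n_phases number of uniform-time phases per cycle (default 20).
#' @param waveform function of phase index vector `j` returning temporal
#'   factors in `[0, 1]`; default `sin^2(pi j / n)`.
#' @param envelope "body" (default smooth envelope) or "rigid" (uniform
#'   translation, useful for validation).
#' @param jitter_sd relative SD of seeded temporal jitter (default 0).
#' @param seed integer seed for the jitter (ignored when `jitter_sd = 0`).
#' @param id label for the motion input.
#' @return a `motion_input`; errors if the requested amplitude would fold
#'   the fields (non-positive Jacobian determinant).
#' @export
generate_motion_input <- function(reference, ctv, amplitude_mm, period_s,
                                  n_phases = 20L,
                                  waveform = function(j) sin(pi * j / n_phases)^2,
                                  envelope = c("body", "rigid"),
                                  jitter_sd = 0, seed = 1L, id = "m1") {
  envelope <- match.arg(envelope)
  amplitude_mm <- rep_len(as.numeric(amplitude_mm), 3L)
  if (any(amplitude_mm < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  d <- grid_shape(reference)
  if (envelope == "rigid") {
    env <- array(1, d)
  } else {
    env <- motion_envelope(reference)
    cen <- mask_centroid(reference, ctv)
    e0 <- interp_trilinear_idx(env, world_to_index(reference, rbind(cen)), fill = 0)
    if (e0 < 0.05) {
      stop("CTV centroid lies outside the motion envelope support", call. = FALSE)
    }
    env <- env / e0 # unit envelope at the CTV centroid
  }
  u <- array(0, c(d, 3))
  for (c in 1:3) if (amplitude_mm[c] != 0) u[, , , c] <- env * amplitude_mm[c]
  spatial <- deformation_field(u, reference$spacing, reference$origin)

  s <- waveform(seq_len(n_phases) - 1)
  if (jitter_sd > 0) {
    rng <- local_rng(seed)
    jit <- 1 + stats::rnorm(n_phases, sd = jitter_sd, mean = 0)
    s <- s * jit
    s[1] <- 0
    on.exit(restore_rng(rng), add = TRUE)
  }
  s[1] <- 0
  m <- motion_input(spatial, s, period_s, id = id, provenance = "measured")

  if (any(amplitude_mm > 0)) {
    jmin <- min_jacobian_separable(spatial, max(abs(s)))
    if (jmin <= 0) {
      stop(sprintf(
        paste0("requested amplitude (%s mm) folds the deformation field ",
               "(min Jacobian determinant %.3f <= 0); reduce the amplitude ",
               "or enlarge the grid/envelope"),
        paste(amplitude_mm, collapse = ", "), jmin), call. = FALSE)
    }
  }
  m
}

# minimum det(I + s * grad(U)) over the grid for the worst-case |s|
min_jacobian_separable <- function(spatial, s_max) {
  scaled <- deformation_field(spatial$u * s_max, spatial$spacing, spatial$origin)
  min(jacobian_determinant_map(scaled)$values)
}

# seed-scoped RNG helpers: save/restore the global stream
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Change the breathing period of a motion input
#'
#' Returns a copy with the same displacement fields and a new period — day-
#' to-day variation of the breathing cycle is emulated by varying the period
#' alone, leaving amplitudes untouched.
#'
#' @param m a `motion_input`.
#' @param new_period_s new breathing period in seconds, `[2.8, 10]`.
#' @param id label for the rescaled copy (default `"<id> (T=...)"`).
#' @return a `motion_input` flagged as period-rescaled.
#' @export
rescale_period <- function(m, new_period_s, id = NULL) {
  if (new_period_s < 2.8 || new_period_s > 10) {
    stop("breathing period must lie in [2.8, 10] s", call. = FALSE)
  }
  if (is.null(id)) id <- sprintf("%s (T=%.1f)", sub(" \\(T=.*\\)$", "", m$id), new_period_s)
  out <- m
  out$period_s <- new_period_s
  out$id <- id
  out$provenance <- "period-rescaled"
  out
}

#' Derive ITV and PTV masks from CTV motion
#'
#' The ITV is the union over all breathing phases of the CTV mask warped to
#' each phase (all phases live on the shared reference grid); the PTV adds
#' an isotropic margin (5 mm default) as a Euclidean ball in mm.
#'
#' @param ctv logical CTV mask.
#' @param motion a `motion_input` or list of them (union over all).
#' @param margin_mm isotropic ITV-to-PTV margin in mm.
#' @param spacing mm per axis (taken from the motion input if omitted).
#' @return list with logical masks `itv` and `ptv`.
#' @export
derive_itv_ptv <- function(ctv, motion, margin_mm = 5, spacing = NULL) {
  if (!any(ctv)) stop("CTV mask is empty", call. = FALSE)
  motions <- if (inherits(motion, "motion_input")) list(motion) else motion
  if (is.null(spacing)) spacing <- motions[[1]]$spatial$spacing
  itv <- ctv
  for (m in motions) {
    for (j in seq_len(n_phases(m)) - 1L) {
      if (abs(m$temporal[j + 1L]) < 1e-12) next
      itv <- itv | warp_mask(ctv, phase_field(m, j))
    }
  }
  ptv <- dilate_mask_mm(itv, spacing, margin_mm)
  list(itv = itv, ptv = ptv)
}

#' Assemble a patient scenario
#'
#' Bundles the reference CT, the structure set (with motion-derived ITV and
#' PTV), the available motion inputs, the prescription and the two field
#' gantry angles. The ITV is derived from the first motion input (the
#' "planning" acquisition), mirroring clinical practice where later repeated
#' measurements do not reshape the target volumes.
#'
#' @param ct reference `voxel_grid` (HU).
#' @param structures `structure_set` with at least GTV/CTV and the OARs.
#' @param motions list of `motion_input` objects (>= 1).
#' @param angles_deg two gantry angles in degrees, `[0, 360)`.
#' @param fraction_dose_gy prescription per fraction in Gy(RBE).
#' @param n_fractions planned number of fractions.
#' @param rbe relative biological effectiveness factor.
#' @param ptv_margin_mm ITV-to-PTV margin in mm.
#' @param itv_from "first" (default) or "all" motion inputs.
#' @return a `patient_scenario` object.
#' @export
patient_scenario <- function(ct, structures, motions,
                             angles_deg = c(160, 210),
                             fraction_dose_gy = 1.8, n_fractions = 28,
                             rbe = 1.1, ptv_margin_mm = 5,
                             itv_from = c("first", "all")) {
  itv_from <- match.arg(itv_from)
  if (inherits(motions, "motion_input")) motions <- list(motions)
  if (length(motions) < 1) stop("at least one motion input is required", call. = FALSE)
  if (any(angles_deg < 0 | angles_deg >= 360) || length(angles_deg) != 2) {
    stop("two gantry angles in [0, 360) are required", call. = FALSE)
  }
  src <- if (itv_from == "first") motions[[1]] else motions
  tv <- derive_itv_ptv(structures$CTV, src, margin_mm = ptv_margin_mm,
                       spacing = ct$spacing)
  masks <- unclass(structures)
  masks$ITV <- tv$itv
  masks$PTV <- tv$ptv
  structures <- structure_set(masks, reference = ct)
  structure(
    list(ct = ct, structures = structures, motions = motions,
         angles_deg = as.numeric(angles_deg),
         prescription = list(fraction_dose_gy = fraction_dose_gy,
                             n_fractions = n_fractions, rbe = rbe)),
    class = "patient_scenario"
  )
}

#' @export
print.patient_scenario <- function(x, ...) {
  cat(sprintf(
    "<patient_scenario> %d motion input(s), fields %g/%g deg, %g Gy(RBE) x %d\n",
    length(x$motions), x$angles_deg[1], x$angles_deg[2],
    x$prescription$fraction_dose_gy, x$prescription$n_fractions))
  invisible(x)
}

#' Zero-motion input (static limit)
#' @param reference the reference `voxel_grid`.
#' @param period_s breathing period (still required for the time structure).
#' @param n_phases phases per cycle.
#' @return a `motion_input` whose 20 fields are identically zero.
#' @export
zero_motion <- function(reference, period_s = 4, n_phases = 20L) {
  motion_input(zero_field(reference), rep(0, n_phases), period_s, id = "static")
}
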