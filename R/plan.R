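#' @keywords internal
# Place spots on a regular BEV lateral grid + WEPL energy layers so that
# every PTV point is geometrically covered. `bev_pts` (n x 3, u/v/d) and
# `wepl_pts` are the PTV voxel samples in this field's BEV frame.
place_spots_field <- function(bev_pts, wepl_pts, machine) {
  sp <- machine$spot_spacing_mm
  ls <- machine$layer_spacing_mm
  u <- bev_pts[, 1]; v <- bev_pts[, 2]
  u_seq <- seq(floor(min(u) / sp) * sp - sp, max(u) + sp, by = sp)
  v_seq <- seq(floor(min(v) / sp) * sp - sp, max(v) + sp, by = sp)
  wmin <- min(wepl_pts); wmax <- max(wepl_pts)
  r_seq <- seq(wmin, wmax, by = ls)
  if (wmax - r_seq[length(r_seq)] > ls / 2) r_seq <- c(r_seq, wmax)
  spots <- vector("list", length(u_seq) * length(v_seq))
  n <- 0L
  for (u0 in u_seq) {
    for (v0 in v_seq) {
      near <- abs(u - u0) <= sp & abs(v - v0) <= sp
      if (!any(near)) next
      wr <- range(wepl_pts[near])
      keep <- r_seq >= wr[1] - ls / 2 & r_seq <= wr[2] + ls / 2
      if (!any(keep)) next
      n <- n + 1L
      spots[[n]] <- tibble::tibble(u = u0, v = v0, range_mm = r_seq[keep])
    }
  }
  if (n == 0L) stop("no spots cover the PTV", call. = FALSE)
  dplyr::bind_rows(spots[seq_len(n)])
}

# dose-influence matrix: rows = target points (u, v, wepl), cols = spots.
# Spots are grouped by energy layer (one Bragg evaluation per layer) and the
# lateral Gaussian is evaluated only inside a truncation box.
spot_influence <- function(pts_u, pts_v, pts_wepl, spots, machine,
                           trunc_sigma = 3.5) {
  sig <- lateral_sigma_mm(pts_wepl, machine)
  two_s2 <- 2 * sig^2
  norm <- 1 / (pi * two_s2)
  A <- matrix(0, length(pts_u), nrow(spots))
  half_max <- trunc_sigma * max(sig)
  for (E in unique(spots$energy_mev)) {
    cols <- which(spots$energy_mev == E)
    dd <- bragg_depth_dose(E, pts_wepl, machine) * norm
    nz <- which(dd > 0)
    if (length(nz) == 0) next
    for (s in cols) {
      du <- pts_u[nz] - spots$u[s]
      inb <- which(abs(du) <= half_max)
      if (length(inb) == 0) next
      dv <- pts_v[nz[inb]] - spots$v[s]
      inb <- inb[abs(dv) <= half_max]
      if (length(inb) == 0) next
      rows <- nz[inb]
      r2 <- (pts_u[rows] - spots$u[s])^2 + (pts_v[rows] - spots$v[s])^2
      A[rows, s] <- dd[rows] * exp(-r2 / two_s2[rows])
    }
  }
  A
}

# Non-negative least-squares spot-weight optimization by accelerated
# projected gradient (FISTA); stops at relative residual < tol, stalled
# progress, or `max_iter` iterations.
optimize_weights <- function(A, target, max_iter = 500, tol = 1e-4) {
  # largest squared singular value by power iteration on t(A) %*% A
  v <- rep(1 / sqrt(ncol(A)), ncol(A))
  for (it in 1:25) {
    v <- crossprod(A, A %*% v)
    v <- v / sqrt(sum(v^2))
  }
  L <- as.numeric(crossprod(A %*% v)) # Rayleigh quotient, |v| = 1
  x <- y <- rep(0, ncol(A))
  tk <- 1
  nt <- sqrt(sum(target^2))
  res_prev <- Inf
  for (it in seq_len(max_iter)) {
    r <- A %*% y - target
    g <- crossprod(A, r)
    xn <- pmax(0, y - as.numeric(g) / L)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- xn + (tk - 1) / tn * (xn - x)
    x <- xn
    tk <- tn
    if (it %% 25 == 0) {
      res <- sqrt(sum((A %*% x - target)^2)) / nt
      if (res < tol || abs(res_prev - res) < 1e-4 * res_prev) break
      res_prev <- res
    }
  }
  as.numeric(x)
}

#' Create an SFUD spot plan for a scenario
#'
#' Builds a two-field single-field-uniform-dose plan on the static reference
#' CT: per field, spots are placed on a regular lateral grid (default 5 mm)
#' and WEPL-spaced energy layers (default 5 mm) covering the PTV, and spot
#' weights are optimized by non-negative multiplicative updates so that each
#' field alone delivers a uniform half-prescription to the PTV. The plan is
#' calibrated so the static CTV median dose is 100% of prescription, and
#' delivery timestamps are attached (see [delivery_timeline()]).
#'
#' @param scenario a `patient_scenario`.
#' @param machine a `machine_model`.
#' @param n_opt_points maximum number of target sample points for the weight
#'   optimization (deterministic stride subsample).
#' @param opt_margin_mm extra isotropic margin around the PTV for spot
#'   placement and optimization, so the lateral/distal falloff starts
#'   outside the PTV rather than eroding its edge dose.
#' @param edge_boost relative target boost for optimization points in the
#'   shell outside the PTV (edge enhancement): a least-squares fit to a flat
#'   target lets the field edge sag; a few percent of shell boost keeps the
#'   PTV-edge dose at prescription.
#' @param max_iter,tol optimizer controls.
#' @return a `spot_plan`: fields (angle, isocentre, BEV spec), a spot tibble
#'   (`field`, `layer`, `energy_mev`, `u`, `v`, `weight`, `timestamp_s`),
#'   the machine model and the dose calibration.
#' @export
plan_sfud <- function(scenario, machine = machine_model(),
                      n_opt_points = 2500, opt_margin_mm = 8,
                      edge_boost = 1.03, max_iter = 1000, tol = 1e-4) {
  ct <- scenario$ct
  ptv0 <- scenario$structures$PTV
  ptv <- if (opt_margin_mm > 0) {
    dilate_mask_mm(ptv0, ct$spacing, opt_margin_mm)
  } else ptv0
  iso <- mask_centroid(ct, scenario$structures$CTV)
  table <- hu_density_table()
  in_ptv <- ptv0[which(ptv)]
  ptv_pts <- grid_points(ct, ptv)

  fields <- list()
  all_spots <- list()
  for (f in 1:2) {
    frame <- beam_frame(scenario$angles_deg[f], iso)
    spec <- bev_grid_spec(ct, frame)
    rho <- bev_density(ct, spec, table)
    wepl <- bev_wepl_from_density(spec, rho)
    bev_pts <- patient_to_bev(spec, ptv_pts)
    wepl_pts <- interp_trilinear_idx(wepl, bev_coord_to_index(spec, bev_pts), fill = 0)

    spots <- place_spots_field(bev_pts, wepl_pts, machine)
    spots$energy_mev <- energy_for_range(spots$range_mm, machine)
    if (any(spots$energy_mev > machine$energy_range_mev[2] |
            spots$energy_mev < machine$energy_range_mev[1])) {
      stop(sprintf(
        "field %d: PTV outside deliverable range (needs %.0f-%.0f MeV)",
        f - 1L, min(spots$energy_mev), max(spots$energy_mev)), call. = FALSE)
    }

    idx <- seq_len(nrow(bev_pts))
    if (length(idx) > n_opt_points) {
      idx <- unique(as.integer(seq(1, length(idx), length.out = n_opt_points)))
    }
    A <- spot_influence(bev_pts[idx, 1], bev_pts[idx, 2], wepl_pts[idx],
                        spots, machine)
    target <- ifelse(in_ptv[idx], 0.5, 0.5 * edge_boost)
    spots$weight <- optimize_weights(A, target,
                                     max_iter = max_iter, tol = tol)
    spots$field <- f - 1L
    all_spots[[f]] <- spots
    fields[[f]] <- list(angle_deg = scenario$angles_deg[f], iso = iso,
                        spec = spec)
  }
  spots <- dplyr::bind_rows(all_spots)
  spots <- spots[spots$weight > 1e-6 * max(spots$weight), ]

  plan <- structure(
    list(fields = fields, spots = spots, machine = machine,
         prescription = scenario$prescription, iso = iso,
         hu_table = table, calibration = 1.0),
    class = "spot_plan"
  )
  plan <- delivery_timeline(plan)
  # calibrate: static CTV median = 100% of prescription
  dose <- compute_static_dose(plan, ct)
  med <- stats::median(dose$values[scenario$structures$CTV])
  plan$calibration <- 100 / med
  plan
}

#' @export
print.spot_plan <- function(x, ...) {
  cat(sprintf(
    "<spot_plan> 2 fields (%g/%g deg), %d spots, %d energy layers, calib %.3g\n",
    x$fields[[1]]$angle_deg, x$fields[[2]]$angle_deg, nrow(x$spots),
    length(unique(paste(x$spots$field, x$spots$energy_mev))), x$calibration))
  invisible(x)
}

#' Attach delivery timestamps to a spot plan
#'
#' Orders each field's spots energy-layer by energy-layer (descending
#' energy) with serpentine lateral scanning inside a layer, and accumulates
#' the delivery clock: spot dwell (weight divided by the per-field dose
#' rate, calibrated so the mean dwell equals the machine's typical dwell) +
#' lateral move time between consecutive spots + energy-layer switch time
#' between layers. Timestamps mark the start of each spot, in seconds from
#' the field start.
#'
#' @param plan a `spot_plan`.
#' @param machine a `machine_model` (defaults to the plan's).
#' @return the plan with `timestamp_s` set; per-field total delivery times
#'   in `plan$field_time_s`.
#' @export
delivery_timeline <- function(plan, machine = NULL) {
  if (is.null(machine)) machine <- plan$machine
  spots <- plan$spots
  out <- vector("list", 2)
  field_time <- numeric(2)
  for (f in 0:1) {
    sf <- spots[spots$field == f, ]
    if (nrow(sf) == 0) next
    # layer order: descending energy; serpentine within layer over v rows
    sf <- sf[order(-sf$energy_mev, sf$v, sf$u), ]
    layers <- unique(sf$energy_mev)
    sf$layer <- match(sf$energy_mev, layers) - 1L
    ord <- unlist(lapply(split(seq_len(nrow(sf)), sf$layer), function(ix) {
      rows <- split(ix, sf$v[ix])
      rows <- lapply(seq_along(rows), function(r) {
        if (r %% 2 == 0) rev(rows[[r]]) else rows[[r]]
      })
      unlist(rows)
    }), use.names = FALSE)
    sf <- sf[ord, ]
    dose_rate <- mean(sf$weight) / machine$dwell_s_typical
    dwell <- sf$weight / dose_rate
    t <- numeric(nrow(sf))
    clock <- 0
    for (s in seq_len(nrow(sf))) {
      if (s > 1) {
        clock <- clock + dwell[s - 1] +
          if (sf$layer[s] != sf$layer[s - 1]) machine$layer_switch_s else machine$move_s
      }
      t[s] <- clock
    }
    sf$timestamp_s <- t
    field_time[f + 1] <- clock + dwell[nrow(sf)]
    out[[f + 1]] <- sf
  }
  plan$spots <- dplyr::bind_rows(out)
  plan$field_time_s <- field_time
  plan
}

# Deposit a set of spots on a BEV WEPL grid (full-grid, truncated lateral
# windows); returns the BEV dose array.
deposit_spots_bev <- function(spec, wepl, spots, machine, trunc_sigma = 3.5) {
  dose <- array(0, spec$n)
  if (nrow(spots) == 0) return(dose)
  u_ax <- spec$lo[1] + (seq_len(spec$n[1]) - 1) * spec$spacing
  v_ax <- spec$lo[2] + (seq_len(spec$n[2]) - 1) * spec$spacing
  for (s in seq_len(nrow(spots))) {
    R <- proton_range_mm(spots$energy_mev[s], machine)
    half <- trunc_sigma * lateral_sigma_mm(R, machine)
    iu <- which(abs(u_ax - spots$u[s]) <= half)
    iv <- which(abs(v_ax - spots$v[s]) <= half)
    if (length(iu) == 0 || length(iv) == 0) next
    wp <- wepl[iu, iv, , drop = FALSE]
    sig <- lateral_sigma_mm(wp, machine)
    two_s2 <- 2 * sig^2
    r2 <- outer((u_ax[iu] - spots$u[s])^2, (v_ax[iv] - spots$v[s])^2, `+`)
    r2 <- array(r2, dim(wp)) # recycled along depth
    dd <- bragg_depth_dose(spots$energy_mev[s], wp, machine)
    dose[iu, iv, ] <- dose[iu, iv, ] +
      spots$weight[s] * dd * exp(-r2 / two_s2) / (pi * two_s2)
  }
  dose
}

#' Static (3D) dose of a spot plan on a CT
#'
#' The paper-style 3D dose calculation (3DDC): per field, radiological depth
#' is traced on the given CT in the field's BEV frame, every spot deposits
#' an analytic Bragg depth-dose times a depth-dependent lateral Gaussian,
#' and the BEV dose is resampled onto the patient grid. Fields are summed
#' and scaled by the plan calibration (static CTV median = 100%).
#'
#' @param plan a `spot_plan`.
#' @param ct a `voxel_grid` (HU) on the reference grid.
#' @return a `voxel_grid` of dose in % of the fraction prescription.
#' @export
compute_static_dose <- function(plan, ct) {
  total <- array(0, grid_shape(ct))
  pts <- grid_points(ct)
  for (f in 0:1) {
    spec <- plan$fields[[f + 1]]$spec
    rho <- bev_density(ct, spec, plan$hu_table)
    wepl <- bev_wepl_from_density(spec, rho)
    dose_bev <- deposit_spots_bev(spec, wepl,
                                  plan$spots[plan$spots$field == f, ],
                                  plan$machine)
    bevc <- patient_to_bev(spec, pts)
    vals <- interp_trilinear_idx(dose_bev, bev_coord_to_index(spec, bevc), fill = 0)
    total <- total + vals
  }
  dim(total) <- grid_shape(ct)
  voxel_grid(total * plan$calibration, ct$spacing, ct$origin)
}
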