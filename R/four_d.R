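#' Assign delivery timestamps to breathing phases
#'
#' Phase bins are uniform in time over one breathing cycle:
#' `phase(t) = (start_phase + floor(n_phases * t / T)) mod n_phases`.
#'
#' @param timestamp_s spot delivery timestamps (s from field start).
#' @param period_s breathing period T (s), > 0.
#' @param start_phase initial breathing phase index at t = 0.
#' @param n_phases phases per cycle (default 20).
#' @return integer phase index per timestamp, in `0..(n_phases-1)`.
#' @export
assign_spots_to_phases <- function(timestamp_s, period_s, start_phase,
                                   n_phases = 20L) {
  stopifnot(period_s > 0, start_phase >= 0, start_phase < n_phases)
  (as.integer(start_phase) +
     floor(n_phases * timestamp_s / period_s)) %% as.integer(n_phases)
}

#' Time-resolved 4D dose of one fraction (full grid)
#'
#' For each field and breathing phase: the spots delivered during that phase
#' (from their timestamps, the breathing period and the field's starting
#' phase) are deposited on the phase geometry — the reference CT warped by
#' the phase field, with radiological depth re-traced on the warped CT — and
#' the phase dose is mapped back to the reference frame by sampling at
#' `x + u_phase(x)`. The fraction dose is the sum over phases and fields.
#'
#' @param plan a `spot_plan` (with timestamps).
#' @param scenario the `patient_scenario` the plan was computed on.
#' @param motion a `motion_input`.
#' @param start_phases integer length-2 `(i, k)`: starting phase of fields
#'   F0 and F1.
#' @return a `voxel_grid` of fraction dose (% of fraction prescription)
#'   with provenance attributes `motion` and `start_phases`.
#' @export
compute_4d_dose <- function(plan, scenario, motion, start_phases = c(0L, 0L)) {
  ct <- scenario$ct
  d <- grid_shape(ct)
  np <- n_phases(motion)
  pts <- grid_points(ct)
  uspat <- matrix(motion$spatial$u, ncol = 3L)
  total <- numeric(prod(d))
  for (f in 0:1) {
    spec <- plan$fields[[f + 1]]$spec
    centers <- bev_centers_patient(spec)
    uspat_bev <- sample_dvf(motion$spatial, centers)
    sf <- plan$spots[plan$spots$field == f, ]
    ph <- assign_spots_to_phases(sf$timestamp_s, motion$period_s,
                                 start_phases[f + 1], np)
    # phases sharing a temporal factor (e.g. the symmetric sin^2 waveform)
    # share the warped geometry; cache wepl and pull-back indices per factor
    geo_cache <- list()
    for (j in sort(unique(ph))) {
      s_j <- motion$temporal[j + 1L]
      key <- sprintf("%.12g", s_j)
      if (is.null(geo_cache[[key]])) {
        rho <- bev_density(ct, spec, plan$hu_table, centers = centers,
                           shift = uspat_bev * s_j)
        bevc <- patient_to_bev(spec, pts + uspat * s_j)
        geo_cache[[key]] <- list(
          wepl = bev_wepl_from_density(spec, rho),
          idx = bev_coord_to_index(spec, bevc)
        )
      }
      geo <- geo_cache[[key]]
      dose_bev <- deposit_spots_bev(spec, geo$wepl, sf[ph == j, ], plan$machine)
      total <- total + interp_trilinear_idx(dose_bev, geo$idx, fill = 0)
    }
  }
  dim(total) <- d
  out <- voxel_grid(total * plan$calibration, ct$spacing, ct$origin)
  attr(out, "motion") <- motion$id
  attr(out, "start_phases") <- as.integer(start_phases)
  out
}

#' Precompute per-starting-phase fraction doses for a scenario
#'
#' The fraction-ensemble machinery evaluates dose at the voxel positions of
#' the tracked structures (pulled back per phase) rather than on the full
#' grid — the exact per-point formula of [compute_4d_dose()] without the
#' intermediate BEV dose grid. For every motion input, every field and every
#' possible starting phase, the dose delivered at the structure points is
#' precomputed, so that any fraction dose is the sum of two per-field
#' vectors and single-fraction ensembles and fractionated treatments reduce
#' to cheap vector arithmetic. Motion inputs sharing the same displacement
#' fields (period-rescaled copies, see [rescale_period()]) share the
#' expensive per-phase geometry. The analytic static dose at the same points
#' (all spots on the undeformed geometry) is stored as the consistent static
#' reference for ensemble comparisons.
#'
#' @param plan a `spot_plan`.
#' @param scenario a `patient_scenario`.
#' @param structures structure names to track (CTV always included).
#' @param max_points_per_structure subsample cap for non-CTV structures.
#' @return an `interplay_table`: per-motion arrays
#'   `[n_points, n_starts, 2 fields]`, the static point dose, and point
#'   metadata.
#' @export
interplay_table <- function(plan, scenario, structures = "CTV",
                            max_points_per_structure = 2000) {
  structures <- union("CTV", structures)
  motions <- scenario$motions
  ids <- vapply(motions, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("motion input ids must be unique", call. = FALSE)
  ct <- scenario$ct
  idx_list <- lapply(structures, function(nm) {
    ix <- which(scenario$structures[[nm]])
    if (nm != "CTV" && length(ix) > max_points_per_structure) {
      ix <- ix[seq(1, length(ix), length.out = max_points_per_structure)]
    }
    ix
  })
  names(idx_list) <- structures
  pts <- grid_points(ct, unlist(idx_list))
  grp_struct <- rep(structures, lengths(idx_list))
  n_pts <- nrow(pts)

  # group motions by identical spatial fields (rescaled copies share them)
  groups <- list()
  for (m in motions) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (identical(groups[[gi]][[1]]$spatial$u, m$spatial$u) &&
          identical(groups[[gi]][[1]]$temporal, m$temporal)) {
        groups[[gi]] <- c(groups[[gi]], list(m))
        placed <- TRUE
        break
      }
    }
    if (!placed) groups <- c(groups, list(list(m)))
  }

  tabs <- vector("list", length(ids))
  names(tabs) <- ids
  static_pts <- NULL
  np <- n_phases(motions[[1]])
  for (grp in groups) {
    motion <- grp[[1]]
    upts <- sample_dvf(motion$spatial, pts)
    D <- lapply(grp, function(m) array(0, c(n_pts, np, 2)))
    for (f in 0:1) {
      spec <- plan$fields[[f + 1]]$spec
      centers <- bev_centers_patient(spec)
      uspat_bev <- sample_dvf(motion$spatial, centers)
      sf <- plan$spots[plan$spots$field == f, ]
      # spot offset bins per motion input: spots in bin b are delivered in
      # phase (start + b) mod np
      bins <- lapply(grp, function(m) {
        floor(np * sf$timestamp_s / m$period_s) %% np
      })
      A_cache <- list() # per temporal factor: sin^2 phases pair up
      for (j in seq_len(np) - 1L) {
        s_j <- motion$temporal[j + 1L]
        key <- sprintf("%.12g", s_j)
        if (is.null(A_cache[[key]])) {
          rho <- bev_density(ct, spec, plan$hu_table, centers = centers,
                             shift = uspat_bev * s_j)
          wepl <- bev_wepl_from_density(spec, rho)
          warped <- pts + upts * s_j
          bevc <- patient_to_bev(spec, warped)
          wepl_p <- interp_trilinear_idx(wepl, bev_coord_to_index(spec, bevc),
                                         fill = 0)
          Anew <- spot_influence(bevc[, 1], bevc[, 2], wepl_p, sf, plan$machine)
          A_cache[[key]] <- Anew * rep(sf$weight * plan$calibration, each = n_pts)
        }
        A <- A_cache[[key]]
        if (j == 0L && identical(grp, groups[[1]])) {
          # phase 0 is EEX (zero field): all spots on the static geometry
          if (f == 0L) static_pts <- numeric(n_pts)
          static_pts <- static_pts + rowSums(A)
        }
        for (gi in seq_along(grp)) {
          b_need <- (j - (seq_len(np) - 1L)) %% np # bin feeding phase j per start
          for (i in seq_len(np) - 1L) {
            cols <- which(bins[[gi]] == b_need[i + 1L])
            if (length(cols) == 0L) next
            D[[gi]][, i + 1L, f + 1L] <- D[[gi]][, i + 1L, f + 1L] +
              rowSums(A[, cols, drop = FALSE])
          }
        }
      }
    }
    for (gi in seq_along(grp)) tabs[[grp[[gi]]$id]] <- D[[gi]]
  }
  structure(
    list(doses = tabs, n_phases = np, static = static_pts,
         point_structure = grp_struct, point_index = unlist(idx_list),
         motion_ids = ids),
    class = "interplay_table"
  )
}

#' Static reference metrics at the table's CTV points
#' @param tab an `interplay_table`.
#' @return list of CTV metrics of the analytic static dose at the tracked
#'   CTV points (same convention as the ensemble metrics).
#' @export
static_point_metrics <- function(tab) {
  ctv_metrics(tab$static[tab$point_structure == "CTV"])
}

# fraction dose vector at the engine points for motion m and starts (i, k)
fraction_dose_points <- function(tab, m_id, i, k) {
  D <- tab$doses[[m_id]]
  D[, i + 1L, 1] + D[, k + 1L, 2]
}

#' Single-fraction interplay ensemble (4Dx1)
#'
#' Enumerates 4D fraction doses over starting-phase combinations for each
#' motion input and reports CTV metrics per ensemble member. The default
#' combines the per-field starting phases as the full grid of `(i, k)`
#' pairs; `combination = "diagonal"` restricts to `i = k`.
#'
#' @param tab an `interplay_table` (see [interplay_table()]), or arguments
#'   to build one via `plan`, `scenario`, `motions`.
#' @param combination "grid" (all `(i, k)` pairs) or "diagonal".
#' @return tibble with columns `m`, `i`, `k`, `d5d95`, `v95`, `v107`, `d2`,
#'   `dmean` (CTV metrics, % of prescription).
#' @export
enumerate_single_fraction <- function(tab, combination = c("grid", "diagonal")) {
  combination <- match.arg(combination)
  np <- tab$n_phases
  ctv <- tab$point_structure == "CTV"
  starts <- if (combination == "grid") {
    expand.grid(i = seq_len(np) - 1L, k = seq_len(np) - 1L)
  } else {
    data.frame(i = seq_len(np) - 1L, k = seq_len(np) - 1L)
  }
  purrr::map_dfr(tab$motion_ids, function(m_id) {
    D <- tab$doses[[m_id]]
    purrr::map_dfr(seq_len(nrow(starts)), function(r) {
      dose <- D[ctv, starts$i[r] + 1L, 1] + D[ctv, starts$k[r] + 1L, 2]
      met <- ctv_metrics(dose)
      tibble::tibble(m = m_id, i = starts$i[r], k = starts$k[r], !!!met)
    })
  })
}

# scalar CTV metric set from a dose vector (% of prescription)
ctv_metrics <- function(dose) {
  list(
    d5d95 = dose_percentile(dose, 5) / dose_percentile(dose, 95),
    v95 = 100 * mean(dose >= 95),
    v107 = 100 * mean(dose >= 107),
    d2 = dose_percentile(dose, 2),
    dmean = mean(dose)
  )
}
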