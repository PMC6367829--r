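test_that("phase assignment wraps uniform time bins", {
  # T = 4 s: bin width 0.2 s; t = 0.3 s falls in phase 1
  expect_equal(assign_spots_to_phases(0.3, 4, 0L), 1L)
  expect_equal(assign_spots_to_phases(0, 7.3, 5L), 5L)
  expect_equal(assign_spots_to_phases(4, 4, 0L), 0L) # t = T wraps
  expect_equal(assign_spots_to_phases(0.95, 4, 18L), (18L + 4L) %% 20L)
  tt <- seq(0, 12, by = 0.05)
  ph <- assign_spots_to_phases(tt, 3.7, 7L)
  expect_true(all(ph >= 0 & ph <= 19))
})

test_that("zero motion makes the 4D fraction dose equal the static dose", {
  scen <- small_scenario()
  ph <- small_phantom()
  scen0 <- patient_scenario(ph$ct, ph$structures, list(zero_motion(ph$ct)))
  plan <- plan_sfud(scen0)
  static <- compute_static_dose(plan, scen0$ct)
  fd <- compute_4d_dose(plan, scen0, scen0$motions[[1]], c(4L, 11L))
  expect_lt(max(abs(fd$values - static$values)) / max(static$values), 1e-3)
})

test_that("interplay table matches a direct two-step composition oracle", {
  # oracle: recompute the fraction dose at the CTV points by composing the
  # steps manually per phase — spot-to-phase assignment, warped geometry,
  # WEPL re-trace, analytic spot dose — independently of the table's
  # offset-bin bookkeeping
  scen <- small_scenario()
  plan <- small_plan()
  m <- scen$motions[[1]]
  tab <- interplay_table(plan, scen)
  ctv <- tab$point_structure == "CTV"
  pts <- grid_points(scen$ct, tab$point_index[ctv])
  upts <- interplay4d:::sample_dvf(m$spatial, pts)
  for (se in list(c(0L, 0L), c(5L, 12L))) {
    oracle <- numeric(nrow(pts))
    for (f in 0:1) {
      spec <- plan$fields[[f + 1]]$spec
      centers <- interplay4d:::bev_centers_patient(spec)
      u_bev <- interplay4d:::sample_dvf(m$spatial, centers)
      sf <- plan$spots[plan$spots$field == f, ]
      ph <- assign_spots_to_phases(sf$timestamp_s, m$period_s, se[f + 1])
      for (j in unique(ph)) {
        s_j <- m$temporal[j + 1]
        rho <- interplay4d:::bev_density(scen$ct, spec, plan$hu_table,
                                         centers = centers, shift = u_bev * s_j)
        wepl <- interplay4d:::bev_wepl_from_density(spec, rho)
        bevc <- interplay4d:::patient_to_bev(spec, pts + upts * s_j)
        wp <- interplay4d:::interp_trilinear_idx(
          wepl, interplay4d:::bev_coord_to_index(spec, bevc), fill = 0)
        A <- interplay4d:::spot_influence(bevc[, 1], bevc[, 2], wp,
                                          sf[ph == j, ], plan$machine)
        oracle <- oracle + as.numeric(A %*% sf$weight[ph == j]) * plan$calibration
      }
    }
    fast <- interplay4d:::fraction_dose_points(tab, "m1", se[1], se[2])[ctv]
    expect_equal(fast, oracle, tolerance = 1e-10)
  }
})

test_that("point path and full-grid path agree up to BEV grid resampling", {
  scen <- small_scenario()
  plan <- small_plan()
  m <- scen$motions[[1]]
  tab <- interplay_table(plan, scen)
  ctv <- tab$point_structure == "CTV"
  ctv_idx <- tab$point_index[ctv]
  fast <- interplay4d:::fraction_dose_points(tab, "m1", 5L, 12L)[ctv]
  full <- compute_4d_dose(plan, scen, m, c(5L, 12L))$values[ctv_idx]
  # the full-grid path resamples a BEV-sampled dose grid, smoothing steep
  # interplay gradients; the two conventions must agree in the mean and
  # broadly per point
  expect_lt(abs(mean(fast) - mean(full)) / mean(full), 0.02)
  expect_lt(stats::median(abs(fast - full)) / mean(full), 0.03)
})

test_that("single-fraction ensemble has the configured size and spread", {
  scen <- small_scenario()
  plan <- small_plan()
  tab <- interplay_table(plan, scen)
  ens <- enumerate_single_fraction(tab)
  expect_equal(nrow(ens), 400) # full 20 x 20 grid of (i, k)
  diag_ens <- enumerate_single_fraction(tab, combination = "diagonal")
  expect_equal(nrow(diag_ens), 20)
  # nonzero motion with T << field time: interplay spreads the metrics
  expect_gt(max(ens$d5d95) - min(ens$d5d95), 0)
  expect_true(all(ens$d5d95 >= 1))
  expect_true(all(ens$v95 <= 100 & ens$v95 >= 0))
  # ensemble mean of dmean stays near the static value (dose conservation)
  sm <- static_point_metrics(tab)
  expect_lt(abs(mean(ens$dmean) - sm$dmean) / sm$dmean, 0.01)
})

test_that("zero-motion ensemble members are identical", {
  ph <- small_phantom()
  scen0 <- patient_scenario(ph$ct, ph$structures, list(zero_motion(ph$ct)))
  plan0 <- plan_sfud(scen0)
  tab0 <- interplay_table(plan0, scen0)
  ens0 <- enumerate_single_fraction(tab0, combination = "diagonal")
  expect_lt(max(ens0$d5d95) - min(ens0$d5d95), 1e-12)
  expect_lt(max(abs(ens0$dmean - mean(ens0$dmean))), 1e-9)
  # and they match the static reference
  sm <- static_point_metrics(tab0)
  expect_equal(ens0$d5d95[1], sm$d5d95, tolerance = 1e-9)
})

test_that("interplay severity grows with IS amplitude", {
  ph <- small_phantom()
  amps <- c(2, 6, 12)
  means <- vapply(amps, function(a) {
    m <- generate_motion_input(ph$ct, ph$structures$CTV, c(1, 1, a), 3, id = "m1")
    scen <- patient_scenario(ph$ct, ph$structures, list(m))
    plan <- plan_sfud(scen)
    tab <- interplay_table(plan, scen)
    mean(enumerate_single_fraction(tab, combination = "diagonal")$d5d95)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
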