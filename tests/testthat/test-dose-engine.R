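test_that("range-energy power law and Bragg peak position agree", {
  machine <- machine_model()
  # R(150 MeV) = 0.0022 * 150^1.77 cm
  expect_equal(proton_range_mm(150, machine), 10 * 0.0022 * 150^1.77)
  expect_lt(abs(proton_range_mm(150, machine) - 156), 1.5)
  expect_gt(proton_range_mm(160, machine), proton_range_mm(150, machine))
  expect_equal(energy_for_range(proton_range_mm(120, machine), machine), 120,
               tolerance = 1e-10)
  # peak at the range, normalized to 1, zero far beyond
  R <- proton_range_mm(150, machine)
  z <- seq(0, R + 60, by = 0.1)
  dd <- bragg_depth_dose(150, z, machine)
  expect_equal(max(dd), 1, tolerance = 1e-3) # peak sampled on a 0.1 mm grid
  expect_equal(z[which.max(dd)], R, tolerance = 0.2)
  expect_equal(bragg_depth_dose(150, R + 50, machine), 0)
  expect_true(all(dd >= 0))
})

test_that("WEPL tracing reproduces analytic depths", {
  g <- water_grid(24, 5, hu = 0) # uniform water
  w <- trace_wepl(g, angle_deg = 0)
  # central axis: WEPL equals geometric depth from the grid entry (beam from
  # anterior travels -y); compare two voxels 50 mm apart
  mid <- 12
  d1 <- w$values[mid, 18, mid]; d2 <- w$values[mid, 8, mid]
  expect_equal(d2 - d1, 50, tolerance = 0.5 * 0.005 * 100)
  # 20 mm slab of density 2 adds 20 mm WEPL downstream
  hu2 <- g$values
  hu2[, 15:18, ] <- 1000 # density 1.6 over 20 mm -> +12 mm extra
  g2 <- voxel_grid(hu2, g$spacing, g$origin)
  w2 <- trace_wepl(g2, angle_deg = 0)
  extra <- (hu_to_density(1000) - 1) * 20
  expect_equal(w2$values[mid, 8, mid] - w$values[mid, 8, mid], extra,
               tolerance = 0.02 * extra + 0.2)
  # oblique 45 degree beam through water: WEPL equals Euclidean path length
  w45 <- trace_wepl(g, angle_deg = 45)
  p_shallow <- c(20, 20, 0); p_deep <- c(-20, -20, 0)
  v <- sample_grid(w45, rbind(p_shallow, p_deep))
  expect_equal(v[2] - v[1], sqrt(2) * 40, tolerance = 0.01 * sqrt(2) * 40 + 0.5)
})

test_that("a single spot has the configured lateral Gaussian width", {
  g <- water_grid(32, 4, hu = 0)
  machine <- machine_model()
  frame <- beam_frame(0, c(0, 0, 0))
  spec <- interplay4d:::bev_grid_spec(g, frame)
  rho <- interplay4d:::bev_density(g, spec, hu_density_table())
  wepl <- interplay4d:::bev_wepl_from_density(spec, rho)
  spots <- tibble::tibble(u = 0, v = 0, energy_mev = 120, weight = 1, field = 0L)
  dose <- interplay4d:::deposit_spots_bev(spec, wepl, spots, machine)
  # lateral profile at a depth upstream of the peak
  R <- proton_range_mm(120, machine)
  k <- which.min(abs((spec$lo[3] + (seq_len(spec$n[3]) - 1) * spec$spacing) + 60))
  u_ax <- spec$lo[1] + (seq_len(spec$n[1]) - 1) * spec$spacing
  iv0 <- which.min(abs(spec$lo[2] + (seq_len(spec$n[2]) - 1) * spec$spacing))
  prof <- dose[, iv0, k]
  keep <- prof > max(prof) * 1e-3
  fit <- stats::lm(log(prof[keep]) ~ I(u_ax[keep]^2))
  sigma_fit <- unname(sqrt(-1 / (2 * stats::coef(fit)[2])))
  wepl_here <- wepl[which.min(abs(u_ax)), iv0, k]
  expect_equal(sigma_fit, lateral_sigma_mm(wepl_here, machine), tolerance = 0.02)
})

test_that("dose is linear in spot weights and additive in identical spots", {
  g <- water_grid(24, 5, hu = 0)
  machine <- machine_model()
  frame <- beam_frame(0, c(0, 0, 0))
  spec <- interplay4d:::bev_grid_spec(g, frame)
  rho <- interplay4d:::bev_density(g, spec, hu_density_table())
  wepl <- interplay4d:::bev_wepl_from_density(spec, rho)
  one <- tibble::tibble(u = 0, v = 0, energy_mev = 100, weight = 1, field = 0L)
  two_half <- tibble::tibble(u = c(0, 0), v = c(0, 0), energy_mev = c(100, 100),
                             weight = c(0.5, 0.5), field = 0L)
  d1 <- interplay4d:::deposit_spots_bev(spec, wepl, one, machine)
  d2 <- interplay4d:::deposit_spots_bev(spec, wepl, two_half, machine)
  expect_equal(d2, d1, tolerance = 1e-12)
  zero <- one; zero$weight <- 0
  expect_true(all(interplay4d:::deposit_spots_bev(spec, wepl, zero, machine) == 0))
})

test_that("integral depth dose is independent of lateral position in water", {
  g <- water_grid(28, 5, hu = 0)
  machine <- machine_model()
  frame <- beam_frame(0, c(0, 0, 0))
  spec <- interplay4d:::bev_grid_spec(g, frame)
  rho <- interplay4d:::bev_density(g, spec, hu_density_table())
  wepl <- interplay4d:::bev_wepl_from_density(spec, rho)
  int_dose <- sapply(c(0, 10, -15), function(u0) {
    s <- tibble::tibble(u = u0, v = 0, energy_mev = 110, weight = 1, field = 0L)
    sum(interplay4d:::deposit_spots_bev(spec, wepl, s, machine))
  })
  expect_lt(max(abs(int_dose / int_dose[1] - 1)), 0.01)
})

test_that("SFUD plan reaches the static quality targets on the phantom", {
  scen <- small_scenario()
  plan <- small_plan()
  dose <- compute_static_dose(plan, scen$ct)
  rep <- dose_report(dose, scen$structures, which = "CTV")
  expect_equal(rep$v95, 100)
  expect_lte(rep$d5d95, 1.05)
  expect_equal(rep$v107, 0)
  expect_lt(rep$d2, 107)
  # SFUD: each field contributes about half the dose
  ctv <- scen$structures$CTV
  f0 <- plan$spots$field == 0
  spec <- plan$fields[[1]]$spec
  rho <- interplay4d:::bev_density(scen$ct, spec, plan$hu_table)
  wepl <- interplay4d:::bev_wepl_from_density(spec, rho)
  d0 <- interplay4d:::deposit_spots_bev(spec, wepl, plan$spots[f0, ], plan$machine)
  pts <- grid_points(scen$ct, ctv)
  v0 <- interplay4d:::interp_trilinear_idx(
    d0, interplay4d:::bev_coord_to_index(spec, interplay4d:::patient_to_bev(spec, pts)),
    fill = 0) * plan$calibration
  expect_equal(median(v0), 50, tolerance = 5)
})

test_that("plan weight optimization is linear in the prescription", {
  A <- matrix(runif(400, 0, 1), 40, 10)
  w1 <- interplay4d:::optimize_weights(A, rep(0.5, 40))
  w2 <- interplay4d:::optimize_weights(A, rep(1.0, 40))
  expect_equal(w2, 2 * w1, tolerance = 1e-6)
})

test_that("delivery timeline accumulates dwell, moves and layer switches", {
  machine <- machine_model(dwell_s_typical = 0.005, move_s = 0.003,
                           layer_switch_s = 1)
  spots <- tibble::tibble(
    field = 0L, u = c(0, 5, 0, 5), v = 0, range_mm = c(100, 100, 95, 95),
    energy_mev = energy_for_range(c(100, 100, 95, 95)), weight = 1
  )
  plan <- structure(list(spots = spots, machine = machine), class = "spot_plan")
  plan <- delivery_timeline(plan, machine)
  tt <- plan$spots$timestamp_s
  expect_equal(tt[1:2], c(0, 0.008))
  # layer switch inserts >= 1 s between layers
  expect_gte(tt[3] - tt[2], 1)
  # total field time = sum of dwells + moves + switches
  expect_equal(plan$field_time_s[1], 4 * 0.005 + 2 * 0.003 + 1)
  # timestamps strictly increasing within the field
  expect_true(all(diff(tt) > 0))
})

test_that("two spots with the given dwell/move give timestamps 0 and 8 ms", {
  machine <- machine_model(dwell_s_typical = 0.005, move_s = 0.003)
  spots <- tibble::tibble(field = 0L, u = c(0, 5), v = 0, range_mm = 100,
                          energy_mev = 100, weight = c(1, 1))
  plan <- structure(list(spots = spots, machine = machine), class = "spot_plan")
  plan <- delivery_timeline(plan, machine)
  expect_equal(plan$spots$timestamp_s, c(0, 0.008))
})
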