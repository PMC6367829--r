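test_that("generated motion reproduces the requested CTV-centroid amplitude", {
  ph <- small_phantom()
  amp <- c(2, 3, 8)
  m <- generate_motion_input(ph$ct, ph$structures$CTV, amp, period_s = 3)
  cen <- mask_centroid(ph$ct, ph$structures$CTV)
  u_ein <- sample_dvf(m$spatial, rbind(cen)) * max(abs(m$temporal))
  expect_equal(as.numeric(u_ein), amp, tolerance = 0.05)
  expect_equal(ein_phase(m), 10L)
  # phase-0 field exactly zero; all phases fold-free
  expect_true(all(phase_field(m, 0)$u == 0))
  for (j in c(5L, 10L, 15L)) {
    expect_gt(min(jacobian_determinant_map(phase_field(m, j))$values), 0)
  }
})

test_that("sin^2 waveform gives half the EIN amplitude at phase 5", {
  ph <- small_phantom()
  m <- generate_motion_input(ph$ct, ph$structures$CTV, c(0, 0, 8), period_s = 4)
  cen <- rbind(mask_centroid(ph$ct, ph$structures$CTV))
  u5 <- sample_dvf(phase_field(m, 5), cen)[3]
  u10 <- sample_dvf(phase_field(m, 10), cen)[3]
  expect_equal(u5 / u10, sin(pi / 4)^2, tolerance = 0.02)
})

test_that("zero amplitude gives identically zero fields", {
  ph <- small_phantom()
  m <- generate_motion_input(ph$ct, ph$structures$CTV, c(0, 0, 0), period_s = 3)
  for (j in seq_len(n_phases(m)) - 1L) {
    expect_true(all(phase_field(m, j)$u == 0))
  }
})

test_that("motion generation is reproducible and amplitude-linear", {
  ph <- small_phantom()
  m1 <- generate_motion_input(ph$ct, ph$structures$CTV, c(1, 1, 4), 3,
                              jitter_sd = 0.05, seed = 7)
  m2 <- generate_motion_input(ph$ct, ph$structures$CTV, c(1, 1, 4), 3,
                              jitter_sd = 0.05, seed = 7)
  expect_identical(m1$spatial$u, m2$spatial$u)
  expect_identical(m1$temporal, m2$temporal)
  m3 <- generate_motion_input(ph$ct, ph$structures$CTV, 2 * c(1, 1, 4), 3)
  m4 <- generate_motion_input(ph$ct, ph$structures$CTV, c(1, 1, 4), 3)
  expect_equal(m3$spatial$u, 2 * m4$spatial$u, tolerance = 1e-12)
})

test_that("excessive amplitude is rejected with a folding diagnostic", {
  ph <- small_phantom()
  expect_error(
    generate_motion_input(ph$ct, ph$structures$CTV, c(0, 0, 60), period_s = 3),
    "fold"
  )
})

test_that("rescale_period changes only the period", {
  ph <- small_phantom()
  m <- generate_motion_input(ph$ct, ph$structures$CTV, c(2, 3, 8), 7.1)
  r <- rescale_period(m, 3.0)
  expect_identical(r$spatial$u, m$spatial$u)
  expect_identical(r$temporal, m$temporal)
  expect_equal(r$period_s, 3.0)
  expect_equal(r$provenance, "period-rescaled")
  # composition equals a direct rescale
  r2 <- rescale_period(rescale_period(m, 3.0), 10.0)
  direct <- rescale_period(m, 10.0)
  expect_identical(r2$spatial$u, direct$spatial$u)
  expect_equal(r2$period_s, direct$period_s)
  expect_error(rescale_period(m, 12), "period")
})

test_that("warp_image matches a pointwise interpolation oracle", {
  g <- water_grid(20, 5)
  d <- dim(g$values)
  # smooth image and smooth field
  ax <- lapply(1:3, function(a) g$origin[a] + (seq_len(d[a]) - 1) * g$spacing[a])
  img <- outer(outer(sin(ax[[1]] / 30), cos(ax[[2]] / 40), `+`), ax[[3]] / 90, `+`)
  gi <- voxel_grid(img, g$spacing, g$origin)
  u <- array(0, c(d, 3))
  u[, , , 3] <- 4 * outer(outer(cos(ax[[1]] / 50), sin(ax[[2]] / 60)), rep(1, d[3]))
  dvf <- deformation_field(u, g$spacing, g$origin)
  w <- warp_image(gi, dvf, fill = 0)
  # oracle: per-voxel manual trilinear interpolation at x + u(x)
  set.seed(1)
  probe <- sample(prod(d), 200)
  ijk <- arrayInd(probe, d)
  for (r in seq_len(20)) {
    v <- ijk[r, ]
    pos <- (v - 1) * g$spacing + g$origin + u[v[1], v[2], v[3], ]
    idx <- (pos - g$origin) / g$spacing + 1
    i0 <- floor(idx); fr <- idx - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      acc <- acc + wgt * img[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    expect_equal(w$values[v[1], v[2], v[3]], acc, tolerance = 1e-6)
  }
  # zero field is the identity
  expect_equal(warp_image(gi, zero_field(gi), fill = 0)$values, img)
})

test_that("a one-voxel translation moves a step edge by one voxel", {
  g <- water_grid(16, 5)
  img <- g$values
  img[, , 1:8] <- 100
  gi <- voxel_grid(img, g$spacing, g$origin)
  dvf <- translation_field(gi, c(0, 0, 5)) # sample one voxel superior
  w <- warp_image(gi, dvf, fill = -1000)
  expect_equal(w$values[8, 8, 1:7], rep(100, 7))
  expect_equal(w$values[8, 8, 8:15], rep(0, 8))
})

test_that("ITV/PTV derivation follows the union-plus-margin definition", {
  ph <- small_phantom()
  ctv <- ph$structures$CTV
  # zero motion: ITV = CTV; zero margin: PTV = ITV
  m0 <- zero_motion(ph$ct)
  tv <- derive_itv_ptv(ctv, m0, margin_mm = 0)
  expect_identical(tv$itv, ctv)
  expect_identical(tv$ptv, tv$itv)
  # rigid IS translation: ITV IS extent grows by the amplitude (+- 1 voxel)
  amp <- 12
  m <- generate_motion_input(ph$ct, ctv, c(0, 0, amp), 3, envelope = "rigid")
  tv2 <- derive_itv_ptv(ctv, m, margin_mm = 0)
  extent_is <- function(mask) {
    z <- range(which(apply(mask, 3, any)))
    diff(z) * ph$ct$spacing[3]
  }
  grown <- extent_is(tv2$itv) - extent_is(ctv)
  expect_lte(abs(grown - amp), ph$ct$spacing[3])
  # margin dilation is symmetric and contains the ITV
  tv3 <- derive_itv_ptv(ctv, m, margin_mm = 6)
  expect_true(all(tv3$ptv[tv3$itv]))
  expect_gt(sum(tv3$ptv), sum(tv3$itv))
})
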