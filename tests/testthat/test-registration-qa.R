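test_that("HU-to-density table is monotone with the expected anchors", {
  tb <- hu_density_table()
  expect_equal(hu_to_density(-1000, tb), 0.001)
  expect_equal(hu_to_density(0, tb), 1.0)
  expect_true(all(diff(hu_to_density(seq(-1100, 1100, by = 10), tb)) >= 0))
  # clamping outside the node range
  expect_equal(hu_to_density(-2000, tb), 0.001)
  expect_equal(hu_to_density(3000, tb), 1.6)
  expect_error(hu_density_table(data.frame(hu = c(0, 100), density = c(1.1, 1.0))),
               "non-decreasing")
})

test_that("Jacobian map is 1 for the identity and analytic for linear fields", {
  g <- water_grid(16, 4)
  expect_equal(jacobian_determinant_map(zero_field(g))$values,
               array(1, dim(g$values)))
  # u = (0.1 x, 0, 0): det(I + grad u) = 1.1 everywhere
  jac <- jacobian_determinant_map(linear_field(g, coef = 0.1, axis = 1))$values
  expect_equal(max(abs(jac - 1.1)), 0, tolerance = 1e-9)
})

test_that("Jacobian map agrees with an independent 4th-order stencil", {
  g <- water_grid(20, 5)
  d <- dim(g$values)
  ax <- lapply(1:3, function(a) g$origin[a] + (seq_len(d[a]) - 1) * g$spacing[a])
  u <- array(0, c(d, 3))
  u[, , , 1] <- 2 * outer(outer(sin(ax[[1]] / 40), cos(ax[[2]] / 50)), rep(1, d[3]))
  u[, , , 3] <- 1.5 * outer(outer(rep(1, d[1]), sin(ax[[2]] / 30)), cos(ax[[3]] / 45))
  dvf <- deformation_field(u, g$spacing, g$origin)
  jac <- jacobian_determinant_map(dvf)$values

  # oracle: 4th-order central differences on the interior
  grad4 <- function(arr, axis, h) {
    d <- dim(arr); n <- d[axis]
    sl <- function(r) {
      ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])); ix[[axis]] <- r
      do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
    }
    core <- (-sl(5:n) + 8 * sl(4:(n - 1)) - 8 * sl(2:(n - 3)) + sl(1:(n - 4))) / (12 * h)
    core
  }
  interior <- function(a) a[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)]
  J <- list()
  for (c in 1:3) for (a in 1:3) {
    gfull <- array(0, d)
    core <- grad4(u[, , , c], a, g$spacing[a])
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[a]] <- 3:(d[a] - 2)
    gfull[idx[[1]], idx[[2]], idx[[3]]] <- core
    J[[paste(c, a)]] <- interior(gfull)
  }
  det4 <- (1 + J[["1 1"]]) * ((1 + J[["2 2"]]) * (1 + J[["3 3"]]) - J[["2 3"]] * J[["3 2"]]) -
    J[["1 2"]] * (J[["2 1"]] * (1 + J[["3 3"]]) - J[["2 3"]] * J[["3 1"]]) +
    J[["1 3"]] * (J[["2 1"]] * J[["3 2"]] - (1 + J[["2 2"]]) * J[["3 1"]])
  expect_lt(max(abs(interior(jac) - det4)), 1e-3)
})

test_that("Jacobian determinant of composed small fields multiplies to 1st order", {
  g <- water_grid(16, 5)
  f1 <- linear_field(g, coef = 0.05, axis = 1)
  f2 <- linear_field(g, coef = 0.04, axis = 3)
  comp <- deformation_field(f1$u + f2$u, g$spacing, g$origin)
  j1 <- jacobian_determinant_map(f1)$values
  j2 <- jacobian_determinant_map(f2)$values
  jc <- jacobian_determinant_map(comp)$values
  expect_lt(max(abs(jc - j1 * j2)), 1e-2)
})

test_that("mass ratio is exactly 1 for the identity and follows det J for linear fields", {
  g <- water_grid(36, 3, hu = 0)
  mask <- ellipsoid_mask(g, c(0, 0, 0), c(30, 30, 30))
  mc <- mass_conservation_ratio(g, zero_field(g), mask)
  expect_identical(mc$ratio, 1.0)
  expect_equal(mc$v_eex_cc, mc$v_ein_cc)
  # pure intensity warping does not conserve mass: a linear field with
  # det J = 1.1 shrinks the pulled-back delineation by 1.1 at constant
  # density, so m_EEX/m_EIN = det J (up to voxelization of the warped mask)
  mc2 <- mass_conservation_ratio(g, linear_field(g, coef = 0.1, axis = 1), mask)
  expect_equal(mc2$ratio, 1.1, tolerance = 0.02)
  # an in-grid translation of uniform tissue conserves mass
  mc3 <- mass_conservation_ratio(g, translation_field(g, c(5, 0, 0)), mask)
  expect_equal(mc3$ratio, 1.0, tolerance = 0.01)
})

test_that("mass ratio is invariant to mask voxel order and errors on empty warps", {
  g <- water_grid(12, 5, hu = 40)
  mask <- ellipsoid_mask(g, c(0, 0, 0), c(15, 15, 15))
  expect_error(mass_conservation_ratio(g, zero_field(g), array(FALSE, dim(g$values))),
               "empty")
  # a translation pushing the mask fully outside the grid empties the warp
  expect_error(
    mass_conservation_ratio(g, translation_field(g, c(200, 0, 0)), mask),
    "warped mask"
  )
})

test_that("QA report covers the OARs and flags folding", {
  scen <- small_scenario()
  qa <- qa_report(scen)
  expect_setequal(unique(qa$organ), c("liver", "kidney_L", "kidney_R", "bowel"))
  expect_true(all(abs(qa$mean_jacobian - 1) < 0.1))
  expect_true(all(qa$n_folding == 0))
  expect_true(all(qa$mass_ratio > 0.8 & qa$mass_ratio < 1.25))
  # zero-motion scenario: everything exactly 1
  ph <- small_phantom()
  scen0 <- patient_scenario(ph$ct, ph$structures, list(zero_motion(ph$ct)))
  qa0 <- qa_report(scen0)
  expect_true(all(qa0$mean_jacobian == 1))
  expect_true(all(qa0$mass_ratio == 1))
  # constructed folding field is reported
  g <- scen$ct
  fold <- linear_field(g, coef = -1.2, axis = 1)
  jm <- jacobian_determinant_map(fold)$values
  expect_true(any(jm <= 0))
})
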