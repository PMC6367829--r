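# Shared fixtures: small phantoms and scenarios, built once per test run.
# Grids are deliberately small (32-48 voxels per axis) so the suite stays
# fast; the acceptance tests use the full study grids.

small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_phantom(phantom_config(48, 5, ctv_volume_cc = 51.9))
    }
    cache
  }
})

# a tiny all-water grid for warp/interpolation tests
water_grid <- function(n = 24, spacing = 5, hu = 0) {
  voxel_grid(array(hu, c(n, n, n)), spacing)
}

# linear-expansion field u = c * (x - x0) along the first axis
linear_field <- function(g, coef = 0.1, axis = 1) {
  d <- dim(g$values)
  u <- array(0, c(d, 3))
  ax <- g$origin[axis] + (seq_len(d[axis]) - 1) * g$spacing[axis]
  comp <- array(0, d)
  perm <- switch(axis, aperm(array(ax, d), c(1, 2, 3)), NULL)
  if (axis == 1) comp <- array(ax, d)
  if (axis == 2) comp <- aperm(array(ax, d[c(2, 1, 3)]), c(2, 1, 3))
  if (axis == 3) comp <- aperm(array(ax, d[c(3, 1, 2)]), c(2, 3, 1))
  u[, , , axis] <- coef * comp
  deformation_field(u, g$spacing, g$origin)
}

# uniform translation field (mm, length-3)
translation_field <- function(g, shift) {
  d <- dim(g$values)
  u <- array(0, c(d, 3))
  for (c in 1:3) u[, , , c] <- shift[c]
  deformation_field(u, g$spacing, g$origin)
}

# small two-field scenario with a single 8 mm IS motion input, cached
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- small_phantom()
      m1 <- generate_motion_input(ph$ct, ph$structures$CTV,
                                  amplitude_mm = c(2, 3, 8), period_s = 3,
                                  id = "m1")
      cache <<- patient_scenario(ph$ct, ph$structures, list(m1))
    }
    cache
  }
})

small_plan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- plan_sfud(small_scenario())
    cache
  }
})
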