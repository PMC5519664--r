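test_that("phantom specs validate their invariants", {
  expect_error(phantom_spec("poiseuille", radius = -1), class = "flow4d_parameter_error")
  expect_error(phantom_spec("poiseuille", radius = 2, spacing = c(3, 3, 3)),
               class = "flow4d_parameter_error")
  expect_error(phantom_spec("branching", radius = c(10, 6)), class = "flow4d_parameter_error")
  expect_error(phantom_spec("branching", radius = c(10, 7, 5)),  # 7+5 > 10
               class = "flow4d_parameter_error")
  expect_error(phantom_spec("branching", flow_split = c(0.3, 0.3)),
               class = "flow4d_parameter_error")
})

test_that("Poiseuille phantom hits its analytic centreline speed and no-slip wall", {
  ph <- gen_phantom(phantom_spec("poiseuille", radius = 10, length = 30,
                                 spacing = c(0.885, 0.885, 1)))
  u_max <- 2 * ph$truth$Q / (pi * 0.01^2)
  expect_lt(abs(max(ph$field$values) / u_max - 1), 0.02)
  expect_equal(ph$truth$u_max, u_max)
  # velocity is exactly zero outside the mask (no-slip construction)
  out <- !ph$mask$values
  expect_equal(max(abs(ph$field$values[, , , 3, 1][out])), 0)
  # analytic self-consistency: EL = dP * Q with dP = 8 mu L Q / (pi R^4)
  mu <- 0.004
  dp <- 8 * mu * 0.03 * ph$truth$Q / (pi * 0.01^4)
  expect_equal(ph$truth$el, dp * ph$truth$Q, tolerance = 1e-12)
  expect_equal(ph$truth$wss, 4 * mu * ph$truth$Q / (pi * 0.01^3), tolerance = 1e-12)
})

test_that("rigid rotation phantom is strain-free with zero net through-flow", {
  rr <- gen_phantom(phantom_spec("rigid_rotation", radius = 8, length = 16,
                                 spacing = c(1, 1, 1)))
  expect_lt(compute_el(rr$field, 1, rr$mask)$el_total, 1e-10)
  q <- flow_rate(rr$field, 1, rr$mask,
                 list(origin = c(0, 0, 8), normal = c(0, 0, 1)))
  expect_lt(abs(q$volume_flow), 1e-12)
})

test_that("Womersley phantom reproduces its closed-form per-frame flow", {
  wm <- gen_phantom(phantom_spec("womersley", radius = 10, length = 16,
                                 spacing = c(1, 1, 1), frames = 8, alpha = 13))
  expect_equal(n_frames(wm$field), 8L)
  qs <- vapply(1:8, function(f) {
    flow_rate(wm$field, f, wm$mask,
              list(origin = c(0, 0, 8), normal = c(0, 0, 1)))$volume_flow
  }, numeric(1))
  # measured flow tracks the analytic waveform within 2% of its amplitude
  expect_lt(max(abs(qs - wm$truth$Q_t)) / wm$truth$Q_amp, 0.02)
  # alpha -> 0 limit sanity: profile energy concentrates like Poiseuille
  expect_equal(wm$truth$Q_t[1], wm$truth$Q_amp)
})

test_that("branching phantom conserves flow across the bifurcation", {
  ph <- gen_phantom(phantom_spec("branching", radius = c(10, 6, 3),
                                 flow_split = c(0.5, 0.5)))
  L <- ph$spec$length
  qin <- flow_rate(ph$field, 1, ph$mask,
                   list(origin = c(0, 0, L / 4), normal = c(0, 0, 1)))
  c1 <- ph$truth$child_centers[1, 1:2]
  # restrict the mask to child 1 alone: the cut plane is infinite, so the
  # full mask at 3L/4 would integrate both children
  ctr <- voxel_centers(ph$mask$geometry)
  in_c1 <- (ctr[, 1] - c1[1])^2 + (ctr[, 2] - c1[2])^2 <=
    ph$truth$child_radii[1]^2 & ctr[, 3] >= L / 2
  m1 <- binary_mask(array(in_c1, ph$mask$geometry$shape) & ph$mask$values,
                    ph$mask$geometry)
  q1 <- flow_rate(ph$field, 1, m1,
                  list(origin = c(c1[1], c1[2], 3 * L / 4), normal = c(0, 0, 1)))
  # plane through the whole cross-section at 3L/4 captures both children
  qout <- flow_rate(ph$field, 1, ph$mask,
                    list(origin = c(0, 0, 3 * L / 4), normal = c(0, 0, 1)))
  expect_equal(ph$truth$Q, sum(ph$truth$Q_children), tolerance = 1e-12)
  expect_lt(abs(qout$volume_flow / qin$volume_flow - 1), 0.03)
  # equal split: child 1 carries Q/2 within 5%
  expect_lt(abs(q1$volume_flow / (ph$truth$Q / 2) - 1), 0.05)
})

test_that("degrade_pcmri is the identity at matched spacing and zero noise", {
  ph <- gen_phantom(phantom_spec("poiseuille", radius = 6, length = 10,
                                 spacing = c(1, 1, 1)))
  spec <- degradation_spec(target_spacing = c(1, 1, 1), noise_sd = 0)
  dg <- degrade_pcmri(ph$field, ph$mask, spec)
  expect_equal(dg$values, ph$field$values, tolerance = 1e-14)
  expect_equal(dg$geometry$shape, ph$field$geometry$shape)
})

test_that("degradation is deterministic by seed and aliases beyond venc", {
  ph <- gen_phantom(phantom_spec("poiseuille", radius = 6, length = 10,
                                 spacing = c(1, 1, 1)))
  spec <- degradation_spec(target_spacing = c(1.25, 1.25, 2), noise_sd = 0.05,
                           venc = 1.5, seed = 9L)
  d1 <- degrade_pcmri(ph$field, ph$mask, spec)
  d2 <- degrade_pcmri(ph$field, ph$mask, spec)
  expect_identical(d1$values, d2$values)
  d3 <- degrade_pcmri(ph$field, ph$mask,
                      degradation_spec(target_spacing = c(1.25, 1.25, 2),
                                       noise_sd = 0.05, venc = 1.5, seed = 10L))
  expect_false(identical(d1$values, d3$values))
  # aliasing rule: a component at venc + 0.1 wraps to venc + 0.1 - 2 venc
  venc <- 0.4
  g <- grid_geometry(c(2, 2, 2), c(1, 1, 1))
  v <- array(0, c(2, 2, 2, 3)); v[, , , 3] <- venc + 0.1
  f <- velocity_field(v, g)
  wr <- degrade_pcmri(f, binary_mask(array(TRUE, c(2, 2, 2)), g),
                      degradation_spec(target_spacing = c(1, 1, 1),
                                       noise_sd = 0, venc = venc))
  expect_equal(wr$values[1, 1, 1, 3, 1], venc + 0.1 - 2 * venc, tolerance = 1e-12)
  expect_true(all(abs(wr$values) <= venc + 1e-12))
})

test_that("partial-volume averaging underestimates small-vessel flow, monotonically in radius", {
  uc <- underestimation_curve(c(2, 3, 5, 8),
                              template = phantom_spec("poiseuille",
                                                      spacing = c(0.5, 0.5, 0.5),
                                                      length = 16),
                              spec = degradation_spec(target_spacing = c(1.25, 1.25, 2)))
  # averaging with zeros cannot inflate net flow (no noise here)
  expect_true(all(uc$ratio <= 1 + 1e-9))
  # the smallest vessel is clearly underestimated
  expect_lt(uc$ratio[1], 0.97)
  # non-decreasing in radius, allowing one inversion
  inversions <- sum(diff(uc$ratio) < 0)
  expect_lte(inversions, 1)
  # at radius >> voxel, the ratio approaches 1
  expect_lt(abs(uc$ratio[4] - 1), 0.05)
})

test_that("a warning (not an error) marks grids coarser than the vessel", {
  ph <- gen_phantom(phantom_spec("poiseuille", radius = 3, length = 10,
                                 spacing = c(1, 1, 1)))
  expect_warning(
    degrade_pcmri(ph$field, ph$mask,
                  degradation_spec(target_spacing = c(7, 7, 7))),
    "partial-volume")
})
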