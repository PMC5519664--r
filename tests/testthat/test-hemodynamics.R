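test_that("sample_inner_velocity reproduces constant and linear fields exactly", {
  g <- grid_geometry(c(12, 12, 12), c(1, 1, 1))
  mask <- make_ball(4, 1)
  mesh <- extract_surface(mask)
  # constant field
  vc <- array(0, c(dim(mask$values), 3)); vc[, , , 1] <- 0.1
  fc <- velocity_field(vc, mask$geometry)
  s <- sample_inner_velocity(mesh, fc, depth = 5e-4)
  expect_true(all(s$valid))
  expect_equal(max(abs(sweep(s$velocity, 2, c(0.1, 0, 0)))), 0, tolerance = 1e-12)
  # linear field u = a . x is reproduced exactly by trilinear interpolation
  a <- c(2, -1, 0.5)  # 1/s
  ctr <- voxel_centers(mask$geometry)
  vl <- array(0, c(dim(mask$values), 3))
  vl[, , , 1] <- array(ctr %*% a * 1e-3, dim(mask$values))
  fl <- velocity_field(vl, mask$geometry)
  s2 <- sample_inner_velocity(mesh, fl, depth = 5e-4)
  pts <- face_centers(mesh) - 0.5 * mesh$normals   # mm
  want <- as.vector(pts %*% a * 1e-3)
  expect_equal(s2$velocity[, 1], want, tolerance = 1e-10)
  expect_equal(max(abs(s2$velocity[, 2:3])), 0)
  expect_error(sample_inner_velocity(mesh, fc, depth = 0), class = "flow4d_parameter_error")
})

test_that("compute_wss matches the hand-evaluated half-voxel gradient", {
  # single face with normal +z at z = 2 mm in a uniform (0.1, 0, 0) field:
  # sampling at depth 0.5 mm gives WSS = 0.004 * 0.1 / 0.0005 = 0.8 Pa
  g <- grid_geometry(c(5, 5, 5), c(1, 1, 1))
  v <- array(0, c(5, 5, 5, 3)); v[, , , 1] <- 0.1
  f <- velocity_field(v, g)
  mesh <- tri_mesh(rbind(c(1, 1, 2), c(3, 1, 2), c(1, 3, 2)),
                   rbind(c(1, 2, 3)))
  expect_equal(mesh$normals[1, ], c(0, 0, 1))
  w <- compute_wss(mesh, f, props = fluid_properties(mu = 0.004), depth = 5e-4)
  expect_equal(w$wss_magnitude[1], 0.8, tolerance = 1e-12)
  expect_equal(w$wss_vector[1, ], c(0.8, 0, 0), tolerance = 1e-12)
  # zero field -> zero WSS
  w0 <- compute_wss(mesh, velocity_field(array(0, c(5, 5, 5, 3)), g), depth = 5e-4)
  expect_equal(max(w0$wss_magnitude), 0)
  # mesh fully outside the grid -> all faces excluded -> error
  far <- tri_mesh(mesh$vertices + 100, mesh$faces)
  expect_error(compute_wss(far, f, depth = 5e-4), class = "flow4d_value_error")
})

test_that("WSS is tangential and magnitude-consistent on a pipe", {
  ph <- gen_phantom(phantom_spec("poiseuille", radius = 10, length = 30,
                                 spacing = c(1, 1, 1)))
  mesh <- extract_surface(ph$mask)
  w <- compute_wss(mesh, ph$field)
  ok <- w$valid
  dots <- abs(rowSums(w$wss_vector[ok, ] * mesh$normals[ok, ]))
  expect_lt(max(dots - 1e-6 * w$wss_magnitude[ok]), 1e-12)
  expect_equal(w$wss_magnitude[ok], sqrt(rowSums(w$wss_vector[ok, ]^2)))
})

test_that("strain_rate is exact on linear fields and strain-free on rotation", {
  g <- grid_geometry(c(8, 8, 8), c(1, 1, 1))
  mask <- binary_mask(array(TRUE, c(8, 8, 8)), g)
  ctr <- voxel_centers(g)
  # uniform translation
  vt <- array(0, c(8, 8, 8, 3)); vt[, , , 2] <- 0.3
  St <- strain_rate(velocity_field(vt, g), 1, mask)
  expect_equal(max(abs(St$tensor), na.rm = TRUE), 0)
  expect_true(all(St$valid))
  # rigid rotation about z: v = omega x r, S = 0
  om <- 10
  vr <- array(0, c(8, 8, 8, 3))
  vr[, , , 1] <- array(-om * ctr[, 2] * 1e-3, c(8, 8, 8))
  vr[, , , 2] <- array(om * ctr[, 1] * 1e-3, c(8, 8, 8))
  Sr <- strain_rate(velocity_field(vr, g), 1, mask)
  expect_lt(max(abs(Sr$tensor), na.rm = TRUE), 1e-10)
  # simple shear u_x = gamma * y with gamma = 100/s
  vs <- array(0, c(8, 8, 8, 3))
  vs[, , , 1] <- array(100 * ctr[, 2] * 1e-3, c(8, 8, 8))
  Ss <- strain_rate(velocity_field(vs, g), 1, mask)
  expect_equal(Ss$tensor[4, 4, 4, 1, 2], 50, tolerance = 1e-8)
  expect_equal(Ss$tensor[4, 4, 4, 2, 1], 50, tolerance = 1e-8)
  expect_equal(Ss$tensor[4, 4, 4, 1, 1], 0)
  expect_equal(Ss$tensor[4, 4, 4, 3, 3], 0)
  # symmetry by construction everywhere
  expect_identical(Ss$tensor[, , , 1, 2], Ss$tensor[, , , 2, 1])
  bad <- binary_mask(array(TRUE, c(2, 2, 2)), grid_geometry(c(2, 2, 2), c(1, 1, 1)))
  expect_error(strain_rate(velocity_field(vs, g), 1, bad), class = "flow4d_shape_error")
})

test_that("eddy viscosities match hand evaluations of the closure formulas", {
  g <- grid_geometry(c(3, 3, 3), c(1, 1, 1))
  kv <- scalar_volume(array(0.01, c(3, 3, 3)), g, unit = "m^2/s^2")
  ev <- scalar_volume(array(0.1, c(3, 3, 3)), g, unit = "m^2/s^3")
  mu_t <- eddy_viscosity_rng(kv, ev, fluid_properties(rho = 1060),
                             closure_model("rng_k_epsilon", c_mu = 0.0845))
  expect_equal(mu_t$values[2, 2, 2], 0.0845 * 1060 * 0.01^2 / 0.1,
               tolerance = 1e-10)
  # k = 0 -> 0; doubling k quadruples mu_t
  k0 <- scalar_volume(array(0, c(3, 3, 3)), g, unit = "m^2/s^2")
  expect_equal(max(eddy_viscosity_rng(k0, ev)$values), 0)
  k2 <- scalar_volume(array(0.02, c(3, 3, 3)), g, unit = "m^2/s^2")
  expect_equal(eddy_viscosity_rng(k2, ev)$values[1, 1, 1] / mu_t$values[1, 1, 1], 4,
               tolerance = 1e-12)
  # epsilon below the floor -> 0, not Inf
  e0 <- scalar_volume(array(0, c(3, 3, 3)), g, unit = "m^2/s^3")
  expect_equal(max(eddy_viscosity_rng(kv, e0)$values), 0)
  expect_error(eddy_viscosity_rng(ev, ev), class = "flow4d_parameter_error")

  # LES: simple shear gamma = 100/s, Cs = 0.1, delta = 1 mm -> 1e-6 Pa s
  gg <- grid_geometry(c(8, 8, 8), c(1, 1, 1))
  ctr <- voxel_centers(gg)
  vs <- array(0, c(8, 8, 8, 3))
  vs[, , , 1] <- array(100 * ctr[, 2] * 1e-3, c(8, 8, 8))
  S <- strain_rate(velocity_field(vs, gg), 1,
                   binary_mask(array(TRUE, c(8, 8, 8)), gg))
  mu_les <- eddy_viscosity_les(S, closure_model("les_smagorinsky", c_s = 0.1,
                                                delta = 1e-3))
  expect_equal(mu_les$values[4, 4, 4], 1e-6, tolerance = 1e-10)
  # rotation and uniform flow give zero
  vr <- array(0, c(8, 8, 8, 3))
  vr[, , , 1] <- array(-10 * ctr[, 2] * 1e-3, c(8, 8, 8))
  vr[, , , 2] <- array(10 * ctr[, 1] * 1e-3, c(8, 8, 8))
  Sr <- strain_rate(velocity_field(vr, gg), 1,
                    binary_mask(array(TRUE, c(8, 8, 8)), gg))
  expect_lt(max(eddy_viscosity_les(Sr)$values), 1e-15)
})

test_that("compute_el agrees with the brute-force dissipation oracle", {
  fx <- make_random_field(c(6, 6, 6), seed = 99)
  el <- compute_el(fx$field, 1, fx$mask, props = fluid_properties(mu = 0.004))
  want <- oracle_el_laminar(fx$field$values[, , , , 1], fx$mask$values,
                            fx$geometry$spacing, mu = 0.004)
  expect_equal(el$el_total, want, tolerance = 1e-12)
  # compartments partition the total exactly
  expect_equal(el$el_total, el$el_boundary_layer + el$el_core, tolerance = 1e-9)
  expect_gte(el$el_boundary_layer, 0)
  expect_gte(el$el_core, 0)
})

test_that("EL vanishes for strain-free fields and is closure-monotone", {
  # uniform translation
  g <- grid_geometry(c(8, 8, 8), c(1, 1, 1))
  mask <- binary_mask(array(TRUE, c(8, 8, 8)), g)
  vt <- array(0, c(8, 8, 8, 3)); vt[, , , 1] <- 0.4
  expect_lt(compute_el(velocity_field(vt, g), 1, mask)$el_total, 1e-10)
  # rigid rotation phantom
  rr <- gen_phantom(phantom_spec("rigid_rotation", radius = 8, length = 16,
                                 spacing = c(1, 1, 1)))
  expect_lt(compute_el(rr$field, 1, rr$mask)$el_total, 1e-10)
  # closure monotonicity on a sheared random field
  fx <- make_random_field(c(7, 7, 7), seed = 3)
  lam <- compute_el(fx$field, 1, fx$mask, model = closure_model("laminar"))
  les <- compute_el(fx$field, 1, fx$mask, model = closure_model("les_smagorinsky"))
  expect_lte(lam$el_total, les$el_total)
  mu_t <- scalar_volume(array(0.001, fx$geometry$shape), fx$geometry, unit = "Pa.s")
  rng <- compute_el(fx$field, 1, fx$mask, model = closure_model("rng_k_epsilon"),
                    mu_t = mu_t)
  expect_lte(lam$el_total, rng$el_total)
  expect_error(compute_el(fx$field, 1, fx$mask,
                          model = closure_model("rng_k_epsilon")),
               class = "flow4d_parameter_error")
})

test_that("halving the voxel size shrinks the EL discretization error", {
  err <- vapply(c(1, 0.5), function(h) {
    ph <- gen_phantom(phantom_spec("poiseuille", radius = 10, length = 30,
                                   spacing = c(h, h, h)))
    el <- compute_el(ph$field, 1, ph$mask)
    abs(el$el_total / ph$truth$el - 1)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("boundary_layer_mask equals the brute-force erosion complement", {
  g <- grid_geometry(c(7, 7, 7), c(1, 1, 1))
  m <- array(FALSE, c(7, 7, 7))
  m[2:6, 2:6, 2:6] <- TRUE  # solid 5^3 cube
  bl <- boundary_layer_mask(binary_mask(m, g))
  expect_equal(sum(bl$values), 5^3 - 3^3)  # 98
  # brute-force: boundary = in-mask voxels with a 6-neighbour outside
  brute <- array(FALSE, c(7, 7, 7))
  for (i in 2:6) for (j in 2:6) for (k in 2:6) {
    nb <- rbind(c(i + 1, j, k), c(i - 1, j, k), c(i, j + 1, k),
                c(i, j - 1, k), c(i, j, k + 1), c(i, j, k - 1))
    brute[i, j, k] <- any(!m[nb])
  }
  expect_identical(bl$values, brute)
  # 1-voxel slab: everything is boundary; partition property
  slab <- array(FALSE, c(7, 7, 7)); slab[2:6, 2:6, 4] <- TRUE
  bls <- boundary_layer_mask(binary_mask(slab, g))
  expect_identical(bls$values, slab)
  core <- m & !bl$values
  expect_identical(bl$values | core, m)
  expect_false(any(bl$values & core))
  expect_error(boundary_layer_mask(binary_mask(array(FALSE, c(7, 7, 7)), g)),
               class = "flow4d_value_error")
})

test_that("flow_rate integrates a Poiseuille pipe to its analytic flow", {
  ph <- gen_phantom(phantom_spec("poiseuille", radius = 10, length = 30,
                                 spacing = c(1, 1, 1)))
  pl <- list(origin = c(0, 0, 15), normal = c(0, 0, 1))
  q <- flow_rate(ph$field, 1, ph$mask, pl, fluid_properties(rho = 1060))
  expect_lt(abs(q$volume_flow / 8.333e-5 - 1), 0.05)
  expect_lt(abs(q$mass_flow / 0.0883 - 1), 0.05)
  # flipping the normal negates both flows exactly
  q2 <- flow_rate(ph$field, 1, ph$mask,
                  list(origin = c(0, 0, 15), normal = c(0, 0, -1)))
  expect_equal(q2$volume_flow, -q$volume_flow)
  # zero field -> zero flow
  z <- velocity_field(array(0, dim(ph$field$values)[1:4]), ph$field$geometry)
  expect_equal(flow_rate(z, 1, ph$mask, pl)$mass_flow, 0)
  # plane entirely outside the lumen -> error
  expect_error(flow_rate(ph$field, 1, ph$mask,
                         list(origin = c(0, 0, 200), normal = c(0, 0, 1))),
               class = "flow4d_value_error")
})

test_that("interpolate_waveform is an exact interpolant with small mid-knot error", {
  t <- seq(0, 0.95, by = 0.05)
  fl <- sin(2 * pi * t)
  w <- interpolate_waveform(t, fl)
  expect_equal(w(t), fl)  # exact at knots
  mid <- t[-1] - 0.025
  expect_lt(max(abs(w(mid) - sin(2 * pi * mid))), 0.01)
  # constant samples -> constant function
  wc <- interpolate_waveform(t, rep(2.5, length(t)))
  expect_equal(wc(seq(0, 0.9, by = 0.01)), rep(2.5, 91), tolerance = 1e-12)
  expect_error(w(1.2), class = "flow4d_value_error")
  expect_error(interpolate_waveform(c(0, 1, 2), c(1, 2, 3)),
               class = "flow4d_parameter_error")
  expect_error(interpolate_waveform(c(0, 2, 1, 3), 1:4), class = "flow4d_value_error")
})
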