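test_that("resample_to_grid is the identity on the source grid and exact on linear fields", {
  fx <- make_random_field(c(6, 6, 6), seed = 7)
  rs <- resample_to_grid(fx$field, fx$geometry, fx$mask)
  idx <- which(fx$mask$values)
  for (d in 1:3)
    expect_equal(rs$values[, , , d, 1][idx], fx$field$values[, , , d, 1][idx])
  expect_true(all(is.na(rs$values[, , , 1, 1][!fx$mask$values])))
  # linear field sampled on a finer grid resamples exactly
  a <- c(1.5, -0.7, 0.3)
  src_g <- grid_geometry(c(11, 11, 11), c(1, 1, 1))
  vals <- array(0, c(11, 11, 11, 3))
  vals[, , , 2] <- array(voxel_centers(src_g) %*% a * 1e-3, c(11, 11, 11))
  src <- velocity_field(vals, src_g)
  tgt <- grid_geometry(c(5, 5, 5), c(1.7, 1.7, 1.7), origin = c(0.4, 0.6, 0.2))
  tmask <- binary_mask(array(TRUE, c(5, 5, 5)), tgt)
  out <- resample_to_grid(src, tgt, tmask)
  want <- voxel_centers(tgt) %*% a * 1e-3
  expect_equal(as.vector(out$values[, , , 2, 1]), as.vector(want), tolerance = 1e-10)
  # no overlap -> error
  far <- grid_geometry(c(3, 3, 3), c(1, 1, 1), origin = c(500, 500, 500))
  expect_error(resample_to_grid(src, far, binary_mask(array(TRUE, c(3, 3, 3)), far)),
               class = "flow4d_value_error")
})

test_that("point-cloud sources are accepted (inverse-distance fallback)", {
  set.seed(4)
  pc <- data.frame(x = runif(300, 0, 10), y = runif(300, 0, 10),
                   z = runif(300, 0, 10))
  pc$u <- 0.2; pc$v <- 0; pc$w <- -0.1
  tgt <- grid_geometry(c(4, 4, 4), c(2, 2, 2), origin = c(2, 2, 2))
  tmask <- binary_mask(array(TRUE, c(4, 4, 4)), tgt)
  out <- resample_to_grid(pc, tgt, tmask)
  expect_equal(unique(round(as.vector(out$values[, , , 1, 1]), 12)), 0.2)
  expect_equal(unique(round(as.vector(out$values[, , , 3, 1]), 12)), -0.1)
})

test_that("partition_regions splits a straight tube into even thirds", {
  ph <- gen_phantom(phantom_spec("poiseuille", radius = 8, length = 60,
                                 spacing = c(1, 1, 1)))
  part <- partition_regions(ph$mask,
                            list(origin = c(0, 0, 20), normal = c(0, 0, 1)),
                            list(origin = c(0, 0, 40), normal = c(0, 0, 1)))
  counts <- table(factor(part$labels[ph$mask$values],
                         levels = c("AAo", "Arch", "DAo")))
  total <- sum(ph$mask$values)
  expect_equal(sum(counts), total)  # labels partition the mask
  for (nm in names(counts))
    expect_lt(abs(counts[[nm]] / (total / 3) - 1), 0.05)
  expect_true(all(part$labels[!ph$mask$values] == "excluded"))
  # planes beyond the grid on one side -> single region
  part1 <- partition_regions(ph$mask,
                             list(origin = c(0, 0, 200), normal = c(0, 0, 1)),
                             list(origin = c(0, 0, 300), normal = c(0, 0, 1)))
  expect_equal(unname(table(part1$labels[ph$mask$values])[["AAo"]]), total)
  expect_error(partition_regions(ph$mask,
                                 list(origin = c(0, 0, 20), normal = c(0, 0, 1)),
                                 list(origin = c(0, 0, 20), normal = c(0, 0, 1))),
               class = "flow4d_parameter_error")
})

make_partition <- function(mask) {
  zr <- range(voxel_centers(mask$geometry)[, 3])
  cuts <- zr[1] + diff(zr) * c(1, 2) / 3
  partition_regions(mask,
                    list(origin = c(0, 0, cuts[1]), normal = c(0, 0, 1)),
                    list(origin = c(0, 0, cuts[2]), normal = c(0, 0, 1)))
}

test_that("compare_fields: self-comparison, anti-correlation, constant offset", {
  fx <- make_random_field(c(6, 6, 9), seed = 31)
  part <- make_partition(fx$mask)
  self <- compare_fields(fx$field, fx$field, part)
  expect_equal(self$r, rep(1, 9), tolerance = 1e-12)
  expect_true(all(self$mean_abs_error == 0))
  expect_true(all(self$n >= 2))
  neg <- velocity_field(-fx$field$values, fx$geometry)
  expect_equal(compare_fields(fx$field, neg, part)$r, rep(-1, 9),
               tolerance = 1e-12)
  # offset on one component: r stays 1, mae = offset, sd = 0
  vo <- fx$field$values
  vo[, , , 2, ] <- vo[, , , 2, ] + 0.05
  off <- compare_fields(fx$field, velocity_field(vo, fx$geometry), part)
  vrow <- off[off$component == "v (RL)", ]
  expect_true(all(vrow$r == 1))
  expect_equal(vrow$mean_abs_error, rep(0.05, 3), tolerance = 1e-12)
  expect_equal(vrow$sd_abs_error, rep(0, 3), tolerance = 1e-12)
})

test_that("Pearson r matches the textbook formula and is affine-invariant", {
  fx <- make_random_field(c(6, 6, 9), seed = 13)
  fy <- make_random_field(c(6, 6, 9), seed = 14)
  fy$field <- velocity_field(fy$field$values, fx$geometry)
  part <- make_partition(fx$mask)
  rep1 <- compare_fields(fx$field, fy$field, part)
  # oracle: textbook sum formula per region/component
  for (reg in c("AAo", "Arch", "DAo")) {
    in_reg <- part$labels == reg
    for (d in 1:3) {
      x <- fx$field$values[, , , d, 1][in_reg]
      y <- fy$field$values[, , , d, 1][in_reg]
      want <- oracle_pearson(x, y)
      got <- rep1$r[rep1$region == reg][d]
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # affine rescaling of one field leaves r unchanged
  aff <- velocity_field(0.35 * fy$field$values + 0.12, fx$geometry)
  rep2 <- compare_fields(fx$field, aff, part)
  expect_equal(rep2$r, rep1$r, tolerance = 1e-12)
  # symmetry
  rep3 <- compare_fields(fy$field, fx$field, part)
  expect_equal(rep3$r, rep1$r, tolerance = 1e-12)
  expect_equal(rep3$mean_abs_error, rep1$mean_abs_error, tolerance = 1e-12)
})

test_that("agreement degrades where PC-MRI underestimates: small branch r < trunk r", {
  ph <- gen_phantom(phantom_spec("branching", spacing = c(0.5, 0.5, 0.5),
                                 length = 40))
  dspec <- degradation_spec(target_spacing = c(1.25, 1.25, 2), noise_sd = 0.02,
                            seed = 5L)
  deg <- degrade_pcmri(ph$field, ph$mask, dspec)
  dm <- coarsen_mask(ph$mask, dspec)
  clean <- resample_to_grid(ph$field, deg$geometry, dm)
  ctr <- voxel_centers(deg$geometry)
  w_deg <- deg$values[, , , 3, 1]
  w_cln <- clean$values[, , , 3, 1]
  zsplit <- ph$truth$z_split
  trunk <- dm$values & array(ctr[, 3] < zsplit - 2, deg$geometry$shape)
  c2 <- ph$truth$child_centers[2, 1:2]
  r2 <- ph$truth$child_radii[2]
  branch <- dm$values &
    array((ctr[, 1] - c2[1])^2 + (ctr[, 2] - c2[2])^2 <= r2^2 &
            ctr[, 3] > zsplit + 2, deg$geometry$shape)
  r_of <- function(sel) {
    ok <- sel & !is.na(w_cln)
    stats::cor(w_deg[ok], w_cln[ok])
  }
  expect_gt(sum(branch), 20)
  expect_gt(r_of(trunk), r_of(branch))
})

test_that("regions with too few joint samples report NA cells, not errors", {
  g <- grid_geometry(c(4, 4, 6), c(1, 1, 1))
  m <- array(FALSE, c(4, 4, 6))
  m[2, 2, 1] <- TRUE  # a single AAo voxel
  m[, , 5:6] <- TRUE
  vals <- array(rnorm(4 * 4 * 6 * 3), c(4, 4, 6, 3))
  f <- velocity_field(vals, g)
  part <- partition_regions(binary_mask(m, g),
                            list(origin = c(0, 0, 2.5), normal = c(0, 0, 1)),
                            list(origin = c(0, 0, 3.5), normal = c(0, 0, 1)))
  rep1 <- compare_fields(f, f, part)
  aao <- rep1[rep1$region == "AAo", ]
  expect_true(all(is.na(aao$r)))
  expect_true(all(aao$n == 1))
  expect_true(all(rep1$n[rep1$region == "DAo"] > 2))
})
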