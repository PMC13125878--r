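# dose sampling, DVH, D_v, delta-D

test_that("trilinear sampling is exact on uniform and linear fields", {
  spec <- phantom_spec(list(sphere_primitive("S", c(40, 40, 40), 15)),
                       grid_shape = c(40, 40, 40), spacing = 2)
  s <- render_mask(spec, "S")
  du <- render_dose(spec, "uniform", level = 10)
  sd_u <- sample_dose(s, du)
  expect_true(all(sd_u$doses == 10))
  expect_equal(sd_u$voxel_volume_cc, 8 / 1000)
  # voxel centers coincide with dose nodes: samples equal node values
  dgauss <- render_dose(spec, "gaussian", peak = 30, width = 25)
  sd_g <- sample_dose(s, dgauss)
  expect_equal(sd_g$doses, dgauss$values[which(s$data)])
  # off-lattice structure on a linear field: exact plane values
  s_off <- structure_mask(s$data, s$spacing, origin = c(0.73, 0.31, 0.57))
  dg <- render_dose(spec, "linear_gradient", level = 30,
                    gradient = c(0.2, -0.1, 1), ref_point = c(40, 40, 40))
  sd_l <- sample_dose(s_off, dg)
  pts <- cardiomotion:::voxel_coords(s_off)
  want <- 30 + 0.2 * (pts[, 1] - 40) - 0.1 * (pts[, 2] - 40) +
    1 * (pts[, 3] - 40)
  expect_lt(max(abs(sd_l$doses - want)), 1e-9)
  # structure outside the dose extent
  s_out <- structure_mask(s$data, s$spacing, origin = c(500, 0, 0))
  expect_error(sample_dose(s_out, dg), "geometry error")
})

test_that("DVH is a valid cumulative curve", {
  cv <- dvh(rep(10, 1000), voxel_volume_cc = 0.008)
  expect_equal(cv$volume_cc[1], 8)
  expect_equal(cv$volume_pct[1], 100)
  expect_true(all(cv$volume_cc[cv$dose_gy <= 10] == 8))
  expect_true(all(cv$volume_cc[cv$dose_gy > 10] == 0))
  expect_true(all(diff(cv$volume_cc) <= 0))
  # linear gradient on a box: V(d) linear between the extremes
  z <- rep(seq(0, 50, by = 1), each = 100)
  doses <- 10 + z  # 1 Gy/mm slab
  cv2 <- dvh(doses, 0.01, bin_width_gy = 1)
  mid <- cv2$dose_gy >= 11 & cv2$dose_gy <= 59
  expect_lt(max(abs(diff(cv2$volume_cc[mid]) - (-1))), 1e-9)
})

test_that("d_cc accumulates the hottest volume with interpolation", {
  expect_equal(d_cc(rep(10, 500), 0.001, 0.03), 10)
  expect_equal(d_cc(c(60, 50, 40), 0.01, 0.03), 40, tolerance = 1e-9)
  expect_equal(d_cc(c(60, 50, 40), 0.01, 0.025), 45, tolerance = 1e-9)
  expect_equal(d_cc(c(60, 50, 40), 0.01, 0.005), 60)  # sub-voxel: max dose
  # monotone non-increasing in v_cc
  set.seed(2)
  doses <- runif(200, 0, 70)
  vals <- vapply(c(0.01, 0.03, 0.1, 0.5), function(v) d_cc(doses, 0.004, v),
                 numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  # volume precondition
  expect_error(d_cc(c(60, 50), 0.01, 0.03), "undefined metric")
})

test_that("delta_d is the IRV minus reference near-maximum dose", {
  spec <- phantom_spec(list(sphere_primitive("S", c(40, 40, 30), 10)),
                       grid_shape = c(40, 40, 40), spacing = 2)
  ref <- render_mask(spec, "S")
  irv <- expand_structure(ref, c(0, 0, 0, 0, 20, 0))  # superior 20 mm
  # gradient increasing superiorly: the IRV reaches higher dose
  dg <- render_dose(spec, "linear_gradient", level = 10, gradient = c(0, 0, 1),
                    ref_point = c(0, 0, 40))
  dd <- delta_d(ref, irv, dg)
  expect_gt(dd$delta, 0)
  expect_equal(dd$d_irv - dd$d_ref, dd$delta)
  # identity and uniform-dose cases
  expect_equal(delta_d(ref, ref, dg)$delta, 0)
  du <- render_dose(spec, "uniform", level = 10)
  expect_equal(delta_d(ref, irv, du)$delta, 0)
  # superset requirement enforced
  shrunk <- structure_mask(ref$data & rev(ref$data), ref$spacing, ref$origin)
  expect_error(delta_d(irv, ref, dg), "superset")
})

test_that("superset monotonicity: delta_d >= 0 over random configurations", {
  set.seed(4)
  for (i in 1:20) {
    blob <- random_blob_mask(n = 22, spacing = c(1.5, 1.5, 2),
                             seed = 100 + i)
    m <- runif(6, 0, 4)
    names(m) <- c("right", "left", "anterior", "posterior", "superior",
                  "inferior")
    irv <- suppressWarnings(expand_structure(blob, m))
    geom <- list(grid_shape = dim(blob$data), spacing = blob$spacing,
                 origin = blob$origin)
    dose <- if (i %% 2 == 0) {
      render_dose(geom, "gaussian", peak = runif(1, 10, 60),
                  center = runif(3, 5, 30), width = runif(1, 5, 20))
    } else {
      render_dose(geom, "linear_gradient", level = runif(1, 5, 40),
                  gradient = runif(3, -0.5, 0.5))
    }
    dd <- delta_d(blob, irv, dose)
    expect_gte(dd$delta, -1e-9)
    # DVH of the superset dominates at every absolute-volume level
    sr <- sample_dose(blob, dose); si <- sample_dose(irv, dose)
    for (d0 in quantile(sr$doses, c(0.2, 0.5, 0.8))) {
      expect_gte(sum(si$doses >= d0) * si$voxel_volume_cc,
                 sum(sr$doses >= d0) * sr$voxel_volume_cc)
    }
  }
})
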