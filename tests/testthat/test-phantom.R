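# synthetic signal + mask + dose generation

test_that("respiratory waveform is periodic, reproducible, and centered", {
  wf <- generate_respiratory_waveform(duration = 20, dt = 0.2, period = 4,
                                      amplitude = 2, baseline = 1)
  # exact periodicity when noise and drift are off
  n_per <- 4 / 0.2
  expect_equal(wf$amplitudes[1:n_per], wf$amplitudes[1:n_per + n_per],
               tolerance = 1e-12)
  # maxima at end-inhale (period/2 + k*period)
  expect_equal(wf$times[which.max(wf$amplitudes)] %% 4, 2)
  # sample mean over whole periods equals the midline
  amps <- wf$amplitudes[-length(wf$amplitudes)]  # drop duplicated endpoint
  expect_equal(mean(amps), 1 + 2 / 2, tolerance = 1e-9)
  # determinism under a fixed seed (with noise on)
  w1 <- generate_respiratory_waveform(duration = 30, dt = 0.1, noise_sd = 0.1,
                                      seed = 7)
  w2 <- generate_respiratory_waveform(duration = 30, dt = 0.1, noise_sd = 0.1,
                                      seed = 7)
  expect_identical(w1$amplitudes, w2$amplitudes)
  # parameter errors
  expect_error(generate_respiratory_waveform(period = -1), "period")
  expect_error(generate_respiratory_waveform(dt = 0.5, period = 4),
               "period/10")
})

test_that("cardiac triggers cover the record with the stated RR model", {
  tr <- generate_cardiac_triggers(duration = 60, mean_rr = 1)
  expect_equal(tr$trigger_times, 0:60)
  expect_true(all(diff(tr$trigger_times) == 1))
  # Monte-Carlo check of the jitter model
  tr2 <- generate_cardiac_triggers(duration = 1100, mean_rr = 1,
                                   rr_jitter_sd = 0.05, seed = 11)
  ints <- diff(tr2$trigger_times)
  expect_gt(length(ints), 1000)
  expect_lt(abs(sd(ints) - 0.05) / 0.05, 0.2)
  expect_true(all(ints > 0))
  # determinism
  tr3 <- generate_cardiac_triggers(duration = 1100, mean_rr = 1,
                                   rr_jitter_sd = 0.05, seed = 11)
  expect_identical(tr2$trigger_times, tr3$trigger_times)
  expect_error(generate_cardiac_triggers(duration = 0.5, mean_rr = 1),
               "duration")
})

test_that("render_mask obeys the voxel-center rule", {
  spec <- phantom_spec(list(sphere_primitive("S", c(35, 35, 35), 10)),
                       grid_shape = c(45, 45, 45), spacing = 1.56)
  m0 <- render_mask(spec, "S")
  # volume vs analytic sphere
  vol <- sum(m0$data) * prod(m0$spacing)
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  # exact lattice translation
  m1 <- render_mask(spec, "S", displacement = c(1.56, 0, 0))
  expect_identical(m1$data[2:45, , ], m0$data[1:44, , ])
  expect_false(any(m1$data[1, , ]))
  # volume quasi-invariance under arbitrary sub-voxel translation: the
  # deviation is lattice-quantization noise, bounded well below the
  # boundary-voxel count (~3% of the volume for r = 10 mm at 1.56 mm)
  set.seed(3)
  for (i in 1:5) {
    mt <- render_mask(spec, "S", displacement = runif(3, -2, 2))
    expect_lt(abs(sum(mt$data) - sum(m0$data)) / sum(m0$data), 0.03)
  }
  # degenerate and out-of-bounds geometry
  expect_error(sphere_primitive("Z", c(0, 0, 0), 0), "radius")
  expect_error(render_mask(spec, "S", displacement = c(40, 0, 0)),
               "geometry error")
})

test_that("phase grid applies cardiac + respiratory + hysteresis displacement", {
  spec <- small_phantom()
  # hysteresis 0: the loop degenerates, AEx and AIn masks identical
  g0 <- render_phase_grid(spec, motion_model(c(-5, 3, -3), c(0, 1, -4), 0))
  for (sub in c("LV", "RCA"))
    for (cp in c("ED", "ES"))
      expect_identical(g0$masks[[sub]][[cp]][["AEx"]]$data,
                       g0$masks[[sub]][[cp]][["AIn"]]$data)
  # zero cardiac amplitude: ED and ES identical within each state
  g1 <- render_phase_grid(spec, motion_model(c(0, 0, 0), c(0, 1, -4), 3))
  for (rs in c("EE", "AEx", "AIn", "EI"))
    expect_identical(g1$masks$LV$ED[[rs]]$data, g1$masks$LV$ES[[rs]]$data)
  # ground truth records the injected respiratory displacement exactly
  m <- motion_model(c(-5, 3, -3), c(0, 0, -6), 2)
  g2 <- render_phase_grid(spec, m)
  gt <- g2$ground_truth
  for (cp in c("ED", "ES")) {
    ee <- gt[gt$substructure == "LV" & gt$cardiac == cp & gt$resp == "EE", ]
    ei <- gt[gt$substructure == "LV" & gt$cardiac == cp & gt$resp == "EI", ]
    expect_equal(ei$si_mm - ee$si_mm, -6)
    expect_equal(ei$rl_mm - ee$rl_mm, 0)
  }
})

test_that("hysteresis loop closes at the respiratory extremes", {
  m <- motion_model(c(0, 0, 0), c(0, 1, -4), hysteresis = 5)
  for (ph in c(0, 1)) {
    d_in <- phase_displacement(m, "ED", list(phase = ph, limb = +1))
    d_ex <- phase_displacement(m, "ED", list(phase = ph, limb = -1))
    expect_lt(max(abs(d_in - d_ex)), 1e-9)
  }
  # mid-respiration separation equals the hysteresis parameter
  d_in <- phase_displacement(m, "ED", "AIn")
  d_ex <- phase_displacement(m, "ED", "AEx")
  expect_equal(sqrt(sum((d_in - d_ex)^2)), 5, tolerance = 1e-12)
  # the offset is perpendicular to the respiratory axis
  expect_lt(abs(sum((d_in - d_ex) * c(0, 1, -4))), 1e-9)
})

test_that("cohort simulation is deterministic under a fixed seed", {
  c1 <- simulate_cohort(small_phantom(), n_subjects = 2, seed = 5,
                        cardiac_sd = 0.5, resp_sd = 0.5)
  c2 <- simulate_cohort(small_phantom(), n_subjects = 2, seed = 5,
                        cardiac_sd = 0.5, resp_sd = 0.5)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(c1$subjects$S01$masks$LV$ES$EI$data,
                   c2$subjects$S01$masks$LV$ES$EI$data)
})

test_that("render_dose modes match their closed forms", {
  spec <- small_phantom()
  du <- render_dose(spec, "uniform", level = 10)
  expect_true(all(du$values == 10))
  # linear gradient: 1 Gy/mm along SI, 30 Gy at the reference plane
  z0 <- 70
  dg <- render_dose(spec, "linear_gradient", level = 30,
                    gradient = c(0, 0, 1), ref_point = c(0, 0, z0))
  k <- which.min(abs(spec$spacing[3] * (0:47) - (z0 + 5)))  # a voxel plane
  z <- spec$spacing[3] * (k - 1)
  expect_equal(dg$values[1, 1, k], 30 + (z - z0), tolerance = 1e-12)
  dgauss <- render_dose(spec, "gaussian", peak = 40, width = 25)
  expect_lte(max(dgauss$values), 40)
  expect_true(all(dgauss$values >= 0))
  expect_error(render_dose(spec, "uniform", level = -5), "parameter error")
})
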