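# excursion metrics: centroid/face displacements, decoupled motion,
# hysteresis, surface distances, MDA/HD95, threshold flags

test_that("centroid displacement components and vector", {
  m <- random_blob_mask(n = 20, spacing = c(1, 1, 1), seed = 1)
  expect_equal(unlist(centroid_displacement(m, m))[1:4],
               c(rl = 0, ap = 0, si = 0, vector = 0))
  # exact lattice shift (+3 RL, +4 AP): Pythagorean vector
  a <- array(FALSE, dim = c(20, 20, 20))
  idx <- which(m$data, arr.ind = TRUE)
  keep <- idx[, 1] <= 17 & idx[, 2] <= 16
  a[cbind(idx[keep, 1] + 3, idx[keep, 2] + 4, idx[keep, 3])] <- TRUE
  b0 <- structure_mask(m$data & array(TRUE, dim(m$data)), m$spacing)
  b0$data[] <- FALSE
  b0$data[idx[keep, , drop = FALSE]] <- TRUE
  b1 <- structure_mask(a, m$spacing)
  d <- centroid_displacement(b0, b1)
  expect_equal(c(d$rl, d$ap, d$si, d$vector), c(3, 4, 0, 5))
  # antisymmetry
  dr <- centroid_displacement(b1, b0)
  expect_equal(c(dr$rl, dr$ap, dr$si), -c(d$rl, d$ap, d$si))
})

test_that("face displacements are signed per-face shifts", {
  b <- box_mask(20, c(5, 10), c(6, 11), c(7, 12), spacing = 1.56)
  a <- array(FALSE, dim = c(20, 20, 20))
  a[5:10, 6:11, (7:12) - 4] <- TRUE  # rigid -4 voxels SI = -6.24 mm
  b2 <- structure_mask(a, 1.56)
  f <- face_displacements(b, b2)
  expect_equal(f$faces[["superior"]], -6.24)
  expect_equal(f$faces[["inferior"]], -6.24)
  expect_equal(unname(f$faces[c("right", "left", "anterior", "posterior")]),
               rep(0, 4))
  expect_equal(f$max_abs, 6.24)
  expect_equal(f$mean_abs, 6.24 * 2 / 6)
  # identity
  expect_equal(face_displacements(b, b)$max_abs, 0)
  # 1-voxel isotropic dilation: every face moves outward one spacing
  grown <- box_mask(20, c(4, 11), c(5, 12), c(6, 13), spacing = 1.56)
  fg <- face_displacements(b, grown)$faces
  expect_equal(unname(fg[c("right", "anterior", "superior")]), rep(1.56, 3))
  expect_equal(unname(fg[c("left", "posterior", "inferior")]), rep(-1.56, 3))
})

test_that("decoupled motion averages within fixed states of the other cycle", {
  # equal ED->ES motion in all four respiratory states
  spec <- small_phantom()
  g <- render_phase_grid(spec, motion_model(c(0, 0, -4), c(0, 1, -3), 2))
  cm <- cardiac_motion(g, "LV")
  expect_lt(max(abs(c(cm$displacement$rl, cm$displacement$ap,
                      cm$displacement$si) - c(0, 0, -4))), 0.5)
  expect_lt(abs(cm$displacement$vector - 4), 0.5)
  expect_identical(sort(cm$states_used), sort(c("EE", "AEx", "AIn", "EI")))
  # mean-of-norms vs norm-of-means: two states with opposite +-2 RL shifts
  base <- box_mask(24, c(8, 14), c(8, 14), c(8, 14), spacing = 1)
  sh <- function(di) {
    a <- array(FALSE, dim = c(24, 24, 24))
    a[(8:14) + di, 8:14, 8:14] <- TRUE
    structure_mask(a, 1)
  }
  grid <- make_grid(list(X = list(
    ED = list(EE = base, EI = base),
    ES = list(EE = sh(2), EI = sh(-2)))),
    resp_states = c("EE", "EI"))
  cm2 <- cardiac_motion(grid, "X")
  expect_equal(cm2$displacement$rl, 0)
  expect_equal(cm2$displacement$vector, 2)
  # insufficient phases
  grid_bad <- make_grid(list(X = list(ED = list(EE = base))),
                        resp_states = c("EE", "EI"))
  expect_error(cardiac_motion(grid_bad, "X"), "insufficient phases")
  expect_error(hysteresis_motion(grid_bad, "X"), "insufficient phases")
})

test_that("hysteresis motion recovers the injected loop width", {
  spec <- small_phantom()
  m0 <- motion_model(c(-5, 3, -3), c(0, 1, -4), hysteresis = 0)
  g0 <- render_phase_grid(spec, m0)
  h0 <- hysteresis_motion(g0, "LV")
  expect_lt(h0$displacement$vector, spec$spacing[1] / 2)
  m6 <- motion_model(c(-5, 3, -3), c(0, 1, -4), hysteresis = 6)
  g6 <- render_phase_grid(spec, m6)
  h6 <- hysteresis_motion(g6, "LV")
  expect_lt(abs(h6$displacement$vector - 6), spec$spacing[1] / 2)
  # direction matches the model's perpendicular
  rec <- c(h6$displacement$rl, h6$displacement$ap, h6$displacement$si)
  expect_lt(max(abs(rec - 6 * m6$hysteresis_dir)), spec$spacing[1] / 2)
})

test_that("cardiac estimate is invariant to respiratory amplitude (decoupling)", {
  spec <- small_phantom()
  g1 <- render_phase_grid(spec, motion_model(c(-5, 3, -3), c(0, 1, -4), 2))
  g2 <- render_phase_grid(spec, motion_model(c(-5, 3, -3), c(0, 2, -8), 2))
  for (sub in c("LV", "RCA")) {
    c1 <- cardiac_motion(g1, sub)$displacement
    c2 <- cardiac_motion(g2, sub)$displacement
    expect_lt(max(abs(c(c1$rl - c2$rl, c1$ap - c2$ap, c1$si - c2$si))),
              spec$spacing[1] / 2)
  }
})

test_that("surface distances match the exhaustive double-loop oracle", {
  for (seed in 1:4) {
    A <- random_blob_mask(n = 22, spacing = c(1.5, 1.5, 2), seed = seed)
    B <- random_blob_mask(n = 22, spacing = c(1.5, 1.5, 2), seed = seed + 50)
    d_impl <- sort(surface_distances(A, B))
    d_oracle <- sort(brute_surface_distances(A, B))
    expect_equal(length(d_impl), length(d_oracle))
    expect_lt(max(abs(d_impl - d_oracle)), 1e-9)
  }
  # trivial cases
  A <- random_blob_mask(n = 16, seed = 9)
  expect_true(all(surface_distances(A, A) == 0))
  a1 <- array(FALSE, dim = c(12, 12, 12)); a1[3, 3, 3] <- TRUE
  a2 <- array(FALSE, dim = c(12, 12, 12)); a2[8, 3, 3] <- TRUE
  s1 <- structure_mask(a1, 1); s2 <- structure_mask(a2, 1)
  expect_equal(as.numeric(surface_distances(s1, s2)), 5)
})

test_that("distance metrics summarize the sample set", {
  dm <- distance_metrics(rep(2, 40))
  expect_equal(c(dm$mda, dm$hd95, dm$max), c(2, 2, 2))
  dm2 <- distance_metrics(0:100)
  expect_equal(dm2$hd95, 95)
  expect_equal(dm2$mda, 50)
  set.seed(1)
  d <- runif(200, 0, 9)
  dm3 <- distance_metrics(d)
  expect_lte(dm3$hd95, dm3$max)
  expect_lte(dm3$mda, dm3$max)
  expect_error(distance_metrics(numeric(0)), "empty")
})

test_that("summary table and 5 mm flags follow the strict-> rule", {
  spec <- small_phantom()
  g <- render_phase_grid(spec, motion_model(c(-5.5, 3.8, -3.6), c(0, 1, -4), 2),
                         subject = "S01")
  tab <- summarize_motion(g)
  expect_setequal(unique(tab$metric),
                  c("rl", "ap", "si", "vector", "mean_face", "max_face",
                    "mda", "hd95"))
  expect_setequal(unique(tab$motion_type),
                  c("cardiac", "respiratory", "hysteresis"))
  fl <- threshold_flags(tab, 5)
  lv_card <- fl$flags[fl$flags$substructure == "LV" &
                        fl$flags$motion_type == "cardiac", ]
  vec <- tab$value_mm[tab$substructure == "LV" & tab$motion_type == "cardiac" &
                        tab$metric == "vector"]
  expect_identical(lv_card$centroid_exceeds, vec > 5)
  # boundary: exactly 5.0 mm is not flagged
  tab2 <- data.frame(subject = "S", substructure = "X",
                     motion_type = "cardiac",
                     metric = c("vector", "max_face"), value_mm = c(5, 5))
  fl2 <- threshold_flags(tab2, 5)
  expect_false(fl2$flags$centroid_exceeds)
  expect_false(fl2$flags$max_face_exceeds)
  # mean-of-norms invariant: vector >= norm of component means
  for (key in split(tab, interaction(tab$substructure, tab$motion_type))) {
    if (nrow(key) == 0) next
    v <- key$value_mm[key$metric == "vector"]
    comps <- key$value_mm[key$metric %in% c("rl", "ap", "si")]
    if (length(v) == 1 && length(comps) == 3)
      expect_gte(v + 1e-9, sqrt(sum(comps^2)))
  }
})
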