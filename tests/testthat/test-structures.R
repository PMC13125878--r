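# mask reductions and the geometric valve/node constructions

test_that("centroid follows the voxel-center convention", {
  a <- array(FALSE, dim = c(10, 10, 10))
  a[3, 5, 7] <- TRUE
  m <- structure_mask(a, spacing = c(1.5, 2, 2.5), origin = c(10, 20, 30))
  expect_equal(centroid(m),
               c(rl = 10 + 1.5 * 2, ap = 20 + 2 * 4, si = 30 + 2.5 * 6))
  a[5, 5, 7] <- TRUE  # two voxels: centroid at the midpoint
  m2 <- structure_mask(a, spacing = c(1.5, 2, 2.5), origin = c(10, 20, 30))
  expect_equal(centroid(m2)[["rl"]], 10 + 1.5 * 3)
  # rasterized sphere: centroid within half a voxel of the true center
  spec <- phantom_spec(list(sphere_primitive("S", c(35, 36, 34), 12)),
                       grid_shape = c(45, 45, 45), spacing = 1.56)
  cs <- centroid(render_mask(spec, "S"))
  expect_true(all(abs(cs - c(35, 36, 34)) < 1.56 / 2))
  expect_error(centroid(structure_mask(array(FALSE, dim = c(2, 2, 2)), 1)),
               "empty structure")
})

test_that("bounding box faces are extreme voxel centers", {
  spec <- phantom_spec(list(sphere_primitive("S", c(35, 35, 35), 12)),
                       grid_shape = c(45, 45, 45), spacing = 1.56)
  m <- render_mask(spec, "S")
  bb <- bounding_box(m)
  for (f in c("right", "anterior", "superior"))
    expect_lt(abs(bb[[f]] - (35 + 12)), 1.56)
  for (f in c("left", "posterior", "inferior"))
    expect_lt(abs(bb[[f]] - (35 - 12)), 1.56)
  # lattice translation moves both faces on the axis by one spacing
  m1 <- render_mask(spec, "S", displacement = c(0, 0, 1.56))
  bb1 <- bounding_box(m1)
  expect_equal(bb1[["superior"]] - bb[["superior"]], 1.56)
  expect_equal(bb1[["inferior"]] - bb[["inferior"]], 1.56)
  expect_equal(bb1[["right"]], bb[["right"]])
})

test_that("centroid and bounding box are translation equivariant", {
  m <- random_blob_mask(n = 24, spacing = c(1.5, 1.5, 2), seed = 4)
  # embed with a margin so integer shifts stay on-grid
  shifted <- function(mask, v) {
    a <- array(FALSE, dim = dim(mask$data))
    idx <- which(mask$data, arr.ind = TRUE)
    idx2 <- sweep(idx, 2, v, "+")
    a[idx2] <- TRUE
    structure_mask(a, mask$spacing, mask$origin)
  }
  for (v in list(c(1, 0, 0), c(0, -2, 1), c(2, 1, -1))) {
    ms <- shifted(m, v)
    t_mm <- v * m$spacing
    expect_equal(centroid(ms), centroid(m) + setNames(t_mm, c("rl", "ap", "si")))
    bb0 <- unclass(bounding_box(m))
    bb1 <- unclass(bounding_box(ms))
    expect_equal(bb1[c("right", "left")], bb0[c("right", "left")] + t_mm[1])
    expect_equal(bb1[c("anterior", "posterior")],
                 bb0[c("anterior", "posterior")] + t_mm[2])
    expect_equal(bb1[c("superior", "inferior")],
                 bb0[c("superior", "inferior")] + t_mm[3])
  }
})

test_that("mask_surface matches the per-voxel neighbour-check oracle", {
  for (seed in 1:3) {
    m <- random_blob_mask(n = 20, seed = seed)
    s <- mask_surface(m)
    oracle_pts <- surface_oracle(m)
    impl_pts <- cardiomotion:::voxel_coords(s)
    expect_equal(impl_pts[order(impl_pts[, 1], impl_pts[, 2], impl_pts[, 3]), ],
                 oracle_pts[order(oracle_pts[, 1], oracle_pts[, 2],
                                  oracle_pts[, 3]), ],
                 ignore_attr = TRUE)
  }
  # solid cube: surface is the shell
  b <- box_mask(10, c(3, 7), c(3, 7), c(3, 7))
  s <- mask_surface(b)
  expect_equal(sum(s$data), 5^3 - 3^3)
})

test_that("derive_valve is expansion-then-intersection", {
  # off-lattice centers so no voxel distance lands exactly on the
  # expansion radius (avoids floating-point boundary ties)
  mk_sphere_pair <- function(gap) {
    spec <- phantom_spec(list(
      sphere_primitive("V", c(30.21, 40.13, 40.37), 12),
      sphere_primitive("N", c(30.21 + 12 + gap + 8, 40.13, 40.37), 8)),
      grid_shape = c(52, 52, 52), spacing = 1.56)
    list(v = render_mask(spec, "V"), n = render_mask(spec, "N"))
  }
  # neighbour > 8 mm away: empty valve with a warning
  far <- mk_sphere_pair(gap = 11)
  expect_warning(valve <- derive_valve(far$v, far$n, 8), "empty")
  expect_equal(sum(valve$data), 0)
  # neighbour inside the expansion: valve equals the neighbour
  near <- mk_sphere_pair(gap = -22)  # heavily overlapping
  valve2 <- derive_valve(near$v, near$n, 30)
  expect_identical(valve2$data, near$n$data)
  # 6 mm gap: volume equals the exhaustive distance-check oracle
  mid <- mk_sphere_pair(gap = 6.13)
  valve3 <- derive_valve(mid$v, mid$n, 8)
  pv <- cardiomotion:::voxel_coords(mid$v)
  pn <- cardiomotion:::voxel_coords(mid$n)
  within8 <- vapply(seq_len(nrow(pn)), function(i) {
    min(sqrt((pv[, 1] - pn[i, 1])^2 + (pv[, 2] - pn[i, 2])^2 +
               (pv[, 3] - pn[i, 3])^2)) <= 8
  }, logical(1))
  expect_equal(sum(valve3$data), sum(within8))
  expect_true(all(valve3$data[mid$n$data] | !valve3$data[mid$n$data]))
  # valve is always a subset of the neighbour
  expect_true(!any(valve3$data & !mid$n$data))
  # grid mismatch
  other <- structure_mask(array(TRUE, dim = c(4, 4, 4)), 1)
  expect_error(derive_valve(mid$v, other, 8), "grid")
})

test_that("derive_node rasterizes a sphere at the landmark", {
  tmpl <- structure_mask(array(FALSE, dim = c(60, 60, 60)), 1.56)
  ctr <- 1.56 * 29  # on a voxel center
  node <- derive_node(c(ctr, ctr, ctr), 10, tmpl, label = "SAN")
  vol <- sum(node$data) * prod(tmpl$spacing)
  expect_lt(abs(vol - 4188.79) / 4188.79, 0.05)
  # reflection symmetry about the center voxel (index 30; reflect 1..59)
  sub <- node$data[1:59, 1:59, 1:59]
  expect_identical(sub, sub[59:1, , ][, 59:1, ][, , 59:1])
  # volume monotone in radius
  node2 <- derive_node(c(ctr, ctr, ctr), 12, tmpl)
  expect_true(all(node2$data[node$data]))
  expect_gt(sum(node2$data), sum(node$data))
  expect_error(derive_node(c(ctr, ctr, ctr), 0, tmpl), "geometry error")
  expect_error(derive_node(c(-500, 0, 0), 10, tmpl), "geometry error")
})
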