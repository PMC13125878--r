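# Fixtures built in code and independent brute-force oracles used across
# the suite. Oracles deliberately avoid the package's own code paths
# (shift-based surface extraction, distance transform, separable
# dilation).

# random blob mask: union of a few random spheres, voxel-center rule
random_blob_mask <- function(n = 28, spacing = c(1.5, 1.5, 2), seed = 1,
                             n_spheres = 3, label = "blob") {
  set.seed(seed)
  ext <- spacing * (n - 1)
  a <- array(FALSE, dim = rep(n, 3))
  ax <- lapply(1:3, function(i) spacing[i] * (0:(n - 1)))
  for (s in seq_len(n_spheres)) {
    ctr <- runif(3, 0.3, 0.7) * ext
    r <- runif(1, 0.12, 0.22) * min(ext)
    d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
                (ax[[3]] - ctr[3])^2, "+")
    a <- a | (d2 <= r^2)
  }
  structure_mask(a, spacing, origin = c(0, 0, 0), label = label)
}

# independent surface extraction: explicit per-voxel neighbour check
surface_oracle <- function(mask) {
  a <- mask$data
  d <- dim(a)
  idx <- which(a, arr.ind = TRUE)
  on_surface <- logical(nrow(idx))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    for (o in 1:6) {
      nb <- v + offs[o, ]
      if (any(nb < 1) || any(nb > d) || !a[nb[1], nb[2], nb[3]]) {
        on_surface[r] <- TRUE
        break
      }
    }
  }
  phys <- sweep(sweep(idx[on_surface, , drop = FALSE] - 1, 2, mask$spacing,
                      "*"), 2, mask$origin, "+")
  phys
}

# exhaustive directed surface distances A -> B (double loop over points)
brute_surface_distances <- function(maskA, maskB) {
  pa <- surface_oracle(maskA)
  pb <- surface_oracle(maskB)
  d <- numeric(nrow(pa))
  for (i in seq_len(nrow(pa))) {
    dd <- sqrt((pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2 +
                 (pb[, 3] - pa[i, 3])^2)
    d[i] <- min(dd)
  }
  d
}

# brute-force anisotropic box dilation via explicit voxel offsets
brute_box_dilate <- function(mask, nvox) {
  # nvox: named voxel counts right/left/anterior/posterior/superior/inferior
  a <- mask$data
  d <- dim(a)
  out <- array(FALSE, dim = d)
  idx <- which(a, arr.ind = TRUE)
  for (dx in -nvox[["left"]]:nvox[["right"]])
    for (dy in -nvox[["posterior"]]:nvox[["anterior"]])
      for (dz in -nvox[["inferior"]]:nvox[["superior"]]) {
        sh <- cbind(idx[, 1] + dx, idx[, 2] + dy, idx[, 3] + dz)
        keep <- sh[, 1] >= 1 & sh[, 1] <= d[1] &
          sh[, 2] >= 1 & sh[, 2] <= d[2] &
          sh[, 3] >= 1 & sh[, 3] <= d[3]
        out[sh[keep, , drop = FALSE]] <- TRUE
      }
  out
}

# hand-build a phase_grid from a list masks[[sub]][[cardiac]][[resp]]
make_grid <- function(masks, cardiac_phases = c("ED", "ES"),
                      resp_states = c("EE", "AEx", "AIn", "EI"),
                      subject = "T01") {
  structure(list(masks = masks, ground_truth = NULL, spec = NULL,
                 model = NULL, subject = subject,
                 cardiac_phases = cardiac_phases,
                 resp_states = resp_states),
            class = "phase_grid")
}

# small box mask: set voxels i1:i2 x j1:j2 x k1:k2 on an n^3 grid
box_mask <- function(n, i, j, k, spacing = 1, origin = c(0, 0, 0)) {
  a <- array(FALSE, dim = rep(n, 3))
  a[i[1]:i[2], j[1]:j[2], k[1]:k[2]] <- TRUE
  structure_mask(a, spacing, origin, label = "box")
}

# a reduced phantom that renders fast (48^3 at 3 mm, ~14 cm extent)
small_phantom <- function() {
  ctr <- c(70, 70, 70)
  phantom_spec(list(
    sphere_primitive("LV", center = ctr, radius = 24),
    sphere_primitive("RCA", center = ctr + c(32, 0, 8), radius = 8)
  ), grid_shape = c(48, 48, 48), spacing = 3, origin = c(0, 0, 0))
}
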