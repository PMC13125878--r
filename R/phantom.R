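# Synthetic cardiorespiratory phantom: surrogate signals, moving
# substructure masks with known ground-truth displacements, and dose grids.

#' Simulate a respiratory surrogate waveform
#'
#' Generates a quasi-periodic bellows-like respiratory amplitude signal on
#' a uniform time grid. The noiseless, drift-free shape is a raised
#' cosine, `baseline + amplitude * (1 - cos(2*pi*t/period)) / 2`, so the
#' signal spans `[baseline, baseline + amplitude]`, end-exhale sits at the
#' minima (t = 0, period, ...) and end-inhale at the maxima (t =
#' period/2, 3*period/2, ...). Optional linear baseline drift and
#' additive Gaussian noise emulate real bellows behaviour.
#'
#' @param duration record length in seconds.
#' @param dt sampling step in seconds; must satisfy `dt < period/10`.
#' @param period respiratory period in seconds (> 0).
#' @param amplitude peak-to-trough amplitude, arbitrary units.
#' @param baseline signal value at end-exhale, arbitrary units.
#' @param drift_rate linear baseline drift, units/s.
#' @param noise_sd additive Gaussian noise SD, units.
#' @param seed integer seed; fixed seed gives bit-identical samples.
#' @return Object of class `resp_waveform`: list with `times`,
#'   `amplitudes`, `period`, `dt` and the generating parameters. The
#'   noise-free midline is `baseline + amplitude/2 + drift_rate * t`.
#' @export
generate_respiratory_waveform <- function(duration = 300, dt = 0.1,
                                          period = 4, amplitude = 1,
                                          baseline = 0, drift_rate = 0,
                                          noise_sd = 0, seed = NULL) {
  if (!is.finite(period) || period <= 0)
    stop("parameter error: period must be > 0", call. = FALSE)
  if (!is.finite(dt) || dt <= 0)
    stop("parameter error: dt must be > 0", call. = FALSE)
  if (dt >= period / 10)
    stop("parameter error: sampling step must be < period/10", call. = FALSE)
  if (noise_sd < 0) stop("parameter error: noise_sd must be >= 0", call. = FALSE)
  times <- seq(0, duration, by = dt)
  clean <- baseline + amplitude * (1 - cos(2 * pi * times / period)) / 2 +
    drift_rate * times
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    clean <- clean + rnorm(length(times), sd = noise_sd)
  }
  structure(
    list(times = times, amplitudes = clean, period = period, dt = dt,
         amplitude = amplitude, baseline = baseline,
         drift_rate = drift_rate, noise_sd = noise_sd, seed = seed),
    class = "resp_waveform"
  )
}

#' Simulate cardiac trigger times
#'
#' Generates strictly increasing trigger times (a pulse-oximeter/ECG
#' surrogate) covering `[0, duration]`: RR intervals are drawn i.i.d.
#' from `N(mean_rr, rr_jitter_sd^2)`; a draw that would be non-positive
#' (non-increasing triggers) is redrawn up to `max_retries` times, after
#' which an error is raised.
#'
#' @param duration record length in seconds (> `mean_rr`).
#' @param mean_rr mean RR interval in seconds (> 0).
#' @param rr_jitter_sd SD of the RR interval, seconds.
#' @param seed integer seed.
#' @param max_retries redraw budget per interval for non-positive draws.
#' @return Object of class `cardiac_triggers`: list with `trigger_times`,
#'   `mean_rr`, `rr_jitter_sd`, `seed`.
#' @export
generate_cardiac_triggers <- function(duration, mean_rr = 1,
                                      rr_jitter_sd = 0, seed = NULL,
                                      max_retries = 1000) {
  if (!is.finite(mean_rr) || mean_rr <= 0)
    stop("parameter error: mean_rr must be > 0", call. = FALSE)
  if (!is.finite(duration) || duration <= mean_rr)
    stop("parameter error: duration must exceed mean_rr", call. = FALSE)
  if (rr_jitter_sd < 0)
    stop("parameter error: rr_jitter_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tt <- 0
  last <- 0
  while (last < duration) {
    rr <- mean_rr + if (rr_jitter_sd > 0) rnorm(1, sd = rr_jitter_sd) else 0
    tries <- 0
    while (rr <= 0) {
      tries <- tries + 1
      if (tries > max_retries)
        stop("rr_jitter_sd too large: could not draw a positive RR interval",
             call. = FALSE)
      rr <- mean_rr + rnorm(1, sd = rr_jitter_sd)
    }
    last <- last + rr
    tt <- c(tt, last)
  }
  structure(
    list(trigger_times = tt, mean_rr = mean_rr,
         rr_jitter_sd = rr_jitter_sd, seed = seed),
    class = "cardiac_triggers"
  )
}

#' Cardiorespiratory motion model for the phantom
#'
#' Prescribes rigid substructure displacement as the sum of a cardiac
#' term and a respiratory term. The cardiac term interpolates from 0 at
#' end-diastole (cardiac phase 0) to `cardiac_amp` at end-systole
#' (cardiac phase 1) with a raised-cosine time course. The respiratory
#' term follows an elliptical loop: the straight limb runs from 0 at
#' end-exhale (respiratory phase 0) to `resp_amp` at end-inhale
#' (respiratory phase 1), and hysteresis adds a perpendicular offset
#' `sign * (hysteresis/2) * sin(pi * phase)` where `sign` is +1 on the
#' inhale limb and -1 on the exhale limb. The loop therefore closes
#' exactly at both respiratory extremes, and the active-exhale to
#' active-inhale separation at mid-respiration equals `hysteresis` mm.
#'
#' The perpendicular direction is the unit vector orthogonal to
#' `resp_amp` obtained by crossing the respiratory direction with the RL
#' axis (falling back to the AP axis when `resp_amp` is RL-aligned, and
#' to the AP axis itself when `resp_amp` is zero).
#'
#' @param cardiac_amp end-diastole to end-systole displacement, mm,
#'   `c(rl, ap, si)`.
#' @param resp_amp end-exhale to end-inhale displacement, mm (typically
#'   SI-dominant and negative, i.e. inferior at inhale... superior motion
#'   conventions follow the RL/AP/SI sign convention of
#'   [structure_mask()]).
#' @param hysteresis perpendicular inhale/exhale limb separation at
#'   mid-respiration, mm (>= 0).
#' @return Object of class `motion_model`.
#' @export
motion_model <- function(cardiac_amp = c(0, 0, 0), resp_amp = c(0, 0, 0),
                         hysteresis = 0) {
  cardiac_amp <- as.numeric(cardiac_amp)
  resp_amp <- as.numeric(resp_amp)
  if (length(cardiac_amp) != 3L || length(resp_amp) != 3L)
    stop("cardiac_amp and resp_amp must be length-3 (rl, ap, si) mm",
         call. = FALSE)
  if (!is.finite(hysteresis) || hysteresis < 0)
    stop("hysteresis must be >= 0 mm", call. = FALSE)
  nr <- sqrt(sum(resp_amp^2))
  if (nr > 0) {
    u <- resp_amp / nr
    perp <- c(0, u[3], -u[2])          # u x e_RL
    if (sqrt(sum(perp^2)) < 1e-12) perp <- c(-u[3], 0, u[1])  # u x e_AP
    perp <- perp / sqrt(sum(perp^2))
  } else {
    perp <- c(0, 1, 0)
  }
  structure(
    list(cardiac_amp = cardiac_amp, resp_amp = resp_amp,
         hysteresis = hysteresis, hysteresis_dir = perp),
    class = "motion_model"
  )
}

# respiratory phase and limb per discrete state
resp_state_phase <- function(state) {
  switch(state,
    EE = list(phase = 0, limb = 0),
    AEx = list(phase = 0.5, limb = -1),
    AIn = list(phase = 0.5, limb = +1),
    EI = list(phase = 1, limb = 0),
    stop(sprintf("unknown respiratory state '%s'", state), call. = FALSE)
  )
}

cardiac_phase_fraction <- function(phase) {
  if (is.character(phase)) {
    switch(phase, ED = 0, ES = 1,
           stop(sprintf("unknown cardiac phase '%s'", phase), call. = FALSE))
  } else {
    p <- as.numeric(phase)
    if (p < 0 || p > 1) stop("cardiac phase fraction must be in [0,1]",
                             call. = FALSE)
    p
  }
}

#' Model displacement at a (cardiac, respiratory) phase pair
#'
#' Evaluates the [motion_model()] at a discrete cardiac phase (`"ED"`,
#' `"ES"`, or a fraction in \[0,1\]) and respiratory state (`"EE"`,
#' `"AEx"`, `"AIn"`, `"EI"`, or a list `list(phase =, limb =)` for
#' continuous evaluation).
#'
#' @param model a [motion_model()].
#' @param cardiac cardiac phase.
#' @param resp respiratory state.
#' @return Displacement in mm, `c(rl, ap, si)`.
#' @export
phase_displacement <- function(model, cardiac = "ED", resp = "EE") {
  pc <- cardiac_phase_fraction(cardiac)
  wc <- (1 - cos(pi * pc)) / 2        # raised cosine, 0 at ED, 1 at ES
  st <- if (is.list(resp)) resp else resp_state_phase(resp)
  d <- model$cardiac_amp * wc +
    model$resp_amp * st$phase +
    st$limb * (model$hysteresis / 2) * sin(pi * st$phase) * model$hysteresis_dir
  names(d) <- c("rl", "ap", "si")
  d
}

#' Geometric phantom specification
#'
#' Defines the voxel grid and a set of geometric substructure primitives
#' (spheres, tubes with a polyline axis, ellipsoids). Defaults match the
#' imaging geometry the package targets: 96^3 voxels at 1.56 mm
#' isotropic spacing (a ~15 cm cube).
#'
#' @param substructures list of primitives from [sphere_primitive()],
#'   [tube_primitive()], [ellipsoid_primitive()].
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing mm per axis (scalar or length 3), > 0.
#' @param origin mm coordinate of the first voxel center.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(substructures, grid_shape = c(96, 96, 96),
                         spacing = 1.56, origin = c(0, 0, 0)) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 2L))
    stop("grid_shape must be 3 integers >= 2", call. = FALSE)
  nm <- vapply(substructures, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate substructure names", call. = FALSE)
  names(substructures) <- nm
  structure(
    list(substructures = substructures, grid_shape = grid_shape,
         spacing = spacing, origin = as.numeric(origin)),
    class = "phantom_spec"
  )
}

#' Phantom primitives
#'
#' Geometric primitives for [phantom_spec()]: a sphere (chamber-like), a
#' tube of constant radius around a polyline axis (coronary-artery-like),
#' and an axis-aligned ellipsoid.
#'
#' @param name substructure label.
#' @param center,semiaxes,radius,axis geometry in mm; `axis` is an n x 3
#'   matrix of polyline vertices.
#' @return A primitive description (list) for [phantom_spec()].
#' @export
sphere_primitive <- function(name, center, radius) {
  if (!is.finite(radius) || radius <= 0)
    stop("geometry error: sphere radius must be > 0", call. = FALSE)
  list(name = name, shape = "sphere", center = as.numeric(center),
       radius = radius)
}

#' @rdname sphere_primitive
#' @export
tube_primitive <- function(name, axis, radius) {
  axis <- as.matrix(axis)
  if (ncol(axis) != 3L || nrow(axis) < 2L)
    stop("tube axis must be an n x 3 matrix with n >= 2", call. = FALSE)
  if (!is.finite(radius) || radius <= 0)
    stop("geometry error: tube radius must be > 0", call. = FALSE)
  list(name = name, shape = "tube", axis = axis, radius = radius)
}

#' @rdname sphere_primitive
#' @export
ellipsoid_primitive <- function(name, center, semiaxes) {
  semiaxes <- as.numeric(semiaxes)
  if (length(semiaxes) != 3L || any(!is.finite(semiaxes)) || any(semiaxes <= 0))
    stop("geometry error: semiaxes must be 3 positive values", call. = FALSE)
  list(name = name, shape = "ellipsoid", center = as.numeric(center),
       semiaxes = semiaxes)
}

#' A small default two-substructure phantom
#'
#' A ventricle-like sphere (`"LV"`, 25 mm radius) and a proximal
#' coronary-artery-like curved tube (`"RCA"`, 2.5 mm radius, ~3 cm long)
#' on the default 96^3 grid at 1.56 mm spacing; sized so that the
#' primitives stay in-grid under displacements up to ~15 mm.
#'
#' @return A [phantom_spec()].
#' @export
default_phantom <- function() {
  ctr <- c(74, 74, 74)  # mm, grid center-ish (extent 0..148.2 mm)
  theta <- seq(0, pi / 2, length.out = 12)
  rca_axis <- cbind(ctr[1] + 33 * cos(theta),
                    ctr[2] + 33 * sin(theta),
                    ctr[3] + seq(10, -10, length.out = 12))
  phantom_spec(list(
    sphere_primitive("LV", center = ctr, radius = 25),
    tube_primitive("RCA", axis = rca_axis, radius = 2.5)
  ))
}

grid_axes <- function(spec) {
  lapply(1:3, function(a)
    spec$origin[a] + spec$spacing[a] * (seq_len(spec$grid_shape[a]) - 1))
}

# physical extent of voxel centers per axis: list of c(lo, hi)
grid_extent <- function(spec) {
  lapply(1:3, function(a)
    c(spec$origin[a],
      spec$origin[a] + spec$spacing[a] * (spec$grid_shape[a] - 1)))
}

primitive_bounds <- function(prim, displacement) {
  switch(prim$shape,
    sphere = {
      c0 <- prim$center + displacement
      rbind(c0 - prim$radius, c0 + prim$radius)
    },
    ellipsoid = {
      c0 <- prim$center + displacement
      rbind(c0 - prim$semiaxes, c0 + prim$semiaxes)
    },
    tube = {
      ax <- sweep(prim$axis, 2, displacement, "+")
      rbind(apply(ax, 2, min) - prim$radius,
            apply(ax, 2, max) + prim$radius)
    }
  )
}

# min distance from each point (n x 3) to a polyline (m x 3), vectorized
points_polyline_dist <- function(pts, axis) {
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(axis) - 1)) {
    p0 <- axis[s, ]
    v <- axis[s + 1, ] - p0
    vv <- sum(v^2)
    w <- sweep(pts, 2, p0, "-")
    t <- if (vv > 0) pmin(1, pmax(0, (w %*% v) / vv)) else rep(0, nrow(pts))
    dd <- (w[, 1] - t * v[1])^2 + (w[, 2] - t * v[2])^2 + (w[, 3] - t * v[3])^2
    dmin <- pmin(dmin, dd)
  }
  sqrt(dmin)
}

#' Rasterize one displaced substructure primitive
#'
#' Renders the named primitive of a [phantom_spec()], rigidly displaced
#' by `displacement` mm, as a binary mask: a voxel is set iff its center
#' lies inside (or on) the displaced primitive. This voxel-center rule
#' makes rasterization exactly equivariant under lattice translations.
#'
#' @param spec a [phantom_spec()].
#' @param substructure name of the primitive to render.
#' @param displacement rigid displacement in mm, `c(rl, ap, si)`.
#' @return A [structure_mask].
#' @export
render_mask <- function(spec, substructure, displacement = c(0, 0, 0)) {
  if (!substructure %in% names(spec$substructures))
    stop(sprintf("unknown substructure '%s'", substructure), call. = FALSE)
  prim <- spec$substructures[[substructure]]
  displacement <- as.numeric(displacement)
  ext <- grid_extent(spec)
  bnd <- primitive_bounds(prim, displacement)
  for (a in 1:3) {
    if (bnd[1, a] < ext[[a]][1] - spec$spacing[a] / 2 ||
        bnd[2, a] > ext[[a]][2] + spec$spacing[a] / 2)
      stop(sprintf(
        "geometry error: displaced primitive '%s' exceeds the grid on axis %d",
        substructure, a), call. = FALSE)
  }
  ax <- grid_axes(spec)
  d <- spec$grid_shape
  inside <- switch(prim$shape,
    sphere = {
      c0 <- prim$center + displacement
      dist2 <- outer(outer((ax[[1]] - c0[1])^2, (ax[[2]] - c0[2])^2, "+"),
                     (ax[[3]] - c0[3])^2, "+")
      dist2 <= prim$radius^2
    },
    ellipsoid = {
      c0 <- prim$center + displacement
      q <- outer(outer(((ax[[1]] - c0[1]) / prim$semiaxes[1])^2,
                       ((ax[[2]] - c0[2]) / prim$semiaxes[2])^2, "+"),
                 ((ax[[3]] - c0[3]) / prim$semiaxes[3])^2, "+")
      q <= 1
    },
    tube = {
      # evaluate only within the tube's bounding box for speed
      keep <- lapply(1:3, function(a)
        which(ax[[a]] >= bnd[1, a] & ax[[a]] <= bnd[2, a]))
      msk <- array(FALSE, dim = d)
      if (all(lengths(keep) > 0)) {
        pts <- as.matrix(expand.grid(ax[[1]][keep[[1]]],
                                     ax[[2]][keep[[2]]],
                                     ax[[3]][keep[[3]]]))
        axis_d <- sweep(prim$axis, 2, displacement, "+")
        hit <- points_polyline_dist(pts, axis_d) <= prim$radius
        sub <- array(hit, dim = lengths(keep))
        msk[keep[[1]], keep[[2]], keep[[3]]] <- sub
      }
      msk
    }
  )
  m <- structure_mask(array(inside, dim = d), spec$spacing, spec$origin,
                      label = substructure)
  if (!any(m$data))
    stop(sprintf("geometry error: primitive '%s' rasterized to an empty mask",
                 substructure), call. = FALSE)
  m
}

#' Render a full cardiac x respiratory phase grid with ground truth
#'
#' Renders every substructure of the phantom at every (cardiac phase,
#' respiratory state) combination, displacing each primitive by
#' [phase_displacement()] of the motion model, and records the exact
#' displacement applied in a ground-truth table.
#'
#' @param spec a [phantom_spec()].
#' @param model a [motion_model()].
#' @param cardiac_phases character, subset of `c("ED", "ES")`.
#' @param resp_states character, subset of
#'   `c("EE", "AEx", "AIn", "EI")`.
#' @param subject optional subject identifier carried into the table.
#' @return Object of class `phase_grid`: `masks[[substructure]][[cardiac]][[resp]]`
#'   plus `ground_truth` (data.frame: substructure, cardiac, resp,
#'   rl_mm, ap_mm, si_mm), the spec and the model.
#' @export
render_phase_grid <- function(spec, model,
                              cardiac_phases = CARDIAC_PHASES,
                              resp_states = RESP_STATES,
                              subject = NA_character_) {
  stopifnot(all(cardiac_phases %in% CARDIAC_PHASES),
            all(resp_states %in% RESP_STATES))
  masks <- list()
  gt <- list()
  for (sub in names(spec$substructures)) {
    masks[[sub]] <- list()
    for (cp in cardiac_phases) {
      masks[[sub]][[cp]] <- list()
      for (rs in resp_states) {
        disp <- phase_displacement(model, cp, rs)
        masks[[sub]][[cp]][[rs]] <- render_mask(spec, sub, disp)
        gt[[length(gt) + 1]] <- data.frame(
          subject = subject, substructure = sub, cardiac = cp, resp = rs,
          rl_mm = disp[1], ap_mm = disp[2], si_mm = disp[3],
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(masks = masks, ground_truth = do.call(rbind, gt),
         spec = spec, model = model, subject = subject,
         cardiac_phases = cardiac_phases, resp_states = resp_states),
    class = "phase_grid"
  )
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf("<phase_grid> %d substructures x %s cardiac x %s respiratory\n",
              length(x$masks), paste(x$cardiac_phases, collapse = "/"),
              paste(x$resp_states, collapse = "/")))
  invisible(x)
}

get_mask <- function(grid, substructure, cardiac, resp) {
  m <- grid$masks[[substructure]][[cardiac]][[resp]]
  if (is.null(m))
    stop(sprintf("insufficient phases: mask (%s, %s, %s) missing",
                 substructure, cardiac, resp), call. = FALSE)
  m
}

has_mask <- function(grid, substructure, cardiac, resp) {
  !is.null(grid$masks[[substructure]][[cardiac]][[resp]])
}

#' Synthetic dose grid
#'
#' Deterministic 3D dose distributions on the phantom grid geometry:
#' `uniform` (constant `level` Gy), `linear_gradient`
#' (`level + gradient . (x - ref_point)`, clipped at 0 Gy), or
#' `gaussian` (`peak * exp(-||x - center||^2 / (2 width^2))`).
#'
#' @param geom a [phantom_spec()] (its grid geometry is used) or a
#'   [structure_mask] template.
#' @param mode one of `"uniform"`, `"linear_gradient"`, `"gaussian"`.
#' @param level dose in Gy (uniform; and value at `ref_point` for the
#'   gradient mode).
#' @param gradient Gy/mm, length 3.
#' @param ref_point mm, length 3; point where the gradient field equals
#'   `level`.
#' @param peak,center,width Gaussian parameters (Gy, mm, mm).
#' @return A [dose_grid].
#' @export
render_dose <- function(geom, mode = c("uniform", "linear_gradient", "gaussian"),
                        level = 10, gradient = c(0, 0, 1),
                        ref_point = NULL, peak = 30, center = NULL,
                        width = 20) {
  mode <- match.arg(mode)
  if (inherits(geom, "structure_mask")) {
    geom <- list(grid_shape = dim(geom$data), spacing = geom$spacing,
                 origin = geom$origin)
  }
  ax <- lapply(1:3, function(a)
    geom$origin[a] + geom$spacing[a] * (seq_len(geom$grid_shape[a]) - 1))
  mid <- vapply(ax, function(v) mean(range(v)), numeric(1))
  d <- geom$grid_shape
  vals <- switch(mode,
    uniform = {
      if (!is.finite(level) || level < 0)
        stop("parameter error: dose level must be >= 0 Gy", call. = FALSE)
      array(level, dim = d)
    },
    linear_gradient = {
      if (!is.finite(level) || level < 0)
        stop("parameter error: dose level must be >= 0 Gy", call. = FALSE)
      if (is.null(ref_point)) ref_point <- mid
      g <- as.numeric(gradient)
      v <- level +
        outer(outer(g[1] * (ax[[1]] - ref_point[1]),
                    g[2] * (ax[[2]] - ref_point[2]), "+"),
              g[3] * (ax[[3]] - ref_point[3]), "+")
      pmax(v, 0)
    },
    gaussian = {
      if (!is.finite(peak) || peak < 0)
        stop("parameter error: peak dose must be >= 0 Gy", call. = FALSE)
      if (is.null(center)) center <- mid
      dist2 <- outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2,
                           "+"), (ax[[3]] - center[3])^2, "+")
      peak * exp(-dist2 / (2 * width^2))
    }
  )
  dose_grid(array(vals, dim = d), geom$spacing, geom$origin)
}

#' Simulate a phantom cohort with known per-subject motion
#'
#' Builds `n_subjects` phase grids from one [phantom_spec()], drawing
#' per-subject motion amplitudes around the stated cohort means. The
#' defaults inject the cohort-mean proximal-coronary cardiac excursion
#' (-5.5, 3.8, -3.6) mm (left/anterior/inferior at end-systole) and an
#' SI-dominant respiratory excursion (0, 1, -4) mm; per-subject
#' hysteresis is drawn uniformly on `hysteresis_range`.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of synthetic subjects.
#' @param cardiac_amp,resp_amp cohort-mean amplitudes, mm `c(rl, ap, si)`.
#' @param cardiac_sd,resp_sd between-subject SD per component, mm.
#' @param hysteresis_range range (mm) for the uniform per-subject
#'   hysteresis draw; a single value fixes it.
#' @param seed integer seed.
#' @param cardiac_phases,resp_states phases to render.
#' @return List with `subjects` (list of `phase_grid`s named S01...),
#'   `ground_truth` (stacked table), and `models`.
#' @export
simulate_cohort <- function(spec = default_phantom(), n_subjects = 10,
                            cardiac_amp = c(-5.5, 3.8, -3.6),
                            resp_amp = c(0, 1, -4),
                            cardiac_sd = 0, resp_sd = 0,
                            hysteresis_range = c(0, 6), seed = 1,
                            cardiac_phases = CARDIAC_PHASES,
                            resp_states = RESP_STATES) {
  set.seed(seed)
  if (length(hysteresis_range) == 1L)
    hysteresis_range <- rep(hysteresis_range, 2L)
  subjects <- list()
  models <- list()
  for (i in seq_len(n_subjects)) {
    id <- sprintf("S%02d", i)
    m <- motion_model(
      cardiac_amp = cardiac_amp + rnorm(3, sd = cardiac_sd),
      resp_amp = resp_amp + rnorm(3, sd = resp_sd),
      hysteresis = runif(1, hysteresis_range[1], hysteresis_range[2]))
    models[[id]] <- m
    subjects[[id]] <- render_phase_grid(spec, m, cardiac_phases, resp_states,
                                        subject = id)
  }
  gt <- do.call(rbind, lapply(subjects, function(g) g$ground_truth))
  rownames(gt) <- NULL
  list(subjects = subjects, ground_truth = gt, models = models)
}
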