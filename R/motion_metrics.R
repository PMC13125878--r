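# Excursion analysis: decoupled cardiac/respiratory/hysteresis centroid
# and bounding-box displacements, directed surface distances, MDA/HD95,
# and 5 mm threshold flags.

new_displacement <- function(rl, ap, si, vector = NULL) {
  if (is.null(vector)) vector <- sqrt(rl^2 + ap^2 + si^2)
  structure(list(rl = rl, ap = ap, si = si, vector = vector),
            class = "displacement")
}

#' @export
print.displacement <- function(x, ...) {
  cat(sprintf("<displacement> RL %+.2f  AP %+.2f  SI %+.2f  |v| %.2f mm\n",
              x$rl, x$ap, x$si, x$vector))
  invisible(x)
}

FACE_NAMES <- c("right", "left", "anterior", "posterior", "superior",
                "inferior")

new_face_displacements <- function(faces) {
  stopifnot(identical(names(faces), FACE_NAMES))
  structure(list(faces = faces, mean_abs = mean(abs(faces)),
                 max_abs = max(abs(faces))),
            class = "face_displacements")
}

#' @export
print.face_displacements <- function(x, ...) {
  cat("<face_displacements> (mm, signed B - A)\n")
  print(round(x$faces, 3))
  cat(sprintf("mean|.| %.3f  max|.| %.3f mm\n", x$mean_abs, x$max_abs))
  invisible(x)
}

#' Centroid displacement between two masks
#'
#' Signed displacement `centroid(B) - centroid(A)` in the RL/AP/SI frame
#' (positive toward right/anterior/superior), with the Euclidean vector
#' magnitude.
#'
#' @param maskA,maskB non-empty [structure_mask]s on the same grid frame.
#' @return Object of class `displacement` with fields `rl`, `ap`, `si`,
#'   `vector` (mm).
#' @export
centroid_displacement <- function(maskA, maskB) {
  d <- centroid(maskB) - centroid(maskA)
  new_displacement(d[["rl"]], d[["ap"]], d[["si"]])
}

#' Bounding-box face displacements between two masks
#'
#' Signed shift of each of the six bounding-box faces from A to B along
#' its own axis (`B - A`, so a face moving rightward/anteriorly/
#' superiorly is positive regardless of which face it is), plus the mean
#' and maximum absolute shift over the six faces.
#'
#' @param maskA,maskB non-empty [structure_mask]s on the same grid frame.
#' @return Object of class `face_displacements`.
#' @export
face_displacements <- function(maskA, maskB) {
  ba <- bounding_box(maskA)
  bb <- bounding_box(maskB)
  new_face_displacements(unclass(bb) - unclass(ba))
}

# average a list of displacement objects: components averaged signed,
# vector = mean of per-pair norms (mean-of-norms convention)
average_displacements <- function(ds) {
  new_displacement(
    rl = mean(vapply(ds, `[[`, numeric(1), "rl")),
    ap = mean(vapply(ds, `[[`, numeric(1), "ap")),
    si = mean(vapply(ds, `[[`, numeric(1), "si")),
    vector = mean(vapply(ds, `[[`, numeric(1), "vector")))
}

average_faces <- function(fs) {
  m <- rowMeans(vapply(fs, function(f) f$faces, numeric(6)))
  names(m) <- FACE_NAMES
  new_face_displacements(m)
}

# shared machinery for the three decoupled motion types: fixed states of
# the "other" cycle define the averaging family
paired_motion <- function(grid, substructure, from, to, over, over_axis) {
  ds <- list(); fs <- list(); used <- character()
  for (o in over) {
    if (over_axis == "resp") {
      okA <- has_mask(grid, substructure, from, o)
      okB <- has_mask(grid, substructure, to, o)
      if (okA && okB) {
        A <- get_mask(grid, substructure, from, o)
        B <- get_mask(grid, substructure, to, o)
      } else next
    } else {
      okA <- has_mask(grid, substructure, o, from)
      okB <- has_mask(grid, substructure, o, to)
      if (okA && okB) {
        A <- get_mask(grid, substructure, o, from)
        B <- get_mask(grid, substructure, o, to)
      } else next
    }
    ds[[length(ds) + 1]] <- centroid_displacement(A, B)
    fs[[length(fs) + 1]] <- face_displacements(A, B)
    used <- c(used, o)
  }
  if (length(ds) == 0L)
    stop(sprintf("insufficient phases: no complete %s/%s pair for '%s'",
                 from, to, substructure), call. = FALSE)
  list(displacement = average_displacements(ds),
       faces = average_faces(fs), states_used = used)
}

#' Decoupled cardiac motion of a substructure
#'
#' Cardiac motion is the end-diastole to end-systole displacement
#' averaged over the respiratory states in which both phases are
#' present; averaging within fixed respiratory states removes the
#' respiratory contribution. Components are averaged signed; the vector
#' magnitude is the mean of the per-state vector norms (mean-of-norms),
#' so it is never smaller than the norm of the averaged components.
#'
#' @param grid a `phase_grid`.
#' @param substructure substructure name.
#' @return List with `displacement` (class `displacement`), `faces`
#'   (class `face_displacements`), and `states_used`.
#' @export
cardiac_motion <- function(grid, substructure) {
  paired_motion(grid, substructure, from = "ED", to = "ES",
                over = grid$resp_states, over_axis = "resp")
}

#' Decoupled respiratory motion of a substructure
#'
#' End-exhale to end-inhale displacement averaged over cardiac phases;
#' the mirror of [cardiac_motion()].
#'
#' @inheritParams cardiac_motion
#' @return As [cardiac_motion()].
#' @export
respiratory_motion <- function(grid, substructure) {
  paired_motion(grid, substructure, from = "EE", to = "EI",
                over = grid$cardiac_phases, over_axis = "cardiac")
}

#' Respiratory hysteresis of a substructure
#'
#' Displacement between the active-exhale and active-inhale positions
#' (AEx to AIn) averaged over cardiac phases; a non-zero vector
#' indicates that the inhale and exhale limbs of the respiratory
#' trajectory do not coincide.
#'
#' @inheritParams cardiac_motion
#' @return As [cardiac_motion()].
#' @export
hysteresis_motion <- function(grid, substructure) {
  paired_motion(grid, substructure, from = "AEx", to = "AIn",
                over = grid$cardiac_phases, over_axis = "cardiac")
}

#' Directed surface distances between two masks
#'
#' For every surface voxel `a` of the reference mask A, the distance
#' `d_a = min_{b in B} ||a - b||` to the surface of the target mask B,
#' in physical mm. Distances are directed (A to B) and not symmetrized;
#' surfaces are the face-adjacency (6-connectivity) boundary voxels.
#'
#' @param refA,targetB non-empty [structure_mask]s on the same grid.
#' @return Numeric vector of distances (mm), one per surface voxel of A,
#'   with attribute `n_points`.
#' @export
surface_distances <- function(refA, targetB) {
  stop_if_grid_mismatch(refA, targetB)
  sa <- mask_surface(refA)
  sb <- mask_surface(targetB)
  d2 <- edt_sq_cpp(as.logical(sb$data), dim(sb$data), sb$spacing)
  d <- sqrt(d2[which(sa$data)])
  attr(d, "n_points") <- length(d)
  d
}

#' Distance-to-agreement summary metrics
#'
#' Mean distance to agreement (MDA, the arithmetic mean) and the
#' 95th-percentile Hausdorff distance (HD95, linear interpolation
#' between closest order statistics, `quantile type = 7`), plus the
#' maximum.
#'
#' @param distances numeric vector from [surface_distances()].
#' @return List of class `distance_metrics` with `mda`, `hd95`, `max`,
#'   `n_points` (mm / count).
#' @export
distance_metrics <- function(distances) {
  if (length(distances) == 0L)
    stop("empty distance sample set", call. = FALSE)
  structure(
    list(mda = mean(distances),
         hd95 = unname(quantile(distances, 0.95, type = 7)),
         max = max(distances),
         n_points = length(distances)),
    class = "distance_metrics")
}

#' Per-substructure motion summary table (long format)
#'
#' Runs the full excursion analysis for every substructure of a phase
#' grid: decoupled cardiac, respiratory, and hysteresis motion (centroid
#' components, vector, mean/max bounding-box face displacement), and the
#' directed surface-distance metrics MDA and HD95 for cardiac
#' (reference end-exhale/end-diastole vs end-exhale/end-systole) and
#' respiratory (vs end-inhale/end-diastole) motion.
#'
#' @param grid a `phase_grid`.
#' @param subject optional subject id (defaults to the grid's).
#' @param substructures subset to analyze (default all).
#' @return data.frame with columns `subject`, `substructure`,
#'   `motion_type` (`cardiac`/`respiratory`/`hysteresis`), `metric`
#'   (`rl`, `ap`, `si`, `vector`, `mean_face`, `max_face`, `mda`,
#'   `hd95`), `value_mm`.
#' @export
summarize_motion <- function(grid, subject = grid$subject,
                             substructures = names(grid$masks)) {
  rows <- list()
  add <- function(sub, type, metric, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject = subject, substructure = sub, motion_type = type,
      metric = metric, value_mm = unname(value), stringsAsFactors = FALSE)
  }
  for (sub in substructures) {
    motions <- list(cardiac = cardiac_motion, respiratory = respiratory_motion,
                    hysteresis = hysteresis_motion)
    for (type in names(motions)) {
      m <- tryCatch(motions[[type]](grid, sub), error = function(e) NULL)
      if (is.null(m)) next
      add(sub, type, "rl", m$displacement$rl)
      add(sub, type, "ap", m$displacement$ap)
      add(sub, type, "si", m$displacement$si)
      add(sub, type, "vector", m$displacement$vector)
      add(sub, type, "mean_face", m$faces$mean_abs)
      add(sub, type, "max_face", m$faces$max_abs)
    }
    # voxelwise metrics: reference = end-exhale, end-diastole
    if (has_mask(grid, sub, "ED", "EE")) {
      ref <- get_mask(grid, sub, "ED", "EE")
      if (has_mask(grid, sub, "ES", "EE")) {
        dm <- distance_metrics(surface_distances(ref, get_mask(grid, sub, "ES", "EE")))
        add(sub, "cardiac", "mda", dm$mda)
        add(sub, "cardiac", "hd95", dm$hd95)
      }
      if (has_mask(grid, sub, "ED", "EI")) {
        dm <- distance_metrics(surface_distances(ref, get_mask(grid, sub, "ED", "EI")))
        add(sub, "respiratory", "mda", dm$mda)
        add(sub, "respiratory", "hd95", dm$hd95)
      }
    }
  }
  do.call(rbind, rows)
}

#' Motion-threshold flags and cohort exceedance counts
#'
#' Flags, per subject, substructure, and motion type, whether the
#' centroid vector displacement and the maximum bounding-box face
#' displacement strictly exceed a threshold (default 5 mm, the common
#' motion-management action level), and counts flagged subjects per
#' cell across the cohort.
#'
#' @param metric_table long-format table from [summarize_motion()]
#'   (possibly stacked over subjects).
#' @param threshold_mm threshold in mm; exceedance is strict (`>`).
#' @return List with `flags` (per subject/substructure/motion type:
#'   `centroid_exceeds`, `max_face_exceeds`) and `counts` (cohort table:
#'   substructure x motion type, number of subjects exceeding for each
#'   of the two measures, plus `n_subjects`).
#' @export
threshold_flags <- function(metric_table, threshold_mm = 5) {
  wide <- metric_table[metric_table$metric %in% c("vector", "max_face"), ]
  key <- interaction(wide$subject, wide$substructure, wide$motion_type,
                     drop = TRUE)
  flags <- do.call(rbind, lapply(split(wide, key), function(d) {
    data.frame(
      subject = d$subject[1], substructure = d$substructure[1],
      motion_type = d$motion_type[1],
      centroid_exceeds = any(d$metric == "vector" &
                               d$value_mm > threshold_mm),
      max_face_exceeds = any(d$metric == "max_face" &
                               d$value_mm > threshold_mm),
      stringsAsFactors = FALSE)
  }))
  rownames(flags) <- NULL
  counts <- aggregate(
    cbind(centroid = flags$centroid_exceeds,
          max_face = flags$max_face_exceeds,
          n_subjects = rep(1L, nrow(flags))),
    by = list(substructure = flags$substructure,
              motion_type = flags$motion_type),
    FUN = sum)
  list(flags = flags, counts = counts, threshold_mm = threshold_mm)
}
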