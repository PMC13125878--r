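# DVH computation and near-maximum dose (D_v, default D_0.03cc)
# evaluation of reference vs IRV structures on a 3D dose grid.

#' 3D dose grid
#'
#' A scalar dose field in Gy on a regular grid, same voxel-center
#' geometry convention as [structure_mask()].
#'
#' @param values 3D numeric array, Gy, all finite and >= 0.
#' @param spacing,origin grid geometry in mm.
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("dose must be a 3D array", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and >= 0 Gy", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0", call. = FALSE)
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, %.2f-%.2f Gy\n",
              paste(dim(x$values), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Sample dose at structure voxel centers
#'
#' Trilinear interpolation of the dose grid at every set-voxel center of
#' the structure (exact for linear dose fields and at coincident grid
#' nodes). The structure and dose grids may differ, but every structure
#' voxel center must lie inside the dose grid's physical extent.
#'
#' @param structure a non-empty [structure_mask].
#' @param dose a [dose_grid].
#' @return List with `doses` (Gy, one per set voxel) and
#'   `voxel_volume_cc` (structure voxel volume in cc).
#' @export
sample_dose <- function(structure, dose) {
  stop_if_empty(structure)
  pts <- voxel_coords(structure)
  nd <- dim(dose$values)
  # continuous 0-based index coordinates in the dose grid
  u <- sweep(sweep(pts, 2, dose$origin, "-"), 2, dose$spacing, "/")
  eps <- 1e-9
  for (a in 1:3) {
    if (any(u[, a] < -eps | u[, a] > nd[a] - 1 + eps))
      stop("geometry error: structure extends outside the dose grid",
           call. = FALSE)
  }
  u <- pmin(pmax(u, 0), matrix(rep(nd - 1, each = nrow(u)), ncol = 3))
  i0 <- pmin(floor(u), matrix(rep(nd - 2, each = nrow(u)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- u - i0
  v <- dose$values
  at <- function(dx, dy, dz)
    v[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  doses <-
    at(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    at(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    at(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    at(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    at(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    at(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    at(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    at(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
  list(doses = as.numeric(doses),
       voxel_volume_cc = prod(structure$spacing) / 1000)
}

#' Cumulative dose-volume histogram
#'
#' Cumulative DVH `V(d)` = volume receiving at least dose `d`, in cc and
#' as a percentage of the structure volume; `V(0)` is the full volume.
#'
#' @param doses per-voxel doses (Gy) from [sample_dose()].
#' @param voxel_volume_cc voxel volume in cc.
#' @param bin_width_gy dose bin width (default 0.1 Gy).
#' @return Object of class `dvh_curve`: data.frame with `dose_gy`,
#'   `volume_cc`, `volume_pct`.
#' @export
dvh <- function(doses, voxel_volume_cc, bin_width_gy = 0.1) {
  if (length(doses) == 0L) stop("empty structure: no dose samples", call. = FALSE)
  edges <- seq(0, max(doses) + bin_width_gy, by = bin_width_gy)
  total <- length(doses) * voxel_volume_cc
  vol <- vapply(edges, function(d) sum(doses >= d) * voxel_volume_cc,
                numeric(1))
  out <- data.frame(dose_gy = edges, volume_cc = vol,
                    volume_pct = 100 * vol / total)
  class(out) <- c("dvh_curve", "data.frame")
  out
}

#' Near-maximum dose D_v (default D_0.03cc)
#'
#' The minimum dose received by the hottest `v_cc` of the structure:
#' voxel doses are sorted in decreasing order and volume is accumulated;
#' the dose at cumulative volume `v_cc` is read off with linear
#' interpolation across the straddling voxel (so the metric is
#' independent of any DVH binning). For `v_cc` at most one voxel volume
#' the result is the maximum dose.
#'
#' @param doses per-voxel doses (Gy).
#' @param voxel_volume_cc voxel volume in cc.
#' @param v_cc evaluation volume in cc (default 0.03).
#' @return Dose in Gy.
#' @export
d_cc <- function(doses, voxel_volume_cc, v_cc = 0.03) {
  if (length(doses) == 0L) stop("empty structure: no dose samples", call. = FALSE)
  if (v_cc <= 0) stop("parameter error: v_cc must be > 0", call. = FALSE)
  total <- length(doses) * voxel_volume_cc
  if (v_cc > total + 1e-12)
    stop(sprintf(
      "undefined metric: structure volume %.4f cc is smaller than v_cc = %g cc",
      total, v_cc), call. = FALSE)
  s <- sort(doses, decreasing = TRUE)
  # piecewise-linear D(v) through (k * vv, s_k); D(v) = s_1 for v <= vv
  vv <- voxel_volume_cc
  if (v_cc <= vv) return(s[1])
  k <- v_cc / vv           # continuous rank
  k0 <- floor(k)
  if (k0 >= length(s)) return(s[length(s)])
  frac <- k - k0
  s[k0] + frac * (s[k0 + 1] - s[k0])
}

#' Change in D_v between a reference structure and its IRV
#'
#' `delta = D_v(IRV) - D_v(reference)` on the same dose grid. The IRV
#' must contain the reference structure; since the hottest-subvolume
#' dose is monotone in the voxel set, the difference is >= 0 up to
#' floating-point rounding.
#'
#' @param reference,irv [structure_mask]s on the same grid,
#'   `irv` containing `reference`.
#' @param dose a [dose_grid].
#' @param v_cc evaluation volume in cc (default 0.03).
#' @return List with `d_ref`, `d_irv`, `delta` (Gy).
#' @export
delta_d <- function(reference, irv, dose, v_cc = 0.03) {
  stop_if_grid_mismatch(reference, irv)
  if (any(reference$data & !irv$data))
    stop("irv must be a superset of the reference structure", call. = FALSE)
  sr <- sample_dose(reference, dose)
  si <- sample_dose(irv, dose)
  d_ref <- d_cc(sr$doses, sr$voxel_volume_cc, v_cc)
  d_irv <- d_cc(si$doses, si$voxel_volume_cc, v_cc)
  list(d_ref = d_ref, d_irv = d_irv, delta = d_irv - d_ref)
}
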