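#' @useDynLib cardiomotion, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rnorm runif sd pchisq pnorm p.adjust aggregate setNames
#' @importFrom utils read.csv write.csv combn packageVersion
NULL

SUBSTRUCTURE_LABELS <- c(
  "RCA", "LMCA", "LADA", "LCX",             # coronary arteries
  "LV", "RV", "LA", "RA",                   # chambers
  "AA", "DA", "PA", "PVs", "IVC", "SVC",    # great vessels
  "WH",                                     # whole heart
  "V-MV", "V-TV", "V-AV", "V-PV",           # valves (geometric)
  "SAN", "AVN"                              # conduction nodes (geometric)
)

CARDIAC_PHASES <- c("ED", "ES")
RESP_STATES <- c("EE", "AEx", "AIn", "EI")

#' Binary structure mask on a regular grid
#'
#' A `structure_mask` holds one substructure at one (cardiac phase,
#' respiratory state) as a 3D logical array together with its physical
#' geometry. The axis convention is fixed throughout the package:
#' array dimension 1 is RL (positive toward patient right), dimension 2
#' is AP (positive anterior), dimension 3 is SI (positive superior).
#' The physical coordinate of the voxel with (1-based) index
#' `(i, j, k)` is `origin + spacing * (c(i, j, k) - 1)` (voxel-center
#' convention); all centroids, bounding-box faces, and distances share
#' this frame.
#'
#' @param data 3D array, logical or 0/1 numeric.
#' @param spacing voxel spacing in mm, length 3 (RL, AP, SI), all > 0.
#' @param origin physical coordinate in mm of the center of voxel
#'   (1,1,1), length 3.
#' @param label optional substructure label (e.g. `"LV"`, `"RCA"`).
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(data, spacing, origin = c(0, 0, 0), label = NA_character_) {
  if (length(dim(data)) != 3L)
    stop("mask data must be a 3D array", call. = FALSE)
  if (is.numeric(data)) {
    r <- round(data)
    if (any(!r %in% c(0, 1)) || any(abs(data - r) > 1e-6))
      stop("mask values must be 0/1", call. = FALSE)
    data <- array(r == 1, dim = dim(data))
  }
  if (!is.logical(data)) stop("mask data must be logical or 0/1", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = origin,
         label = as.character(label)),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf(
    "<structure_mask> %s  %d x %d x %d voxels, spacing %s mm, %d set (%.2f cc)\n",
    ifelse(is.na(x$label), "(unlabelled)", x$label),
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    paste(signif(x$spacing, 4), collapse = " x "),
    sum(x$data), mask_volume_cc(x)))
  invisible(x)
}

mask_nonempty <- function(mask) any(mask$data)

stop_if_empty <- function(mask, what = "mask") {
  if (!mask_nonempty(mask))
    stop(sprintf("empty structure: %s has no set voxels", what), call. = FALSE)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("masks are not on the same grid (dim/spacing/origin mismatch)",
         call. = FALSE)
}

#' Volume of a structure mask
#'
#' @param mask a [structure_mask].
#' @return Volume in cubic centimetres (voxel count times voxel volume).
#' @export
mask_volume_cc <- function(mask) {
  sum(mask$data) * prod(mask$spacing) / 1000
}

# Physical coordinates (mm) of all set voxel centers, n x 3 matrix.
voxel_coords <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

#' Centroid of a structure mask
#'
#' Unweighted mean of the physical (voxel-center) coordinates of all set
#' voxels, in mm, in the RL/AP/SI frame.
#'
#' @param mask a [structure_mask].
#' @return Named numeric vector `c(rl, ap, si)` in mm.
#' @export
centroid <- function(mask) {
  stop_if_empty(mask)
  ctr <- colMeans(voxel_coords(mask))
  names(ctr) <- c("rl", "ap", "si")
  ctr
}

#' Axis-aligned bounding box of a structure mask
#'
#' Face coordinates are the extreme *voxel-center* coordinates of the set
#' voxels on each axis (not outer voxel edges), so they live in the same
#' frame as [centroid()]: right/left on RL, anterior/posterior on AP,
#' superior/inferior on SI.
#'
#' @param mask a [structure_mask].
#' @return Named numeric vector of class `bounding_box` with elements
#'   `right, left, anterior, posterior, superior, inferior` (mm);
#'   `right >= left`, `anterior >= posterior`, `superior >= inferior`.
#' @export
bounding_box <- function(mask) {
  stop_if_empty(mask)
  xyz <- voxel_coords(mask)
  bb <- c(
    right = max(xyz[, 1]), left = min(xyz[, 1]),
    anterior = max(xyz[, 2]), posterior = min(xyz[, 2]),
    superior = max(xyz[, 3]), inferior = min(xyz[, 3])
  )
  class(bb) <- "bounding_box"
  bb
}

#' @export
print.bounding_box <- function(x, ...) {
  cat("<bounding_box> (mm, voxel-center faces)\n")
  print(round(unclass(x), 3))
  invisible(x)
}

# Squared Euclidean distance (mm^2) from every voxel center to the nearest
# set voxel center of `mask`. Inf where mask is empty.
mask_distance_sq <- function(mask) {
  edt_sq_cpp(as.logical(mask$data), dim(mask$data), mask$spacing)
}

#' Surface voxels of a mask
#'
#' A set voxel belongs to the surface if at least one of its six
#' face-adjacent neighbours is unset (voxels on the grid border count as
#' having unset neighbours outside the grid).
#'
#' @param mask a [structure_mask].
#' @return A [structure_mask] whose set voxels are the surface voxels.
#' @export
mask_surface <- function(mask) {
  stop_if_empty(mask)
  a <- mask$data
  d <- dim(a)
  # neighbour-all-set test via shifts; border padded with FALSE
  shift_fill <- function(a, axis, by) {
    out <- array(FALSE, dim = d)
    n <- d[axis]
    if (abs(by) >= n) return(out)
    src <- if (by > 0) 1:(n - by) else (1 - by):n
    dst <- if (by > 0) (1 + by):n else 1:(n + by)
    ix <- list(1:d[1], 1:d[2], 1:d[3])
    ixs <- ix; ixs[[axis]] <- src
    ixd <- ix; ixd[[axis]] <- dst
    out[ixd[[1]], ixd[[2]], ixd[[3]]] <- a[ixs[[1]], ixs[[2]], ixs[[3]]]
    out
  }
  interior <- a
  for (axis in 1:3) {
    interior <- interior & shift_fill(a, axis, 1L) & shift_fill(a, axis, -1L)
  }
  out <- mask
  out$data <- a & !interior
  out
}

#' Valve construction by ventricular expansion and masking
#'
#' Builds a geometric cardiac valve as the Boolean intersection of an
#' isotropic expansion of a ventricle with the neighbouring chamber or
#' great vessel (mitral/tricuspid valve from LV/RV vs atrium; aortic and
#' pulmonary valve from LV/RV vs AA/PA). The expansion is computed by
#' thresholding the Euclidean distance transform of the ventricle at
#' `expansion_mm`, which is sub-voxel accurate and spacing-aware.
#'
#' @param ventricle,neighbor [structure_mask]s on the same grid.
#' @param expansion_mm isotropic expansion in mm (default 8).
#' @param label label for the derived valve mask.
#' @return A [structure_mask]; empty (with a warning) when the neighbour
#'   lies entirely farther than `expansion_mm` from the ventricle.
#' @export
derive_valve <- function(ventricle, neighbor, expansion_mm = 8,
                         label = "valve") {
  stop_if_grid_mismatch(ventricle, neighbor)
  stop_if_empty(ventricle, "ventricle")
  stop_if_empty(neighbor, "neighbor")
  if (!is.finite(expansion_mm) || expansion_mm < 0)
    stop("expansion_mm must be a non-negative number", call. = FALSE)
  d2 <- mask_distance_sq(ventricle)
  expanded <- array(d2 <= expansion_mm^2, dim = dim(ventricle$data))
  out <- ventricle
  out$data <- expanded & neighbor$data
  out$label <- label
  if (!any(out$data))
    warning(sprintf(
      "derived valve '%s' is empty: neighbor lies > %g mm from the ventricle",
      label, expansion_mm), call. = FALSE)
  out
}

#' Spherical conduction-node construction
#'
#' Rasterizes a sphere of given radius at an anatomically chosen landmark
#' (e.g. the SVC/RA junction for the sinoatrial node) onto the grid of a
#' template mask, using the voxel-center-inside-sphere rule. The landmark
#' is an input point: its anatomical placement is a manual step upstream
#' of this package.
#'
#' @param center sphere center, mm, length-3 (RL, AP, SI).
#' @param radius_mm sphere radius in mm (default 10, i.e. 1 cm).
#' @param template a [structure_mask] defining grid shape, spacing and
#'   origin.
#' @param label label for the node mask (e.g. `"SAN"`).
#' @return A [structure_mask].
#' @export
derive_node <- function(center, radius_mm = 10, template, label = "node") {
  if (!inherits(template, "structure_mask"))
    stop("template must be a structure_mask", call. = FALSE)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("geometry error: node radius must be > 0", call. = FALSE)
  center <- as.numeric(center)
  if (length(center) != 3L) stop("center must be length 3 (mm)", call. = FALSE)
  d <- dim(template$data)
  ax <- lapply(1:3, function(a)
    template$origin[a] + template$spacing[a] * (seq_len(d[a]) - 1))
  dist2 <- outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, "+"),
                 (ax[[3]] - center[3])^2, "+")
  out <- template
  out$data <- array(dist2 <= radius_mm^2, dim = d)
  out$label <- label
  if (!any(out$data))
    stop("geometry error: node sphere does not intersect the grid",
         call. = FALSE)
  out
}
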