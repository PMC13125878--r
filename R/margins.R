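# Internal organ-at-risk volume (IRV) margins: per-direction maximal
# outward bounding-box displacements, and anisotropic mask expansion.

#' Derive directional IRV margins from a phase grid
#'
#' For each of the six directions (right, left, anterior, posterior,
#' superior, inferior), the margin is the maximum *outward* shift of the
#' corresponding bounding-box face over the relevant phase pairs,
#' floored at 0 (a face moving inward does not enlarge the at-risk
#' envelope). Cardiac margins use the end-diastole to end-systole pair
#' within each available respiratory state; respiratory margins use the
#' end-exhale to end-inhale pair within each available cardiac phase;
#' cardiorespiratory margins are the per-direction sum of the two — the
#' worst-case envelope of combined motion, not a Boolean union of the
#' two IRVs.
#'
#' @param grid a `phase_grid`.
#' @param substructure substructure name.
#' @param motion_type `"cardiac"`, `"respiratory"`, or
#'   `"cardiorespiratory"`.
#' @return Named numeric vector of class `margin_set` (mm, all >= 0)
#'   with elements `right, left, anterior, posterior, superior,
#'   inferior` and attribute `motion_type`.
#' @export
derive_margins <- function(grid, substructure,
                           motion_type = c("cardiac", "respiratory",
                                           "cardiorespiratory")) {
  motion_type <- match.arg(motion_type)
  if (motion_type == "cardiorespiratory") {
    mc <- derive_margins(grid, substructure, "cardiac")
    mr <- derive_margins(grid, substructure, "respiratory")
    out <- unclass(mc) + unclass(mr)
    return(margin_set(out, "cardiorespiratory"))
  }
  pairs <- list()
  if (motion_type == "cardiac") {
    for (rs in grid$resp_states)
      if (has_mask(grid, substructure, "ED", rs) &&
          has_mask(grid, substructure, "ES", rs))
        pairs[[length(pairs) + 1]] <- list(
          A = get_mask(grid, substructure, "ED", rs),
          B = get_mask(grid, substructure, "ES", rs))
  } else {
    for (cp in grid$cardiac_phases)
      if (has_mask(grid, substructure, cp, "EE") &&
          has_mask(grid, substructure, cp, "EI"))
        pairs[[length(pairs) + 1]] <- list(
          A = get_mask(grid, substructure, cp, "EE"),
          B = get_mask(grid, substructure, cp, "EI"))
  }
  if (length(pairs) == 0L)
    stop(sprintf("insufficient phases for %s margins of '%s'",
                 motion_type, substructure), call. = FALSE)
  # outward sign per face: + faces (right/anterior/superior) outward is +,
  # - faces (left/posterior/inferior) outward is -
  outward_sign <- c(right = 1, left = -1, anterior = 1, posterior = -1,
                    superior = 1, inferior = -1)
  m <- rep(0, 6)
  names(m) <- FACE_NAMES
  for (p in pairs) {
    shift <- face_displacements(p$A, p$B)$faces
    m <- pmax(m, outward_sign * shift)
  }
  margin_set(pmax(m, 0), motion_type)
}

margin_set <- function(m, motion_type = NA_character_) {
  m <- as.numeric(m)
  if (length(m) != 6L) stop("margin set must have 6 values", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("parameter error: margins must be finite and >= 0 mm", call. = FALSE)
  names(m) <- FACE_NAMES
  attr(m, "motion_type") <- motion_type
  class(m) <- "margin_set"
  m
}

#' @export
print.margin_set <- function(x, ...) {
  cat(sprintf("<margin_set> %s (mm outward)\n",
              attr(x, "motion_type")))
  print(round(unclass(x)[FACE_NAMES], 3))
  invisible(x)
}

# 1D asymmetric binary dilation along one array axis by [-nlo, +nhi] voxels
dilate_axis <- function(a, axis, nlo, nhi) {
  if (nlo == 0L && nhi == 0L) return(a)
  d <- dim(a)
  out <- a
  ix <- list(1:d[1], 1:d[2], 1:d[3])
  n <- d[axis]
  for (by in c(if (nhi > 0) 1:nhi else integer(), if (nlo > 0) -(1:nlo) else integer())) {
    src <- if (by > 0) 1:(n - by) else (1 - by):n
    dst <- if (by > 0) (1 + by):n else 1:(n + by)
    ixs <- ix; ixs[[axis]] <- src
    ixd <- ix; ixd[[axis]] <- dst
    out[ixd[[1]], ixd[[2]], ixd[[3]]] <-
      out[ixd[[1]], ixd[[2]], ixd[[3]]] | a[ixs[[1]], ixs[[2]], ixs[[3]]]
  }
  out
}

#' Expand a structure by directional margins (IRV construction)
#'
#' Minkowski sum of the mask with the axis-aligned box spanning
#' `[-left, +right] x [-posterior, +anterior] x [-inferior, +superior]`
#' mm. Margins are converted to whole voxels by ceiling (conservative);
#' the result always contains the input mask. Expansion that would
#' extend beyond the grid is clipped with a warning.
#'
#' @param mask a [structure_mask].
#' @param margins a `margin_set` (or named length-6 vector, mm >= 0).
#' @return The expanded [structure_mask] (the IRV).
#' @export
expand_structure <- function(mask, margins) {
  if (!inherits(margins, "margin_set")) margins <- margin_set(margins)
  stop_if_empty(mask)
  m <- unclass(margins)
  vox <- function(mm, axis) as.integer(ceiling(mm / mask$spacing[axis] - 1e-9))
  n <- c(right = vox(m[["right"]], 1), left = vox(m[["left"]], 1),
         anterior = vox(m[["anterior"]], 2), posterior = vox(m[["posterior"]], 2),
         superior = vox(m[["superior"]], 3), inferior = vox(m[["inferior"]], 3))
  # clipping check: does any set voxel sit closer to the border than its margin?
  d <- dim(mask$data)
  idx <- which(mask$data, arr.ind = TRUE)
  clipped <-
    any(idx[, 1] + n[["right"]] > d[1]) || any(idx[, 1] - n[["left"]] < 1) ||
    any(idx[, 2] + n[["anterior"]] > d[2]) || any(idx[, 2] - n[["posterior"]] < 1) ||
    any(idx[, 3] + n[["superior"]] > d[3]) || any(idx[, 3] - n[["inferior"]] < 1)
  if (clipped)
    warning("IRV expansion clipped at the grid boundary", call. = FALSE)
  a <- mask$data
  a <- dilate_axis(a, 1L, n[["left"]], n[["right"]])
  a <- dilate_axis(a, 2L, n[["posterior"]], n[["anterior"]])
  a <- dilate_axis(a, 3L, n[["inferior"]], n[["superior"]])
  out <- mask
  out$data <- a
  out$label <- paste0(mask$label, "_IRV")
  out
}
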