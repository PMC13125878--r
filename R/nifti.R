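# Minimal NIfTI-1 I/O in base R (.nii and .nii.gz, single-file).
# Scope: 3D volumes, axis-aligned orientations. Written volumes use an
# sform affine; on read, any axis-aligned (permutation/flip) affine is
# reoriented to the package's RL/AP/SI (= RAS+) convention, and an
# explicit error is raised for oblique orientations.

NIFTI_DTYPES <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4` = list(what = "integer", size = 2L, signed = TRUE, bitpix = 16L),
  `8` = list(what = "integer", size = 4L, signed = TRUE, bitpix = 32L),
  `16` = list(what = "double", size = 4L, signed = TRUE, bitpix = 32L),
  `64` = list(what = "double", size = 8L, signed = TRUE, bitpix = 64L),
  `512` = list(what = "integer", size = 2L, signed = FALSE, bitpix = 16L)
)

open_bin <- function(path, mode) {
  con <- gzfile(path, mode)  # reads plain files transparently too
  con
}

#' Write a 3D volume as NIfTI-1
#'
#' Writes a single-file NIfTI-1 volume (`.nii`, or gzipped when the path
#' ends in `.gz`) with a diagonal sform affine encoding the package's
#' RL/AP/SI (RAS+) axis convention and the voxel-center origin.
#'
#' @param data 3D array (logical, integer, or double).
#' @param path output path.
#' @param spacing,origin grid geometry, mm.
#' @param datatype NIfTI datatype code: 2 (uint8), 16 (float32) or 64
#'   (float64).
#' @return The path, invisibly.
#' @export
write_nifti <- function(data, path, spacing, origin = c(0, 0, 0),
                        datatype = 64L) {
  d <- dim(data)
  if (length(d) != 3L) stop("only 3D volumes are supported", call. = FALSE)
  datatype <- as.integer(datatype)
  if (!as.character(datatype) %in% c("2", "16", "64"))
    stop("supported write datatypes: 2 (uint8), 16 (float32), 64 (float64)",
         call. = FALSE)
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  con <- open_bin(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }
  wi(348L, 4L)                       # sizeof_hdr
  wc("", 10L); wc("", 18L)           # data_type, db_name
  wi(0L, 4L); wi(0L, 2L)             # extents, session_error
  wc("r", 1L); wc("", 1L)            # regular, dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)   # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)         # intent_p1..3, intent_code
  wi(datatype, 2L); wi(spec$bitpix, 2L); wi(0L, 2L)  # datatype,bitpix,slice_start
  wf(c(1, spacing, 1, 1, 1, 1))      # pixdim[8]
  wf(352)                            # vox_offset
  wf(1); wf(0)                       # scl_slope, scl_inter
  wi(0L, 2L); wc("", 1L)             # slice_end, slice_code
  writeBin(as.raw(2L), con)          # xyzt_units: mm
  wf(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                  # glmax, glmin
  wc("cardiomotion", 80L); wc("", 24L)  # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)             # qform_code=0, sform_code=1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))     # quatern b,c,d; qoffset x,y,z
  wf(c(spacing[1], 0, 0, origin[1])) # srow_x
  wf(c(0, spacing[2], 0, origin[2])) # srow_y
  wf(c(0, 0, spacing[3], origin[3])) # srow_z
  wc("", 16L)
  wc("n+1", 4L)                      # magic
  writeBin(raw(4L), con)             # no extensions
  if (spec$what == "integer") {
    writeBin(as.integer(data), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(data), con, size = spec$size, endian = "little")
  }
  invisible(path)
}

# quaternion (b,c,d) + qfac -> 3x3 rotation, per the NIfTI-1 standard
quat_to_mat <- function(b, c, d, qfac) {
  a2 <- 1 - b * b - c * c - d * d
  a <- sqrt(max(a2, 0))
  m <- rbind(
    c(a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c)),
    c(2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b)),
    c(2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - b * b - c * c))
  m[, 3] <- m[, 3] * ifelse(qfac < 0, -1, 1)
  m
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 volume (plain or gzipped), applies
#' scl_slope/scl_inter scaling when set, and reorients the array to the
#' package's RL/AP/SI (RAS+) convention from the sform (preferred) or
#' qform affine. Axis-aligned permutations and flips are handled; an
#' oblique affine raises an error, as the mapping to RL/AP/SI would be
#' ambiguous.
#'
#' @param path file path.
#' @return List with `data` (3D array), `spacing`, `origin` (mm, RAS+).
#' @export
read_nifti <- function(path) {
  con <- open_bin(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header", call. = FALSE)
  endian <- "little"
  geti <- function(off, size, n = 1L)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian)
  getf <- function(off, n = 1L)
    readBin(hdr[(off + 1):(off + 4L * n)], "double", n = n, size = 4L,
            endian = endian)
  if (geti(0L, 4L) != 348L) {
    endian <- "big"
    if (geti(0L, 4L) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic)", call. = FALSE)
  dims <- geti(40L, 2L, 8L)
  ndim <- dims[1]
  if (ndim < 3L || any(dims[5:8][seq_len(max(0, ndim - 3))] > 1L))
    stop("only 3D volumes are supported", call. = FALSE)
  d <- dims[2:4]
  datatype <- geti(70L, 2L)
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec))
    stop(sprintf("unsupported NIfTI datatype %d", datatype), call. = FALSE)
  pixdim <- getf(76L, 8L)
  vox_offset <- getf(108L)
  scl_slope <- getf(112L)
  scl_inter <- getf(116L)
  qform_code <- geti(252L, 2L)
  sform_code <- geti(254L, 2L)
  n <- prod(d)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data", call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  a <- array(vals, dim = d)

  # affine: voxel (0-based) index -> mm
  if (sform_code > 0L) {
    M <- rbind(getf(280L, 4L), getf(296L, 4L), getf(312L, 4L))
  } else if (qform_code > 0L) {
    b <- getf(256L); cc <- getf(260L); dd <- getf(264L)
    off <- getf(268L, 3L)
    R <- quat_to_mat(b, cc, dd, pixdim[1])
    M <- cbind(R %*% diag(pixdim[2:4]), off)
  } else {
    M <- cbind(diag(pixdim[2:4]), c(0, 0, 0))
  }
  reor <- reorient_to_ras(a, M)
  list(data = reor$data, spacing = reor$spacing, origin = reor$origin)
}

# Map an axis-aligned affine to RAS+: permute/flip array axes so that
# array axis 1/2/3 increase toward right/anterior/superior.
reorient_to_ras <- function(a, M) {
  R <- M[, 1:3, drop = FALSE]
  perm <- integer(3)
  sgn <- numeric(3)
  for (w in 1:3) {
    v <- which.max(abs(R[w, ]))
    others <- abs(R[w, -v])
    if (any(others > 1e-4 * max(abs(R[w, v]), 1e-12)))
      stop("orientation ambiguity: oblique NIfTI affine cannot be mapped to RL/AP/SI",
           call. = FALSE)
    perm[w] <- v
    sgn[w] <- sign(R[w, v])
  }
  if (length(unique(perm)) != 3L)
    stop("orientation ambiguity: degenerate NIfTI affine", call. = FALSE)
  d <- dim(a)
  a2 <- aperm(a, perm)
  d2 <- d[perm]
  spacing <- numeric(3)
  first_idx <- integer(3)  # 0-based voxel index (in file order) of new origin
  for (w in 1:3) {
    spacing[w] <- abs(R[w, perm[w]])
    first_idx[perm[w]] <- if (sgn[w] < 0) d[perm[w]] - 1L else 0L
  }
  for (w in 1:3) {
    if (sgn[w] < 0) {
      idx <- list(1:d2[1], 1:d2[2], 1:d2[3])
      idx[[w]] <- rev(idx[[w]])
      a2 <- a2[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
  }
  origin <- as.numeric(M %*% c(first_idx, 1))
  if (any(spacing <= 0))
    stop("invalid NIfTI: non-positive voxel spacing", call. = FALSE)
  list(data = a2, spacing = spacing, origin = origin)
}

#' Mask and dose grid file I/O
#'
#' `write_mask()`/`read_mask()` store a [structure_mask] as a uint8
#' NIfTI volume; reading enforces binary values (0/1 after rounding)
#' and the axis convention from the affine. `write_dose()`/`read_dose()`
#' do the same for a [dose_grid] at float64 precision.
#'
#' @param mask a [structure_mask]; `dose` a [dose_grid].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param label substructure label to attach on read.
#' @return `read_mask()` a [structure_mask]; `read_dose()` a
#'   [dose_grid]; writers return the path invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  write_nifti(array(as.integer(mask$data), dim = dim(mask$data)), path,
              mask$spacing, mask$origin, datatype = 2L)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, label = NA_character_) {
  v <- read_nifti(path)
  r <- round(v$data)
  if (any(!r %in% c(0, 1)) || any(abs(v$data - r) > 1e-6))
    stop("non-binary volume passed as mask", call. = FALSE)
  structure_mask(array(r == 1, dim = dim(v$data)), v$spacing, v$origin, label)
}

#' @rdname write_mask
#' @param dose a [dose_grid].
#' @export
write_dose <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  write_nifti(dose$values, path, dose$spacing, dose$origin, datatype = 64L)
}

#' @rdname write_mask
#' @export
read_dose <- function(path) {
  v <- read_nifti(path)
  dose_grid(v$data, v$spacing, v$origin)
}
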