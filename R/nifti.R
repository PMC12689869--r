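# Minimal NIfTI-1 single-file I/O (.nii / .nii.gz): enough of the standard to
# round-trip 3D image and label volumes with voxel spacing. No pre-installed
# R package reads NIfTI in this stack, so the codec is implemented here and
# cross-checked against Python's nibabel in the test suite.

nifti_dtypes <- list(
  uint8 = list(code = 2L, bitpix = 8L, what = "integer", size = 1L, signed = FALSE),
  int16 = list(code = 4L, bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32 = list(code = 8L, bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "numeric", size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "numeric", size = 8L, signed = TRUE)
)

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D volume as NIfTI-1
#'
#' @param data numeric or integer 3D array in `(x, y, z)` order.
#' @param path output path; `.nii` or `.nii.gz`.
#' @param spacing voxel spacing per axis in mm (length 3, recycled).
#' @param dtype storage type: `"float32"`, `"int16"`, `"uint8"`, `"int32"`
#'   or `"float64"`.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), dtype = "float32") {
  stopifnot(length(dim(data)) == 3L)
  dt <- nifti_dtypes[[dtype]]
  if (is.null(dt)) stop(sprintf("unsupported dtype '%s'", dtype), call. = FALSE)
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  wi <- function(v, size = 4L) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(348L)                               # sizeof_hdr
  writeBin(raw(36L), con)                # unused (data_type, db_name, extents, session_error, regular, dim_info)
  wi(c(3L, dim(data), 1L, 1L, 1L, 1L), size = 2L) # dim[8]
  wf(c(0, 0, 0))                         # intent_p1..p3
  wi(0L, size = 2L)                      # intent_code
  wi(dt$code, size = 2L)                 # datatype
  wi(dt$bitpix, size = 2L)               # bitpix
  wi(0L, size = 2L)                      # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))          # pixdim[8] (qfac = 1)
  wf(352)                                # vox_offset
  wf(1); wf(0)                           # scl_slope, scl_inter
  wi(0L, size = 2L)                      # slice_end
  writeBin(raw(2L), con)                 # slice_code, xyzt_units
  wf(c(0, 0, 0))                         # cal_max, cal_min, slice_duration
  wf(0)                                  # toffset
  wi(c(0L, 0L))                          # glmax, glmin
  writeBin(raw(104L), con)               # descrip[80] + aux_file[24]
  wi(0L, size = 2L)                      # qform_code
  wi(1L, size = 2L)                      # sform_code
  wf(c(0, 0, 0, 0, 0, 0))                # quatern_b..d, qoffset_x..z
  wf(c(spacing[1L], 0, 0, 0))            # srow_x
  wf(c(0, spacing[2L], 0, 0))            # srow_y
  wf(c(0, 0, spacing[3L], 0))            # srow_z
  writeBin(raw(16L), con)                # intent_name[16]
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)                 # extension flag
  if (dt$what == "integer") {
    storage.mode(data) <- "integer"
    writeBin(as.vector(data), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.vector(as.numeric(data)), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports uncompressed and gzipped single-file NIfTI with the data types
#' written by [write_nifti()]; applies the scl slope/intercept when present.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return `list(data = 3D array, spacing = numeric(3))`.
#' @export
read_nifti <- function(path) {
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  rint <- function(off, size, n = 1L, signed = TRUE) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = signed)
  }
  rfloat <- function(off, n = 1L) {
    readBin(hdr[(off + 1L):(off + 4L * n)], "numeric", n = n, size = 4L,
            endian = "little")
  }
  if (rint(0L, 4L) != 348L) stop("not a little-endian NIfTI-1 file", call. = FALSE)
  dims <- rint(40L, 2L, 8L)
  nd <- dims[1L]
  if (nd < 3L) dims[(nd + 2L):4L] <- 1L
  shape <- dims[2:4]
  datatype <- rint(70L, 2L)
  dt <- NULL
  for (nm in names(nifti_dtypes)) {
    if (nifti_dtypes[[nm]]$code == datatype) dt <- nifti_dtypes[[nm]]
  }
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype code %d", datatype), call. = FALSE)
  pixdim <- rfloat(76L, 8L)
  vox_offset <- rfloat(108L)
  scl_slope <- rfloat(112L)
  scl_inter <- rfloat(116L)
  skip <- vox_offset - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n_vox <- prod(shape)
  vals <- if (dt$what == "integer" && dt$size <= 2L) {
    readBin(con, "integer", n = n_vox, size = dt$size, endian = "little",
            signed = dt$signed)
  } else if (dt$what == "integer") {
    readBin(con, "integer", n = n_vox, size = dt$size, endian = "little")
  } else {
    readBin(con, "numeric", n = n_vox, size = dt$size, endian = "little")
  }
  if (length(vals) != n_vox) stop("truncated NIfTI data section", call. = FALSE)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, shape), spacing = pixdim[2:4])
}

# Volume layout helpers: phantom cases store (slice, H, W); NIfTI stores
# (x, y, z) = (W, H, slice).
volume_to_nifti_order <- function(v) aperm(v, c(3L, 2L, 1L))
nifti_to_volume_order <- function(v) aperm(v, c(3L, 2L, 1L))

#' Write a phantom case as a NIfTI image/label pair
#'
#' @param case a [generate_case()] result.
#' @param dir output directory; files `<stem>_image.nii.gz` and
#'   `<stem>_label.nii.gz`.
#' @param stem file stem.
#' @param slice_thickness out-of-plane spacing in mm.
#' @return The two file paths, invisibly.
#' @export
write_case_nifti <- function(case, dir, stem = "case", slice_thickness = 5) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- c(case$spacing, case$spacing, slice_thickness)
  img <- file.path(dir, paste0(stem, "_image.nii.gz"))
  lab <- file.path(dir, paste0(stem, "_label.nii.gz"))
  write_nifti(volume_to_nifti_order(case$hu_volume), img, sp, "float32")
  write_nifti(volume_to_nifti_order(case$label_volume), lab, sp, "uint8")
  invisible(c(image = img, label = lab))
}

#' Read a NIfTI image/label pair into the case layout
#'
#' @param image_path,label_path NIfTI files written by [write_case_nifti()]
#'   or any compatible tool.
#' @return `list(hu_volume, label_volume, spacing)` with `(slice, H, W)`
#'   arrays.
#' @export
read_case_nifti <- function(image_path, label_path = NULL) {
  img <- read_nifti(image_path)
  out <- list(hu_volume = nifti_to_volume_order(img$data),
              spacing = img$spacing[1L])
  if (!is.null(label_path)) {
    lab <- read_nifti(label_path)
    out$label_volume <- array(as.integer(round(nifti_to_volume_order(lab$data))),
                              dim(out$hu_volume))
  }
  out
}
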