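#' Minimal NIfTI-1 volume I/O
#'
#' Self-contained reader/writer for uncompressed single-file NIfTI-1
#' (`.nii`) volumes with float32 data, little-endian, up to 4
#' dimensions — sufficient to exchange echo stacks and parameter maps
#' with standard neuroimaging tools (nibabel, FSL, ITK-SNAP).  The
#' affine is a diagonal sform built from the pixel dimensions; units
#' are recorded in the header `descrip` field.
#'
#' @param x Numeric array (2-4 dimensions).
#' @param path Output path ending in `.nii`.
#' @param pixdim Voxel dimensions, one per array dimension (mm for the
#'   first three, arbitrary for the fourth).
#' @param descrip Free-text description (at most 79 characters kept).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = rep(1, length(dim(x))),
                        descrip = "") {
  dm <- dim(x)
  if (is.null(dm)) stop("'x' must be an array")
  if (length(dm) > 4L) stop("at most 4 dimensions supported")
  if (length(pixdim) != length(dm)) {
    stop("'pixdim' must have one entry per array dimension")
  }
  dim8 <- c(length(dm), dm, rep(1L, 7L - length(dm)))
  pd8 <- c(1, pixdim, rep(1, 7 - length(pixdim)))
  con <- file(path, "wb")
  on.exit(close(con))
  wi32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wi16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  wf32 <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wchar <- function(s, len) {
    raw_s <- charToRaw(substr(s, 1, len - 1))
    writeBin(c(raw_s, raw(len - length(raw_s))), con)
  }
  wi32(348)                       # sizeof_hdr
  wchar("", 10); wchar("", 18)    # data_type, db_name
  wi32(0); wi16(0)                # extents, session_error
  writeBin(charToRaw("r"), con)   # regular
  writeBin(raw(1), con)           # dim_info
  wi16(dim8)                      # dim[8]
  wf32(c(0, 0, 0))                # intent_p1..p3
  wi16(0)                         # intent_code
  wi16(16); wi16(32)              # datatype float32, bitpix
  wi16(0)                         # slice_start
  wf32(pd8)                       # pixdim[8]
  wf32(352)                       # vox_offset
  wf32(1); wf32(0)                # scl_slope, scl_inter
  wi16(0); writeBin(raw(1), con)  # slice_end, slice_code
  writeBin(as.raw(2L), con)       # xyzt_units: mm
  wf32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  wi32(0); wi32(0)                # glmax, glmin
  wchar(descrip, 80)
  wchar("", 24)                   # aux_file
  wi16(0); wi16(1)                # qform_code, sform_code
  wf32(c(0, 0, 0)); wf32(c(0, 0, 0)) # quatern, qoffset
  wf32(c(pd8[2], 0, 0, 0))        # srow_x
  wf32(c(0, pd8[3], 0, 0))        # srow_y
  wf32(c(0, 0, pd8[4], 0))        # srow_z
  wchar("", 16)                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con) # magic
  writeBin(raw(4), con)           # extension flag
  wf32(as.vector(x))
  invisible(path)
}

#' @rdname write_nifti
#' @return `read_nifti()` returns the array with attributes `pixdim`
#'   and `descrip`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = "little")
  }
  if (rd(0, "integer", 1, 4) != 348L) stop("not a NIfTI-1 file")
  dim8 <- rd(40, "integer", 8, 2)
  datatype <- rd(70, "integer", 1, 2)
  if (datatype != 16L) stop("only float32 NIfTI volumes supported")
  pd8 <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  descrip <- rawToChar(rd(148, "raw", 80, 1)[cumsum(rd(148, "raw", 80, 1) == as.raw(0)) == 0])
  nd <- dim8[1]
  dm <- dim8[2:(1 + nd)]
  if (vox_offset > 352) readBin(con, "raw", vox_offset - 352)
  x <- readBin(con, "double", n = prod(dm), size = 4, endian = "little")
  array(x, dm,
        dimnames = NULL) -> out
  attr(out, "pixdim") <- pd8[2:(1 + nd)]
  attr(out, "descrip") <- descrip
  out
}

#' Export a patient's echo stack as NIfTI plus JSON sidecar
#'
#' Writes one 4D volume (rows x cols x 1 x echoes) per protocol,
#' together with a sidecar recording the protocol timing, noise level
#' and (for simulated patients) the ground truth.
#'
#' @param patient A patient record from [simulate_cohort()].
#' @param protocols Named list of [protocol()] objects matching the
#'   record's series.
#' @param sigma Noise SD used at acquisition.
#' @param dir Output directory (created if missing).
#' @param pixel_spacing In-plane pixel size in mm.
#' @return Character vector of the `.nii` paths written, invisibly.
#' @export
export_patient_nifti <- function(patient, protocols, sigma, dir,
                                 pixel_spacing = 2.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(patient$series_by_protocol)) {
    ser <- patient$series_by_protocol[[nm]]
    arr <- array(ser, c(dim(ser)[1:2], 1L, dim(ser)[3]))
    p <- file.path(dir, sprintf("%s_%s.nii", patient$id, nm))
    write_nifti(arr, p, pixdim = c(pixel_spacing, pixel_spacing, 1, 1),
                descrip = sprintf("echo stack %s; magnitude a.u.", nm))
    proto <- protocols[[nm]]
    jsonlite::write_json(list(
      id = patient$id, protocol = nm,
      te_s = echo_times(proto), sigma = sigma,
      truth = list(w = patient$true_state$w, f = patient$true_state$f,
                   r2star = patient$true_state$r2star,
                   swap_applied = patient$swap_applied)
    ), sub("\\.nii$", ".json", p), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
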