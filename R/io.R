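#' Volume I/O (NIfTI-1)
#'
#' Minimal single-file NIfTI-1 support (`.nii`, `.nii.gz`): 3D volumes,
#' dtypes uint8 / int16 / int32 / float32 / float64, both endiannesses on
#' read, little-endian on write. The isotropic voxel size is carried in
#' `pixdim`; the energy (kVp) or material tag is stored in the header
#' `descrip` field and recovered on read. This intentionally covers only
#' what the pipeline writes; it is not a general NIfTI implementation.
#'
#' @param vol a [energy_volume()], [concentration_volume()], or bare
#'   3D array (label volumes included).
#' @param path output path; gzip compression if it ends in `.gz`.
#' @param dtype on-disk data type.
#' @return `read_volume()` returns the array with `voxel_mm` and, when
#'   recorded, `kvp`/`material` attributes restored (and the matching
#'   class). `write_volume()` returns `path` invisibly.
#' @export
write_volume <- function(vol, path,
                         dtype = c("float32", "float64", "int16", "int32",
                                   "uint8")) {
  dtype <- match.arg(dtype)
  stopifnot(length(dim(vol)) == 3)
  d <- dim(vol)
  voxel_mm <- attr(vol, "voxel_mm") %||% 1
  descrip <- if (!is.null(attr(vol, "kvp")))
    sprintf("demict kvp=%s", attr(vol, "kvp"))
  else if (!is.null(attr(vol, "material")))
    sprintf("demict material=%s", attr(vol, "material"))
  else "demict"
  code <- switch(dtype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L)
  bitpix <- switch(dtype, uint8 = 8L, int16 = 16L, int32 = 32L,
                   float32 = 32L, float64 = 64L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(s, n) {
    r <- charToRaw(s)
    c(r[seq_len(min(n, length(r)))], raw(max(0, n - length(r))))
  }
  wb(348L, 4)                               # sizeof_hdr
  writeBin(raw(10 + 18), con)               # data_type, db_name
  wb(0L, 4); wb(0L, 2)                      # extents, session_error
  writeBin(charToRaw("r"), con); writeBin(raw(1), con)  # regular, dim_info
  wb(as.integer(c(3, d, 1, 1, 1, 1)), 2)    # dim[8]
  wb(numeric(3), 4)                         # intent_p1..3
  wb(0L, 2)                                 # intent_code
  wb(code, 2); wb(bitpix, 2); wb(0L, 2)     # datatype, bitpix, slice_start
  wb(c(1, rep(voxel_mm, 3), 0, 0, 0, 0), 4) # pixdim[8]
  wb(352, 4)                                # vox_offset
  wb(c(1, 0), 4)                            # scl_slope, scl_inter
  wb(0L, 2); writeBin(raw(1), con)          # slice_end, slice_code
  writeBin(as.raw(2L), con)                 # xyzt_units = mm
  wb(numeric(4), 4)                         # cal_max/min, slice_dur, toffset
  wb(c(0L, 0L), 4)                          # glmax, glmin
  writeBin(pad(descrip, 80), con)           # descrip
  writeBin(raw(24), con)                    # aux_file
  wb(c(0L, 1L), 2)                          # qform_code, sform_code
  wb(numeric(6), 4)                         # quatern, qoffset
  wb(c(voxel_mm, 0, 0, 0), 4)               # srow_x
  wb(c(0, voxel_mm, 0, 0), 4)               # srow_y
  wb(c(0, 0, voxel_mm, 0), 4)               # srow_z
  writeBin(raw(16), con)                    # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)                     # no extensions
  v <- as.vector(vol)
  if (dtype %in% c("float32", "float64"))
    writeBin(as.numeric(v), con, size = bitpix / 8, endian = "little")
  else
    writeBin(as.integer(round(v)), con, size = bitpix / 8, endian = "little")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("volume file does not exist: %s", path), call. = FALSE)
  con <- gzfile(path, "rb")   # reads plain files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file (truncated header)",
                              call. = FALSE)
  rb <- function(off, what, n, size, endian) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rb(0, "integer", 1, 4, endian) != 348L) {
    endian <- "big"
    if (rb(0, "integer", 1, 4, endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic)", call. = FALSE)
  dim0 <- rb(40, "integer", 8, 2, endian)
  nd <- dim0[1]
  if (nd < 3) stop("expected a 3D volume", call. = FALSE)
  d <- dim0[2:4]
  if (nd > 3 && any(dim0[5:(nd + 1)] > 1))
    stop("only 3D volumes are supported", call. = FALSE)
  code <- rb(70, "integer", 1, 2, endian)
  pixdim <- rb(76, "numeric", 8, 4, endian)
  vox_offset <- rb(108, "numeric", 1, 4, endian)
  scl_slope <- rb(112, "numeric", 1, 4, endian)
  scl_inter <- rb(116, "numeric", 1, 4, endian)
  descrip <- {
    r <- hdr[149:228]
    r <- r[cummax(as.integer(r != 0)) > 0 | as.integer(r) != 0]
    r <- r[seq_len(max(0, which(r != 0)))]
    if (length(r)) rawToChar(r[r != 0]) else ""
  }
  n <- prod(d)
  skip <- max(0, round(vox_offset) - 348)
  if (skip > 0) readBin(con, "raw", skip)
  v <- switch(as.character(code),
    "2" = as.numeric(readBin(con, "integer", n, 1, signed = FALSE,
                             endian = endian)),
    "4" = as.numeric(readBin(con, "integer", n, 2, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", n, 4, endian = endian)),
    "16" = readBin(con, "numeric", n, 4, endian = endian),
    "64" = readBin(con, "numeric", n, 8, endian = endian),
    stop(sprintf("unsupported NIfTI datatype code %d", code), call. = FALSE))
  if (length(v) < n) stop("truncated NIfTI data section", call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  dim(v) <- d
  voxel_mm <- pixdim[2]
  if (grepl("kvp=", descrip)) {
    kvp <- as.numeric(sub(".*kvp=([0-9.]+).*", "\\1", descrip))
    return(energy_volume(v, voxel_mm, kvp))
  }
  if (grepl("material=", descrip)) {
    mat <- sub(".*material=([a-z]+).*", "\\1", descrip)
    return(concentration_volume(v, voxel_mm, mat))
  }
  attr(v, "voxel_mm") <- voxel_mm
  v
}

#' Read a co-registered energy pair
#'
#' @param path40,path80 NIfTI paths for the 40 and 80 kVp volumes.
#' @return List `v40`, `v80`; errors if grids mismatch.
#' @export
read_volume_pair <- function(path40, path80) {
  v40 <- read_volume(path40)
  v80 <- read_volume(path80)
  check_same_grid(v40, v80, "paired energy volumes")
  if (!isTRUE(all.equal(attr(v40, "voxel_mm"), attr(v80, "voxel_mm"))))
    stop("paired volumes have different voxel sizes", call. = FALSE)
  list(v40 = v40, v80 = v80)
}

#' Biomarker table I/O
#'
#' UTF-8 CSV with a header row; the canonical table artifact of the
#' pipeline.
#'
#' @param records biomarker data frame from [quantify_biomarkers()].
#' @param path CSV path.
#' @export
write_biomarkers_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_biomarkers_csv
#' @export
read_biomarkers_csv <- function(path) {
  read.csv(path, fileEncoding = "UTF-8")
}
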