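# MetaImage (.mha/.mhd) and NIfTI-1 (.nii/.nii.gz) I/O for axis-aligned
# volumes. Only the geometry this package models is honored: spacing and
# origin. Orientation is assumed identity (direction cosines / qform-sform
# rotations are rejected); this matches the axis-aligned grid model used
# throughout.

#' Read a 3D volume from MetaImage or NIfTI
#'
#' Supported: uncompressed local-data `.mha`, `.mhd` with a sidecar `.raw`/
#' `.zraw`(uncompressed only), and NIfTI-1 `.nii` / `.nii.gz`. Geometry
#' (spacing, origin) is taken from the header; the grid must be axis-aligned.
#'
#' @param path file to read.
#' @param modality `"CT"` or `"CBCT"` tag for the returned volume.
#' @param as_mask if `TRUE` return a [binary_mask()] (values must be 0/1).
#' @return An `ImageVolume` (or `BinaryMask` when `as_mask = TRUE`).
#' @export
read_volume <- function(path, modality = "CT", as_mask = FALSE) {
  if (!file.exists(path)) stop("cannot read volume: file not found: ", path)
  ext <- tolower(path)
  v <- if (grepl("\\.mha$|\\.mhd$", ext)) read_metaimage(path)
  else if (grepl("\\.nii$|\\.nii\\.gz$", ext)) read_nifti(path)
  else stop("unsupported volume format (expect .mha/.mhd/.nii/.nii.gz): ", path)
  if (as_mask) binary_mask(v$voxels, v$spacing, v$origin)
  else image_volume(v$voxels, v$spacing, v$origin, modality)
}

#' Write a 3D volume to MetaImage or NIfTI
#'
#' Format is chosen from the extension. Voxels are stored as float32 (masks
#' as uint8), so round-tripping an image is exact to float32 precision and a
#' mask is exact.
#'
#' @param v `ImageVolume` or `BinaryMask`.
#' @param path output path ending in `.mha`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  ext <- tolower(path)
  if (grepl("\\.mha$", ext)) write_metaimage(v, path)
  else if (grepl("\\.nii$|\\.nii\\.gz$", ext)) write_nifti(v, path)
  else stop("unsupported output format (expect .mha/.nii/.nii.gz): ", path)
  invisible(path)
}

met_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer", MET_SHORT = "integer",
               MET_USHORT = "integer", MET_INT = "integer", MET_UINT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
met_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
               MET_INT = 4, MET_UINT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)
met_signed <- c(MET_UCHAR = FALSE, MET_CHAR = TRUE, MET_SHORT = TRUE, MET_USHORT = FALSE,
                MET_INT = TRUE, MET_UINT = FALSE, MET_FLOAT = TRUE, MET_DOUBLE = TRUE)

# Read one header line from a binary connection without read-ahead, so the
# connection is positioned exactly at the start of LOCAL pixel data afterwards.
read_line_raw <- function(con) {
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) return(if (length(bytes)) rawToChar(bytes) else character(0))
    if (b == as.raw(10)) return(rawToChar(bytes))
    if (b != as.raw(13)) bytes <- c(bytes, b)
  }
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- read_line_raw(con)
    if (length(line) == 0) stop("malformed MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed MetaImage header line in ", path, ": ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  if (ndims != 3) stop("only 3D MetaImage supported: ", path)
  dm <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% hdr$ElementSize %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% "0 0 0", "\\s+")[[1]])
  if (!is.null(hdr$TransformMatrix)) {
    tm <- as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]])
    if (max(abs(tm - as.numeric(diag(3)))) > 1e-6)
      stop("non-identity TransformMatrix (oblique grid) unsupported: ", path)
  }
  type <- hdr$ElementType
  if (is.null(type) || !type %in% names(met_types)) stop("unsupported ElementType in ", path)
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage unsupported: ", path)
  n <- prod(dm)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_con <- file(file.path(dirname(path), hdr$ElementDataFile), "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vox <- readBin(raw_con, what = met_types[[type]], n = n, size = met_sizes[[type]],
                 signed = met_signed[[type]], endian = "little")
  if (length(vox) != n) stop("truncated MetaImage data: ", path)
  list(voxels = array(as.numeric(vox), dim = dm), spacing = spacing, origin = origin)
}

write_metaimage <- function(v, path) {
  is_mask <- inherits(v, "BinaryMask")
  dm <- dim(v$voxels)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(v$origin, digits = 17), collapse = " ")),
           "CenterOfRotation = 0 0 0",
           paste("ElementSpacing =", paste(format(v$spacing, digits = 17), collapse = " ")),
           paste("DimSize =", paste(dm, collapse = " ")),
           paste("ElementType =", if (is_mask) "MET_UCHAR" else "MET_FLOAT"),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (is_mask) writeBin(as.integer(v$voxels), con, size = 1)
  else writeBin(as.numeric(v$voxels), con, size = 4, endian = "little")
}

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", tolower(path))) gzfile(path, mode) else file(path, mode)
}

read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = "little")
  if (sizeof_hdr != 348) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  readBin(con, "raw", 36)                      # unused fields
  dimv <- readBin(con, "integer", 8, 2, endian = "little")
  if (dimv[1] < 3) stop("need a 3D NIfTI volume: ", path)
  dm <- dimv[2:4]
  readBin(con, "raw", 14)                      # intent params/codes
  datatype <- readBin(con, "integer", 1, 2, endian = "little")
  readBin(con, "integer", 1, 2, endian = "little")  # bitpix
  readBin(con, "integer", 1, 2, endian = "little")  # slice_start
  pixdim <- readBin(con, "numeric", 8, 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, 4, endian = "little")
  scl_slope <- readBin(con, "numeric", 1, 4, endian = "little")
  scl_inter <- readBin(con, "numeric", 1, 4, endian = "little")
  readBin(con, "raw", 132)            # slice_end..aux_file
  qform_code <- readBin(con, "integer", 1, 2, endian = "little")
  sform_code <- readBin(con, "integer", 1, 2, endian = "little")
  quat <- readBin(con, "numeric", 6, 4, endian = "little")  # quatern b,c,d + qoffset x,y,z
  srow <- matrix(readBin(con, "numeric", 12, 4, endian = "little"), 3, 4, byrow = TRUE)
  readBin(con, "raw", 20)             # intent_name + magic
  spacing <- abs(pixdim[2:4])
  if (sform_code > 0) {
    rot <- srow[, 1:3]
    if (max(abs(abs(rot) - diag(spacing))) > 1e-3 * max(spacing))
      stop("rotated/oblique NIfTI grids unsupported: ", path)
    origin <- srow[, 4]
  } else if (qform_code > 0) {
    if (max(abs(quat[1:3])) > 1e-6) stop("rotated qform unsupported: ", path)
    origin <- quat[4:6]
  } else origin <- c(0, 0, 0)
  n <- prod(dm)
  # skip to vox_offset from start of data stream
  already <- 348
  skip <- round(vox_offset) - already
  if (skip > 0) readBin(con, "raw", skip)
  vox <- switch(as.character(datatype),
    "2" = readBin(con, "integer", n, 1, signed = FALSE, endian = "little"),
    "4" = readBin(con, "integer", n, 2, signed = TRUE, endian = "little"),
    "8" = readBin(con, "integer", n, 4, signed = TRUE, endian = "little"),
    "16" = readBin(con, "numeric", n, 4, endian = "little"),
    "64" = readBin(con, "numeric", n, 8, endian = "little"),
    "512" = readBin(con, "integer", n, 2, signed = FALSE, endian = "little"),
    stop("unsupported NIfTI datatype ", datatype, ": ", path))
  if (length(vox) != n) stop("truncated NIfTI data: ", path)
  vox <- as.numeric(vox)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vox <- vox * scl_slope + scl_inter
  list(voxels = array(vox, dim = dm), spacing = spacing, origin = origin)
}

write_nifti <- function(v, path) {
  is_mask <- inherits(v, "BinaryMask")
  dm <- dim(v$voxels)
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wb_i <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wb_f <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wb_i(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)
  wb_i(c(3, dm, 1, 1, 1, 1), 2)                  # dim
  writeBin(raw(14), con)
  wb_i(if (is_mask) 2 else 16, 2)                # datatype uint8 / float32
  wb_i(if (is_mask) 8 else 32, 2)                # bitpix
  wb_i(0, 2)                                     # slice_start
  wb_f(c(1, v$spacing, 0, 0, 0, 0))              # pixdim
  wb_f(352)                                      # vox_offset
  wb_f(c(1, 0))                                  # scl_slope, scl_inter
  writeBin(raw(132), con)                        # slice_end..aux_file
  wb_i(c(0, 1), 2)                               # qform_code=0, sform_code=1
  wb_f(c(0, 0, 0, 0, 0, 0))                      # quaternion + qoffset
  wb_f(c(v$spacing[1], 0, 0, v$origin[1],
         0, v$spacing[2], 0, v$origin[2],
         0, 0, v$spacing[3], v$origin[3]))       # srow
  writeBin(c(charToRaw("cbctreg"), raw(16 - 7)), con)   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)            # magic
  writeBin(raw(4), con)                                 # extension flag
  if (is_mask) wb_i(v$voxels, 1) else wb_f(v$voxels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
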