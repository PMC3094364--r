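#' Read a CT volume from a standard medical-image file
#'
#' Supports MetaImage (`.mha` with embedded data, `.mhd` + `.raw`) and
#' NIfTI-1 (`.nii`, `.nii.gz`, via \pkg{RNifti}).  Only axis-aligned
#' geometries are accepted: the NIfTI xform must be diagonal (no oblique
#' direction cosines) and MetaImage `TransformMatrix`, when present, must be
#' the identity.
#'
#' @param path file to read.
#' @param format `"auto"` (from the extension), `"metaimage"` or `"nifti"`.
#' @param modality modality tag stored on the returned volume.
#' @return An [image_volume()].
#' @seealso [write_image()]
#' @export
read_image <- function(path, format = c("auto", "metaimage", "nifti"),
                       modality = "synthetic") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("cannot read image: file '%s' does not exist", path),
         call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         metaimage = read_metaimage(path, modality),
         nifti = read_nifti(path, modality))
}

#' Write a CT volume to a standard medical-image file
#'
#' The written file round-trips through [read_image()] with identical voxel
#' values (data are stored as IEEE doubles for MetaImage and as the NIfTI
#' float64 datatype).
#'
#' @param img an [image_volume()].
#' @param path output path; parent directory must exist.
#' @param format `"auto"`, `"metaimage"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, format = c("auto", "metaimage", "nifti")) {
  stopifnot_image(img)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!dir.exists(dirname(path)))
    stop(sprintf("parent directory '%s' does not exist", dirname(path)),
         call. = FALSE)
  switch(format,
         metaimage = write_metaimage(img, path),
         nifti = write_nifti_image(img, path))
  invisible(path)
}

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.(mha|mhd)$", lp)) return("metaimage")
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  stop(sprintf("cannot infer image format from '%s' (use .mha/.mhd or .nii/.nii.gz)",
               path), call. = FALSE)
}

## ---- MetaImage ----------------------------------------------------------

metaio_types <- c(MET_DOUBLE = "double", MET_FLOAT = "double",
                  MET_SHORT = "integer", MET_USHORT = "integer",
                  MET_INT = "integer", MET_UCHAR = "integer",
                  MET_CHAR = "integer")
metaio_sizes <- c(MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
                  MET_USHORT = 2L, MET_INT = 4L, MET_UCHAR = 1L, MET_CHAR = 1L)

read_metaimage <- function(path, modality) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("'%s': truncated MetaImage header", path), call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L)
      stop(sprintf("'%s': malformed MetaImage header line '%s'", path, line),
           call. = FALSE)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (!identical(hdr$NDims, "3"))
    stop(sprintf("'%s': only 3D MetaImage volumes are supported", path),
         call. = FALSE)
  if (!is.null(hdr$CompressedData) &&
      tolower(hdr$CompressedData) %in% c("true", "1"))
    stop(sprintf("'%s': compressed MetaImage data are not supported", path),
         call. = FALSE)
  if (!is.null(hdr$TransformMatrix)) {
    tm <- as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]])
    if (any(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1)) > 1e-6))
      stop(sprintf("'%s': oblique TransformMatrix is not supported", path),
           call. = FALSE)
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr$ElementType
  if (!type %in% names(metaio_types))
    stop(sprintf("'%s': unsupported ElementType %s", path, type), call. = FALSE)
  msb <- !is.null(hdr$BinaryDataByteOrderMSB) &&
    tolower(hdr$BinaryDataByteOrderMSB) %in% c("true", "1")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, metaio_types[[type]], n = n, size = metaio_sizes[[type]],
                   endian = if (msb) "big" else "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath))
      stop(sprintf("'%s': data file '%s' not found", path, rawpath),
           call. = FALSE)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, metaio_types[[type]], n = n, size = metaio_sizes[[type]],
                   endian = if (msb) "big" else "little")
  }
  if (length(raw) != n)
    stop(sprintf("'%s': expected %d voxels, read %d", path, n, length(raw)),
         call. = FALSE)
  image_volume(array(as.double(raw), dims), spacing, origin, modality)
}

write_metaimage <- function(img, path) {
  d <- img_dim(img)
  mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (mhd) paste0(tools::file_path_sans_ext(basename(path)), ".raw")
              else "LOCAL"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           sprintf("Offset = %.10g %.10g %.10g", img$origin[1], img$origin[2],
                   img$origin[3]),
           sprintf("ElementSpacing = %.10g %.10g %.10g", img$spacing[1],
                   img$spacing[2], img$spacing[3]),
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           "ElementType = MET_DOUBLE",
           sprintf("ElementDataFile = %s", datafile))
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (!mhd) {
    writeBin(as.double(img$voxels), con, size = 8L, endian = "little")
    close(con)
  } else {
    close(con)
    rcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(as.double(img$voxels), rcon, size = 8L, endian = "little")
    close(rcon)
  }
  invisible(path)
}

## ---- NIfTI --------------------------------------------------------------

read_nifti <- function(path, modality) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s': only 3D NIfTI volumes are supported", path),
         call. = FALSE)
  xf <- RNifti::xform(nii)
  rot <- xf[1:3, 1:3]
  if (any(abs(rot - diag(diag(rot))) > 1e-4))
    stop(sprintf("'%s': oblique or flipped NIfTI orientation is not supported",
                 path), call. = FALSE)
  spacing <- abs(diag(rot))
  origin <- xf[1:3, 4]
  image_volume(array(as.double(arr), dim(arr)), spacing, origin, modality)
}

write_nifti_image <- function(img, path) {
  nii <- RNifti::asNifti(img$voxels)
  RNifti::pixdim(nii) <- img$spacing
  m <- diag(c(img$spacing, 1))
  m[1:3, 4] <- img$origin
  RNifti::qform(nii) <- structure(m, code = 2L)
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

## ---- Landmarks ----------------------------------------------------------

#' Labeled physical landmarks
#'
#' A landmark set is a tibble with columns `label`, `x_mm`, `y_mm`, `z_mm`
#' and a `frame` attribute recording which image space the coordinates live
#' in (`"kVCT"` or `"MVCT"`).  Labels must be unique.
#'
#' @param label character vector of unique labels.
#' @param x,y,z physical coordinates in mm.
#' @param frame `"kVCT"` or `"MVCT"`.
#' @return A tibble of class `landmark_set`.
#' @export
landmark_set <- function(label, x, y, z, frame = c("kVCT", "MVCT")) {
  frame <- match.arg(frame)
  label <- as.character(label)
  if (anyDuplicated(label))
    stop("landmark labels must be unique", call. = FALSE)
  out <- tibble::tibble(label = label, x_mm = as.numeric(x),
                        y_mm = as.numeric(y), z_mm = as.numeric(z))
  class(out) <- c("landmark_set", class(out))
  attr(out, "frame") <- frame
  out
}

landmark_matrix <- function(marks) {
  as.matrix(marks[, c("x_mm", "y_mm", "z_mm")])
}

#' Read landmarks from a comma-separated table
#'
#' Expected columns (header required): `label, x_mm, y_mm, z_mm`.
#'
#' @param path CSV file.
#' @param frame coordinate frame of the file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, frame = c("kVCT", "MVCT")) {
  frame <- match.arg(frame)
  if (!file.exists(path))
    stop(sprintf("cannot read landmarks: '%s' does not exist", path),
         call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  landmark_set(df$label, df$x_mm, df$y_mm, df$z_mm, frame)
}

#' Write landmarks to CSV
#' @param marks a [landmark_set()].
#' @param path output CSV path.
#' @export
write_landmarks <- function(marks, path) {
  write.csv(as.data.frame(marks[, c("label", "x_mm", "y_mm", "z_mm")]),
            path, row.names = FALSE)
  invisible(path)
}
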