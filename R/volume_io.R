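#' Read a 3D density volume
#'
#' Reads a MetaImage (`.mha`) or NIfTI (`.nii`/`.nii.gz`) scalar volume. The
#' first array axis of the result is taken as the axial (slice) axis; this is
#' the package-wide convention and matches how [write_volume()] stores data.
#'
#' @param path path to an existing image file.
#' @param format `"metaimage"`, `"nifti"`, or `"auto"` (infer from extension).
#' @return A [density_volume()] with the voxel size read from the header.
#'   If the header voxel spacing is anisotropic beyond 0.1% a warning is
#'   emitted and the first spacing is used.
#' @export
read_volume <- function(path, format = c("auto", "metaimage", "nifti")) {
  format <- resolve_format(path, match.arg(format))
  if (!file.exists(path)) stop("file not found: ", path)
  img <- switch(format,
                metaimage = read_mha(path),
                nifti = read_nii(path))
  if (length(dim(img$voxels)) != 3L)
    stop("expected a 3D image, got rank ", length(dim(img$voxels)))
  density_volume(img$voxels, img$voxel_size_mm,
                 name = sub("\\.(mha|nii(\\.gz)?)$", "", basename(path)))
}

#' Write a 3D density volume
#'
#' MetaImage volumes are stored as `MET_DOUBLE`, NIfTI as float64, so density
#' round-trips through [read_volume()] are bit-exact.
#'
#' @param vol a [density_volume()] (or [normalized_volume()]).
#' @param path output path; extension must match the format.
#' @param format `"auto"`, `"metaimage"` or `"nifti"`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, format = c("auto", "metaimage", "nifti")) {
  format <- resolve_format(path, match.arg(format))
  stopifnot(inherits(vol, "density_volume") || inherits(vol, "normalized_volume"))
  switch(format,
         metaimage = write_mha(vol$voxels, vol$voxel_size_mm, path,
                               type = "MET_DOUBLE"),
         nifti = write_nii(vol$voxels, vol$voxel_size_mm, path,
                           datatype = "double"))
  invisible(path)
}

#' Read or write a binary compartment mask
#'
#' Any nonzero stored value is binarized to 1 on read.
#'
#' @param path image path.
#' @param format `"auto"`, `"metaimage"` or `"nifti"`.
#' @param label compartment label to attach to the mask.
#' @return [read_mask()] returns a [compartment_mask()]; [write_mask()]
#'   invisibly returns `path`.
#' @export
read_mask <- function(path, format = c("auto", "metaimage", "nifti"),
                      label = "bone") {
  format <- resolve_format(path, match.arg(format))
  if (!file.exists(path)) stop("file not found: ", path)
  img <- switch(format,
                metaimage = read_mha(path),
                nifti = read_nii(path))
  if (length(dim(img$voxels)) != 3L)
    stop("expected a 3D image, got rank ", length(dim(img$voxels)))
  compartment_mask(array(img$voxels != 0, dim = dim(img$voxels)),
                   label = label, voxel_size_mm = img$voxel_size_mm)
}

#' @rdname read_mask
#' @param mask a [compartment_mask()].
#' @export
write_mask <- function(mask, path, format = c("auto", "metaimage", "nifti")) {
  format <- resolve_format(path, match.arg(format))
  stopifnot(inherits(mask, "compartment_mask"))
  vox <- array(as.numeric(mask$voxels), dim = dim(mask$voxels))
  switch(format,
         metaimage = write_mha(vox, mask$voxel_size_mm, path,
                               type = "MET_UCHAR"),
         nifti = write_nii(vox, mask$voxel_size_mm, path, datatype = "uint8"))
  invisible(path)
}

#' Calibrate native scanner units to densities
#'
#' Applies the scanner's affine calibration `raw * slope + intercept` to map
#' native units to mg HA/cm^3. Calibration constants are scanner-specific and
#' must be supplied by the user; they are never assumed.
#'
#' @param raw numeric 3D array in native units.
#' @param slope mg HA/cm^3 per native unit; must be nonzero.
#' @param intercept mg HA/cm^3 offset.
#' @param voxel_size_mm isotropic voxel size of the grid.
#' @param name identifier for the resulting volume.
#' @return A [density_volume()].
#' @export
#' @examples
#' calibrate_native_to_density(array(1875, c(1, 1, 1)), 0.2, -100)$voxels[1]
calibrate_native_to_density <- function(raw, slope, intercept,
                                        voxel_size_mm = 0.0607, name = "") {
  if (!is.numeric(slope) || length(slope) != 1L || slope == 0)
    stop("slope must be a nonzero scalar")
  raw <- check_grid3(raw, "raw")
  density_volume(raw * slope + intercept, voxel_size_mm, name)
}

resolve_format <- function(path, format) {
  if (format != "auto") {
    ok <- switch(format,
                 metaimage = grepl("\\.mha$", path, ignore.case = TRUE),
                 nifti = grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    if (!ok) stop("file extension of '", basename(path),
                  "' does not match format '", format, "'")
    return(format)
  }
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return("metaimage")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  stop("cannot infer format from extension of '", basename(path),
       "' (use .mha, .nii or .nii.gz)")
}

# -- minimal MetaImage (.mha, LOCAL payload) codec ----------------------------
# Header is plain text "Key = Value" lines followed by the raw little-endian
# voxel payload. Only the single-file (.mha, ElementDataFile = LOCAL) flavor
# is supported.

write_mha <- function(voxels, voxel_size_mm, path,
                      type = c("MET_DOUBLE", "MET_UCHAR")) {
  type <- match.arg(type)
  d <- dim(voxels)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    "Offset = 0 0 0",
    "CenterOfRotation = 0 0 0",
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            voxel_size_mm, voxel_size_mm, voxel_size_mm),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementType = %s", type),
    "ElementDataFile = LOCAL")
  writeLines(hdr, con, sep = "\n")
  if (type == "MET_DOUBLE")
    writeBin(as.vector(voxels), con, size = 8L, endian = "little")
  else
    writeBin(as.integer(voxels), con, size = 1L, endian = "little")
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readBin(con, "raw", n = 1L)
    chars <- raw(0)
    while (length(line) == 1L && line != as.raw(10L)) {
      chars <- c(chars, line)
      line <- readBin(con, "raw", n = 1L)
    }
    txt <- rawToChar(chars)
    kv <- strsplit(txt, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed MetaImage header line: ", txt)
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only single-file MetaImage (ElementDataFile = LOCAL) is supported")
  if (identical(hdr[["CompressedData"]], "True"))
    stop("compressed MetaImage payloads are not supported")
  if (identical(hdr[["BinaryDataByteOrderMSB"]], "True"))
    stop("big-endian MetaImage payloads are not supported")
  ndims <- as.integer(hdr[["NDims"]])
  if (!identical(ndims, 3L))
    stop("expected a 3D image, header declares NDims = ", ndims)
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  n <- prod(d)
  type <- hdr[["ElementType"]]
  voxels <- switch(type,
    MET_DOUBLE = readBin(con, "double", n = n, size = 8L, endian = "little"),
    MET_FLOAT = readBin(con, "double", n = n, size = 4L, endian = "little"),
    MET_UCHAR = as.numeric(readBin(con, "integer", n = n, size = 1L,
                                   signed = FALSE, endian = "little")),
    MET_SHORT = as.numeric(readBin(con, "integer", n = n, size = 2L,
                                   signed = TRUE, endian = "little")),
    stop("unsupported MetaImage ElementType: ", type))
  if (length(voxels) != n) stop("truncated MetaImage payload in ", path)
  list(voxels = array(voxels, dim = d),
       voxel_size_mm = check_spacing(spacing))
}

read_nii <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
    img <- array(as.vector(img), dim = d[1:3])
    d <- d[1:3]
  }
  spacing <- RNifti::pixdim(img)[seq_along(d)]
  list(voxels = array(as.numeric(img), dim = d),
       voxel_size_mm = check_spacing(spacing[1:min(3, length(spacing))]))
}

write_nii <- function(voxels, voxel_size_mm, path,
                      datatype = c("double", "uint8")) {
  datatype <- match.arg(datatype)
  img <- RNifti::asNifti(voxels)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

check_spacing <- function(spacing) {
  spacing <- spacing[is.finite(spacing) & spacing > 0]
  if (length(spacing) == 0L) return(0.0607)
  if (max(spacing) / min(spacing) > 1.001)
    warning("anisotropic voxel spacing in header; using the first axis spacing")
  spacing[1]
}
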