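#' Read and write CT volumes and organ masks
#'
#' Volumes and masks are stored either as NIfTI-1 (`.nii`, `.nii.gz`,
#' through RNifti) or MetaImage (`.mha` single file, `.mhd` + `.raw`
#' pair). World coordinates are mm; the affine/offset carries the origin
#' (centre of the first voxel) and the per-axis spacing, interpreted in
#' the LPS convention. A write -> read round trip preserves voxels,
#' spacing and origin exactly for NIfTI and MetaImage (both store
#' double-precision voxels).
#'
#' @param path file path; the extension selects the format.
#' @param volume a [CTVolume-class].
#' @return `readVolume` returns a [CTVolume-class]; the writers return
#'   the path invisibly.
#' @export
readVolume <- function(path) {
  raw <- .readImage(path)
  new("CTVolume", voxels = raw$voxels, spacing = raw$spacing,
      origin = raw$origin)
}

#' @rdname readVolume
#' @export
writeVolume <- function(volume, path) {
  .writeImage(volume@voxels, volume@spacing, volume@origin, path)
  invisible(path)
}

#' @rdname readVolume
#' @param masks an [OrganMaskSet-class].
#' @param dir directory for the per-structure mask files.
#' @param prefix file-name prefix, e.g. `patient_001`.
#' @param format `"nii.gz"`, `"nii"`, `"mha"` or `"mhd"`.
#' @param spacing,origin grid geometry for the mask files (take them from
#'   the paired volume).
#' @export
writeMasks <- function(masks, dir, prefix = "phantom", format = "nii.gz",
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in structureNames(masks)) {
    p <- file.path(dir, sprintf("%s_mask_%s.%s", prefix, nm, format))
    .writeImage(array(as.double(masks@masks[[nm]]), dim(masks)),
                spacing, origin, p)
  }
  invisible(dir)
}

#' @rdname readVolume
#' @param reference optional [CTVolume-class]; masks must match its grid.
#' @export
readMasks <- function(dir, prefix = "phantom", format = "nii.gz",
                      reference = NULL) {
  m <- lapply(STRUCTURES, function(nm) {
    p <- file.path(dir, sprintf("%s_mask_%s.%s", prefix, nm, format))
    if (!file.exists(p)) stop("missing mask file for structure '", nm, "': ", p)
    raw <- .readImage(p)
    if (!is.null(reference) && !identical(dim(raw$voxels), dim(reference)))
      stop("mask '", nm, "' shape (", paste(dim(raw$voxels), collapse = "x"),
           ") does not match the volume (",
           paste(dim(reference), collapse = "x"), ")")
    raw$voxels > 0.5
  })
  names(m) <- STRUCTURES
  new("OrganMaskSet", masks = m)
}

.imageFormat <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else if (grepl("\\.mha$", low)) "mha"
  else if (grepl("\\.mhd$", low)) "mhd"
  else stop("unsupported image extension for '", path,
            "' (expected .nii, .nii.gz, .mha or .mhd)")
}

.readImage <- function(path) {
  fmt <- .imageFormat(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    list(voxels = array(as.double(img), dim(img)[1:3]),
         spacing = abs(c(xf[1, 1], xf[2, 2], xf[3, 3])),
         origin = as.double(xf[1:3, 4]))
  } else {
    .readMeta(path)
  }
}

.writeImage <- function(voxels, spacing, origin, path) {
  fmt <- .imageFormat(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(voxels)
    RNifti::pixdim(img) <- spacing
    af <- diag(4)
    diag(af)[1:3] <- spacing
    af[1:3, 4] <- origin
    RNifti::qform(img) <- structure(af, code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    .writeMeta(voxels, spacing, origin, path)
  }
}

# --- minimal MetaImage (ITK .mha/.mhd) support: text header + raw block ---

.writeMeta <- function(voxels, spacing, origin, path) {
  fmt <- .imageFormat(path)
  d <- dim(voxels)
  dataFile <- if (fmt == "mha") "LOCAL" else paste0(
    sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(origin, digits = 17), collapse = " ")),
           paste("ElementSpacing =", paste(format(spacing, digits = 17), collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           "AnatomicalOrientation = LPS",
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", dataFile))
  if (fmt == "mha") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.vector(voxels), con, size = 8, endian = "little")
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), dataFile), "wb")
    on.exit(close(con))
    writeBin(as.vector(voxels), con, size = 8, endian = "little")
  }
}

.readMeta <- function(path) {
  fmt <- .imageFormat(path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("truncated MetaImage header in ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementType"]], "MET_DOUBLE"))
    stop("unsupported MetaImage ElementType: ", hdr[["ElementType"]])
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  n <- prod(d)
  if (identical(hdr[["ElementDataFile"]], "LOCAL")) {
    vox <- readBin(con, "double", n = n, size = 8, endian = "little")
  } else {
    rawPath <- file.path(dirname(path), hdr[["ElementDataFile"]])
    rcon <- file(rawPath, "rb")
    on.exit(close(rcon), add = TRUE)
    vox <- readBin(rcon, "double", n = n, size = 8, endian = "little")
  }
  if (length(vox) != n) stop("MetaImage data block shorter than DimSize in ", path)
  list(voxels = array(vox, d),
       spacing = as.double(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]),
       origin = as.double(strsplit(hdr[["Offset"]], "\\s+")[[1]]))
}
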