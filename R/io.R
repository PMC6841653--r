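#' Read a 3-D volume from disk
#'
#' Supports MetaImage (`.mhd` text header + `.raw` payload) and NIfTI-1
#' (`.nii`, `.nii.gz`). Spacing and origin are taken from the header
#' (MetaImage `ElementSpacing`/`Offset`; NIfTI `pixdim`/`qoffset`);
#' intensities are returned unmodified.
#'
#' @param path file path ending in `.mhd`, `.nii` or `.nii.gz`.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    read_mhd(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_nifti_volume(path)
  } else {
    stop("unsupported volume format: '", path,
         "' (expected .mhd, .nii or .nii.gz)")
  }
}

#' Write a 3-D volume to disk
#'
#' Format chosen by extension as in [read_volume()]. The header records
#' spacing and origin so that write-then-read is an identity. Integer-valued
#' data (e.g. label volumes) are stored as 16-bit integers in MetaImage
#' (`MET_SHORT`), everything else as 32-bit float.
#'
#' @param volume a [voxel_volume()] (or `bone_mask` / label volume).
#' @param path output path with a supported extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "voxel_volume"))
    volume <- voxel_volume(volume$data, volume$spacing, volume$origin,
                           volume$name %||% "volume")
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    write_mhd(volume, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_nifti_volume(volume, path)
  } else {
    stop("unsupported volume format: '", path,
         "' (expected .mhd, .nii or .nii.gz)")
  }
  invisible(path)
}

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  need <- c("DimSize", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("corrupt MetaImage header '", path, "': missing field ", miss[1])
  dim <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  if (length(dim) != 3 || any(is.na(dim)))
    stop("corrupt MetaImage header '", path, "': bad DimSize '", kv$DimSize, "'")
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  if (any(is.na(spacing)))
    stop("corrupt MetaImage header '", path, "': bad ElementSpacing")
  type <- kv$ElementType
  raw_path <- file.path(dirname(path), kv$ElementDataFile)
  n <- prod(dim)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- switch(type,
    MET_SHORT = readBin(con, "integer", n, size = 2, signed = TRUE,
                        endian = "little"),
    MET_FLOAT = readBin(con, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    MET_UCHAR = readBin(con, "integer", n, size = 1, signed = FALSE,
                        endian = "little"),
    stop("corrupt MetaImage header '", path, "': unsupported ElementType '",
         type, "'"))
  if (length(vals) < n)
    stop("raw payload '", raw_path, "' shorter than DimSize implies")
  voxel_volume(array(as.numeric(vals), dim), spacing, origin,
               name = sub("\\.mhd$", "", basename(path), ignore.case = TRUE))
}

write_mhd <- function(volume, path) {
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  int_like <- all(volume$data == round(volume$data)) &&
    max(abs(volume$data)) <= 32767
  type <- if (int_like) "MET_SHORT" else "MET_FLOAT"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(volume$data), collapse = " ")),
           paste("ElementSpacing =", paste(format(volume$spacing, digits = 15),
                                           collapse = " ")),
           paste("Offset =", paste(format(volume$origin, digits = 15),
                                   collapse = " ")),
           paste("ElementType =", type),
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (int_like)
    writeBin(as.integer(volume$data), con, size = 2, endian = "little")
  else
    writeBin(as.numeric(volume$data), con, size = 4, endian = "little")
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  spacing <- hdr$pixdim[2:4]
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  voxel_volume(array(as.numeric(img), dim(img)[1:3]), spacing, origin,
               name = sub("\\.nii(\\.gz)?$", "", basename(path),
                          ignore.case = TRUE))
}

write_nifti_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
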