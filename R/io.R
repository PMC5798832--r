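#' Read a 3D image volume from NIfTI or NRRD
#'
#' Loads a scalar 3D volume and its voxel spacing from the file header.
#' NIfTI (`.nii`, `.nii.gz`) is read through the RNifti library; NRRD
#' (`.nrrd`) through a small built-in reader supporting raw and gzip
#' encodings.
#'
#' @param path file path.
#' @param format `"nifti"`, `"nrrd"`, or `"auto"` (from the extension).
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("load error: no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  }
  if (format == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("load error reading ", path, ": ",
                                             conditionMessage(e)))
    arr <- as.array(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
      arr <- array(arr, dim(arr)[1:3])
    }
    if (length(dim(arr)) != 3L)
      stop("geometry error: ", path, " has rank ", length(dim(arr)),
           ", expected 3")
    sp <- abs(RNifti::pixdim(img))[1:3]
    image_volume(arr, spacing = sp)
  } else {
    nr <- read_nrrd(path)
    image_volume(nr$data, spacing = nr$spacing)
  }
}

#' Write a 3D image volume to NIfTI or NRRD
#'
#' @param volume an [image_volume()].
#' @param path destination; `.nii`/`.nii.gz` selects NIfTI, `.nrrd` NRRD.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(volume$voxels, volume$spacing, path)
  } else {
    img <- RNifti::asNifti(volume$voxels)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path, datatype = "double")
  }
  invisible(path)
}

# --- minimal NRRD support (raw / gzip encodings, 3D scalar volumes) --------

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("load error: ", path, " is not NRRD")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("load error: truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":=?", fixed = FALSE)[[1]]
    if (length(kv) >= 2L)
      fields[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  dimn <- as.integer(fields[["dimension"]])
  if (is.na(dimn) || dimn != 3L)
    stop("geometry error: NRRD dimension ", fields[["dimension"]],
         " in ", path, ", expected 3")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- fields[["type"]]
  enc <- tolower(fields[["encoding"]])
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(vecs, function(v) {
      sqrt(sum(as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])^2))
    }, numeric(1))
  }
  n <- prod(sizes)
  sz <- switch(type,
               "double" = 8L, "float" = 4L,
               "int" = 4L, "short" = 2L, "uchar" = 1L,
               stop("load error: unsupported NRRD type '", type, "'"))
  what <- if (type %in% c("double", "float")) "double" else "integer"
  payload <- readBin(con, "raw", n = file.info(path)$size)
  if (enc == "gzip") payload <- memDecompress(payload, type = "gzip")
  if (length(payload) < n * sz) stop("load error: truncated NRRD data in ", path)
  vals <- readBin(payload, what, n = n, size = sz, endian = "little")
  list(data = array(as.double(vals), sizes), spacing = spacing)
}

write_nrrd <- function(arr, spacing, path, encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  header <- c("NRRD0004",
              "# scalar 3D volume",
              "type: double",
              "dimension: 3",
              paste("sizes:", paste(dim(arr), collapse = " ")),
              paste("spacings:", paste(format(spacing, digits = 15),
                                       collapse = " ")),
              "endian: little",
              paste0("encoding: ", encoding),
              "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  payload <- writeBin(as.double(arr), raw(), size = 8L, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  writeBin(payload, con)
  invisible(path)
}
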