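#' Volume and image input/output
#'
#' Flow volumes travel on disk as multi-page TIFF (one page per depth) or as
#' NumPy \code{.npy} arrays; en face images as 8-bit grayscale PNG. In memory
#' the canonical representation is always a numeric array in \code{[0, 1]}
#' with axes (depth, y, x); integer files are mapped to \code{[0, 1]} by the
#' scale factor recorded in the metadata (255 for uint8, 65535 for uint16).
#'
#' @name volume_io
NULL

#' Construct volume metadata
#'
#' @param dtype_on_disk one of \code{"uint8"}, \code{"uint16"}, \code{"float32"}
#' @param scale factor mapping stored integers to \code{[0,1]}; defaults to the
#'   dtype's full range (1 for float32)
#' @return a \code{volume_meta} list with fields \code{axes_order} (always
#'   \code{"ZYX"}), \code{dtype_on_disk} and \code{scale}
#' @export
volume_meta <- function(dtype_on_disk = "float32", scale = NULL) {
  dtype_on_disk <- match.arg(dtype_on_disk, c("uint8", "uint16", "float32"))
  if (is.null(scale)) {
    scale <- switch(dtype_on_disk, uint8 = 255, uint16 = 65535, float32 = 1)
  }
  stopifnot(scale > 0)
  structure(list(axes_order = "ZYX", dtype_on_disk = dtype_on_disk,
                 scale = scale), class = "volume_meta")
}

check_volume_range <- function(volume, what = "volume") {
  if (!all(is.finite(volume))) {
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  }
  rng <- range(volume)
  if (rng[1] < 0 || rng[2] > 1) {
    stop(sprintf("%s values must lie in [0, 1] (found range [%g, %g])",
                 what, rng[1], rng[2]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a flow volume to disk
#'
#' @param volume 3D array (depth, y, x) with values in \code{[0, 1]}; values
#'   outside the range are an error, never silently clipped
#' @param path output path; extension selects the format (\code{.tif}/
#'   \code{.tiff} multi-page TIFF, \code{.npy} NumPy)
#' @param meta a [volume_meta()]; controls the on-disk dtype
#' @return `path`, invisibly
#' @export
write_volume <- function(volume, path, meta = volume_meta()) {
  stopifnot(is.array(volume), length(dim(volume)) == 3,
            inherits(meta, "volume_meta"))
  check_volume_range(volume)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(dim(volume)[1]), function(z) volume[z, , ])
    bits <- switch(meta$dtype_on_disk, uint8 = 8L, uint16 = 16L, float32 = 32L)
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else if (ext == "npy") {
    write_npy(scale_to_disk(volume, meta), path, meta$dtype_on_disk)
  } else {
    stop("unsupported volume format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a flow volume from disk
#'
#' @param path a multi-page TIFF or \code{.npy} file
#' @return list with \code{volume} (array in \code{[0,1]}, axes z, y, x) and
#'   \code{meta} (a [volume_meta()])
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    shp <- dim(pages[[1]])
    for (i in seq_along(pages)) {
      if (length(dim(pages[[i]])) > 2) pages[[i]] <- pages[[i]][, , 1]
      if (!identical(dim(pages[[i]]), shp)) {
        stop(sprintf("ragged TIFF: page %d has shape %s, expected %s", i,
                     paste(dim(pages[[i]]), collapse = "x"),
                     paste(shp, collapse = "x")), call. = FALSE)
      }
    }
    volume <- array(0, c(length(pages), shp[1], shp[2]))
    for (z in seq_along(pages)) volume[z, , ] <- pages[[z]]
    # readTIFF already rescales integer samples to [0,1]
    meta <- volume_meta("float32")
    volume[volume < 0] <- 0; volume[volume > 1] <- 1
  } else if (ext == "npy") {
    raw <- read_npy(path)
    if (length(dim(raw$data)) != 3) {
      stop("expected a 3D array in ", path, call. = FALSE)
    }
    meta <- volume_meta(raw$dtype)
    volume <- raw$data / meta$scale
    volume[volume > 1] <- 1
  } else {
    stop("unsupported volume format: .", ext, call. = FALSE)
  }
  list(volume = volume, meta = meta)
}

scale_to_disk <- function(volume, meta) {
  if (meta$dtype_on_disk == "float32") volume
  else round(volume * meta$scale)
}

#' Write an en face image as 8-bit grayscale PNG
#'
#' @param image matrix in \code{[0,1]}
#' @param path output path
#' @return `path`, invisibly
#' @export
write_enface_png <- function(image, path) {
  stopifnot(is.matrix(image))
  check_volume_range(image, "image")
  png::writePNG(image, path)
  invisible(path)
}

#' Read a grayscale en face image from PNG
#'
#' Color PNGs are reduced to their first channel.
#'
#' @param path input path
#' @return matrix in \code{[0,1]}
#' @export
read_enface_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

# --- minimal NumPy .npy v1.0 codec (C-order) ------------------------------
# Covers the dtypes the pipeline writes: uint8, uint16, float32, float64.

npy_descr <- c(uint8 = "|u1", uint16 = "<u2", float32 = "<f4", float64 = "<f8")

write_npy <- function(data, path, dtype = "float32") {
  stopifnot(is.array(data) || is.matrix(data))
  descr <- npy_descr[[dtype]]
  shp <- dim(data)
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%s), }",
                    descr, paste0(paste(shp, collapse = ", "),
                                  if (length(shp) == 1) "," else ""))
  # pad so magic(6)+version(2)+len(2)+header is a multiple of 64, ending in \n
  base_len <- 10L + nchar(header) + 1L
  pad <- (64L - base_len %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  # C-order: last axis fastest. R arrays are column-major (first fastest), so
  # transpose by reversing the axis order before flattening.
  flat <- as.vector(aperm(data, rev(seq_along(shp))))
  if (dtype %in% c("uint8", "uint16")) {
    size <- if (dtype == "uint8") 1 else 2
    writeBin(as.integer(flat), con, size = size, endian = "little")
  } else {
    size <- if (dtype == "float32") 4 else 8
    writeBin(as.double(flat), con, size = size, endian = "little")
  }
  invisible(path)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY")))) {
    stop("not an .npy file: ", path, call. = FALSE)
  }
  ver <- readBin(con, "raw", 2)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shp <- as.integer(strsplit(gsub("\\s|,$", "", shape_str), ",")[[1]])
  dtype <- names(npy_descr)[match(descr, npy_descr)]
  if (is.na(dtype)) stop("unsupported .npy dtype: ", descr, call. = FALSE)
  n <- prod(shp)
  flat <- switch(dtype,
    uint8   = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    uint16  = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                 endian = "little")),
    float32 = readBin(con, "numeric", n, size = 4, endian = "little"),
    float64 = readBin(con, "numeric", n, size = 8, endian = "little"))
  data <- if (fortran) array(flat, shp)
          else aperm(array(flat, rev(shp)), rev(seq_along(shp)))
  list(data = data, dtype = dtype, shape = shp)
}
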