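#' Read a grayscale brain slice from PNG or TIFF
#'
#' Reads an 8- or 16-bit grayscale image (one slice per file). Multi-channel
#' images are collapsed to grayscale by channel averaging.
#'
#' @param path file path ending in .png, .tif or .tiff
#' @param id identifier stored with the slice; defaults to the file name
#' @return a [BrainSlice-class]
#' @export
readBrainSlice <- function(path, id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bit <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bit <- attr(arr, "bits.per.sample")
    bit <- if (is.null(bit)) 8L else as.integer(bit)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(arr)) == 3L)
    arr <- apply(arr, c(1, 2), mean)
  if (!bit %in% c(8L, 16L))
    bit <- if (bit <= 8L) 8L else 16L
  # readers return values scaled to [0,1]; restore integer intensities
  px <- round(arr * (2^bit - 1))
  new("BrainSlice", pixels = px, bitDepth = bit, id = id)
}

#' Write a brain slice as a 16-bit PNG
#'
#' @param x a [BrainSlice-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeBrainSlice <- function(x, path) {
  png::writePNG(x@pixels / (2^x@bitDepth - 1), path,
                dpi = NULL)
  invisible(path)
}

#' Write / read a corner sequence as CSV
#'
#' Columns `m`, `n` (1-based row/col) and `importance`, in row-major corner
#' order.
#'
#' @param x a [CornerSet-class]
#' @param path CSV path
#' @return `path` (write) or a [CornerSet-class] (read)
#' @export
writeCornerCSV <- function(x, path) {
  df <- data.frame(m = x@coords[, 1], n = x@coords[, 2],
                   importance = x@importance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCornerCSV
#' @param dim image dimensions to record, if known
#' @param theta detection threshold to record, if known
#' @param id identifier
#' @export
readCornerCSV <- function(path, dim = NA_integer_, theta = NA_real_,
                          id = basename(path)) {
  df <- utils::read.csv(path)
  newCornerSet(cbind(m = as.integer(df$m), n = as.integer(df$n)),
               importance = df$importance,
               response = rep(NA_real_, nrow(df)),
               theta = theta, dim = as.integer(dim), id = id)
}

# internal constructor enforcing row-major order
newCornerSet <- function(coords, importance, response, theta, dim, id) {
  coords <- matrix(as.integer(coords), ncol = 2,
                   dimnames = list(NULL, c("m", "n")))
  if (nrow(coords)) {
    o <- order(coords[, 1], coords[, 2])
    coords <- coords[o, , drop = FALSE]
    importance <- importance[o]
    response <- response[o]
  }
  new("CornerSet", coords = coords, importance = as.numeric(importance),
      response = as.numeric(response), theta = theta,
      dim = as.integer(dim), id = id)
}
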