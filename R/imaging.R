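#' Validate a grayscale image matrix
#'
#' A grayscale image is an integer matrix of 8-bit intensities in
#' \[0, 255\] with at least 3 rows and 3 columns (the minimum extent any
#' neighborhood operator needs).  All descriptor functions in the package
#' accept either the output of [load_grayscale()] or any numeric matrix
#' satisfying these constraints.
#'
#' @param x a numeric matrix of intensities in \[0, 255\].
#' @return an integer matrix of class `"gray_image"`.
#' @export
gray_image <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a gray image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 3L || ncol(x) < 3L) {
    stop("image must be at least 3x3, got ", nrow(x), "x", ncol(x),
         call. = FALSE)
  }
  if (anyNA(x)) stop("image contains missing values", call. = FALSE)
  if (min(x) < 0 || max(x) > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!is.integer(x)) {
    if (max(abs(x - round(x))) > 1e-8) {
      stop("intensities must be whole numbers (8-bit gray levels)",
           call. = FALSE)
    }
    storage.mode(x) <- "integer"
  }
  class(x) <- c("gray_image", class(unclass(x)))
  x
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, 8 bpp, range [%d, %d]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# Internal: coerce to a validated plain integer matrix.
as_gray_matrix <- function(img) {
  img <- gray_image(img)
  unclass(img)
}

#' Read an image file as an 8-bit grayscale matrix
#'
#' Reads PNG, TIFF or JPEG images.  RGB (or RGBA, alpha ignored) inputs are
#' converted to luma with the ITU-R BT.601 weights 0.299, 0.587, 0.114 and
#' rounded to the nearest integer; single-channel 8-bit inputs pass through
#' unchanged.  JPEG support requires the `EBImage` package.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return a [gray_image()] matrix (rows = image rows, top to bottom).
#' @export
load_grayscale <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("cannot read image file: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("reading JPEG requires the EBImage package", call. = FALSE)
      }
      a <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores x (columns) in the first dimension; transpose back.
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    },
    stop("unsupported image format '", ext, "' for: ", path, call. = FALSE)
  )
  if (is.list(arr)) {
    stop("multi-page TIFF not supported: ", path, call. = FALSE)
  }
  vals <- arr * 255
  if (length(dim(vals)) == 3L) {
    nch <- dim(vals)[3L]
    if (nch < 3L) {
      gray <- vals[, , 1L]          # gray+alpha: use the gray channel
    } else {
      gray <- 0.299 * vals[, , 1L] + 0.587 * vals[, , 2L] +
        0.114 * vals[, , 3L]
    }
  } else {
    gray <- vals
  }
  gray_image(round(gray))
}

#' Contrast enhancement by saturated histogram stretching
#'
#' Linearly stretches the intensity histogram so that a fixed fraction of
#' pixel mass saturates at each end of the 8-bit range.  With `n` pixels
#' and `k = floor(saturation * n)`, the stretch limits are the (k+1)-th
#' smallest and (k+1)-th largest intensities; each pixel `p` maps to
#' `round((p - lo) * 255 / (hi - lo))` clipped to \[0, 255\].  At most a
#' `saturation` fraction of pixels (more only under intensity ties) lies
#' strictly outside \[lo, hi\] beforehand.  A near-constant image
#' (`hi == lo`) is returned unchanged with a warning.
#'
#' @param img a [gray_image()] or numeric matrix in \[0, 255\].
#' @param saturation fraction of pixel mass clipped at each extreme,
#'   in \[0, 0.5); default 0.01.
#' @return the enhanced [gray_image()].
#' @export
enhance_contrast <- function(img, saturation = 0.01) {
  m <- as_gray_matrix(img)
  if (!is.numeric(saturation) || length(saturation) != 1L ||
      saturation < 0 || saturation >= 0.5) {
    stop("`saturation` must lie in [0, 0.5)", call. = FALSE)
  }
  s <- sort(as.vector(m))
  n <- length(s)
  k <- floor(saturation * n)
  lo <- s[k + 1L]
  hi <- s[n - k]
  if (hi == lo) {
    warning("degenerate stretch (constant intensity); image unchanged")
    return(gray_image(m))
  }
  out <- round((m - lo) * 255 / (hi - lo))
  out[out < 0L] <- 0L
  out[out > 255L] <- 255L
  gray_image(out)
}
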