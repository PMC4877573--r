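#' Local binary pattern parameters
#'
#' The classic 3x3 operator uses `P = 8` neighbors at radius `R = 1`
#' (integer pixel offsets, no interpolation), producing codes in
#' \[0, 255\] and a 256-bin histogram — one bin per gray level.  For
#' other `P`/`R` the neighbor offsets are the rounded points on the
#' circle of radius `R` at angles `2*pi*p/P`, starting east (angle 0)
#' and proceeding counterclockwise.
#'
#' @param P number of neighbors (>= 1); histogram length is `2^P`.
#' @param R neighborhood radius in pixels (>= 1, integer).
#' @return a list of class `"lbp_params"` with the neighbor offsets.
#' @export
lbp_params <- function(P = 8L, R = 1L) {
  if (P < 1L) stop("`P` must be >= 1", call. = FALSE)
  if (P > 24L) stop("`P` > 24 would need a histogram of > 2^24 bins",
                    call. = FALSE)
  if (R < 1L || R != round(R)) stop("`R` must be a positive integer",
                                    call. = FALSE)
  ang <- 2 * pi * (seq_len(P) - 1L) / P
  # matrix rows grow downward, so counterclockwise means di = -sin
  offsets <- cbind(di = as.integer(round(-R * sin(ang))),
                   dj = as.integer(round(R * cos(ang))))
  structure(list(P = as.integer(P), R = as.integer(R), offsets = offsets),
            class = "lbp_params")
}

#' Local binary pattern code of one pixel
#'
#' Compares the center pixel with each of its `P` neighbors; neighbor `p`
#' contributes `2^p` when its value is greater than or equal to the
#' center (the sign function assigns 1 to non-negative differences, so a
#' constant patch codes to `2^P - 1`).
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param i,j row/column of the center pixel (1-based), at least `R`
#'   pixels from every border.
#' @param params an [lbp_params()].
#' @return integer code in \[0, 2^P - 1\].
#' @export
lbp_code <- function(img, i, j, params = lbp_params()) {
  m <- as_gray_matrix(img)
  R <- params$R
  if (i <= R || i > nrow(m) - R || j <= R || j > ncol(m) - R) {
    stop("pixel (", i, ", ", j, ") is within ", R,
         " pixels of the border; codes are defined on the interior only",
         call. = FALSE)
  }
  gc <- m[i, j]
  bits <- m[cbind(i + params$offsets[, "di"], j + params$offsets[, "dj"])] >= gc
  sum(as.integer(bits) * 2^(seq_len(params$P) - 1L))
}

#' Local binary pattern histogram descriptor
#'
#' Computes the LBP code of every interior pixel (those at least `R`
#' pixels from every border) and returns the histogram of raw counts over
#' all `2^P` codes.  The counts total `(M - 2R) * (N - 2R)` exactly.
#' Codes depend only on the sign of intensity differences, so the
#' histogram is invariant to adding a constant to the image or to any
#' strictly increasing intensity remapping.
#'
#' @param img a [gray_image()] or numeric matrix of size at least
#'   `(2R+1) x (2R+1)`.
#' @param params an [lbp_params()].
#' @param normalize return relative frequencies instead of raw counts.
#' @return numeric vector of length `2^P` (default 256).
#' @export
lbp_histogram <- function(img, params = lbp_params(), normalize = FALSE) {
  m <- as_gray_matrix(img)
  R <- params$R
  M <- nrow(m)
  N <- ncol(m)
  if (M < 2L * R + 1L || N < 2L * R + 1L) {
    stop("image must be at least ", 2L * R + 1L, "x", 2L * R + 1L,
         " for R = ", R, call. = FALSE)
  }
  ri <- (R + 1L):(M - R)
  ci <- (R + 1L):(N - R)
  center <- m[ri, ci, drop = FALSE]
  code <- matrix(0, nrow(center), ncol(center))
  for (p in seq_len(params$P)) {
    di <- params$offsets[p, "di"]
    dj <- params$offsets[p, "dj"]
    nb <- m[ri + di, ci + dj, drop = FALSE]
    code <- code + (nb >= center) * 2^(p - 1L)
  }
  h <- tabulate(as.vector(code) + 1L, nbins = 2L^params$P)
  if (normalize) h / sum(h) else as.numeric(h)
}
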