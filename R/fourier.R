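#' Centered Fourier magnitude spectrum
#'
#' Computes the 2-D discrete Fourier transform of an image (unnormalized
#' forward convention) and shifts the zero-frequency bin to the central
#' coordinates, so low frequencies sit at the middle of the array and high
#' frequencies at the borders.  Using 0-based indices the center lands at
#' `(floor(M/2), floor(N/2))`; the `center` field reports the 1-based R
#' subscripts.  Parseval's identity holds in this convention:
#' `sum(magnitudes^2) == M * N * sum(pixels^2)`.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @return an object of class `"fourier_spectrum"`: a list with
#'   `magnitudes` (M x N non-negative matrix), `center` (1-based row/col of
#'   the zero-frequency bin) and `dims`.
#' @export
centered_spectrum <- function(img) {
  m <- as_gray_matrix(img)
  M <- nrow(m)
  N <- ncol(m)
  F <- stats::fft(m)
  # fftshift: roll each dimension by floor(dim/2) so DC lands mid-array
  ri <- ((seq_len(M) - 1L - floor(M / 2)) %% M) + 1L
  ci <- ((seq_len(N) - 1L - floor(N / 2)) %% N) + 1L
  mag <- Mod(F)[ri, ci, drop = FALSE]
  structure(
    list(magnitudes = mag,
         center = c(floor(M / 2) + 1L, floor(N / 2) + 1L),
         dims = c(M, N)),
    class = "fourier_spectrum"
  )
}

#' @export
print.fourier_spectrum <- function(x, ...) {
  cat(sprintf("<fourier_spectrum> %d x %d, center (%d, %d), total |F| = %.4g\n",
              x$dims[1], x$dims[2], x$center[1], x$center[2],
              sum(x$magnitudes)))
  invisible(x)
}

as_spectrum <- function(spec) {
  if (inherits(spec, "fourier_spectrum")) return(spec)
  if (inherits(spec, "gray_image") || is.matrix(spec)) {
    return(centered_spectrum(spec))
  }
  stop("`spec` must be a fourier_spectrum or an image matrix", call. = FALSE)
}

# Euclidean distance of every bin from the spectrum center, in bin units.
spectrum_distances <- function(spec) {
  M <- spec$dims[1]
  N <- spec$dims[2]
  dr <- seq_len(M) - spec$center[1]
  dc <- seq_len(N) - spec$center[2]
  sqrt(outer(dr^2, dc^2, `+`))
}

#' Cumulative circular (disk) Fourier descriptor
#'
#' For integer radii `g = 1 ... G` with `G = floor(min(M, N)/2) - 1`, sums
#' the spectrum magnitudes of all bins whose Euclidean distance from the
#' center is at most `g` (the zero-frequency bin included).  The result is
#' a non-decreasing sequence of disk sums; for the 2080 x 1540 images of a
#' typical 20x-objective acquisition G = 769.
#'
#' @param spec a `"fourier_spectrum"` (or an image, which is transformed
#'   first).
#' @return numeric vector of length `G`.
#' @export
circular_descriptor <- function(spec) {
  spec <- as_spectrum(spec)
  M <- spec$dims[1]
  N <- spec$dims[2]
  G <- floor(min(M, N) / 2) - 1L
  if (min(M, N) < 6L) {
    stop("image too small for circular descriptor: min dimension ",
         min(M, N), " < 6", call. = FALSE)
  }
  d <- spectrum_distances(spec)
  # bin k of ceiling(d) collects mass with k-1 < d <= k; disk sum over
  # d <= g is then the cumulative sum over bins 0..g
  b <- pmin(ceiling(d), G + 1)
  acc <- numeric(G + 2L)
  agg <- rowsum(as.vector(spec$magnitudes), as.integer(b))
  acc[as.integer(rownames(agg)) + 1L] <- agg
  cumsum(acc)[2L:(G + 1L)]
}

#' Ring-wedge partition for the circular-angular descriptor
#'
#' @param ring_radii strictly increasing positive radii (pixels) bounding
#'   the annuli; default `c(3, 6, 9, 12, 15, 18, 21, 24)`.
#' @param n_angles number of equal angular wedges; default 8.
#' @return a list of class `"ring_wedge_partition"`.
#' @export
ring_wedge_partition <- function(ring_radii = seq(3, 24, by = 3),
                                 n_angles = 8L) {
  if (length(ring_radii) < 1L || any(ring_radii <= 0) ||
      any(diff(ring_radii) <= 0)) {
    stop("`ring_radii` must be strictly increasing and positive",
         call. = FALSE)
  }
  if (n_angles < 1L) stop("`n_angles` must be >= 1", call. = FALSE)
  structure(list(ring_radii = as.numeric(ring_radii),
                 n_angles = as.integer(n_angles)),
            class = "ring_wedge_partition")
}

#' Circular-angular (ring-wedge) Fourier descriptor
#'
#' Partitions the centered spectrum into `n_rings * n_angles` sectors
#' (default 8 x 8 = 64): annuli are half-open in Euclidean distance from
#' the center, `(0, r1], (r1, r2], ...` (the zero-frequency bin, whose
#' angle is undefined, is excluded), and wedges are
#' `[k*2*pi/n_angles, (k+1)*2*pi/n_angles)` measured counterclockwise from
#' the positive horizontal-frequency axis.  Each descriptor entry is the
#' sum of magnitudes falling in one sector, ordered ring-major (all wedges
#' of ring 1, then ring 2, ...).
#'
#' @param spec a `"fourier_spectrum"` (or an image).
#' @param partition a [ring_wedge_partition()].
#' @return numeric vector of length `n_rings * n_angles`.
#' @export
circular_angular_descriptor <- function(spec,
                                        partition = ring_wedge_partition()) {
  spec <- as_spectrum(spec)
  if (!inherits(partition, "ring_wedge_partition")) {
    stop("`partition` must be a ring_wedge_partition", call. = FALSE)
  }
  radii <- partition$ring_radii
  n_ang <- partition$n_angles
  half_extent <- floor(min(spec$dims) / 2)
  if (max(radii) > half_extent) {
    stop("outermost radius ", max(radii), " exceeds the spectrum half ",
         "extent ", half_extent, call. = FALSE)
  }
  M <- spec$dims[1]
  N <- spec$dims[2]
  dr <- seq_len(M) - spec$center[1]            # +down in matrix rows
  dc <- seq_len(N) - spec$center[2]
  d <- sqrt(outer(dr^2, dc^2, `+`))
  # angle from the +u (horizontal) axis, counterclockwise with +v upward
  ang <- atan2(outer(-dr, rep(1, N)), outer(rep(1, M), dc)) %% (2 * pi)
  ring <- findInterval(d, radii, left.open = TRUE) + 1L
  wedge <- pmin(floor(ang / (2 * pi / n_ang)), n_ang - 1L)
  keep <- d > 0 & d <= max(radii)
  sector <- (ring[keep] - 1L) * n_ang + wedge[keep] + 1L
  out <- numeric(length(radii) * n_ang)
  agg <- rowsum(as.vector(spec$magnitudes)[as.vector(keep)],
                as.integer(sector))
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Fourier texture feature vector
#'
#' Computes the centered spectrum once and returns either the cumulative
#' circular descriptor alone (`mode = "circular"`, length
#' `floor(min(M,N)/2) - 1`) or that vector followed by the 64-sector
#' circular-angular descriptor (`mode = "circular-angular"`).  For a
#' 2080 x 1540 image the two modes give 769 and 833 features.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param mode `"circular"` or `"circular-angular"` (circular followed by
#'   ring-wedge sectors).
#' @param partition ring-wedge partition used in `"circular-angular"` mode.
#' @return numeric feature vector.
#' @export
fourier_features <- function(img, mode = c("circular", "circular-angular"),
                             partition = ring_wedge_partition()) {
  mode <- match.arg(mode)
  spec <- centered_spectrum(img)
  circ <- circular_descriptor(spec)
  if (mode == "circular") {
    circ
  } else {
    c(circ, circular_angular_descriptor(spec, partition))
  }
}
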