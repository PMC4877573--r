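#' Parameters of the corrosion cellular automaton
#'
#' The texture image is treated as a metal surface: each pixel is a cell
#' whose 8-bit gray level is its state.  A cell whose state exceeds the
#' minimum of its Moore (8-connected) neighborhood by more than the
#' surface-roughness threshold `v` corrodes, losing `floor(gamma * d)`
#' state units, where `d` is that difference and `gamma` the pitting
#' power.  Defaults follow the standard setting `v = 2`, `gamma = 0.05`,
#' `iters = 200`.
#'
#' @param v surface-roughness threshold in intensity units (>= 0).
#' @param gamma pitting power in \[0, 1\].
#' @param iters number of automaton iterations (descriptor length).
#' @return a list of class `"cita_params"`.
#' @export
cita_params <- function(v = 2, gamma = 0.05, iters = 200L) {
  if (v < 0) stop("`v` must be >= 0", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]", call. = FALSE)
  if (iters < 1L) stop("`iters` must be >= 1", call. = FALSE)
  structure(list(v = as.numeric(v), gamma = as.numeric(gamma),
                 iters = as.integer(iters)),
            class = "cita_params")
}

#' Initialize a corrosion-automaton state from an image
#'
#' @param img a [gray_image()] or numeric matrix; its gray levels are the
#'   256 possible initial cell states.
#' @return an object of class `"cita_state"` with fields `grid` (current
#'   states), `t` (completed iterations) and `mass_series` (cumulative
#'   corroded mass after each completed iteration).
#' @export
cita_state <- function(img) {
  structure(list(grid = as_gray_matrix(img), t = 0L,
                 mass_series = numeric(0)),
            class = "cita_state")
}

#' @export
print.cita_state <- function(x, ...) {
  cat(sprintf("<cita_state> %d x %d, t = %d, cumulative mass = %s\n",
              nrow(x$grid), ncol(x$grid), x$t,
              if (x$t == 0L) "0" else format(x$mass_series[x$t])))
  invisible(x)
}

#' Advance the corrosion automaton by one synchronous iteration
#'
#' All cells are updated from the time-t grid simultaneously.  Border
#' cells use only their in-grid neighbors (no padding).  The iteration's
#' total corroded mass (sum of `floor(gamma * d)` over corroding cells)
#' is added to the running cumulative total appended to `mass_series`.
#'
#' @param state a [cita_state()].
#' @param params a [cita_params()].
#' @return the updated `"cita_state"`.
#' @export
cita_step <- function(state, params = cita_params()) {
  if (!inherits(state, "cita_state")) {
    stop("`state` must be a cita_state", call. = FALSE)
  }
  res <- cita_run(state$grid, params$v, params$gamma, 1L)
  prev <- if (state$t == 0L) 0 else state$mass_series[state$t]
  state$grid <- res$grid
  state$t <- state$t + 1L
  state$mass_series <- c(state$mass_series, prev + res$mass[1L])
  state
}

#' Corrosion-inspired texture descriptor
#'
#' Runs the corrosion automaton for `params$iters` iterations starting
#' from the image and returns the cumulative corroded-mass series, a
#' non-decreasing curve of length `iters` (default 200) characterizing
#' how fast local intensity relief erodes at each scale of iteration.
#' Images with no neighbor difference exceeding `v` never corrode and
#' yield an all-zero descriptor.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param params a [cita_params()].
#' @return numeric vector of length `params$iters`.
#' @export
cita_descriptor <- function(img, params = cita_params()) {
  if (!inherits(params, "cita_params")) {
    stop("`params` must be a cita_params", call. = FALSE)
  }
  res <- cita_run(as_gray_matrix(img), params$v, params$gamma, params$iters)
  as.numeric(res$mass)
}
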