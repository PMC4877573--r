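#' Generative model of one species' epidermis texture
#'
#' The generator composes three layers that together exercise every
#' descriptor family: a mosaic of pavement cells (a jittered-seed
#' nearest-region partition with darker cell walls), an isotropic
#' `1/f^exponent` spectral background noise, and anti-aliased dark
#' elliptical stomata with a lighter pore slit, whose count, axis lengths
#' and orientations are drawn from the stated distributions.  It is a
#' minimal texture family, not a biological rendering.
#'
#' @param stomata_density expected stomata count per image (Poisson mean).
#' @param length_mean,length_sd guard-cell length (ellipse major axis) in
#'   pixels: mean and sd of a normal truncated at 0.
#' @param width_mean,width_sd stomatal-complex width (minor axis) in
#'   pixels; `length_mean >= width_mean > 0` is required.
#' @param orientation_concentration concentration of stomatal orientations
#'   around `orientation_mean` (0 = uniform on the circle; larger values
#'   give sd about `1/sqrt(concentration)` radians).
#' @param orientation_mean preferred orientation in radians.
#' @param mosaic_cell_scale pavement-cell diameter in pixels.
#' @param spectral_exponent slope of the radial power law of the
#'   background noise (power ~ `1/f^exponent`).
#' @param base_intensity,contrast mean gray level of the pavement-cell
#'   field and the intensity scale of walls/stomata/noise, in \[0, 255\]
#'   units.
#' @return a list of class `"species_model"`.
#' @export
species_model <- function(stomata_density = 60,
                          length_mean = 18, length_sd = 2,
                          width_mean = 12, width_sd = 1.5,
                          orientation_concentration = 0,
                          orientation_mean = 0,
                          mosaic_cell_scale = 20,
                          spectral_exponent = 2.5,
                          base_intensity = 150,
                          contrast = 60) {
  if (stomata_density < 0) stop("`stomata_density` must be >= 0",
                                call. = FALSE)
  if (!(length_mean >= width_mean && width_mean > 0)) {
    stop("need length_mean >= width_mean > 0", call. = FALSE)
  }
  if (length_sd < 0 || width_sd < 0) stop("axis sds must be >= 0",
                                          call. = FALSE)
  if (orientation_concentration < 0) {
    stop("`orientation_concentration` must be >= 0", call. = FALSE)
  }
  if (mosaic_cell_scale <= 2) stop("`mosaic_cell_scale` must exceed 2 px",
                                   call. = FALSE)
  structure(list(stomata_density = stomata_density,
                 length_mean = length_mean, length_sd = length_sd,
                 width_mean = width_mean, width_sd = width_sd,
                 orientation_concentration = orientation_concentration,
                 orientation_mean = orientation_mean,
                 mosaic_cell_scale = mosaic_cell_scale,
                 spectral_exponent = spectral_exponent,
                 base_intensity = base_intensity, contrast = contrast),
            class = "species_model")
}

#' Multiplicative trait shift emulating phenotypic plasticity
#'
#' Applied to a [species_model()] it rescales the stomatal trait
#' parameters (density, length, width — sds scaled with their means so
#' the coefficient of variation is preserved) while leaving the
#' micro-texture parameters (mosaic scale, spectral exponent, intensity)
#' untouched, emulating an individual of the same species grown in a
#' different environment.
#'
#' @param density_factor,length_factor,width_factor positive multipliers.
#' @return a list of class `"plasticity_shift"`.
#' @export
plasticity_shift <- function(density_factor = 1, length_factor = 1,
                             width_factor = 1) {
  if (density_factor <= 0 || length_factor <= 0 || width_factor <= 0) {
    stop("all shift factors must be > 0", call. = FALSE)
  }
  structure(list(density_factor = density_factor,
                 length_factor = length_factor,
                 width_factor = width_factor),
            class = "plasticity_shift")
}

#' Apply a plasticity shift to a species model
#'
#' @param model a [species_model()].
#' @param shift a [plasticity_shift()].
#' @return the shifted [species_model()].
#' @export
apply_shift <- function(model, shift) {
  stopifnot(inherits(model, "species_model"),
            inherits(shift, "plasticity_shift"))
  species_model(
    stomata_density = model$stomata_density * shift$density_factor,
    length_mean = model$length_mean * shift$length_factor,
    length_sd = model$length_sd * shift$length_factor,
    width_mean = model$width_mean * shift$width_factor,
    width_sd = model$width_sd * shift$width_factor,
    orientation_concentration = model$orientation_concentration,
    orientation_mean = model$orientation_mean,
    mosaic_cell_scale = model$mosaic_cell_scale,
    spectral_exponent = model$spectral_exponent,
    base_intensity = model$base_intensity,
    contrast = model$contrast
  )
}

# Isotropic 1/f^exponent Gaussian random field, unit variance.
spectral_noise <- function(M, N, exponent) {
  white <- matrix(rnorm(M * N), M, N)
  F <- stats::fft(white)
  fi <- (seq_len(M) - 1L) / M
  fi <- pmin(fi, 1 - fi)
  fj <- (seq_len(N) - 1L) / N
  fj <- pmin(fj, 1 - fj)
  fr <- sqrt(outer(fi^2, fj^2, `+`))
  amp <- fr^(-exponent / 2)
  amp[1L, 1L] <- 0
  field <- Re(stats::fft(F * amp, inverse = TRUE)) / (M * N)
  field / stats::sd(field)
}

# Jittered-seed nearest-region partition (cell id per pixel).  The
# nearest seed is searched over the pixel's 3x3 block of grid cells,
# which is exact for the jitter amplitude used (0.45 of the spacing) up
# to negligible corner cases; the windowed rule is the partition's
# definition.
mosaic_ids <- function(M, N, spacing) {
  gi <- ceiling(M / spacing) + 2L      # one padding ring of cells
  gj <- ceiling(N / spacing) + 2L
  cx <- matrix((seq_len(gi) - 1.5) * spacing + spacing / 2, gi, gj) +
    matrix(runif(gi * gj, -0.45, 0.45) * spacing, gi, gj)
  cy <- matrix(rep((seq_len(gj) - 1.5) * spacing + spacing / 2,
                   each = gi), gi, gj) +
    matrix(runif(gi * gj, -0.45, 0.45) * spacing, gi, gj)
  px <- matrix(seq_len(M), M, N)
  py <- matrix(rep(seq_len(N), each = M), M, N)
  bi <- pmin(pmax(floor((px - 0.5) / spacing) + 2L, 2L), gi - 1L)
  bj <- pmin(pmax(floor((py - 0.5) / spacing) + 2L, 2L), gj - 1L)
  best <- matrix(Inf, M, N)
  id <- matrix(1L, M, N)
  for (oi in -1L:1L) {
    for (oj in -1L:1L) {
      ci <- bi + oi
      cj <- bj + oj
      lin <- cbind(as.vector(ci), as.vector(cj))
      d2 <- (px - cx[lin])^2 + (py - cy[lin])^2
      upd <- d2 < best
      best[upd] <- d2[upd]
      id[upd] <- (ci[upd] - 1L) * gj + cj[upd]
    }
  }
  id
}

# Draw from a normal truncated at (0, Inf) by rejection.
rtrunc_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out <= 0)
  }
  out
}

# Box downsample by integer factor ss (block mean).
box_downsample <- function(x, ss) {
  if (ss == 1L) return(x)
  M <- nrow(x) %/% ss
  N <- ncol(x) %/% ss
  x <- x[seq_len(M * ss), seq_len(N * ss), drop = FALSE]
  dim(x) <- c(ss, M, ss * N)
  x <- colMeans(x)                       # M x (ss*N)
  dim(x) <- c(M, ss, N)
  x <- apply(x, c(1L, 3L), mean)
  x
}

#' Generate one synthetic epidermis image with its trait measurements
#'
#' Renders the model at `supersample` times the target resolution and box
#' downsamples, so ellipse and wall edges are anti-aliased.  The returned
#' trait vector holds the realized stomata count and the means of the
#' realized major/minor axes — the synthetic analogue of manual
#' measurement ground truth (model means are reported when no stoma was
#' drawn).  Identical `(model, size, seed)` give a bit-identical image.
#'
#' @param model a [species_model()].
#' @param size integer `c(M, N)`, at least 64 x 64.
#' @param seed integer seed for all randomness in this image.
#' @param supersample anti-aliasing factor (integer >= 1; default 2).
#' @return a list with `image` (a [gray_image()]) and `traits` (named
#'   vector `density`, `guard_cell_length`, `complex_width`).
#' @export
generate_image <- function(model, size = c(256L, 256L), seed = 1L,
                           supersample = 2L) {
  stopifnot(inherits(model, "species_model"))
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 64L)) {
    stop("`size` must be c(M, N) with both >= 64", call. = FALSE)
  }
  ss <- as.integer(supersample)
  with_seed(seed, {
    M <- size[1] * ss
    N <- size[2] * ss
    ctr <- model$contrast

    # pavement-cell mosaic with per-cell intensity variation
    id <- mosaic_ids(M, N, model$mosaic_cell_scale * ss)
    ncell <- max(id)
    cell_val <- model$base_intensity + rnorm(ncell, 0, 0.10 * ctr)
    canvas <- matrix(cell_val[id], M, N)

    # darker cell walls where the partition changes (2 px wide before
    # downsampling)
    wall <- matrix(FALSE, M, N)
    wall[-M, ] <- wall[-M, ] | (id[-M, ] != id[-1L, ])
    wall[-1L, ] <- wall[-1L, ] | (id[-M, ] != id[-1L, ])
    wall[, -N] <- wall[, -N] | (id[, -N] != id[, -1L])
    wall[, -1L] <- wall[, -1L] | (id[, -N] != id[, -1L])
    canvas[wall] <- canvas[wall] - 0.5 * ctr

    # power-law background noise
    canvas <- canvas + 0.12 * ctr *
      spectral_noise(M, N, model$spectral_exponent)

    # stomata: dark ellipse, lighter pore slit along the major axis
    n_stom <- rpois(1L, model$stomata_density)
    lens <- rtrunc_pos(n_stom, model$length_mean, model$length_sd)
    wids <- rtrunc_pos(n_stom, model$width_mean, model$width_sd)
    wids <- pmin(wids, 0.95 * lens)
    if (model$orientation_concentration == 0) {
      thetas <- runif(n_stom, 0, 2 * pi)
    } else {
      thetas <- model$orientation_mean +
        rnorm(n_stom, 0, 1 / sqrt(model$orientation_concentration))
    }
    xs <- runif(n_stom, 1, M)
    ys <- runif(n_stom, 1, N)
    for (s in seq_len(n_stom)) {
      a <- lens[s] * ss / 2
      b <- wids[s] * ss / 2
      rb <- ceiling(a) + 2L
      ri <- max(1L, floor(xs[s] - rb)):min(M, ceiling(xs[s] + rb))
      ci <- max(1L, floor(ys[s] - rb)):min(N, ceiling(ys[s] + rb))
      dx <- outer(rep(1, length(ri)), ci - ys[s])        # along columns
      dy <- outer(-(ri - xs[s]), rep(1, length(ci)))     # +y upward
      xr <- dx * cos(thetas[s]) + dy * sin(thetas[s])
      yr <- -dx * sin(thetas[s]) + dy * cos(thetas[s])
      e_out <- (xr / a)^2 + (yr / b)^2
      e_in <- (xr / (0.70 * a))^2 + (yr / (0.22 * b))^2
      patch <- canvas[ri, ci]
      patch[e_out <= 1] <- patch[e_out <= 1] - 0.45 * ctr
      patch[e_in <= 1] <- patch[e_in <= 1] + 0.60 * ctr
      canvas[ri, ci] <- patch
    }

    out <- box_downsample(canvas, ss)
    out <- round(out)
    out[out < 0] <- 0
    out[out > 255] <- 255
    traits <- c(
      density = as.numeric(n_stom),
      guard_cell_length = if (n_stom > 0) mean(lens) else model$length_mean,
      complex_width = if (n_stom > 0) mean(wids) else model$width_mean
    )
    list(image = gray_image(out), traits = traits)
  })
}

#' Generate a labeled multi-species dataset
#'
#' Draws `n_per_class` seeded images per species model.  Per-image seeds
#' are derived deterministically from the master seed, so the full
#' dataset is reproducible bit-for-bit.
#'
#' @param models a named list of [species_model()]s (names become species
#'   labels; unnamed models are labeled `species1, species2, ...`).
#' @param n_per_class images per species.
#' @param size,supersample image geometry, as in [generate_image()].
#' @param seed master seed.
#' @param environment environment tag stored with every sample.
#' @return a list with `images` (list of [gray_image()]), `labels`
#'   (data frame `sample_id`, `species`, `environment`) and `traits`
#'   (data frame `sample_id`, `density`, `guard_cell_length`,
#'   `complex_width`).
#' @export
generate_dataset <- function(models, n_per_class, size = c(256L, 256L),
                             seed = 1L, environment = "gallery_forest",
                             supersample = 2L) {
  if (!is.list(models) || length(models) < 1L) {
    stop("`models` must be a non-empty list of species models",
         call. = FALSE)
  }
  nm <- names(models)
  if (is.null(nm)) nm <- paste0("species", seq_along(models))
  total <- length(models) * n_per_class
  img_seeds <- with_seed(seed, sample.int(.Machine$integer.max, total))
  images <- vector("list", total)
  ids <- character(total)
  spec <- character(total)
  traits <- matrix(0, total, 3L)
  idx <- 0L
  for (m in seq_along(models)) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      g <- generate_image(models[[m]], size = size, seed = img_seeds[idx],
                          supersample = supersample)
      images[[idx]] <- g$image
      ids[idx] <- paste0(nm[m], "_", environment, "_", i)
      spec[idx] <- nm[m]
      traits[idx, ] <- g$traits
    }
  }
  list(
    images = images,
    labels = data.frame(sample_id = ids, species = spec,
                        environment = rep(environment, length(ids)),
                        stringsAsFactors = FALSE),
    traits = data.frame(sample_id = ids, density = traits[, 1],
                        guard_cell_length = traits[, 2],
                        complex_width = traits[, 3],
                        stringsAsFactors = FALSE)
  )
}

#' Generate a two-environment plasticity pair for one species
#'
#' Environment 1 draws from the model as given; environment 2 draws from
#' the trait-shifted model ([apply_shift()]) under a different
#' environment tag but the same species label.  Because the shift leaves
#' the micro-texture parameters untouched, texture descriptors stay
#' informative across environments while the measured traits drift by
#' the shift factors.
#'
#' @param model a [species_model()].
#' @param shift a [plasticity_shift()].
#' @param n_env1,n_env2 images per environment.
#' @param size,seed,supersample as in [generate_dataset()].
#' @param species species label used for both environments.
#' @param environments length-2 character vector of environment tags.
#' @return a list with elements `env1` and `env2`, each as returned by
#'   [generate_dataset()] for the single species.
#' @export
generate_plasticity_pair <- function(model, shift, n_env1 = 6L,
                                     n_env2 = 9L, size = c(256L, 256L),
                                     seed = 1L, species = "species1",
                                     environments = c("gallery_forest",
                                                      "marsh_camp"),
                                     supersample = 2L) {
  stopifnot(inherits(model, "species_model"),
            inherits(shift, "plasticity_shift"))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2L))
  m2 <- apply_shift(model, shift)
  env1 <- generate_dataset(stats::setNames(list(model), species), n_env1,
                           size = size, seed = seeds[1],
                           environment = environments[1],
                           supersample = supersample)
  env2 <- generate_dataset(stats::setNames(list(m2), species), n_env2,
                           size = size, seed = seeds[2],
                           environment = environments[2],
                           supersample = supersample)
  list(env1 = env1, env2 = env2)
}

#' Eight well-separated example species models
#'
#' A fixed panel of models whose mosaic scales, spectral exponents,
#' stomatal densities, sizes and orientation regimes differ enough that
#' texture descriptors separate them cleanly; used in examples, tests and
#' the worked analyses.
#'
#' @param n number of models, up to 8.
#' @return a named list of [species_model()]s.
#' @export
example_species_models <- function(n = 8L) {
  panel <- list(
    ilex = species_model(stomata_density = 30, length_mean = 24,
                         length_sd = 2, width_mean = 16, width_sd = 1.5,
                         orientation_concentration = 0,
                         mosaic_cell_scale = 28, spectral_exponent = 3.2,
                         base_intensity = 160, contrast = 60),
    myrsine = species_model(stomata_density = 90, length_mean = 12,
                            length_sd = 1.2, width_mean = 8, width_sd = 1,
                            orientation_concentration = 0,
                            mosaic_cell_scale = 12,
                            spectral_exponent = 1.8,
                            base_intensity = 140, contrast = 70),
    handroanthus = species_model(stomata_density = 55, length_mean = 18,
                                 length_sd = 2, width_mean = 13,
                                 width_sd = 1.5,
                                 orientation_concentration = 6,
                                 orientation_mean = 0,
                                 mosaic_cell_scale = 20,
                                 spectral_exponent = 2.6,
                                 base_intensity = 170, contrast = 50),
    xylopia = species_model(stomata_density = 120, length_mean = 9,
                            length_sd = 1, width_mean = 6, width_sd = 0.8,
                            orientation_concentration = 0,
                            mosaic_cell_scale = 36,
                            spectral_exponent = 2.2,
                            base_intensity = 130, contrast = 80),
    miconia = species_model(stomata_density = 45, length_mean = 28,
                            length_sd = 3, width_mean = 24, width_sd = 2,
                            orientation_concentration = 0,
                            mosaic_cell_scale = 16,
                            spectral_exponent = 3.6,
                            base_intensity = 185, contrast = 45),
    tapirira = species_model(stomata_density = 70, length_mean = 16,
                             length_sd = 1.8, width_mean = 10,
                             width_sd = 1.2,
                             orientation_concentration = 6,
                             orientation_mean = pi / 2,
                             mosaic_cell_scale = 24,
                             spectral_exponent = 1.4,
                             base_intensity = 150, contrast = 65),
    guapira = species_model(stomata_density = 15, length_mean = 34,
                            length_sd = 3, width_mean = 22, width_sd = 2,
                            orientation_concentration = 0,
                            mosaic_cell_scale = 44,
                            spectral_exponent = 2.9,
                            base_intensity = 120, contrast = 75),
    symplocos = species_model(stomata_density = 100, length_mean = 14,
                              length_sd = 1.5, width_mean = 12,
                              width_sd = 1.2,
                              orientation_concentration = 3,
                              orientation_mean = pi / 4,
                              mosaic_cell_scale = 9,
                              spectral_exponent = 2.0,
                              base_intensity = 200, contrast = 55)
  )
  if (n < 1L || n > length(panel)) {
    stop("`n` must lie in [1, ", length(panel), "]", call. = FALSE)
  }
  panel[seq_len(n)]
}
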