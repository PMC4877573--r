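#' Extract one texture descriptor from an image
#'
#' Applies optional contrast enhancement and then one of the four
#' descriptor families.  Descriptor lengths: `fourier-circular`
#' `floor(min(M,N)/2) - 1` (769 at 2080 x 1540); `fourier-circular-angular`
#' that plus the 64 ring-wedge sectors (833 at 2080 x 1540); `cita`
#' `params$iters` (default 200); `lbp` `2^P` (default 256).
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param method one of `"fourier-circular"`, `"fourier-circular-angular"`,
#'   `"cita"`, `"lbp"`.
#' @param enhance apply [enhance_contrast()] first (default `TRUE`).
#' @param saturation saturation fraction for the enhancement.
#' @param cita a [cita_params()].
#' @param lbp an [lbp_params()].
#' @param partition a [ring_wedge_partition()] for the circular-angular
#'   sectors.
#' @return numeric feature vector.
#' @export
texture_descriptor <- function(img,
                               method = c("fourier-circular",
                                          "fourier-circular-angular",
                                          "cita", "lbp"),
                               enhance = TRUE, saturation = 0.01,
                               cita = cita_params(), lbp = lbp_params(),
                               partition = ring_wedge_partition()) {
  method <- match.arg(method)
  img <- as_gray_matrix(img)
  if (enhance) {
    img <- withCallingHandlers(
      enhance_contrast(img, saturation),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  switch(method,
         `fourier-circular` = fourier_features(img, "circular"),
         `fourier-circular-angular` =
           fourier_features(img, "circular-angular", partition),
         cita = cita_descriptor(img, cita),
         lbp = lbp_histogram(img, lbp))
}

#' Build a feature table from a generated dataset
#'
#' Convenience wrapper extracting one descriptor per image of a
#' [generate_dataset()] result (or any list with `images` and `labels`).
#' With `method = "quantitative"` the manual stomatal traits are used as
#' the 3-feature vector instead of a texture descriptor; appending
#' `"+quantitative"` to a texture method fuses the traits onto the
#' texture features ([fuse_features()]).
#'
#' @param dataset a list with `images`, `labels` and (for trait modes)
#'   `traits`, as produced by [generate_dataset()].
#' @param method descriptor name as in [texture_descriptor()], or
#'   `"quantitative"`, or `"<texture>+quantitative"`.
#' @param ... passed on to [texture_descriptor()].
#' @return a [feature_table()].
#' @export
dataset_feature_table <- function(dataset, method = "fourier-circular",
                                  ...) {
  lab <- dataset$labels
  if (identical(method, "quantitative")) {
    empty <- feature_table(matrix(numeric(0), nrow(lab), 0L),
                           lab$species, lab$sample_id, lab$environment)
    return(fuse_features(empty, dataset$traits))
  }
  fuse <- grepl("\\+quantitative$", method)
  base_method <- sub("\\+quantitative$", "", method)
  feats <- t(vapply(dataset$images,
                    function(im) texture_descriptor(im, base_method, ...),
                    texture_descriptor(dataset$images[[1L]], base_method,
                                       ...)))
  ft <- feature_table(feats, lab$species, lab$sample_id, lab$environment)
  if (fuse) ft <- fuse_features(ft, dataset$traits)
  ft
}

#' Merge two labeled datasets
#'
#' Concatenates the images, labels and traits of two [generate_dataset()]
#' results (e.g. a base population and a second-environment set for the
#' joint plasticity protocol).
#'
#' @param a,b dataset lists as returned by [generate_dataset()].
#' @return a merged dataset list.
#' @export
merge_datasets <- function(a, b) {
  list(images = c(a$images, b$images),
       labels = rbind(a$labels, b$labels),
       traits = rbind(a$traits, b$traits))
}
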