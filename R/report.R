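#' Extract descriptors for a directory of images into a feature CSV
#'
#' Reads every image listed in the labels CSV (columns `sample_id`,
#' `file`, `species`, and optionally `environment`) from `image_dir`,
#' extracts the requested descriptor and writes one row per image in the
#' [write_feature_table()] layout.  Unreadable images are skipped with a
#' warning; if all fail, an error is raised.  Mixed image sizes are
#' rejected for size-dependent descriptors (the circular descriptor
#' length depends on the image extent) rather than silently resampled.
#'
#' @param image_dir directory holding the image files.
#' @param labels_csv CSV with columns `sample_id`, `file`, `species` and
#'   optionally `environment`.
#' @param out_csv output feature CSV path.
#' @param method,enhance,saturation,... as in [texture_descriptor()].
#' @return the output path, invisibly.
#' @export
run_extract <- function(image_dir, labels_csv, out_csv,
                        method = "fourier-circular", enhance = TRUE,
                        saturation = 0.01, ...) {
  lab <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "file", "species") %in% names(lab))) {
    stop("labels CSV must have columns sample_id, file, species",
         call. = FALSE)
  }
  if (is.null(lab$environment)) lab$environment <- ""
  rows <- list()
  keep <- logical(nrow(lab))
  dims <- NULL
  for (i in seq_len(nrow(lab))) {
    path <- file.path(image_dir, lab$file[i])
    img <- tryCatch(load_grayscale(path), error = function(e) {
      warning("skipping ", path, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(img)) next
    if (is.null(dims)) {
      dims <- dim(img)
    } else if (!identical(dim(img), dims) &&
               startsWith(method, "fourier")) {
      stop("image sizes differ (", paste(dims, collapse = "x"), " vs ",
           paste(dim(img), collapse = "x"), "); the circular descriptor ",
           "length depends on the size — crop or resize first",
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <-
      texture_descriptor(img, method, enhance = enhance,
                         saturation = saturation, ...)
    keep[i] <- TRUE
  }
  if (!length(rows)) stop("no image could be read", call. = FALSE)
  ft <- feature_table(do.call(rbind, rows), lab$species[keep],
                      lab$sample_id[keep], lab$environment[keep])
  write_feature_table(ft, out_csv)
}

#' Render cross-validation results as an accuracy table
#'
#' Formats one row per result in the conventional layout: feature name,
#' number of retained PCA components, mean success rate with its standard
#' deviation over repeats, and any per-class columns, e.g.
#' `45  96.60 (+/-1.27)`.
#'
#' @param results a named list of `"cv_result"` objects (names become the
#'   feature column).
#' @param per_class optional character vector of class names whose
#'   per-class success rates are appended as columns.
#' @return a data frame (also printed) with columns `feature`, `#`,
#'   `rate` and one column per requested class.
#' @export
run_report <- function(results, per_class = NULL) {
  if (!length(results)) stop("need at least one result", call. = FALSE)
  if (is.null(names(results))) {
    names(results) <- paste0("feature", seq_along(results))
  }
  df <- data.frame(
    feature = names(results),
    `#` = vapply(results, function(r) r$n_components, integer(1)),
    rate = vapply(results, function(r) {
      sprintf("%.2f (±%.2f)", r$mean_accuracy, r$std_accuracy)
    }, character(1)),
    check.names = FALSE, row.names = NULL, stringsAsFactors = FALSE
  )
  for (cl in per_class) {
    df[[paste0("% ", cl)]] <- vapply(results, function(r) {
      v <- unname(r$per_class_rate[cl])
      if (is.na(v)) NA_real_ else round(v)
    }, numeric(1))
  }
  print(df, row.names = FALSE)
  invisible(df)
}
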