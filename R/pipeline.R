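#' Per-sample feature table with class and environment labels
#'
#' The substrate of all classification steps: a numeric feature matrix
#' (one row per sample, uniform length) together with a sample id, a
#' species label and an environment tag per row.
#'
#' @param features numeric matrix (samples x features); zero columns are
#'   allowed (e.g. before fusing in manual traits).
#' @param species character vector of class labels, one per row.
#' @param sample_id optional character ids; defaults to `s1, s2, ...`.
#' @param environment optional character environment tags; default `""`.
#' @return an object of class `"feature_table"` with fields `sample_id`,
#'   `species`, `environment`, `features`.
#' @export
feature_table <- function(features, species, sample_id = NULL,
                          environment = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features) && ncol(features) > 0L) {
    stop("`features` must be numeric", call. = FALSE)
  }
  n <- nrow(features)
  species <- as.character(species)
  if (length(species) != n) {
    stop("`species` must have one label per feature row", call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n))
  if (is.null(environment)) environment <- rep("", n)
  if (length(sample_id) != n || length(environment) != n) {
    stop("`sample_id` and `environment` must have one entry per row",
         call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(features) <- NULL
  structure(list(sample_id = as.character(sample_id), species = species,
                 environment = as.character(environment),
                 features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features, %d species\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$species))))
  invisible(x)
}

subset_table <- function(ft, idx) {
  feature_table(ft$features[idx, , drop = FALSE], ft$species[idx],
                ft$sample_id[idx], ft$environment[idx])
}

#' Read / write a feature table as CSV
#'
#' The on-disk layout is one row per sample with columns
#' `sample_id, species, environment, f1, f2, ...`.
#'
#' @param path CSV file path.
#' @return `read_feature_table` returns a [feature_table()];
#'   `write_feature_table` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(sample_id = "character",
                                       species = "character",
                                       environment = "character"))
  need <- c("sample_id", "species", "environment")
  if (!all(need %in% names(df))) {
    stop("feature CSV must have columns sample_id, species, environment",
         call. = FALSE)
  }
  feat <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  storage.mode(feat) <- "double"
  feature_table(feat, df$species, df$sample_id, df$environment)
}

#' @rdname read_feature_table
#' @param ft a [feature_table()].
#' @export
write_feature_table <- function(ft, path) {
  feat <- ft$features
  if (ncol(feat) > 0L) colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  df <- data.frame(sample_id = ft$sample_id, species = ft$species,
                   environment = ft$environment, feat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Fit a z-score standardization on a training matrix; constant columns are
# centered but left unscaled.
fit_standardizer <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2L, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(center = mu, scale = s)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2L, std$center, "-"), 2L, std$scale, "/")
}

# Fit mean-centered PCA on a training matrix, capping the number of
# components at the available rank.
fit_pca <- function(x, n_components) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  list(center = pc$center, rotation = pc$rotation[, seq_len(k), drop = FALSE],
       sdev = pc$sdev[seq_len(k)], n_components = k)
}

apply_pca <- function(fit, x) {
  sweep(x, 2L, fit$center, "-") %*% fit$rotation
}

#' Reduce a feature table by principal component analysis
#'
#' Projects the mean-centered features onto the leading principal
#' components (ordered by decreasing explained variance).  With
#' `n_components = "auto"` the component count is chosen by stratified
#' cross-validation accuracy over a grid.
#'
#' @param ft a [feature_table()].
#' @param n_components number of components to retain, or `"auto"`.
#' @param classifier,k,folds,repeats,seed,grid settings for the `"auto"`
#'   search: candidate counts (`grid`, default `2:min(40, rank)`),
#'   classifier used to score them, and the CV design.
#' @return the reduced [feature_table()], with attributes
#'   `"explained_variance"` (fraction per component) and `"n_components"`.
#' @export
pca_reduce <- function(ft, n_components, classifier = c("knn", "lda"),
                       k = 1L, folds = 6L, repeats = 1L, seed = 1L,
                       grid = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  x <- ft$features
  rank_cap <- min(nrow(x) - 1L, ncol(x))
  if (identical(n_components, "auto")) {
    classifier <- match.arg(classifier)
    if (is.null(grid)) grid <- seq(2L, min(40L, rank_cap))
    grid <- grid[grid <= rank_cap]
    acc <- vapply(grid, function(nc) {
      stratified_cv(ft, classifier = classifier, k = k, folds = folds,
                    repeats = repeats, seed = seed, pca = nc)$mean_accuracy
    }, numeric(1))
    n_components <- grid[which.max(acc)]
  }
  if (n_components > rank_cap) {
    stop("n_components = ", n_components, " exceeds the data rank cap ",
         rank_cap, call. = FALSE)
  }
  fit <- fit_pca(x, n_components)
  proj <- apply_pca(fit, x)
  out <- feature_table(proj, ft$species, ft$sample_id, ft$environment)
  tot <- sum(apply(x, 2L, stats::var))
  attr(out, "explained_variance") <- fit$sdev^2 / tot
  attr(out, "n_components") <- fit$n_components
  out
}

#' k-nearest-neighbor classification
#'
#' Labels each test sample by the majority class among its `k` nearest
#' training samples under Euclidean distance.  Ties are deterministic:
#' equal distances are broken by the lower training-row index, and vote
#' ties by the lexicographically smallest class label.  `k = 1` is the
#' nearest-neighbor rule.
#'
#' @param train,test [feature_table()]s with matching feature length
#'   (`test` may also be a bare numeric matrix).
#' @param k number of neighbors, at most `nrow(train)`.
#' @return character vector of predicted species for the test rows.
#' @export
knn_predict <- function(train, test, k = 1L) {
  stopifnot(inherits(train, "feature_table"))
  xtr <- train$features
  xte <- if (inherits(test, "feature_table")) test$features else as.matrix(test)
  if (nrow(xtr) == 0L) stop("empty training table", call. = FALSE)
  if (ncol(xtr) != ncol(xte)) {
    stop("feature length mismatch: train ", ncol(xtr), " vs test ",
         ncol(xte), call. = FALSE)
  }
  if (k < 1L || k > nrow(xtr)) {
    stop("`k` must lie in [1, n_train]", call. = FALSE)
  }
  # squared Euclidean distances, all test rows at once
  d2 <- outer(rowSums(xte^2), rowSums(xtr^2), "+") - 2 * xte %*% t(xtr)
  labs <- train$species
  apply(d2, 1L, function(dr) {
    nn <- order(dr)[seq_len(k)]           # order() is stable: index ties
    votes <- table(labs[nn])
    names(votes)[which.max(votes)][1L]    # table() is sorted by label
  })
}

#' Gaussian linear discriminant classification
#'
#' Fits a linear discriminant with class means, a pooled within-class
#' covariance and empirical class priors; each test sample is assigned
#' the class maximizing the linear discriminant score
#' `x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c`.  A ridge
#' `ridge * trace(S)/p` is added to the diagonal to stabilize
#' near-singular pooled covariances (e.g. after aggressive PCA).
#'
#' @param train,test [feature_table()]s with matching feature length.
#' @param ridge ridge coefficient relative to the mean diagonal of the
#'   pooled covariance; default `1e-6`.
#' @return character vector of predicted species for the test rows.
#' @export
lda_predict <- function(train, test, ridge = 1e-6) {
  stopifnot(inherits(train, "feature_table"))
  xtr <- train$features
  xte <- if (inherits(test, "feature_table")) test$features else as.matrix(test)
  classes <- sort(unique(train$species))
  if (length(classes) < 2L) {
    stop("LDA needs at least 2 classes in training", call. = FALSE)
  }
  n <- nrow(xtr)
  p <- ncol(xtr)
  if (n <= length(classes)) {
    singletons <- names(which(table(train$species) < 2L))
    stop("cannot pool within-class covariance (", n, " samples, ",
         length(classes), " classes",
         if (length(singletons)) paste0("; single-sample classes: ",
                                        paste(singletons, collapse = ", ")),
         ")", call. = FALSE)
  }
  mu <- t(vapply(classes, function(cl) {
    colMeans(xtr[train$species == cl, , drop = FALSE])
  }, numeric(p)))
  Sw <- matrix(0, p, p)
  for (ci in seq_along(classes)) {
    xc <- xtr[train$species == classes[ci], , drop = FALSE]
    xc <- sweep(xc, 2L, mu[ci, ], "-")
    Sw <- Sw + crossprod(xc)
  }
  Sw <- Sw / (n - length(classes))
  lam <- ridge * sum(diag(Sw)) / p
  if (!is.finite(lam) || lam <= 0) lam <- ridge
  S <- Sw + diag(lam, p)
  Sinv_mu <- solve(S, t(mu))                    # p x C
  const <- -0.5 * colSums(t(mu) * Sinv_mu) +
    log(as.numeric(table(factor(train$species, classes))) / n)
  scores <- xte %*% Sinv_mu + matrix(const, nrow(xte), length(classes),
                                     byrow = TRUE)
  classes[max.col(scores, ties.method = "first")]
}

# Dispatch to the configured classifier.
predict_labels <- function(train, test, classifier, k = 1L, ridge = 1e-6) {
  switch(classifier,
         knn = knn_predict(train, test, k = k),
         lda = lda_predict(train, test, ridge = ridge),
         stop("unknown classifier: ", classifier, call. = FALSE))
}

# Stratified fold assignment: within each class the members (canonically
# ordered by sample id, so the split depends only on ids and the seed,
# not on row order) are shuffled and dealt onto a randomly rotated fold
# sequence, keeping per-class counts within one sample of proportionality.
stratified_folds <- function(species, folds, sample_id) {
  fold_of <- integer(length(species))
  for (cl in sort(unique(species))) {
    idx <- which(species == cl)
    idx <- idx[order(sample_id[idx])]
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep_len(sample.int(folds), length(idx))
  }
  fold_of
}

#' Stratified repeated cross-validation
#'
#' Splits samples into `folds` class-stratified subsets, uses each subset
#' once as the test set with the remainder as training, and pools the
#' predictions so every sample is classified exactly once per repeat; the
#' whole scheme is repeated `repeats` times with fresh shuffles to obtain
#' a standard deviation.  Standardization and PCA (when enabled) are
#' fitted on the training folds only.
#'
#' @param ft a [feature_table()].
#' @param classifier `"knn"` or `"lda"`.
#' @param k neighbors for k-NN (default 1).
#' @param folds number of folds (default 6).
#' @param repeats number of repetitions (default 10).
#' @param seed master seed; per-repeat shuffle seeds are derived from it.
#' @param pca `"off"` for no reduction, or an integer component count.
#' @param standardize z-score features using training-fold statistics.
#' @param ridge ridge coefficient for LDA.
#' @param reduce_folds if `TRUE`, a class smaller than `folds` reduces the
#'   fold count (with a warning) instead of erroring.
#' @return an object of class `"cv_result"`: `mean_accuracy` and
#'   `std_accuracy` in percent over repeats, `per_class_rate` (percent per
#'   species, averaged over repeats), `n_components`, and the
#'   configuration used.
#' @export
stratified_cv <- function(ft, classifier = c("knn", "lda"), k = 1L,
                          folds = 6L, repeats = 10L, seed = 1L,
                          pca = "off", standardize = TRUE, ridge = 1e-6,
                          reduce_folds = FALSE) {
  stopifnot(inherits(ft, "feature_table"))
  classifier <- match.arg(classifier)
  n <- nrow(ft$features)
  class_sizes <- table(ft$species)
  if (min(class_sizes) < 2L) {
    stop("every class needs >= 2 samples for stratified CV", call. = FALSE)
  }
  if (min(class_sizes) < folds) {
    if (!reduce_folds) {
      stop("smallest class has ", min(class_sizes), " samples < ", folds,
           " folds; set reduce_folds = TRUE to shrink the fold count",
           call. = FALSE)
    }
    folds <- as.integer(min(class_sizes))
    warning("fold count reduced to ", folds,
            " to fit the smallest class")
  }
  if (identical(pca, "auto")) {
    rank_cap <- n - ceiling(n / folds) - 1L
    grid <- seq(2L, min(40L, rank_cap, ncol(ft$features)))
    acc_grid <- vapply(grid, function(nc) {
      stratified_cv(ft, classifier = classifier, k = k, folds = folds,
                    repeats = 1L, seed = seed, pca = nc,
                    standardize = standardize, ridge = ridge,
                    reduce_folds = reduce_folds)$mean_accuracy
    }, numeric(1))
    pca <- grid[which.max(acc_grid)]
  }
  use_pca <- !identical(pca, "off") && !is.null(pca)
  repeat_seeds <- with_seed(seed, sample.int(.Machine$integer.max, repeats))

  acc <- numeric(repeats)
  per_class <- matrix(0, repeats, length(class_sizes),
                      dimnames = list(NULL, names(class_sizes)))
  ncomp_used <- integer(0)
  for (r in seq_len(repeats)) {
    fold_of <- with_seed(repeat_seeds[r],
                         stratified_folds(ft$species, folds,
                                          ft$sample_id))
    pred <- character(n)
    for (f in seq_len(folds)) {
      te <- which(fold_of == f)
      tr <- which(fold_of != f)
      train <- subset_table(ft, tr)
      xte <- ft$features[te, , drop = FALSE]
      if (standardize) {
        std <- fit_standardizer(train$features)
        train$features <- apply_standardizer(std, train$features)
        xte <- apply_standardizer(std, xte)
      }
      if (use_pca) {
        fit <- fit_pca(train$features, as.integer(pca))
        ncomp_used <- c(ncomp_used, fit$n_components)
        train$features <- apply_pca(fit, train$features)
        xte <- apply_pca(fit, xte)
      }
      pred[te] <- predict_labels(train, xte, classifier, k = k,
                                 ridge = ridge)
    }
    acc[r] <- 100 * mean(pred == ft$species)
    per_class[r, ] <- 100 * vapply(names(class_sizes), function(cl) {
      mean(pred[ft$species == cl] == cl)
    }, numeric(1))
  }
  structure(
    list(mean_accuracy = mean(acc), std_accuracy = stats::sd(acc),
         accuracy_per_repeat = acc,
         per_class_rate = colMeans(per_class),
         n_components = if (use_pca) as.integer(round(mean(ncomp_used)))
                        else ncol(ft$features),
         classifier = classifier, k = k, folds = folds, repeats = repeats,
         seed = seed, pca = pca, standardize = standardize, ridge = ridge),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold x %d: %.2f%% (+/-%.2f), # = %d\n",
              x$classifier, x$folds, x$repeats, x$mean_accuracy,
              x$std_accuracy, x$n_components))
  invisible(x)
}

#' Split-environment (plasticity) evaluation
#'
#' Trains on one full table and evaluates on a held-out table — typically
#' samples of one species grown in a different environment — reporting
#' the overall and per-class success rates.  Standardization and PCA
#' (when enabled) are fitted on the training table only.
#'
#' @param train,test [feature_table()]s; every test species must occur in
#'   training.
#' @inheritParams stratified_cv
#' @return a list with `overall_rate` (percent), `per_class_rate`
#'   (percent per test species), `predicted`, and `n_components`.
#' @export
split_environment_eval <- function(train, test,
                                   classifier = c("knn", "lda"), k = 1L,
                                   pca = "off", standardize = TRUE,
                                   ridge = 1e-6) {
  stopifnot(inherits(train, "feature_table"),
            inherits(test, "feature_table"))
  classifier <- match.arg(classifier)
  missing_cls <- setdiff(unique(test$species), unique(train$species))
  if (length(missing_cls)) {
    stop("test species absent from training: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  xte <- test$features
  tr <- train
  if (standardize) {
    std <- fit_standardizer(tr$features)
    tr$features <- apply_standardizer(std, tr$features)
    xte <- apply_standardizer(std, xte)
  }
  ncomp <- ncol(tr$features)
  if (!identical(pca, "off") && !is.null(pca)) {
    fit <- fit_pca(tr$features, as.integer(pca))
    ncomp <- fit$n_components
    tr$features <- apply_pca(fit, tr$features)
    xte <- apply_pca(fit, xte)
  }
  pred <- predict_labels(tr, xte, classifier, k = k, ridge = ridge)
  per_class <- vapply(sort(unique(test$species)), function(cl) {
    100 * mean(pred[test$species == cl] == cl)
  }, numeric(1))
  list(overall_rate = 100 * mean(pred == test$species),
       per_class_rate = per_class, predicted = pred,
       n_components = ncomp)
}

#' Fuse texture features with manual stomatal traits
#'
#' Appends the three manually measured stomatal traits — density,
#' guard-cell length and stomatal-complex width — to each sample's
#' texture feature vector, increasing the feature length by exactly 3.
#' With a zero-column texture table this produces the trait-only
#' (quantitative) feature set.
#'
#' @param texture a [feature_table()].
#' @param traits a data frame with columns `sample_id`, `density`,
#'   `guard_cell_length`, `complex_width`.
#' @return the fused [feature_table()].
#' @export
fuse_features <- function(texture, traits) {
  stopifnot(inherits(texture, "feature_table"))
  need <- c("sample_id", "density", "guard_cell_length", "complex_width")
  if (!all(need %in% names(traits))) {
    stop("`traits` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pos <- match(texture$sample_id, traits$sample_id)
  if (anyNA(pos)) {
    stop("missing trait rows for samples: ",
         paste(texture$sample_id[is.na(pos)], collapse = ", "),
         call. = FALSE)
  }
  tr <- as.matrix(traits[pos, c("density", "guard_cell_length",
                                "complex_width")])
  storage.mode(tr) <- "double"
  feature_table(cbind(texture$features, unname(tr)), texture$species,
                texture$sample_id, texture$environment)
}
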