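# Small geometry + no supersampling keeps the statistical checks cheap.
fast_model <- function(...) {
  args <- list(...)
  defaults <- list(stomata_density = 20, length_mean = 10, length_sd = 1,
                   width_mean = 6, width_sd = 0.8, mosaic_cell_scale = 12,
                   spectral_exponent = 2, base_intensity = 150,
                   contrast = 60)
  do.call(species_model, utils::modifyList(defaults, args))
}

test_that("species_model and plasticity_shift validate their parameters", {
  expect_error(species_model(length_mean = 5, width_mean = 8),
               "length_mean >= width_mean")
  expect_error(species_model(stomata_density = -1), ">= 0")
  expect_error(plasticity_shift(density_factor = 0), "> 0")
  shifted <- apply_shift(fast_model(), plasticity_shift(0.5, 1.5, 1.3))
  expect_equal(shifted$stomata_density, 10)
  expect_equal(shifted$length_mean, 15)
  expect_equal(shifted$width_mean, 7.8)
  expect_equal(shifted$mosaic_cell_scale, 12)     # micro-texture untouched
  expect_equal(shifted$spectral_exponent, 2)
})

test_that("image generation is deterministic and respects the size contract", {
  m <- fast_model()
  g1 <- generate_image(m, c(64, 80), seed = 5, supersample = 1)
  g2 <- generate_image(m, c(64, 80), seed = 5, supersample = 1)
  expect_identical(g1$image, g2$image)
  expect_identical(g1$traits, g2$traits)
  g3 <- generate_image(m, c(64, 80), seed = 6, supersample = 1)
  expect_false(identical(g1$image, g3$image))
  expect_equal(dim(g1$image), c(64L, 80L))
  expect_true(min(g1$image) >= 0L && max(g1$image) <= 255L)
  expect_error(generate_image(m, c(32, 64), seed = 1), ">= 64")
})

test_that("zero stomatal density yields zero realized density", {
  g <- generate_image(fast_model(stomata_density = 0), c(64, 64),
                      seed = 3, supersample = 1)
  expect_equal(unname(g$traits["density"]), 0)
})

test_that("realized stomata counts are Poisson around the model density", {
  n_img <- 400
  counts <- vapply(seq_len(n_img), function(s) {
    generate_image(fast_model(stomata_density = 50, mosaic_cell_scale = 20),
                   c(64, 64), seed = 2000 + s, supersample = 1)$traits["density"]
  }, numeric(1))
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / n_img))
  lens <- vapply(seq_len(60), function(s) {
    generate_image(fast_model(length_mean = 10, length_sd = 1),
                   c(64, 64), seed = 3000 + s,
                   supersample = 1)$traits["guard_cell_length"]
  }, numeric(1))
  expect_lt(abs(mean(lens) - 10), 0.5)
})

test_that("datasets are labeled, sized and reproducible", {
  models <- list(one = fast_model(), two = fast_model(spectral_exponent = 3))
  ds <- generate_dataset(models, 4, c(64, 64), seed = 9, supersample = 1)
  expect_length(ds$images, 8L)
  expect_equal(table(ds$labels$species),
               table(rep(c("one", "two"), each = 4)), ignore_attr = TRUE)
  expect_equal(nrow(ds$traits), 8L)
  expect_identical(ds$labels$sample_id, ds$traits$sample_id)
  ds2 <- generate_dataset(models, 4, c(64, 64), seed = 9, supersample = 1)
  expect_identical(ds$images, ds2$images)
  single <- generate_dataset(list(fast_model()), 5, c(64, 64), seed = 1,
                             supersample = 1)
  expect_length(unique(single$labels$species), 1L)
})

test_that("plasticity pairs shift trait means by the stated factors only", {
  pair <- generate_plasticity_pair(
    fast_model(stomata_density = 40), plasticity_shift(0.5, 1.5, 1.3),
    n_env1 = 40, n_env2 = 40, size = c(64, 64), seed = 21,
    species = "tap", supersample = 1
  )
  expect_identical(unique(pair$env1$labels$species), "tap")
  expect_identical(unique(pair$env2$labels$species), "tap")
  expect_identical(unique(pair$env1$labels$environment), "gallery_forest")
  expect_identical(unique(pair$env2$labels$environment), "marsh_camp")
  t1 <- colMeans(pair$env1$traits[, -1])
  t2 <- colMeans(pair$env2$traits[, -1])
  # 40 images per environment: generous 3-sigma-ish Monte-Carlo bands
  expect_lt(abs(t2["density"] / t1["density"] - 0.5), 0.12)
  expect_lt(abs(t2["guard_cell_length"] / t1["guard_cell_length"] - 1.5),
            0.12)
  expect_lt(abs(t2["complex_width"] / t1["complex_width"] - 1.3), 0.12)
})

test_that("micro-texture parameters separate classes that traits cannot", {
  # two models differing only in spectral exponent: identical trait
  # distributions, distinguishable Fourier spectra
  models <- list(lowf = fast_model(spectral_exponent = 1.2),
                 highf = fast_model(spectral_exponent = 3.5))
  ds <- generate_dataset(models, 20, c(96, 96), seed = 31, supersample = 1)
  tr <- ds$traits
  for (col in c("density", "guard_cell_length", "complex_width")) {
    p <- t.test(tr[[col]][ds$labels$species == "lowf"],
                tr[[col]][ds$labels$species == "highf"])$p.value
    expect_gt(p, 0.01)
  }
  ft <- dataset_feature_table(ds, "fourier-circular")
  cv <- stratified_cv(ft, "knn", folds = 4, repeats = 3, seed = 5,
                      pca = 10)
  expect_gt(cv$mean_accuracy, 90)
})

test_that("identity shift makes split accuracy match joint within noise", {
  models <- example_species_models(3)
  base <- generate_dataset(models, 8, c(64, 64), seed = 41, supersample = 1)
  pair <- generate_plasticity_pair(models[[1]], plasticity_shift(1, 1, 1),
                                   n_env1 = 0, n_env2 = 6,
                                   size = c(64, 64), seed = 43,
                                   species = names(models)[1],
                                   supersample = 1)
  joint <- merge_datasets(base, pair$env2)
  ft_joint <- dataset_feature_table(joint, "fourier-circular")
  cv <- stratified_cv(ft_joint, "knn", folds = 6, repeats = 10, seed = 3,
                      pca = 8)
  ft_tr <- dataset_feature_table(base, "fourier-circular")
  ft_te <- dataset_feature_table(pair$env2, "fourier-circular")
  split <- split_environment_eval(ft_tr, ft_te, "knn", pca = 8)
  cls <- names(models)[1]
  # null shift: the two environments are draws from one model, so the
  # held-out rate should sit near the joint per-class rate (a lower bound
  # of 10 points guards the small-sample standard deviation)
  expect_lt(abs(split$overall_rate - cv$per_class_rate[[cls]]),
            3 * max(cv$std_accuracy, 10))
})
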