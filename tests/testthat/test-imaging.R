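test_that("gray_image validates its invariants", {
  expect_s3_class(gray_image(matrix(0:8, 3, 3)), "gray_image")
  expect_error(gray_image(matrix(0:3, 2, 2)), "3x3")
  expect_error(gray_image(matrix(-1, 3, 3)), "\\[0, 255\\]")
  expect_error(gray_image(matrix(256, 3, 3)), "\\[0, 255\\]")
  expect_error(gray_image(matrix(1.5, 3, 3)), "whole numbers")
})

test_that("load_grayscale converts RGB by BT.601 luma and passes gray through", {
  # pure red, green, blue, white pixels in a 3x3 RGB PNG
  rgb <- array(0, c(3, 3, 3))
  rgb[1, 1, ] <- c(1, 0, 0)
  rgb[1, 2, ] <- c(0, 1, 0)
  rgb[1, 3, ] <- c(0, 0, 1)
  rgb[2, 1, ] <- c(1, 1, 1)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgb, path)
  img <- load_grayscale(path)
  expect_identical(img[1, 1], 76L)            # round(0.299 * 255)
  expect_identical(img[1, 2], 150L)           # round(0.587 * 255)
  expect_identical(img[1, 3], 29L)            # round(0.114 * 255)
  expect_identical(img[2, 1], 255L)           # weights sum to 1
  expect_identical(img[3, 3], 0L)

  gray <- matrix(seq(0L, 248L, by = 8L), 4, 8) / 255
  gpath <- withr::local_tempfile(fileext = ".png")
  png::writePNG(gray, gpath)
  back <- load_grayscale(gpath)
  expect_identical(unclass(back)[, ], matrix(seq(0L, 248L, by = 8L), 4, 8))

  tpath <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(gray, tpath)
  expect_identical(unclass(load_grayscale(tpath))[, ],
                   matrix(seq(0L, 248L, by = 8L), 4, 8))
})

test_that("load_grayscale fails loudly on bad paths and formats", {
  expect_error(load_grayscale("/nonexistent/x.png"), "cannot read")
  bad <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", bad)
  expect_error(load_grayscale(bad), "unsupported image format")
})

test_that("enhance_contrast matches the percentile-stretch convention", {
  # constant image: degenerate stretch, unchanged with a warning
  const <- matrix(128L, 10, 10)
  expect_warning(out <- enhance_contrast(const), "degenerate")
  expect_identical(unclass(out)[, ], unclass(const))

  # 100 pixels 0..99 at 1% saturation: lo = 1, hi = 98
  img <- matrix(0:99, 10, 10)
  e <- enhance_contrast(img, 0.01)
  expect_identical(e[img == 1], 0L)
  expect_identical(e[img == 98], 255L)
  expect_identical(e[img == 0], 0L)           # clipped below lo
  expect_identical(e[img == 99], 255L)        # clipped above hi

  # >= 1% mass already at both extremes, rest linear: identity map
  vals <- c(0L, 0L, round(seq(1, 254, length.out = 96)), 255L, 255L)
  m <- matrix(as.integer(vals), 10, 10)
  expect_identical(unclass(enhance_contrast(m, 0.01))[, ], unclass(m)[, ])
})

test_that("enhance_contrast is monotone, idempotent within 1 level, and spans 0..255", {
  for (s in 1:5) {
    img <- random_gray(24, 17, seed = 100 + s)
    e1 <- enhance_contrast(img)
    # monotone: input ordering preserved
    o <- order(as.vector(img))
    expect_true(all(diff(as.vector(e1)[o]) >= 0))
    # histogram support includes both extremes
    expect_true(min(e1) == 0L && max(e1) == 255L)
    # idempotent up to rounding
    e2 <- enhance_contrast(e1)
    expect_lte(max(abs(unclass(e2) - unclass(e1))), 1L)
  }
})
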