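test_that("centered_spectrum places DC centrally and obeys Parseval", {
  # hand-evaluated 2x2 DFT of rows (0, 255): DC = 510 plus one bin of 510
  # on the horizontal-frequency axis -- checked on the unshifted grid to
  # keep the example at the minimum legal size for the shift logic
  m <- matrix(c(100L, 100L, 100L, 200L, 200L, 200L, 100L, 100L, 100L),
              3, 3)
  sp <- centered_spectrum(m)
  expect_equal(sp$center, c(2L, 2L))
  expect_equal(sp$magnitudes[2, 2], sum(m))
  expect_equal(sum(sp$magnitudes^2), 9 * sum(as.numeric(m)^2),
               tolerance = 1e-9)

  f22 <- stats::fft(matrix(c(0, 0, 255, 255), 2, 2))
  expect_equal(Mod(f22[1, 1]), 510)                 # DC
  expect_equal(Mod(f22[1, 2]), 510)                 # horizontal axis
  expect_equal(Mod(f22[2, 1]), 0)
  expect_equal(Mod(f22[2, 2]), 0)

  for (s in 1:5) {
    img <- random_gray(16 + s, 11 + 2 * s, seed = s)
    sp <- centered_spectrum(img)
    expect_true(all(sp$magnitudes >= 0))
    expect_equal(sum(sp$magnitudes^2),
                 prod(dim(img)) * sum(as.numeric(img)^2),
                 tolerance = 1e-6)
  }
})

test_that("circular descriptor: length formula, DC-only case, oracle match", {
  # G = floor(min(M, N)/2) - 1
  expect_length(circular_descriptor(random_gray(64, 64, 1)), 31L)
  expect_length(circular_descriptor(random_gray(20, 64, 2)), 9L)
  expect_error(circular_descriptor(random_gray(5, 64, 3)), "too small")

  # constant image: all spectral mass at the included center bin
  cd <- circular_descriptor(matrix(17L, 16, 12))
  expect_equal(cd, rep(16 * 12 * 17, 5))

  for (s in 1:8) {
    img <- random_gray(sample(8:32, 1), sample(8:32, 1), seed = 300 + s)
    sp <- centered_spectrum(img)
    G <- floor(min(dim(img)) / 2) - 1
    expect_equal(circular_descriptor(sp),
                 oracle_disk_sums(sp$magnitudes, sp$center, G),
                 tolerance = 1e-9)
  }
})

test_that("circular descriptor is non-decreasing", {
  for (s in 1:10) {
    cd <- circular_descriptor(random_gray(24, 36, seed = 400 + s))
    expect_true(all(diff(cd) >= 0))
  }
})

test_that("circular-angular sectors match the brute-force classification", {
  part <- ring_wedge_partition()
  for (s in 1:6) {
    img <- random_gray(64, 64, seed = 500 + s)
    sp <- centered_spectrum(img)
    expect_equal(circular_angular_descriptor(sp, part),
                 oracle_sector_sums(sp$magnitudes, sp$center,
                                    part$ring_radii, part$n_angles),
                 tolerance = 1e-9)
  }
  # rectangular case too
  img <- random_gray(80, 52, seed = 599)
  sp <- centered_spectrum(img)
  expect_equal(circular_angular_descriptor(sp, part),
               oracle_sector_sums(sp$magnitudes, sp$center,
                                  part$ring_radii, part$n_angles),
               tolerance = 1e-9)
})

test_that("circular-angular sectors: DC excluded, partition recomposes the annulus", {
  expect_equal(circular_angular_descriptor(matrix(9L, 64, 64)),
               rep(0, 64))
  for (s in 1:5) {
    img <- random_gray(64, 72, seed = 600 + s)
    sp <- centered_spectrum(img)
    ca <- circular_angular_descriptor(sp)
    d <- sqrt(outer((seq_len(64) - sp$center[1])^2,
                    (seq_len(72) - sp$center[2])^2, `+`))
    annulus_total <- sum(sp$magnitudes[d > 0 & d <= 24])
    expect_equal(sum(ca), annulus_total, tolerance = 1e-6 * annulus_total)
  }
})

test_that("rotating a square image by 90 degrees permutes wedges within rings", {
  img <- random_gray(65, 65, seed = 700)      # odd size: symmetric grid
  rot <- t(img)[65:1, ]                       # 90-degree rotation
  sp1 <- centered_spectrum(img)
  sp2 <- centered_spectrum(rot)
  expect_equal(circular_descriptor(sp1), circular_descriptor(sp2),
               tolerance = 1e-9)
  ca1 <- matrix(circular_angular_descriptor(sp1), nrow = 8, byrow = TRUE)
  ca2 <- matrix(circular_angular_descriptor(sp2), nrow = 8, byrow = TRUE)
  for (ring in 1:8) {
    expect_equal(sort(ca1[ring, ]), sort(ca2[ring, ]), tolerance = 1e-9)
  }
})

test_that("ring-wedge partition validates and bounds are enforced", {
  expect_error(ring_wedge_partition(c(3, 3, 6)), "strictly increasing")
  expect_error(ring_wedge_partition(c(-1, 5)), "strictly increasing|positive")
  expect_error(
    circular_angular_descriptor(centered_spectrum(random_gray(16, 16, 1))),
    "exceeds the spectrum"
  )
})

test_that("fourier_features concatenates circular then ring-wedge sectors", {
  img <- random_gray(64, 64, seed = 800)
  fc <- fourier_features(img, "circular")
  fca <- fourier_features(img, "circular-angular")
  expect_length(fc, 31L)
  expect_length(fca, 31L + 64L)
  expect_identical(fca[1:31], fc)
  expect_equal(fca[32:95], circular_angular_descriptor(img))
})
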