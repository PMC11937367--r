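test_that("stain separation inverts the forward optical-density model", {
  M <- default_stain_vectors()
  # pure white image: zero optical density, both channels ~ 0
  white <- stain_image(array(255, c(8, 8, 3)), pixel_size = 1)
  ch <- separate_stains(white)
  expect_lt(max(abs(ch[[1]])), 1e-2)
  expect_lt(max(abs(ch[[2]])), 1e-2)

  # single-stain image: the other channel stays near zero
  conc <- matrix(runif(64, 0.3, 0.8), 8, 8)
  px <- array(0, c(8, 8, 3))
  for (k in 1:3) px[, , k] <- round(255 * 10^(-conc * M[1, k]))
  ch1 <- separate_stains(stain_image(px, 1))
  expect_lt(max(ch1$novared), 0.01 * max(ch1$hematoxylin))

  # forward-mixed two-stain image: recovered concentrations within 2% RMS
  set.seed(6)
  c1 <- matrix(runif(400, 0.1, 0.9), 20, 20)
  c2 <- matrix(runif(400, 0.1, 0.9), 20, 20)
  px2 <- array(0, c(20, 20, 3))
  for (k in 1:3) px2[, , k] <- round(255 * 10^(-(c1 * M[1, k] + c2 * M[2, k])))
  ch2 <- separate_stains(stain_image(px2, 1))
  rms <- function(a, b) sqrt(mean((a - b)^2)) / mean(b)
  expect_lt(rms(ch2$hematoxylin, c1), 0.02)
  expect_lt(rms(ch2$novared, c2), 0.02)

  # unmixing then forward mixing reproduces the image within quantization
  recon <- array(0, c(20, 20, 3))
  for (k in 1:3)
    recon[, , k] <- 255 * 10^(-(ch2$hematoxylin * M[1, k] + ch2$novared * M[2, k]))
  expect_lt(max(abs(recon - px2)), 1.5)

  collinear <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_error(separate_stains(white, collinear), "collinear")
})

test_that("positive-mask thresholding handles fixed, degenerate and Otsu rules", {
  tissue <- binary_mask(matrix(TRUE, 10, 10), "tissue")
  const <- matrix(0.8, 10, 10)
  # fixed threshold below a constant channel: everything positive
  pm <- positive_mask(const, tissue, threshold = 0.5)
  expect_true(all(pm == tissue))
  # constant channel under Otsu: degenerate histogram, empty mask
  pm0 <- positive_mask(const, tissue, threshold = "otsu")
  expect_equal(sum(pm0), 0)
  expect_error(positive_mask(const, binary_mask(matrix(FALSE, 10, 10), "tissue")),
               "empty")

  # bimodal channel: Otsu lands between the planted levels and attains
  # the exhaustive between-class-variance maximum
  set.seed(12)
  vals <- matrix(c(rnorm(600, 0.15, 0.02), rnorm(400, 0.85, 0.03)), 25, 40)
  pm1 <- positive_mask(vals, binary_mask(matrix(TRUE, 25, 40), "tissue"))
  th <- attr(pm1, "threshold")
  expect_gt(th, 0.25); expect_lt(th, 0.75)
  expect_gte(otsu_bcv(as.vector(vals), th),
             0.999 * otsu_oracle_max(as.vector(vals)))
  expect_equal(sum(pm1), sum(vals > 0.5))
})

test_that("stained-area percentage follows its defining ratio", {
  total <- binary_mask(matrix(TRUE, 10, 10), "tissue")
  expect_equal(area_percent(total, total), 100)
  half <- binary_mask(matrix(rep(c(TRUE, FALSE), each = 50), 10, 10), "positive_stain")
  expect_equal(area_percent(half, total), 50)
  none <- binary_mask(matrix(FALSE, 10, 10), "positive_stain")
  expect_equal(area_percent(none, total), 0)
  expect_error(area_percent(half, none), "empty")
  # positive outside total is clipped by the intersection
  outside <- binary_mask(matrix(TRUE, 10, 10), "positive_stain")
  partial_total <- binary_mask(matrix(rep(c(TRUE, FALSE), 50), 10, 10), "tissue")
  expect_equal(area_percent(outside, partial_total), 100)
})

test_that("reciprocal mean intensity follows the 255-minus-mean formula", {
  pos <- binary_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2), "positive_stain")
  img <- matrix(c(100, 200, 7, 9), 2, 2)
  expect_equal(mean_reciprocal_intensity(img, pos), 255 - 150)
  # constant region c gives exactly 255 - c for every 8-bit level
  for (c in c(0, 1, 127, 254, 255)) {
    expect_equal(mean_reciprocal_intensity(matrix(c, 2, 2),
                                           binary_mask(matrix(TRUE, 2, 2), "positive_stain")),
                 255 - c)
  }
  empty <- binary_mask(matrix(FALSE, 2, 2), "positive_stain")
  expect_warning(v <- mean_reciprocal_intensity(img, empty), "undefined")
  expect_true(is.na(v))
})

test_that("the stained-slide generator plants a recoverable positive fraction", {
  g <- generate_ihc_image(histology_fixture_config(positive_fraction = 0.3, seed = 2))
  expect_equal(g$truth$planted_positive_fraction, 0.3, tolerance = 1e-4)
  q <- ihc_quantify(g$image)
  expect_equal(q$area_percent, 30, tolerance = 2)     # percentage points
  # zero planted fraction: nothing positive downstream
  g0 <- generate_ihc_image(histology_fixture_config(positive_fraction = 0, seed = 3))
  q0 <- ihc_quantify(g0$image, threshold = 0.5)
  expect_equal(q0$area_percent, 0)
  # determinism
  g2 <- generate_ihc_image(histology_fixture_config(positive_fraction = 0.3, seed = 2))
  expect_identical(g$image, g2$image)
  expect_error(generate_ihc_image(histology_fixture_config(positive_fraction = 1.3)),
               "\\[0, 1\\]")
})

test_that("stain images survive a TIFF round trip", {
  g <- generate_ihc_image(histology_fixture_config(image_shape = c(32L, 32L), seed = 4))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stain_image(g$image, path)
  back <- read_stain_image(path, pixel_size = g$image$pixel_size)
  expect_equal(back$pixels, g$image$pixels)
})
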