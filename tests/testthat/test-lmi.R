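test_that("band masks give constant chords equal to the band width", {
  g <- generate_alveolar_mask(histology_fixture_config(airspace_mode = "band",
                                                       band_width = 40, seed = 1))
  expect_equal(g$truth$planted_mean_chord, 40)
  r <- lmi(g$mask, pixel_size = 1)
  expect_equal(r$mean_chord, 40, tolerance = 1 / 40)  # +- 1 px
  expect_true(all(r$chords == 40))

  # two equal-coverage bands of widths 30 and 50: mean chord 40
  m <- matrix(FALSE, 60, 200)
  m[, 21:50] <- TRUE    # 30 px band
  m[, 121:170] <- TRUE  # 50 px band
  r2 <- lmi(binary_mask(m, "airspace"), pixel_size = 1, orientation = "horizontal")
  expect_equal(r2$mean_chord, 40)
})

test_that("disk masks converge to the analytic pi*d/4 mean chord", {
  g <- generate_alveolar_mask(histology_fixture_config(
    airspace_mode = "disks", disk_diameter = 80, n_disks = 1,
    image_shape = c(200L, 200L), seed = 4))
  expect_equal(g$truth$planted_mean_chord, pi * 80 / 4)
  r <- lmi(g$mask, pixel_size = 1, line_spacing = 1)
  expect_equal(r$mean_chord, pi * 80 / 4, tolerance = 0.05)

  # airspace area fraction matches the geometric area within 1%
  geo <- g$truth$planted_positive_fraction
  expect_equal(sum(g$mask) / length(g$mask), geo, tolerance = 0.01)

  # several disks, coarser resolution via pixel_size covariance
  g3 <- generate_alveolar_mask(histology_fixture_config(
    airspace_mode = "disks", disk_diameter = 60, n_disks = 4,
    image_shape = c(300L, 300L), seed = 11))
  r3 <- lmi(g3$mask, pixel_size = 1)
  expect_equal(r3$mean_chord, pi * 60 / 4, tolerance = 0.05)
})

test_that("LMI is covariant with pixel size and excludes border chords", {
  g <- generate_alveolar_mask(histology_fixture_config(
    airspace_mode = "disks", disk_diameter = 80, n_disks = 1,
    image_shape = c(160L, 160L), seed = 6))
  r1 <- lmi(g$mask, pixel_size = 1)
  r2 <- lmi(g$mask, pixel_size = 2.5)
  expect_equal(r2$mean_chord, 2.5 * r1$mean_chord)

  # an air band touching the left border yields no valid horizontal chord
  m <- matrix(FALSE, 20, 40); m[, 1:10] <- TRUE
  expect_warning(r <- lmi(binary_mask(m, "airspace"), 1, orientation = "horizontal"),
                 "no valid")
  expect_true(is.na(r$mean_chord))
  expect_error(lmi(binary_mask(matrix(TRUE, 5, 5), "airspace"), 1), "both airspace and tissue")
})

test_that("disk placement refuses geometry that cannot fit", {
  expect_error(generate_alveolar_mask(histology_fixture_config(
    airspace_mode = "disks", disk_diameter = 300, image_shape = c(100L, 100L))),
    "does not fit")
  expect_error(generate_alveolar_mask(histology_fixture_config(
    airspace_mode = "band", band_width = 500, image_shape = c(100L, 100L))),
    "does not fit")
  expect_error(generate_alveolar_mask(histology_fixture_config(
    airspace_mode = "disks", disk_diameter = 60, n_disks = 50,
    image_shape = c(150L, 150L))), "non-overlapping")
})

test_that("per-animal aggregation averages fields and flags odd counts", {
  expect_equal(lmi_per_animal(c(60, 60, 60, 60, 60))$overall_mean, 60)
  expect_equal(lmi_per_animal(c(50, 60, 70, 60, 60))$overall_mean, 60)
  expect_warning(a <- lmi_per_animal(c(55, 65)), "expected 5 fields")
  expect_equal(a$overall_mean, 60)
  expect_error(lmi_per_animal(numeric(0)), "at least one")
  set.seed(2)
  x <- runif(5, 40, 90)
  expect_equal(lmi_per_animal(x)$overall_mean, mean(x))
})

test_that("paired LMI comparison matches the closed-form paired t-test", {
  set.seed(88)
  ctl <- rnorm(6, 60, 8)
  ela <- ctl + 20 + rnorm(6, 0, 0.5)
  r <- compare_lmi_paired(list(control = ctl, elastase = ela), control = "control")
  expect_equal(r$estimate, mean(ela - ctl), tolerance = 1e-8)
  expect_lt(r$p_adjusted, 0.001)
  # closed-form paired t oracle
  d <- ela - ctl
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * stats::pt(-abs(t_stat), df = length(d) - 1)
  expect_equal(r$p_adjusted, p_oracle, tolerance = 0.05 * p_oracle)

  # identical pairs: zero difference, p = 1
  r0 <- compare_lmi_paired(list(control = ctl, mock = ctl), "control")
  expect_equal(r0$estimate, 0)
  expect_equal(r0$p_adjusted, 1)

  # three conditions route through paired Dunnett
  trt <- ctl - 15 + rnorm(6, 0, 0.5)
  r3 <- compare_lmi_paired(list(control = ctl, elastase = ela, treated = trt),
                           control = "control")
  expect_equal(nrow(r3), 2)
  expect_true(all(r3$p_adjusted < 0.01))
  expect_error(compare_lmi_paired(list(control = ctl, x = ela[-1]), "control"),
               "same animals")
})

test_that("masks survive a PNG round trip", {
  g <- generate_alveolar_mask(histology_fixture_config(
    airspace_mode = "band", band_width = 30, image_shape = c(64L, 64L), seed = 9))
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(g$mask, path)
  back <- read_mask(path)
  expect_equal(unclass(back)[, ], unclass(g$mask)[, ], ignore_attr = TRUE)
})
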