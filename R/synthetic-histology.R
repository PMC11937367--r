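#' Configuration for synthetic histology fixtures
#'
#' Parameterizes two image generators: a stained-slide emulator
#' (chromogen-positive pixels forward-mixed with a counterstain over a
#' tissue region on a white slide background) and a structural
#' airspace-mask emulator for stereology (a single air band of known
#' width, or non-overlapping air disks of known diameter, for which the
#' mean chord length over uniform parallel secants is known in closed
#' form: the band width, and pi*d/4 for disks).
#'
#' @param image_shape c(height, width) in pixels.
#' @param pixel_size um/pixel.
#' @param positive_fraction fraction of tissue pixels carrying the
#'   positive chromogen (in `[0,1]`).
#' @param positive_intensity_mean,background_intensity_mean target 8-bit
#'   intensity levels (0-255) of positive and background tissue pixels.
#' @param airspace_mode "band" or "disks".
#' @param band_width air band width (um), band mode.
#' @param disk_diameter air disk diameter (um), disks mode.
#' @param n_disks number of disks, disks mode.
#' @param seed integer seed.
#' @return object of class `histology_fixture_config`.
#' @export
histology_fixture_config <- function(image_shape = c(256L, 256L),
                                     pixel_size = 1,
                                     positive_fraction = 0.3,
                                     positive_intensity_mean = 100,
                                     background_intensity_mean = 210,
                                     airspace_mode = c("band", "disks"),
                                     band_width = 40,
                                     disk_diameter = 80,
                                     n_disks = 1L,
                                     seed = 1L) {
  airspace_mode <- match.arg(airspace_mode)
  if (length(image_shape) != 2L || any(image_shape < 8L))
    stop_input("image_shape must be c(height, width), each >= 8")
  if (pixel_size <= 0) stop_input("pixel_size must be > 0")
  positive_fraction <- assert_prob(positive_fraction, "positive_fraction")
  if (positive_intensity_mean < 0 || positive_intensity_mean > 255 ||
      background_intensity_mean < 0 || background_intensity_mean > 255)
    stop_input("intensity means must lie in [0, 255]")
  structure(list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    positive_fraction = positive_fraction,
    positive_intensity_mean = positive_intensity_mean,
    background_intensity_mean = background_intensity_mean,
    airspace_mode = airspace_mode, band_width = band_width,
    disk_diameter = disk_diameter, n_disks = assert_count(n_disks, "n_disks"),
    seed = as.integer(seed)
  ), class = "histology_fixture_config")
}

#' Generate a synthetic stained-slide image with planted positive fraction
#'
#' The field is a tissue rectangle surrounded by a white (slide
#' background) margin. A planted fraction of tissue pixels carries the
#' red chromogen at an absorbance giving the configured positive
#' intensity; all tissue pixels carry a light counterstain. The RGB image
#' is synthesized by forward optical-density mixing with the package's
#' default stain vectors, so stain separation inverts a known model. The
#' planted positive fraction is bookkept exactly (count of planted
#' pixels over tissue pixels).
#'
#' @param config a [histology_fixture_config()].
#' @return list with `image` (a [stain_image()]) and `truth` (a
#'   `fixture_truth` with `planted_positive_fraction`).
#' @export
generate_ihc_image <- function(config) {
  stopifnot(inherits(config, "histology_fixture_config"))
  set.seed(substream_seed(config$seed, "ihc"))
  h <- config$image_shape[1]; w <- config$image_shape[2]
  margin <- max(2L, round(0.05 * min(h, w)))
  tissue <- matrix(FALSE, h, w)
  tissue[(margin + 1):(h - margin), (margin + 1):(w - margin)] <- TRUE
  n_tissue <- sum(tissue)
  n_pos <- round(config$positive_fraction * n_tissue)
  pos_idx <- sample(which(tissue), n_pos)
  positive <- matrix(FALSE, h, w); positive[pos_idx] <- TRUE

  # absorbances giving the target 8-bit levels at unit stain vectors,
  # with mild lognormal concentration jitter
  a_pos <- -log10(max(config$positive_intensity_mean, 1) / 255)
  a_bg  <- -log10(max(config$background_intensity_mean, 1) / 255)
  c_hem <- matrix(0, h, w); c_red <- matrix(0, h, w)
  c_hem[tissue] <- a_bg * exp(rnorm(n_tissue, 0, 0.05))
  c_red[positive] <- a_pos * exp(rnorm(n_pos, 0, 0.05))

  M <- default_stain_vectors()
  px <- array(255, dim = c(h, w, 3))
  for (ch in 1:3) {
    od <- c_hem * M[1, ch] + c_red * M[2, ch]
    px[, , ch] <- round(255 * 10^(-od))
  }
  image <- stain_image(px, pixel_size = config$pixel_size,
                       field_id = sprintf("synthetic_ihc_seed%d", config$seed))
  truth <- structure(list(
    expected_candidate_set = character(0), expected_stage_counts = NULL,
    planted_effect_ratio = NA_real_,
    planted_positive_fraction = n_pos / n_tissue,
    planted_mean_chord = NA_real_
  ), class = "fixture_truth")
  list(image = image, truth = truth)
}

#' Generate a synthetic alveolar airspace mask with known mean chord
#'
#' Band mode places a single full-height vertical air band of the
#' configured width (every horizontal chord equals the band width).
#' Disks mode places non-overlapping air disks of the configured
#' diameter by rejection sampling (failing loudly after a bounded number
#' of attempts rather than overlapping silently); the mean chord of a
#' disk over uniform parallel secants is pi*d/4. The planted mean chord
#' and the geometric airspace area fraction are recorded as truth.
#'
#' @param config a [histology_fixture_config()] with `airspace_mode` set.
#' @return list with `mask` (an airspace [binary_mask()]) and `truth`.
#' @export
generate_alveolar_mask <- function(config) {
  stopifnot(inherits(config, "histology_fixture_config"))
  set.seed(substream_seed(config$seed, "mask"))
  h <- config$image_shape[1]; w <- config$image_shape[2]
  ps <- config$pixel_size
  m <- matrix(FALSE, h, w)

  if (config$airspace_mode == "band") {
    bw_px <- round(config$band_width / ps)
    if (bw_px < 1L || bw_px > w - 4L)
      stop_input("band width %g um does not fit the %d px wide field", config$band_width, w)
    start <- floor((w - bw_px) / 2) + 1L
    m[, start:(start + bw_px - 1L)] <- TRUE
    planted_chord <- bw_px * ps
    area_frac <- bw_px / w
  } else {
    r_px <- config$disk_diameter / (2 * ps)
    if (2 * r_px > min(h, w) - 4)
      stop_input("disk diameter %g um does not fit the field", config$disk_diameter)
    centers <- matrix(numeric(0), ncol = 2)
    attempts <- 0L
    while (nrow(centers) < config$n_disks) {
      attempts <- attempts + 1L
      if (attempts > 10000L)
        stop_input("could not place %d non-overlapping disks after 10000 attempts",
                   config$n_disks)
      cand <- c(runif(1, r_px + 2, h - r_px - 1),
                runif(1, r_px + 2, w - r_px - 1))
      if (nrow(centers)) {
        d2 <- (centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2
        if (any(d2 < (2 * r_px + 2)^2)) next
      }
      centers <- rbind(centers, cand)
    }
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (i in seq_len(nrow(centers))) {
      m <- m | ((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= r_px^2)
    }
    planted_chord <- pi * config$disk_diameter / 4
    area_frac <- config$n_disks * pi * r_px^2 / (h * w)
  }

  truth <- structure(list(
    expected_candidate_set = character(0), expected_stage_counts = NULL,
    planted_effect_ratio = NA_real_, planted_positive_fraction = area_frac,
    planted_mean_chord = planted_chord
  ), class = "fixture_truth")
  list(mask = binary_mask(m, "airspace"), truth = truth)
}
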