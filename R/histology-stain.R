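#' Default stain optical-density basis
#'
#' Two unit absorbance vectors (rows): hematoxylin counterstain and a red
#' peroxidase chromogen (NovaRed-like; absorbs green/blue). Values follow
#' the widely used published RGB absorbance coefficients for hematoxylin
#' and red AEC-class chromogens, normalized to unit length.
#'
#' @return 2x3 matrix with rownames `hematoxylin`, `novared`.
#' @export
default_stain_vectors <- function() {
  m <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
             novared     = c(0.274, 0.680, 0.680))
  m / sqrt(rowSums(m^2))
}

#' Construct a stain image
#'
#' @param pixels H x W x 3 numeric array of 8-bit intensities (0-255).
#' @param pixel_size physical pixel size in um/pixel (> 0).
#' @param field_id optional field label.
#' @return object of class `stain_image`.
#' @export
stain_image <- function(pixels, pixel_size, field_id = "field1") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_input("pixels must be an H x W x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_input("channel values must lie in [0, 255]")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_input("pixel_size must be a single positive number (um/pixel)")
  structure(list(pixels = pixels, pixel_size = pixel_size, field_id = field_id),
            class = "stain_image")
}

#' Construct a binary mask
#'
#' @param m logical matrix.
#' @param semantics one of "positive_stain", "tissue", "airspace".
#' @return object of class `binary_mask` (logical matrix with a
#'   `semantics` attribute).
#' @export
binary_mask <- function(m, semantics = c("positive_stain", "tissue", "airspace")) {
  semantics <- match.arg(semantics)
  if (!is.matrix(m)) stop_input("mask must be a matrix")
  storage.mode(m) <- "logical"
  structure(m, semantics = semantics, class = c("binary_mask", "matrix", "array"))
}

# optical density of 8-bit intensities; 0 is clamped to 1 before the log
od_transform <- function(I) -log10(pmax(I, 1) / 255)

#' Separate two stains by optical-density unmixing
#'
#' Applies the Beer-Lambert optical-density transform per channel, then
#' least-squares unmixing onto the two stain absorbance vectors, clamping
#' concentrations at zero. With the package's forward stain-mixing model
#' this inverts synthesis exactly up to 8-bit quantization.
#'
#' @param image a [stain_image()].
#' @param stain_vectors 2x3 matrix of linearly independent unit absorbance
#'   vectors (rows); default [default_stain_vectors()].
#' @return list of two H x W concentration matrices (named after the
#'   stain vector rows) with the stain matrix attached as attribute
#'   `"stain_vectors"`.
#' @export
separate_stains <- function(image, stain_vectors = default_stain_vectors()) {
  stopifnot(inherits(image, "stain_image"))
  M <- as.matrix(stain_vectors)
  if (!all(dim(M) == c(2L, 3L))) stop_input("stain_vectors must be 2 x 3")
  if (abs(det(M %*% t(M))) < 1e-8)
    stop_input("stain vectors are collinear; cannot unmix")
  dims <- dim(image$pixels)
  od <- matrix(od_transform(as.vector(image$pixels)), ncol = 3L)  # n x 3
  P <- solve(M %*% t(M), M)              # 2 x 3 pseudoinverse rows
  conc <- od %*% t(P)                    # n x 2
  conc[conc < 0] <- 0
  out <- list(matrix(conc[, 1], dims[1], dims[2]),
              matrix(conc[, 2], dims[1], dims[2]))
  names(out) <- rownames(M) %||% c("stain1", "stain2")
  attr(out, "stain_vectors") <- M
  out
}

#' Tissue mask by white-background removal
#'
#' Pixels whose mean channel luminance is below `cutoff` of the 8-bit
#' maximum are called tissue; near-white slide background is excluded. An
#' optional exclusion mask (TRUE = exclude) removes manually annotated
#' regions such as airway walls and vessels.
#'
#' @param image a [stain_image()].
#' @param cutoff luminance fraction of 255 regarded as background
#'   (default 0.95).
#' @param exclusion optional logical matrix of pixels to exclude.
#' @return a tissue [binary_mask()].
#' @export
tissue_mask <- function(image, cutoff = 0.95, exclusion = NULL) {
  stopifnot(inherits(image, "stain_image"))
  lum <- (image$pixels[, , 1] + image$pixels[, , 2] + image$pixels[, , 3]) / 3
  m <- lum < cutoff * 255
  if (!is.null(exclusion)) {
    if (!all(dim(exclusion) == dim(m))) stop_input("exclusion mask shape mismatch")
    m <- m & !exclusion
  }
  binary_mask(m, "tissue")
}

#' Threshold a concentration channel into a positive-stain mask
#'
#' Pixels inside the tissue mask whose stain concentration exceeds the
#' threshold. `threshold = "otsu"` computes Otsu's threshold from the
#' within-tissue concentration histogram only; a numeric threshold is
#' applied as given. A degenerate (constant) within-tissue histogram
#' yields an empty positive mask.
#'
#' @param channel concentration matrix from [separate_stains()].
#' @param tissue a tissue [binary_mask()].
#' @param threshold "otsu" or a fixed numeric concentration cutoff.
#' @return a positive-stain [binary_mask()] with the threshold used
#'   attached as attribute `"threshold"`.
#' @export
positive_mask <- function(channel, tissue, threshold = "otsu") {
  if (!all(dim(channel) == dim(tissue))) stop_input("channel/tissue shape mismatch")
  if (!any(tissue)) stop_input("tissue mask is empty")
  vals <- channel[tissue]
  if (identical(threshold, "otsu")) {
    rng <- range(vals)
    if (diff(rng) < 1e-12) {
      th <- Inf  # constant histogram: nothing distinguishably positive
    } else {
      th <- EBImage::otsu(matrix(vals, ncol = 1L), range = rng, levels = 256L)
    }
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    th <- threshold
  } else stop_input("threshold must be \"otsu\" or a single number")
  m <- binary_mask(tissue & channel > th, "positive_stain")
  attr(m, "threshold") <- th
  m
}

#' Positive-area percentage (stained-area formula)
#'
#' `Area(%) = Area(positive) / Area(total) * 100`, with the positive mask
#' first intersected with the total mask.
#'
#' @param positive positive-stain [binary_mask()].
#' @param total total-area (tissue) [binary_mask()].
#' @return percentage in `[0, 100]`.
#' @export
area_percent <- function(positive, total) {
  if (!all(dim(positive) == dim(total))) stop_input("mask shape mismatch")
  n_total <- sum(total)
  if (n_total == 0) stop_input("total mask is empty")
  100 * sum(positive & total) / n_total
}

#' Reciprocal mean intensity of positive pixels
#'
#' `255 - mean(intensity over positive pixels)` on the 8-bit scale where
#' 0 is the darkest shade and 255 the lightest; the reciprocal value
#' therefore grows with staining strength. An empty positive mask yields
#' `NA` with a warning rather than an error.
#'
#' @param channel 8-bit intensity matrix (0-255) of the separated stain
#'   image.
#' @param positive positive-stain [binary_mask()].
#' @return value in `[0, 255]`, or `NA_real_` if no positive pixels.
#' @export
mean_reciprocal_intensity <- function(channel, positive) {
  if (!all(dim(channel) == dim(positive))) stop_input("shape mismatch")
  if (!any(positive)) {
    warning("no positive pixels; reciprocal intensity undefined")
    return(NA_real_)
  }
  255 - mean(channel[positive])
}

# 8-bit reconstruction of a single separated stain at unit absorbance:
# the gray value the pixel would have if only this stain were present
separated_intensity8 <- function(concentration) {
  round(255 * 10^(-concentration))
}

#' Full immunohistochemistry quantification of one field
#'
#' Convenience pipeline: stain separation, tissue masking, positive-pixel
#' thresholding, positive-area percentage and reciprocal mean intensity of
#' the chromogen channel.
#'
#' @param image a [stain_image()].
#' @param stain_vectors stain basis; default [default_stain_vectors()].
#' @param stain which separated channel is the chromogen (default 2).
#' @param threshold passed to [positive_mask()].
#' @param background_cutoff passed to [tissue_mask()].
#' @param exclusion optional exclusion mask, see [tissue_mask()].
#' @return object of class `ihc_quant`: list with `area_percent`,
#'   `mean_reciprocal_intensity`, `n_positive_pixels`, `n_tissue_pixels`,
#'   `threshold`, `field_id`.
#' @export
ihc_quantify <- function(image, stain_vectors = default_stain_vectors(),
                         stain = 2L, threshold = "otsu",
                         background_cutoff = 0.95, exclusion = NULL) {
  channels <- separate_stains(image, stain_vectors)
  tm <- tissue_mask(image, cutoff = background_cutoff, exclusion = exclusion)
  pm <- positive_mask(channels[[stain]], tm, threshold = threshold)
  mri <- if (any(pm)) {
    mean_reciprocal_intensity(separated_intensity8(channels[[stain]]), pm)
  } else NA_real_
  structure(list(
    area_percent = area_percent(pm, tm),
    mean_reciprocal_intensity = mri,
    n_positive_pixels = sum(pm),
    n_tissue_pixels = sum(tm),
    threshold = attr(pm, "threshold"),
    field_id = image$field_id
  ), class = "ihc_quant")
}

#' @export
print.ihc_quant <- function(x, ...) {
  cat(sprintf("IHC quantification [%s]\n", x$field_id))
  cat(sprintf("  positive area            : %.2f%%\n", x$area_percent))
  cat(sprintf("  reciprocal mean intensity: %s\n",
              ifelse(is.na(x$mean_reciprocal_intensity), "NA",
                     sprintf("%.1f", x$mean_reciprocal_intensity))))
  cat(sprintf("  positive / tissue pixels : %d / %d\n",
              x$n_positive_pixels, x$n_tissue_pixels))
  invisible(x)
}

#' Read / write stain images as 8-bit RGB TIFF
#' @param path file path.
#' @param pixel_size um/pixel to attach on read.
#' @param field_id field label.
#' @return a [stain_image()].
#' @export
read_stain_image <- function(path, pixel_size, field_id = basename(path)) {
  arr <- tiff::readTIFF(path)
  stain_image(round(arr * 255), pixel_size = pixel_size, field_id = field_id)
}

#' @rdname read_stain_image
#' @param image a [stain_image()] to write.
#' @export
write_stain_image <- function(image, path) {
  tiff::writeTIFF(image$pixels / 255, path, bits.per.sample = 8L)
  invisible(path)
}
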