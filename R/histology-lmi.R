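#' Mean linear intercept (LMI) of one field
#'
#' Stereological estimate of the average free-airspace distance: parallel
#' test lines are laid across the binary airspace mask at the given
#' spacing; every maximal run of airspace pixels along a line is one
#' chord; chords touching the image border are excluded (their true
#' length is unknown); the field LMI is the mean chord length in um.
#' Both horizontal and vertical line families are measured and pooled by
#' default.
#'
#' @param airspace [binary_mask()] with TRUE = airspace.
#' @param pixel_size um/pixel.
#' @param line_spacing spacing between test lines in um; default one line
#'   per pixel row/column.
#' @param orientation "both" (default), "horizontal" or "vertical".
#' @return object of class `lmi_result`: list with `chords` (um),
#'   `mean_chord` (um; `NA` with a warning when no valid chord exists),
#'   `n_chords`, `n_lines`, `line_spacing`, `orientation`, `pixel_size`.
#' @export
lmi <- function(airspace, pixel_size, line_spacing = NULL,
                orientation = c("both", "horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(airspace)) stop_input("airspace mask must be a matrix")
  if (pixel_size <= 0) stop_input("pixel_size must be > 0")
  if (all(airspace) || !any(airspace))
    stop_input("mask must contain both airspace and tissue")
  step <- if (is.null(line_spacing)) 1L else max(1L, round(line_spacing / pixel_size))

  runs_on_line <- function(v) {
    r <- rle(v)
    if (!any(r$values)) return(integer(0))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & starts > 1L & ends < length(v)  # drop border-touching
    r$lengths[keep]
  }

  chords <- integer(0); n_lines <- 0L
  if (orientation %in% c("both", "horizontal")) {
    rows <- seq(1L, nrow(airspace), by = step)
    n_lines <- n_lines + length(rows)
    for (i in rows) chords <- c(chords, runs_on_line(airspace[i, ]))
  }
  if (orientation %in% c("both", "vertical")) {
    cols <- seq(1L, ncol(airspace), by = step)
    n_lines <- n_lines + length(cols)
    for (j in cols) chords <- c(chords, runs_on_line(airspace[, j]))
  }

  chords_um <- chords * pixel_size
  mean_chord <- if (length(chords_um)) mean(chords_um) else {
    warning("no valid (non-border) airspace chords on any test line")
    NA_real_
  }
  structure(list(chords = chords_um, mean_chord = mean_chord,
                 n_chords = length(chords_um), n_lines = n_lines,
                 line_spacing = step * pixel_size, orientation = orientation,
                 pixel_size = pixel_size),
            class = "lmi_result")
}

#' @export
print.lmi_result <- function(x, ...) {
  cat(sprintf("LMI: %s um (%d chords on %d %s lines, spacing %.3g um)\n",
              ifelse(is.na(x$mean_chord), "NA", sprintf("%.2f", x$mean_chord)),
              x$n_chords, x$n_lines, x$orientation, x$line_spacing))
  invisible(x)
}

#' Per-animal LMI across fields
#'
#' Unweighted mean of the per-field mean chord lengths; the reference
#' protocol scores 5 fields per animal, and a deviation from 5 fields is
#' flagged with a warning but not an error.
#'
#' @param fields list of `lmi_result` objects, or numeric vector of
#'   per-field mean chords (um).
#' @return list with `overall_mean` (um), `per_field_mean`, `n_fields`.
#' @export
lmi_per_animal <- function(fields) {
  means <- if (is.numeric(fields)) fields else
    vapply(fields, function(f) f$mean_chord, numeric(1))
  if (!length(means)) stop_input("at least one field is required")
  if (length(means) != 5L)
    warning(sprintf("expected 5 fields per animal, got %d", length(means)))
  list(overall_mean = mean(means), per_field_mean = means,
       n_fields = length(means))
}

#' Paired comparison of per-animal LMI between conditions
#'
#' Each animal serves as its own control (slices from the same animal are
#' matched across conditions), removing between-animal inflation
#' variability. Two conditions are compared with a paired t-test; more
#' than two with a paired one-way ANOVA plus Dunnett many-to-one
#' contrasts against the control condition.
#'
#' @param lmi_by_condition named list of per-animal LMI vectors (um), in
#'   shared animal order.
#' @param control name of the control condition.
#' @return a `comparison_result` (see [anova_dunnett()]); for the
#'   two-condition case a one-row data.frame with the paired-t result.
#' @export
compare_lmi_paired <- function(lmi_by_condition, control) {
  if (!is.list(lmi_by_condition) || length(lmi_by_condition) < 2L)
    stop_input("need >= 2 conditions")
  if (!control %in% names(lmi_by_condition))
    stop_input("control condition '%s' not present", control)
  lens <- lengths(lmi_by_condition)
  if (length(unique(lens)) != 1L)
    stop_input("paired design requires the same animals in every condition")
  if (length(lmi_by_condition) == 2L) {
    other <- setdiff(names(lmi_by_condition), control)
    x <- lmi_by_condition[[other]]; y <- lmi_by_condition[[control]]
    diffs <- x - y
    if (all(diffs == 0)) {
      out <- data.frame(comparison = paste(other, "-", control),
                        estimate = 0, statistic = 0, p_adjusted = 1,
                        n = length(x), stringsAsFactors = FALSE)
    } else {
      ht <- t.test(x, y, paired = TRUE)
      out <- data.frame(comparison = paste(other, "-", control),
                        estimate = unname(ht$estimate),
                        statistic = unname(ht$statistic),
                        p_adjusted = ht$p.value,
                        n = length(x), stringsAsFactors = FALSE)
    }
    structure(out, omnibus_p = out$p_adjusted, method = "paired t-test",
              class = c("comparison_result", "data.frame"))
  } else {
    anova_dunnett(lmi_by_condition, control = control, paired = TRUE)
  }
}

#' Read / write binary masks as 8-bit PNG
#' @param path file path.
#' @param semantics mask semantics, see [binary_mask()].
#' @return a [binary_mask()].
#' @export
read_mask <- function(path, semantics = "airspace") {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  binary_mask(m > 0.5, semantics)
}

#' @rdname read_mask
#' @param mask a [binary_mask()] to write.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
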