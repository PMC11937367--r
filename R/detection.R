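#' Construct a protein detection table
#'
#' A detection table holds one record per (protein, fraction, replicate)
#' from a paired secretome experiment: the extracellular-vesicle (EV)
#' fraction and the soluble-factor (SF) fraction of conditioned medium,
#' each measured in R biological replicates (four in the reference design).
#'
#' @param df data.frame with columns `protein_id`, `gene_symbol`,
#'   `fraction` (values "EV" or "SF"), `replicate` (integer >= 1) and
#'   `detected` (logical), optionally `intensity`.
#' @return a `detection_table` (validated data.frame).
#' @export
detection_table <- function(df) {
  required <- c("protein_id", "gene_symbol", "fraction", "replicate", "detected")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_input("detection table lacks column(s): %s", paste(missing, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$protein_id <- as.character(df$protein_id)
  df$gene_symbol <- normalize_symbols(df$gene_symbol)
  df$fraction <- as.character(df$fraction)
  df$replicate <- as.integer(df$replicate)
  df$detected <- as.logical(df$detected)
  if (nrow(df)) {
    bad <- setdiff(unique(df$fraction), c("EV", "SF"))
    if (length(bad))
      stop_input("unknown fraction label(s): %s", paste(bad, collapse = ", "))
    if (any(!nzchar(df$gene_symbol)))
      stop_input("empty gene_symbol in detection table")
    if (any(is.na(df$replicate)) || any(df$replicate < 1L))
      stop_input("replicate indices must be integers >= 1")
    key <- paste(df$protein_id, df$fraction, df$replicate, sep = "\r")
    if (anyDuplicated(key))
      stop_input("duplicate (protein_id, fraction, replicate) records")
  }
  class(df) <- c("detection_table", "data.frame")
  df
}

#' Read a detection table from TSV/CSV
#'
#' Column names can be remapped with `dialect` (a named character vector
#' `c(standard_name = file_column_name)`). If the file carries an
#' `intensity` column and no `detected` column, detection is binarized as
#' `intensity > intensity_threshold` (strictly greater; non-imputed
#' label-free quantities are positive when observed).
#'
#' @param path file path (.tsv/.txt tab-separated, .csv comma-separated).
#' @param dialect optional named character vector mapping standard column
#'   names to the file's column names.
#' @param intensity_threshold detection cutoff applied to intensities.
#' @return a [detection_table()].
#' @export
read_detection_table <- function(path, dialect = NULL, intensity_threshold = 0) {
  df <- read_table_auto(path)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      src <- dialect[[std]]
      if (!src %in% names(df))
        stop_input("dialect column '%s' not found in %s", src, path)
      names(df)[names(df) == src] <- std
    }
  }
  if (!"detected" %in% names(df)) {
    if (!"intensity" %in% names(df))
      stop_input("%s has neither 'detected' nor 'intensity' column", path)
    df$detected <- as.numeric(df$intensity) > intensity_threshold
  }
  detection_table(df)
}

#' Write a detection table as TSV
#' @param x a [detection_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}

n_replicates_of <- function(table, fraction) {
  reps <- unique(table$replicate[table$fraction == fraction])
  if (!length(reps)) 0L else length(reps)
}

#' Replicate-consistent proteins of one fraction
#'
#' Returns the gene symbols detected in at least `min_replicates`
#' replicates of the given fraction. The default requires detection in
#' every replicate ("consistently present in all replicates");
#' `min_replicates = 1` yields the identified-at-least-once universe.
#'
#' @param table a [detection_table()].
#' @param fraction "EV" or "SF".
#' @param min_replicates minimum number of replicates with a detection;
#'   default: all replicates present for that fraction.
#' @return sorted character vector of gene symbols.
#' @export
consistent_proteins <- function(table, fraction, min_replicates = NULL) {
  stopifnot(inherits(table, "detection_table"))
  fraction <- match.arg(fraction, c("EV", "SF"))
  sub <- table[table$fraction == fraction, , drop = FALSE]
  if (!nrow(sub))
    stop_input("fraction '%s' absent from detection table", fraction)
  R <- n_replicates_of(table, fraction)
  min_replicates <- min_replicates %||% R
  if (min_replicates > R)
    stop_input("min_replicates (%d) exceeds available replicates (%d)", min_replicates, R)
  hits <- sub[sub$detected, , drop = FALSE]
  if (!nrow(hits)) return(character(0))
  # a gene may be represented by several protein accessions; count a
  # replicate once per gene if any accession was detected in it
  key <- unique(hits[, c("gene_symbol", "replicate")])
  counts <- table(key$gene_symbol)
  sort(names(counts)[counts >= min_replicates])
}

#' Partition two gene sets into a two-set Venn layout
#'
#' @param ev_set,sf_set character vectors of gene symbols.
#' @return object of class `venn_partition`: list with disjoint elements
#'   `ev_only`, `both`, `sf_only`.
#' @export
venn_partition <- function(ev_set, sf_set) {
  ev_set <- unique(normalize_symbols(ev_set))
  sf_set <- unique(normalize_symbols(sf_set))
  out <- list(
    ev_only = sort(setdiff(ev_set, sf_set)),
    both    = sort(intersect(ev_set, sf_set)),
    sf_only = sort(setdiff(sf_set, ev_set))
  )
  structure(out, class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("EV/SF set partition\n")
  cat(sprintf("  EV only: %d\n  shared : %d\n  SF only: %d\n",
              length(x$ev_only), length(x$both), length(x$sf_only)))
  invisible(x)
}
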