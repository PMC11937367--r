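#' Assemble the annotation bundle driving the funnel filters
#'
#' The bundle carries the biological knowledge behind each prioritization
#' stage: which genes are growth factors or cytokines, which are predicted
#' to be secreted (one boolean call per predictor, e.g. a signal-peptide
#' predictor and a transmembrane-topology predictor), which ligands pair
#' with which receptors, and which receptors are expressed in the target
#' recipient cells (alveolar type 1 and 2 cells by default).
#'
#' @param growth_factors character vector of growth-factor/cytokine gene
#'   symbols (e.g. read from a GMT file with [read_gene_sets()]).
#' @param secretion_calls data.frame with columns `gene_symbol`,
#'   `predictor`, `secreted` (logical).
#' @param ligand_receptor_pairs data.frame with columns `ligand`, `receptor`.
#' @param receptor_expression data.frame with columns `receptor`,
#'   `cell_type`, `expressed` (logical).
#' @param target_cell_types cell types a candidate's receptor must be
#'   expressed in; default `c("AT1", "AT2")`.
#' @return object of class `annotation_bundle`.
#' @export
annotation_bundle <- function(growth_factors,
                              secretion_calls,
                              ligand_receptor_pairs,
                              receptor_expression,
                              target_cell_types = c("AT1", "AT2")) {
  growth_factors <- sort(unique(normalize_symbols(growth_factors)))
  sc <- as.data.frame(secretion_calls, stringsAsFactors = FALSE)
  if (!all(c("gene_symbol", "predictor", "secreted") %in% names(sc)))
    stop_input("secretion_calls needs columns gene_symbol, predictor, secreted")
  sc$gene_symbol <- normalize_symbols(sc$gene_symbol)
  sc$predictor <- as.character(sc$predictor)
  sc$secreted <- as.logical(sc$secreted)

  lr <- as.data.frame(ligand_receptor_pairs, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(lr)))
    stop_input("ligand_receptor_pairs needs columns ligand, receptor")
  lr$ligand <- normalize_symbols(lr$ligand)
  lr$receptor <- normalize_symbols(lr$receptor)
  lr <- unique(lr[, c("ligand", "receptor")])

  rx <- as.data.frame(receptor_expression, stringsAsFactors = FALSE)
  if (!all(c("receptor", "cell_type", "expressed") %in% names(rx)))
    stop_input("receptor_expression needs columns receptor, cell_type, expressed")
  rx$receptor <- normalize_symbols(rx$receptor)
  rx$cell_type <- as.character(rx$cell_type)
  rx$expressed <- as.logical(rx$expressed)

  target_cell_types <- unique(as.character(target_cell_types))
  structure(list(
    growth_factors = growth_factors,
    secretion_calls = sc,
    ligand_receptor_pairs = lr,
    receptor_expression = rx,
    target_cell_types = target_cell_types
  ), class = "annotation_bundle")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat("annotation bundle\n")
  cat(sprintf("  growth factors/cytokines: %d genes\n", length(x$growth_factors)))
  cat(sprintf("  secretion predictors    : %s\n",
              paste(unique(x$secretion_calls$predictor), collapse = ", ")))
  cat(sprintf("  ligand-receptor pairs   : %d\n", nrow(x$ligand_receptor_pairs)))
  cat(sprintf("  target cell types       : %s\n",
              paste(x$target_cell_types, collapse = ", ")))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path (one set per line: name, description, genes).
#' @return named list of character vectors with normalized symbols.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_input("gene-set file does not exist: %s", path)
  sets <- fgsea::gmtPathways(path)
  if (!length(sets) || !length(unlist(sets)))
    stop_input("gene-set file is empty: %s", path)
  lapply(sets, normalize_symbols)
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation bundle from its on-disk representation
#'
#' @param gmt path to the growth-factor/cytokine GMT file (all sets in the
#'   file are unioned).
#' @param secretion path to TSV with columns gene_symbol, predictor, secreted.
#' @param ligand_receptor path to TSV with columns ligand, receptor.
#' @param expression path to TSV with columns receptor, cell_type, expressed.
#' @param target_cell_types see [annotation_bundle()].
#' @return an [annotation_bundle()].
#' @export
read_annotation_bundle <- function(gmt, secretion, ligand_receptor, expression,
                                   target_cell_types = c("AT1", "AT2")) {
  sets <- read_gene_sets(gmt)
  annotation_bundle(
    growth_factors = unique(unlist(sets, use.names = FALSE)),
    secretion_calls = read_table_auto(secretion),
    ligand_receptor_pairs = read_table_auto(ligand_receptor),
    receptor_expression = read_table_auto(expression),
    target_cell_types = target_cell_types
  )
}

#' Write an annotation bundle to a directory
#' @param bundle an [annotation_bundle()].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_annotation_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gmt = file.path(dir, "growth_factors.gmt"),
    secretion = file.path(dir, "secretion_calls.tsv"),
    ligand_receptor = file.path(dir, "ligand_receptor_pairs.tsv"),
    expression = file.path(dir, "receptor_expression.tsv")
  )
  write_gene_sets(list(GROWTH_FACTORS_CYTOKINES = bundle$growth_factors), paths[["gmt"]])
  write_tsv(bundle$secretion_calls, paths[["secretion"]])
  write_tsv(bundle$ligand_receptor_pairs, paths[["ligand_receptor"]])
  write_tsv(bundle$receptor_expression, paths[["expression"]])
  invisible(paths)
}

#' Build receptor expression flags from an expression matrix
#'
#' Helper for when per-cell-type receptor expression is available as a
#' fraction-of-cells-expressing matrix rather than precomputed booleans:
#' a receptor is called expressed in a cell type when expressed in at
#' least `min_fraction` of its cells.
#'
#' @param expr numeric matrix, rows = receptor genes, columns = cell types,
#'   entries = fraction of cells expressing (in `[0,1]`).
#' @param min_fraction call threshold; default 0.10.
#' @return data.frame with columns receptor, cell_type, expressed.
#' @export
expression_flags <- function(expr, min_fraction = 0.10) {
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_input("expr must have receptor rownames and cell-type colnames")
  out <- expand.grid(receptor = rownames(expr), cell_type = colnames(expr),
                     stringsAsFactors = FALSE)
  out$expressed <- as.vector(expr >= min_fraction)
  out$receptor <- normalize_symbols(out$receptor)
  out
}
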