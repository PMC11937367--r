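#' Keep candidates annotated as growth factors or cytokines
#'
#' @param candidates character vector of gene symbols.
#' @param bundle an [annotation_bundle()] with a loaded (non-empty)
#'   growth-factor/cytokine set; an empty loaded set is an input error,
#'   distinguished from a legitimately empty intersection.
#' @return sorted character vector (possibly empty) of annotated factors.
#' @export
annotate_factors <- function(candidates, bundle) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  if (!length(bundle$growth_factors))
    stop_input("growth-factor/cytokine gene set is empty; refusing to filter")
  sort(intersect(unique(normalize_symbols(candidates)), bundle$growth_factors))
}

#' Keep factors predicted to be secreted
#'
#' Combines the per-predictor boolean secretion calls. `mode = "any"`
#' (default) keeps a factor predicted secreted by at least one predictor;
#' `mode = "all"` requires every predictor with a call to agree. Factors
#' with no call from any predictor are handled by `missing_policy`
#' (default: treated as not secreted).
#'
#' @param factors character vector of gene symbols.
#' @param bundle an [annotation_bundle()].
#' @param mode "any" or "all".
#' @param missing_policy "not_secreted" (drop, default) or "secreted" (keep).
#' @return sorted character vector of retained factors.
#' @export
secretion_filter <- function(factors, bundle, mode = c("any", "all"),
                             missing_policy = c("not_secreted", "secreted")) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  mode <- match.arg(mode)
  missing_policy <- match.arg(missing_policy)
  sc <- bundle$secretion_calls
  if (!nrow(sc) || !length(unique(sc$predictor)))
    stop_input("annotation bundle declares no secretion predictors")
  factors <- unique(normalize_symbols(factors))
  agg <- if (mode == "any") any else all
  keep <- vapply(factors, function(g) {
    calls <- sc$secreted[sc$gene_symbol == g]
    calls <- calls[!is.na(calls)]
    if (!length(calls)) missing_policy == "secreted" else agg(calls)
  }, logical(1))
  sort(factors[keep])
}

#' Keep factors with a receptor expressed in the target cells
#'
#' A factor survives when at least one of its receptor partners (from the
#' ligand--receptor pair table) is expressed in at least one target cell
#' type. Factors with no pair entry are dropped with a recorded reason,
#' not an error.
#'
#' @param factors character vector of gene symbols.
#' @param bundle an [annotation_bundle()].
#' @return data.frame of kept candidates with columns `gene_symbol`,
#'   `receptors` and `cell_types` (comma-joined); the dropped factors and
#'   their reasons are attached as attribute `"dropped"`.
#' @export
receptor_filter <- function(factors, bundle) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  lr <- bundle$ligand_receptor_pairs
  rx <- bundle$receptor_expression
  rx <- rx[rx$cell_type %in% bundle$target_cell_types & rx$expressed, , drop = FALSE]
  factors <- unique(normalize_symbols(factors))

  rows <- lapply(factors, function(g) {
    partners <- lr$receptor[lr$ligand == g]
    if (!length(partners))
      return(data.frame(gene_symbol = g, receptors = NA_character_,
                        cell_types = NA_character_, kept = FALSE,
                        reason = "no known receptor", stringsAsFactors = FALSE))
    hit <- rx[rx$receptor %in% partners, , drop = FALSE]
    if (!nrow(hit))
      return(data.frame(gene_symbol = g, receptors = NA_character_,
                        cell_types = NA_character_, kept = FALSE,
                        reason = "receptor not expressed in target cells",
                        stringsAsFactors = FALSE))
    data.frame(gene_symbol = g,
               receptors = paste(sort(unique(hit$receptor)), collapse = ","),
               cell_types = paste(sort(unique(hit$cell_type)), collapse = ","),
               kept = TRUE, reason = NA_character_, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows) %||%
    data.frame(gene_symbol = character(), receptors = character(),
               cell_types = character(), kept = logical(), reason = character())
  kept <- all[which(all$kept), c("gene_symbol", "receptors", "cell_types"), drop = FALSE]
  kept <- kept[order(kept$gene_symbol), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "dropped") <- all[which(!all$kept), c("gene_symbol", "reason"), drop = FALSE]
  kept
}

#' Run the full secretome prioritization funnel
#'
#' Executes the stages in order: proteins identified in at least one
#' replicate, proteins consistently detected in all replicates of each
#' fraction, EV/SF partition of the consistent sets, growth-factor and
#' cytokine annotation, secretion-prediction filtering, and
#' ligand--receptor matching against target-cell receptor expression.
#' Every stage's surviving set is a subset of the previous stage's within
#' each compartment, and final candidates carry their compartment
#' provenance (EV_only / both / SF_only) plus matched receptors.
#'
#' @param table a [detection_table()].
#' @param bundle an [annotation_bundle()].
#' @param min_replicates consistency requirement; default all replicates.
#' @param secretion_mode passed to [secretion_filter()].
#' @param missing_policy passed to [secretion_filter()].
#' @return object of class `funnel_result`: list with `stage_counts`
#'   (data.frame stage/compartment/count), `surviving_sets`, `partition`,
#'   `candidates` (data.frame with provenance and receptor matches) and
#'   `params`.
#' @export
run_funnel <- function(table, bundle, min_replicates = NULL,
                       secretion_mode = c("any", "all"),
                       missing_policy = c("not_secreted", "secreted")) {
  stopifnot(inherits(table, "detection_table"))
  secretion_mode <- match.arg(secretion_mode)
  missing_policy <- match.arg(missing_policy)

  empty_candidates <- data.frame(
    gene_symbol = character(), provenance = character(),
    receptors = character(), cell_types = character(),
    stringsAsFactors = FALSE)

  has_ev <- any(table$fraction == "EV")
  has_sf <- any(table$fraction == "SF")
  identified <- list(
    EV = if (has_ev) consistent_proteins(table, "EV", 1L) else character(0),
    SF = if (has_sf) consistent_proteins(table, "SF", 1L) else character(0))
  consistent <- list(
    EV = if (has_ev) consistent_proteins(table, "EV", min_replicates) else character(0),
    SF = if (has_sf) consistent_proteins(table, "SF", min_replicates) else character(0))
  part <- venn_partition(consistent$EV, consistent$SF)
  compartment_of <- function(genes) {
    ifelse(genes %in% part$both, "both",
           ifelse(genes %in% part$ev_only, "EV_only", "SF_only"))
  }

  universe <- sort(union(consistent$EV, consistent$SF))
  factors <- annotate_factors(universe, bundle)
  secreted <- secretion_filter(factors, bundle, mode = secretion_mode,
                               missing_policy = missing_policy)
  matched <- receptor_filter(secreted, bundle)
  candidates <- if (nrow(matched)) {
    data.frame(gene_symbol = matched$gene_symbol,
               provenance = compartment_of(matched$gene_symbol),
               receptors = matched$receptors,
               cell_types = matched$cell_types,
               stringsAsFactors = FALSE)
  } else empty_candidates

  by_comp <- function(genes) {
    comp <- compartment_of(genes)
    c(EV_only = sum(comp == "EV_only"), both = sum(comp == "both"),
      SF_only = sum(comp == "SF_only"))
  }
  fac_c <- by_comp(factors); sec_c <- by_comp(secreted); cand_c <- by_comp(candidates$gene_symbol)
  stage_counts <- rbind(
    data.frame(stage = "identified", compartment = c("EV", "SF"),
               count = c(length(identified$EV), length(identified$SF))),
    data.frame(stage = "consistent", compartment = c("EV", "SF"),
               count = c(length(consistent$EV), length(consistent$SF))),
    data.frame(stage = "partition", compartment = c("EV_only", "both", "SF_only"),
               count = c(length(part$ev_only), length(part$both), length(part$sf_only))),
    data.frame(stage = "growth_factors", compartment = c("total", "EV_only", "both", "SF_only"),
               count = c(length(factors), fac_c[["EV_only"]], fac_c[["both"]], fac_c[["SF_only"]])),
    data.frame(stage = "secreted", compartment = c("total", "EV_only", "both", "SF_only"),
               count = c(length(secreted), sec_c[["EV_only"]], sec_c[["both"]], sec_c[["SF_only"]])),
    data.frame(stage = "receptor_matched", compartment = c("total", "EV_only", "both", "SF_only"),
               count = c(nrow(candidates), cand_c[["EV_only"]], cand_c[["both"]], cand_c[["SF_only"]]))
  )

  structure(list(
    stage_counts = stage_counts,
    surviving_sets = list(identified = identified, consistent = consistent,
                          growth_factors = factors, secreted = secreted,
                          receptor_matched = sort(candidates$gene_symbol)),
    partition = part,
    candidates = candidates[order(candidates$gene_symbol), , drop = FALSE],
    dropped = attr(matched, "dropped"),
    params = list(min_replicates = min_replicates, secretion_mode = secretion_mode,
                  missing_policy = missing_policy)
  ), class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("secretome prioritization funnel\n")
  sc <- x$stage_counts
  for (st in unique(sc$stage)) {
    rows <- sc[sc$stage == st, ]
    cat(sprintf("  %-17s %s\n", st,
                paste(sprintf("%s=%d", rows$compartment, rows$count), collapse = "  ")))
  }
  if (nrow(x$candidates)) {
    cat("candidates:\n")
    cat(sprintf("  %s [%s] via %s\n", x$candidates$gene_symbol,
                x$candidates$provenance, x$candidates$receptors), sep = "")
  } else cat("candidates: none\n")
  invisible(x)
}

#' Serialize a funnel result
#'
#' Writes the stage counts and candidates as TSV plus the whole result as
#' JSON into `dir`.
#'
#' @param x a `funnel_result`.
#' @param dir output directory (created if missing).
#' @return named vector of paths, invisibly.
#' @export
write_funnel_result <- function(x, dir) {
  stopifnot(inherits(x, "funnel_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stages = file.path(dir, "stage_counts.tsv"),
             candidates = file.path(dir, "candidates.tsv"),
             json = file.path(dir, "funnel_result.json"))
  write_tsv(x$stage_counts, paths[["stages"]])
  write_tsv(x$candidates, paths[["candidates"]])
  jsonlite::write_json(unclass(x), paths[["json"]], auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(paths)
}

#' Marker enrichment between EV- and SF-consistent proteins
#'
#' Community EV guidelines expect transmembrane and GPI-anchored marker
#' proteins to be enriched in vesicle preparations relative to the
#' soluble fraction. This builds the 2x2 table (marker vs non-marker x
#' EV-consistent vs SF-consistent) and returns the odds ratio with a
#' hypergeometric (Fisher) exact p-value.
#'
#' @param table a [detection_table()].
#' @param marker_set non-empty character vector of marker gene symbols.
#' @param min_replicates consistency requirement, as in [consistent_proteins()].
#' @return list with `odds_ratio` (conditional MLE; `Inf` sentinel when
#'   markers are absent from SF), `p_value`, `counts` (2x2 matrix) and
#'   `continuity_corrected` flag (TRUE when a zero margin forced a
#'   Haldane-corrected sample odds ratio, reported as `odds_ratio_corrected`).
#' @export
marker_enrichment <- function(table, marker_set, min_replicates = NULL) {
  marker_set <- unique(normalize_symbols(marker_set))
  if (!length(marker_set)) stop_input("marker_set must be non-empty")
  ev <- consistent_proteins(table, "EV", min_replicates)
  sf <- consistent_proteins(table, "SF", min_replicates)
  counts <- matrix(c(
    sum(ev %in% marker_set), sum(sf %in% marker_set),
    sum(!ev %in% marker_set), sum(!sf %in% marker_set)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("marker", "non_marker"), c("EV", "SF")))
  ft <- fisher.test(counts)
  zero_margin <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  out <- list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
              counts = counts, continuity_corrected = zero_margin)
  if (zero_margin || any(counts == 0)) {
    cc <- counts + 0.5
    out$odds_ratio_corrected <- (cc[1, 1] * cc[2, 2]) / (cc[1, 2] * cc[2, 1])
    out$continuity_corrected <- TRUE
  }
  out
}
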