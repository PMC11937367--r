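#' Configuration for the synthetic secretome fixture
#'
#' Emulates the structure of a paired EV/SF secretome proteomics
#' experiment with four biological replicates per fraction. Default
#' consistency rates are the rates observed in the reference experiment
#' (564/1262 EV proteins and 1658/2090 SF proteins consistent in all four
#' replicates).
#'
#' @param n_proteins number of proteins in the table.
#' @param n_replicates replicates per fraction (default 4).
#' @param frac_consistent_ev,frac_consistent_sf probability that a decoy
#'   protein is consistently detected in the EV / SF fraction.
#' @param n_planted_candidates number of planted true candidates that must
#'   survive every funnel stage.
#' @param detection_noise probability that a consistent protein drops out
#'   of one replicate (default 0). Dropouts are bookkept: a planted
#'   candidate losing its consistency is removed from the expected truth.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   fixtures.
#' @return object of class `secretome_fixture_config`.
#' @export
secretome_fixture_config <- function(n_proteins,
                                     n_replicates = 4L,
                                     frac_consistent_ev = 0.45,
                                     frac_consistent_sf = 0.79,
                                     n_planted_candidates = 3L,
                                     detection_noise = 0,
                                     seed = 1L) {
  n_proteins <- assert_count(n_proteins, "n_proteins", min = 1L)
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 1L)
  n_planted_candidates <- assert_count(n_planted_candidates, "n_planted_candidates")
  if (n_planted_candidates > n_proteins)
    stop_input("n_planted_candidates (%d) exceeds n_proteins (%d)",
               n_planted_candidates, n_proteins)
  structure(list(
    n_proteins = n_proteins, n_replicates = n_replicates,
    frac_consistent_ev = assert_prob(frac_consistent_ev, "frac_consistent_ev"),
    frac_consistent_sf = assert_prob(frac_consistent_sf, "frac_consistent_sf"),
    n_planted_candidates = n_planted_candidates,
    detection_noise = assert_prob(detection_noise, "detection_noise"),
    seed = as.integer(seed)
  ), class = "secretome_fixture_config")
}

#' Generate a secretome fixture with planted ground truth
#'
#' Builds a [detection_table()], a matching [annotation_bundle()] and a
#' `fixture_truth` record. Planted candidates are consistently detected
#' (in SF only or in both fractions), annotated as growth factors,
#' predicted secreted by both predictors, and paired to a receptor
#' expressed in a target cell type. Decoy proteins are constructed to
#' fail at controlled stages: replicate inconsistency, missing
#' growth-factor annotation, negative secretion calls, a missing
#' ligand--receptor pair, or a receptor not expressed in the target
#' cells. Expected stage counts and the expected candidate set are
#' recorded by direct bookkeeping during generation (for the default
#' funnel options: full consistency, any-predictor secretion).
#'
#' @param config a [secretome_fixture_config()].
#' @return list with elements `table`, `bundle`, `truth`.
#' @export
generate_secretome_fixture <- function(config) {
  stopifnot(inherits(config, "secretome_fixture_config"))
  set.seed(substream_seed(config$seed, "secretome"))
  n <- config$n_proteins
  R <- config$n_replicates
  k <- config$n_planted_candidates
  genes <- sprintf("GENE%05d", seq_len(n))
  planted <- genes[seq_len(k)]

  # per-protein design: compartment consistency + designated failure stage
  fate <- character(n)                 # decoy failure stage
  cons_ev <- logical(n); cons_sf <- logical(n)
  provenance <- rep(NA_character_, n)
  if (k > 0) {
    provenance[seq_len(k)] <- sample(c("SF_only", "both"), k, replace = TRUE)
    cons_sf[seq_len(k)] <- TRUE
    cons_ev[seq_len(k)] <- provenance[seq_len(k)] == "both"
    fate[seq_len(k)] <- "candidate"
  }
  if (n > k) {
    idx <- (k + 1L):n
    cons_ev[idx] <- runif(length(idx)) < config$frac_consistent_ev
    cons_sf[idx] <- runif(length(idx)) < config$frac_consistent_sf
    consistent <- cons_ev[idx] | cons_sf[idx]
    fate[idx][!consistent] <- "inconsistent"
    fate[idx][consistent] <- sample(
      c("not_growth_factor", "not_secreted", "no_receptor", "receptor_not_expressed"),
      sum(consistent), replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
  }

  # detection patterns per (protein, fraction): a consistent pattern is all
  # R replicates; inconsistent proteins are seen in 1..R-1 replicates of at
  # least one fraction (when R == 1 inconsistency is impossible, so such
  # proteins are absent from both fractions)
  det_ev <- matrix(FALSE, n, R); det_sf <- matrix(FALSE, n, R)
  det_ev[cons_ev, ] <- TRUE
  det_sf[cons_sf, ] <- TRUE
  partial <- function() {
    if (R == 1L) return(rep(FALSE, 1L))
    m <- sample.int(R - 1L, 1L)
    out <- rep(FALSE, R); out[sample.int(R, m)] <- TRUE; out
  }
  for (i in which(fate == "inconsistent")) {
    which_frac <- sample(c("EV", "SF", "both_partial"), 1L)
    if (which_frac %in% c("EV", "both_partial")) det_ev[i, ] <- partial()
    if (which_frac %in% c("SF", "both_partial")) det_sf[i, ] <- partial()
  }

  # bookkept dropout noise: a consistent (protein, fraction) loses one
  # replicate with probability detection_noise, and the ledger is updated
  # before the truth is frozen
  if (config$detection_noise > 0 && R > 1L) {
    for (i in seq_len(n)) {
      if (cons_ev[i] && runif(1) < config$detection_noise) {
        det_ev[i, sample.int(R, 1L)] <- FALSE
        cons_ev[i] <- FALSE
      }
      if (cons_sf[i] && runif(1) < config$detection_noise) {
        det_sf[i, sample.int(R, 1L)] <- FALSE
        cons_sf[i] <- FALSE
      }
    }
  }

  # annotation bundle: planted candidates carry every required annotation;
  # decoys carry exactly the annotations of the stages they must pass
  gf_fates <- c("candidate", "not_secreted", "no_receptor", "receptor_not_expressed")
  gf_set <- genes[fate %in% gf_fates]
  secreted_yes <- genes[fate %in% c("candidate", "no_receptor", "receptor_not_expressed")]
  secreted_no <- genes[fate == "not_secreted"]
  sc <- rbind(
    expand.grid(gene_symbol = secreted_yes, predictor = c("SignalP", "Phobius"),
                secreted = TRUE, stringsAsFactors = FALSE),
    expand.grid(gene_symbol = secreted_no, predictor = c("SignalP", "Phobius"),
                secreted = FALSE, stringsAsFactors = FALSE))

  paired_genes <- genes[fate %in% c("candidate", "receptor_not_expressed")]
  lr <- if (length(paired_genes)) {
    data.frame(ligand = paired_genes,
               receptor = paste0("RCPT_", paired_genes),
               stringsAsFactors = FALSE)
  } else data.frame(ligand = character(), receptor = character())
  rx_rows <- lapply(seq_len(n), function(i) {
    if (!fate[i] %in% c("candidate", "receptor_not_expressed")) return(NULL)
    cell_hit <- if (fate[i] == "candidate") sample(c("AT1", "AT2"), 1L) else NA
    data.frame(receptor = paste0("RCPT_", genes[i]),
               cell_type = c("AT1", "AT2"),
               expressed = c("AT1", "AT2") %in% cell_hit,
               stringsAsFactors = FALSE)
  })
  rx <- do.call(rbind, rx_rows) %||%
    data.frame(receptor = character(), cell_type = character(), expressed = logical())
  if (!nrow(lr)) {  # keep the bundle structurally valid with no pairs
    lr <- data.frame(ligand = "NONE", receptor = "RCPT_NONE", stringsAsFactors = FALSE)
    rx <- data.frame(receptor = "RCPT_NONE", cell_type = c("AT1", "AT2"),
                     expressed = FALSE, stringsAsFactors = FALSE)
  }
  if (!nrow(sc))
    sc <- data.frame(gene_symbol = "NONE", predictor = c("SignalP", "Phobius"),
                     secreted = FALSE, stringsAsFactors = FALSE)
  bundle <- annotation_bundle(gf_set, sc, lr, rx)

  # emit dense long-format records
  rec <- function(det, fraction) {
    data.frame(protein_id = rep(paste0("ACC_", genes), each = R),
               gene_symbol = rep(genes, each = R),
               fraction = fraction,
               replicate = rep(seq_len(R), times = n),
               detected = as.vector(t(det)),
               stringsAsFactors = FALSE)
  }
  table <- detection_table(rbind(rec(det_ev, "EV"), rec(det_sf, "SF")))

  # truth by bookkeeping (default funnel options)
  surviving <- fate == "candidate" & (cons_ev | cons_sf)
  expected <- sort(genes[surviving])
  still_gf <- gf_set[gf_set %in% genes[cons_ev | cons_sf]]
  still_secreted <- still_gf[still_gf %in% c(secreted_yes)]
  expected_counts <- list(
    identified_EV = sum(rowSums(det_ev) >= 1L),
    identified_SF = sum(rowSums(det_sf) >= 1L),
    consistent_EV = sum(cons_ev),
    consistent_SF = sum(cons_sf),
    shared = sum(cons_ev & cons_sf),
    growth_factors = length(still_gf),
    secreted = length(still_secreted),
    candidates = length(expected))

  truth <- structure(list(
    expected_candidate_set = expected,
    expected_stage_counts = expected_counts,
    planted_effect_ratio = NA_real_,
    planted_positive_fraction = NA_real_,
    planted_mean_chord = NA_real_
  ), class = "fixture_truth")

  list(table = table, bundle = bundle, truth = truth)
}

#' Write fixture ground truth as JSON
#' @param truth a `fixture_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixture_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
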