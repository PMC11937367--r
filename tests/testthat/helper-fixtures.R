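# Small hand-built inputs shared across tests.

toy_detection_table <- function() {
  # 3 proteins x 2 replicates x 2 fractions; P3 inconsistent in EV
  rows <- expand.grid(gene = c("P1", "P2", "P3"), fraction = c("EV", "SF"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  rows$protein_id <- paste0("ACC_", rows$gene)
  rows$gene_symbol <- rows$gene
  rows$detected <- TRUE
  rows$detected[rows$gene == "P3" & rows$fraction == "EV" & rows$replicate == 2] <- FALSE
  detection_table(rows[, c("protein_id", "gene_symbol", "fraction", "replicate", "detected")])
}

toy_bundle <- function() {
  annotation_bundle(
    growth_factors = c("P1", "P2", "GF_EXTRA"),
    secretion_calls = data.frame(
      gene_symbol = c("P1", "P1", "P2", "P2"),
      predictor = c("SignalP", "Phobius", "SignalP", "Phobius"),
      secreted = c(TRUE, FALSE, FALSE, FALSE)),
    ligand_receptor_pairs = data.frame(ligand = "P1", receptor = "R1"),
    receptor_expression = data.frame(
      receptor = c("R1", "R1"), cell_type = c("AT1", "AT2"),
      expressed = c(FALSE, TRUE)))
}

# A deterministic study-scale synthetic detection table + annotation bundle
# constructed to the published stage cardinalities of the reference
# experiment: 1262/2090 identified, 564/1658 consistent, 476 shared,
# 43 growth factors (2 EV-only / 30 SF-only / 11 both), 32 secreted,
# 12 receptor-matched candidates (7 SF-only + 5 both). Entirely synthetic
# gene identities; only the set sizes mirror the study.
study_scale_fixture <- function() {
  ev_only <- sprintf("EVO%04d", 1:88)
  both <- sprintf("BTH%04d", 1:476)
  sf_only <- sprintf("SFO%04d", 1:1182)
  ev_extra <- sprintf("IEV%04d", 1:698)   # identified but inconsistent, EV
  sf_extra <- sprintf("ISF%04d", 1:432)   # identified but inconsistent, SF

  consistent_rows <- function(genes, fraction) {
    data.frame(protein_id = paste0("ACC_", rep(genes, each = 4)),
               gene_symbol = rep(genes, each = 4), fraction = fraction,
               replicate = rep(1:4, times = length(genes)), detected = TRUE,
               stringsAsFactors = FALSE)
  }
  partial_rows <- function(genes, fraction) {
    k <- rep_len(1:3, length(genes))  # detected in 1..3 of 4 replicates
    data.frame(protein_id = paste0("ACC_", rep(genes, times = k)),
               gene_symbol = rep(genes, times = k), fraction = fraction,
               replicate = unlist(lapply(k, seq_len)), detected = TRUE,
               stringsAsFactors = FALSE)
  }
  table <- detection_table(rbind(
    consistent_rows(c(ev_only, both), "EV"),
    consistent_rows(c(both, sf_only), "SF"),
    partial_rows(ev_extra, "EV"),
    partial_rows(sf_extra, "SF")))

  # growth factors: 2 EV-only, 11 both, 30 SF-only
  gf <- c(ev_only[1:2], both[1:11], sf_only[1:30])
  # secreted: 1 of the EV-only, 9 of the both, 22 of the SF-only factors
  secreted <- c(ev_only[1], both[1:9], sf_only[1:22])
  not_secreted <- setdiff(gf, secreted)
  # receptor-matched: 5 both + 7 SF-only; the rest lack a pair or an
  # expressed receptor
  matched <- c(both[1:5], sf_only[1:7])
  unmatched_with_pair <- c(both[6:7], sf_only[8:9])  # pair exists, receptor silent

  sc <- rbind(
    expand.grid(gene_symbol = secreted, predictor = c("SignalP", "Phobius"),
                secreted = TRUE, stringsAsFactors = FALSE),
    expand.grid(gene_symbol = not_secreted, predictor = c("SignalP", "Phobius"),
                secreted = FALSE, stringsAsFactors = FALSE))
  lr <- data.frame(ligand = c(matched, unmatched_with_pair),
                   receptor = paste0("R_", c(matched, unmatched_with_pair)),
                   stringsAsFactors = FALSE)
  rx <- data.frame(receptor = paste0("R_", c(matched, unmatched_with_pair)),
                   cell_type = rep_len(c("AT2", "AT1"), length(matched) + length(unmatched_with_pair)),
                   expressed = c(rep(TRUE, length(matched)),
                                 rep(FALSE, length(unmatched_with_pair))),
                   stringsAsFactors = FALSE)
  list(table = table, bundle = annotation_bundle(gf, sc, lr, rx))
}

# exhaustive ECDF sup-distance: the brute-force two-sample KS oracle
ks_oracle_D <- function(x, y) {
  ts <- sort(unique(c(x, y)))
  max(abs(vapply(ts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# between-class variance of a candidate threshold, and its exhaustive
# maximum over a dense grid: the Otsu oracle (the optimum is a plateau
# wherever a gap separates the classes, so optimality is checked by
# attained variance, not by a unique argmax)
otsu_bcv <- function(vals, t) {
  lo <- vals[vals <= t]; hi <- vals[vals > t]
  if (!length(lo) || !length(hi)) return(0)
  w1 <- length(lo) / length(vals)
  w1 * (1 - w1) * (mean(lo) - mean(hi))^2
}

otsu_oracle_max <- function(vals, levels = 512L) {
  grid <- seq(min(vals), max(vals), length.out = levels)
  max(vapply(grid, function(t) otsu_bcv(vals, t), numeric(1)))
}

# all multisets of the given size over a value alphabet, as a list
all_multisets <- function(alphabet, size) {
  if (size == 1L) return(as.list(alphabet))
  grid <- do.call(expand.grid, rep(list(alphabet), size))
  sorted <- unique(t(apply(as.matrix(grid), 1L, sort)))
  lapply(seq_len(nrow(sorted)), function(i) sorted[i, ])
}
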