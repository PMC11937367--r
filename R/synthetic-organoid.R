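#' Configuration for the synthetic organoid experiment
#'
#' Defaults encode the study conditions of the organoid assay: 10,000
#' epithelial cells seeded per insert, a 1% control colony-forming
#' efficiency (CFE), a 1.75x treatment effect on CFE (the calibrated
#' lead-candidate effect, ~+75%), a 0.6x CFE under cigarette-smoke
#' extract (CSE) with a +0.15 shift of the diameter log-mean, and
#' right-skewed lognormal diameters (log-mean log(120 um), log-sd 0.4)
#' truncated at the >50 um day-14 scoring rule.
#'
#' @param n_seeded epithelial cells seeded per culture (default 10000).
#' @param baseline_cfe control probability that a seeded cell forms an
#'   organoid (default 0.01).
#' @param treatment_cfe_ratio multiplicative treatment effect on CFE
#'   (default 1.75).
#' @param cse_cfe_ratio multiplicative CSE effect on CFE (default 0.6).
#' @param diameter_log_mean,diameter_log_sd lognormal diameter parameters
#'   (um scale).
#' @param cse_diameter_shift additive shift of the diameter log-mean under
#'   CSE (default +0.15).
#' @param n_replicates paired biological replicates (animals).
#' @param conditions conditions to generate; any subset of
#'   `c("control", "treated", "cse")`.
#' @param seed integer seed.
#' @return object of class `organoid_fixture_config`.
#' @export
organoid_fixture_config <- function(n_seeded = 10000L,
                                    baseline_cfe = 0.01,
                                    treatment_cfe_ratio = 1.75,
                                    cse_cfe_ratio = 0.6,
                                    diameter_log_mean = log(120),
                                    diameter_log_sd = 0.4,
                                    cse_diameter_shift = 0.15,
                                    n_replicates = 1L,
                                    conditions = c("control", "treated"),
                                    seed = 1L) {
  n_seeded <- assert_count(n_seeded, "n_seeded", min = 1L)
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 1L)
  baseline_cfe <- assert_prob(baseline_cfe, "baseline_cfe")
  if (treatment_cfe_ratio <= 0 || cse_cfe_ratio <= 0)
    stop_input("CFE ratios must be positive")
  if (baseline_cfe * treatment_cfe_ratio > 1)
    stop_input("baseline_cfe * treatment_cfe_ratio exceeds 1 (not a probability)")
  conditions <- match.arg(conditions, c("control", "treated", "cse"),
                          several.ok = TRUE)
  structure(list(
    n_seeded = n_seeded, baseline_cfe = baseline_cfe,
    treatment_cfe_ratio = treatment_cfe_ratio, cse_cfe_ratio = cse_cfe_ratio,
    diameter_log_mean = diameter_log_mean, diameter_log_sd = diameter_log_sd,
    cse_diameter_shift = cse_diameter_shift,
    n_replicates = n_replicates, conditions = conditions,
    seed = as.integer(seed)
  ), class = "organoid_fixture_config")
}

# organoid type mixtures per condition: alveolar-dominant at baseline,
# more alveolar under treatment, more marker-negative under CSE
.type_probs <- list(
  control = c(SPC_pos = 0.55, ACT_pos = 0.25, SPC_ACT_pos = 0.10, SPC_ACT_neg = 0.10),
  treated = c(SPC_pos = 0.65, ACT_pos = 0.18, SPC_ACT_pos = 0.09, SPC_ACT_neg = 0.08),
  cse     = c(SPC_pos = 0.40, ACT_pos = 0.30, SPC_ACT_pos = 0.08, SPC_ACT_neg = 0.22)
)

#' Generate a synthetic organoid experiment with planted effects
#'
#' Per replicate and condition, the organoid count is drawn binomially
#' from (n_seeded, condition CFE); diameters are lognormal truncated to
#' the >50 um scoring rule; organoid type counts are multinomial draws.
#' Replicate labels are shared across conditions, emulating the paired
#' (same-animal) design.
#'
#' @param config an [organoid_fixture_config()].
#' @return list with `experiment` (an `organoid_experiment`: `$counts`
#'   data.frame and `$diameters` long data.frame) and `truth`
#'   (a `fixture_truth` carrying the planted effect ratio).
#' @export
generate_organoid_experiment <- function(config) {
  stopifnot(inherits(config, "organoid_fixture_config"))
  set.seed(substream_seed(config$seed, "organoid"))
  cfe_of <- c(control = config$baseline_cfe,
              treated = config$baseline_cfe * config$treatment_cfe_ratio,
              cse = config$baseline_cfe * config$cse_cfe_ratio)
  mlog_of <- c(control = config$diameter_log_mean,
               treated = config$diameter_log_mean,
               cse = config$diameter_log_mean + config$cse_diameter_shift)

  counts <- NULL; diam <- NULL
  for (r in seq_len(config$n_replicates)) {
    rid <- sprintf("animal%02d", r)
    for (cond in config$conditions) {
      n_org <- rbinom(1L, config$n_seeded, cfe_of[[cond]])
      d <- rtrunc_lnorm(n_org, mlog_of[[cond]], config$diameter_log_sd, lower = 50)
      tc <- if (n_org > 0) {
        as.integer(stats::rmultinom(1L, n_org, .type_probs[[cond]]))
      } else rep(0L, 4L)
      counts <- rbind(counts, data.frame(
        condition = cond, replicate_id = rid,
        n_seeded = config$n_seeded, n_organoids = n_org,
        SPC_pos = tc[1], ACT_pos = tc[2], SPC_ACT_pos = tc[3], SPC_ACT_neg = tc[4],
        stringsAsFactors = FALSE))
      if (n_org > 0)
        diam <- rbind(diam, data.frame(condition = cond, replicate_id = rid,
                                       diameter = d, stringsAsFactors = FALSE))
    }
  }
  experiment <- structure(list(counts = counts,
                               diameters = diam %||% data.frame(
                                 condition = character(), replicate_id = character(),
                                 diameter = numeric())),
                          class = "organoid_experiment")
  truth <- structure(list(
    expected_candidate_set = character(0),
    expected_stage_counts = NULL,
    planted_effect_ratio = config$treatment_cfe_ratio,
    planted_positive_fraction = NA_real_,
    planted_mean_chord = NA_real_
  ), class = "fixture_truth")
  list(experiment = experiment, truth = truth)
}

# lognormal truncated to (lower, Inf) by rejection; the truncation mass is
# tiny at the defaults (P[X <= 50] ~ 1.4%) so this converges immediately
rtrunc_lnorm <- function(n, meanlog, sdlog, lower) {
  if (n == 0L) return(numeric(0))
  out <- rlnorm(n, meanlog, sdlog)
  bad <- which(out <= lower)
  while (length(bad)) {
    out[bad] <- rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[out[bad] <= lower]
  }
  out
}

#' Write an organoid experiment as TSV files
#' @param experiment an `organoid_experiment`.
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_organoid_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "organoid_counts.tsv"),
             diameters = file.path(dir, "organoid_diameters.tsv"))
  write_tsv(experiment$counts, paths[["counts"]])
  write_tsv(experiment$diameters, paths[["diameters"]])
  invisible(paths)
}

#' Read an organoid experiment from TSV files
#' @param counts path to the per-culture counts table.
#' @param diameters optional path to the long-format diameters table.
#' @return an `organoid_experiment`.
#' @export
read_organoid_experiment <- function(counts, diameters = NULL) {
  ct <- read_table_auto(counts)
  need <- c("condition", "replicate_id", "n_seeded", "n_organoids")
  if (!all(need %in% names(ct)))
    stop_input("organoid counts table needs columns: %s", paste(need, collapse = ", "))
  dm <- if (!is.null(diameters)) read_table_auto(diameters) else
    data.frame(condition = character(), replicate_id = character(), diameter = numeric())
  structure(list(counts = ct, diameters = dm), class = "organoid_experiment")
}
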