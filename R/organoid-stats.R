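#' Colony-forming efficiency
#'
#' CFE is the percentage of seeded epithelial progenitor cells that have
#' formed an organoid (>50 um) by the day-14 readout:
#' `100 * n_organoids / n_seeded`. Vectorized; linear in `n_organoids`
#' and scale-free in `(k*n_organoids, k*n_seeded)`.
#'
#' @param n_organoids organoid count(s).
#' @param n_seeded seeded cell count(s), > 0.
#' @return CFE in percent.
#' @export
cfe <- function(n_organoids, n_seeded) {
  if (any(n_seeded <= 0)) stop_input("n_seeded must be > 0")
  if (any(n_organoids < 0)) stop_input("n_organoids must be >= 0")
  100 * n_organoids / n_seeded
}

#' Apply the strict >50 um diameter scoring rule
#'
#' @param diameters numeric vector (um).
#' @param min_diameter scoring cutoff (default 50 um); the comparison is
#'   strictly greater-than.
#' @return filtered vector, input order preserved.
#' @export
filter_diameters <- function(diameters, min_diameter = 50) {
  diameters[diameters > min_diameter]
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over thresholds of the absolute ECDF difference.
#' The default p-value is the asymptotic two-sided Kolmogorov
#' distribution with the effective-sample-size correction
#' `n_eff = n_x * n_y / (n_x + n_y)`; exact small-sample p available via
#' `exact = TRUE`. Ties (as arise in rounded diameter data) are accepted;
#' the D statistic is exact regardless.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact compute the exact p-value (small samples, no ties).
#' @return list with `D`, `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (!length(x) || !length(y)) stop_input("both samples must be non-empty")
  ht <- suppressWarnings(ks.test(x, y, alternative = "two.sided", exact = exact))
  list(D = unname(ht$statistic), p_value = ht$p.value,
       n_x = length(x), n_y = length(y))
}

#' Bonferroni-corrected per-comparison alpha
#'
#' Returns the full-precision corrected alpha together with the display
#' value used in figure-legend style: four decimals by default, three
#' decimals when the fourth carries essentially no information (the
#' 3-decimal rounding changes the value by less than 2.5e-4). This
#' reproduces legend conventions such as 0.0167 (m=3), 0.0125 (m=4),
#' 0.004 (m=12) and 0.025 (m=2) at family alpha 0.05.
#'
#' @param family_alpha family-wise error rate (default 0.05).
#' @param m number of comparisons (>= 1).
#' @return list with `alpha` (full precision), `display` (rounded
#'   numeric) and `m`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m) {
  m <- assert_count(m, "m", min = 1L)
  family_alpha <- assert_prob(family_alpha, "family_alpha")
  full <- family_alpha / m
  display <- if (abs(full - round(full, 3)) < 2.5e-4) round(full, 3) else round(full, 4)
  list(alpha = full, display = display, m = m)
}

#' Organoid type proportions
#'
#' Converts counts over the four immunofluorescence categories
#' (SPC+, ACT+, SPC+/ACT+, SPC-/ACT-) -- or any named count vector --
#' into percentages summing to 100.
#'
#' @param type_counts named non-negative count vector with positive total.
#' @return named numeric vector of percentages.
#' @export
organoid_type_proportions <- function(type_counts) {
  type_counts <- unlist(type_counts)
  if (any(type_counts < 0)) stop_input("type counts must be non-negative")
  total <- sum(type_counts)
  if (total <= 0) stop_input("total organoid type count must be > 0")
  100 * type_counts / total
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Omnibus one-way ANOVA followed by Dunnett's test of every non-control
#' group against the shared control, controlling the family-wise error
#' rate via the multivariate-t many-to-one distribution (equal-variance
#' assumption). When `paired = TRUE` the groups must have equal lengths
#' in shared replicate order, and a randomized-block (replicate) term
#' absorbs the within-replicate pairing before the Dunnett contrasts.
#'
#' @param groups named list of numeric samples.
#' @param control name of the control group.
#' @param paired treat positions across groups as matched replicates.
#' @return object of class `comparison_result`: data.frame with one row
#'   per non-control group (estimate, statistic, adjusted p), plus
#'   attributes `omnibus_p` and `method`.
#' @export
anova_dunnett <- function(groups, control, paired = FALSE) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_input("`groups` must be a named list of >= 2 samples")
  if (!control %in% names(groups))
    stop_input("control group '%s' not present", control)
  lens <- lengths(groups)
  if (paired && length(unique(lens)) != 1L)
    stop_input("paired design requires equal group lengths")
  levels <- c(control, setdiff(names(groups), control))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lens), levels = levels),
    block = factor(unlist(lapply(lens, seq_len))))

  # degenerate case: zero residual variance (identical constants) breaks
  # the multivariate-t adjustment; nothing can be significant
  fit <- if (paired) aov(y ~ group + block, data = df) else aov(y ~ group, data = df)
  an <- summary(fit)[[1]]
  omnibus_p <- an[["Pr(>F)"]][rownames(an) == "group" |
                                trimws(rownames(an)) == "group"][1]
  resid_ss <- sum(stats::residuals(fit)^2)
  comparisons <- levels[-1]
  if (resid_ss < 1e-24) {
    means <- vapply(groups, mean, numeric(1))
    est <- means[comparisons] - means[control]
    out <- data.frame(comparison = paste(comparisons, "-", control),
                      estimate = unname(est),
                      statistic = ifelse(est == 0, 0, sign(est) * Inf),
                      p_adjusted = as.numeric(est == 0),
                      stringsAsFactors = FALSE)
    omnibus_p <- if (all(est == 0)) 1 else 0
  } else {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    sm <- summary(gl)
    out <- data.frame(comparison = names(sm$test$coefficients),
                      estimate = unname(sm$test$coefficients),
                      statistic = unname(sm$test$tstat),
                      p_adjusted = unname(as.numeric(sm$test$pvalues)),
                      stringsAsFactors = FALSE)
  }
  out$n <- unname(lens[setdiff(levels, control)])
  structure(out,
            omnibus_p = omnibus_p,
            method = if (paired) "paired one-way ANOVA, Dunnett test"
                     else "one-way ANOVA, Dunnett test",
            class = c("comparison_result", "data.frame"))
}

#' Paired percent change in colony-forming efficiency
#'
#' For each replicate pair, computes `100 * (CFE_t - CFE_c) / CFE_c`,
#' then reports the mean over pairs with a seeded percentile bootstrap
#' confidence interval (2,000 resamples by default). Pairs whose control
#' CFE is zero are excluded with a warning; if all pairs are excluded
#' this is an error.
#'
#' @param treated,control data.frames with columns `replicate_id`,
#'   `n_organoids`, `n_seeded` (e.g. condition-subsets of an
#'   `organoid_experiment$counts`), or `organoid_experiment` objects
#'   holding a single condition.
#' @param n_boot bootstrap resamples.
#' @param conf_level confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return list with `estimate` (mean percent change), `ci` (percentile
#'   interval), `pairs` (per-pair table), `n_pairs`.
#' @export
effect_estimate <- function(treated, control, n_boot = 2000L,
                            conf_level = 0.95, seed = 1L) {
  as_counts <- function(x) {
    if (inherits(x, "organoid_experiment")) x <- x$counts
    need <- c("replicate_id", "n_organoids", "n_seeded")
    if (!all(need %in% names(x)))
      stop_input("effect_estimate inputs need columns: %s", paste(need, collapse = ", "))
    x
  }
  t <- as_counts(treated); c <- as_counts(control)
  ids <- intersect(t$replicate_id, c$replicate_id)
  if (!length(ids)) stop_input("no matched replicate pairs")
  t <- t[match(ids, t$replicate_id), ]; c <- c[match(ids, c$replicate_id), ]
  cfe_t <- cfe(t$n_organoids, t$n_seeded)
  cfe_c <- cfe(c$n_organoids, c$n_seeded)
  zero <- cfe_c == 0
  if (any(zero)) {
    warning(sprintf("excluding %d pair(s) with zero control CFE: %s",
                    sum(zero), paste(ids[zero], collapse = ", ")))
    ids <- ids[!zero]; cfe_t <- cfe_t[!zero]; cfe_c <- cfe_c[!zero]
  }
  if (!length(ids)) stop_input("all pairs excluded (zero control CFE)")
  pct <- 100 * (cfe_t - cfe_c) / cfe_c
  set.seed(substream_seed(seed, "bootstrap"))
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(pct[sample.int(length(pct), replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  list(estimate = mean(pct),
       ci = unname(quantile(boot, c(alpha, 1 - alpha))),
       pairs = data.frame(replicate_id = ids, cfe_control = cfe_c,
                          cfe_treated = cfe_t, percent_change = pct,
                          stringsAsFactors = FALSE),
       n_pairs = length(ids),
       conf_level = conf_level)
}
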