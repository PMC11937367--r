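test_that("colony-forming efficiency is percent of seeded cells", {
  expect_equal(cfe(0, 10000), 0)
  expect_equal(cfe(120, 10000), 1.2)
  expect_error(cfe(5, 0), "n_seeded")
  expect_error(cfe(-1, 100), "n_organoids")
  # linear in the numerator, scale-free under joint scaling
  expect_equal(cfe(3 * 40, 10000), 3 * cfe(40, 10000))
  expect_equal(cfe(7 * 40, 7 * 10000), cfe(40, 10000))
})

test_that("diameter filter is strictly greater-than and order preserving", {
  expect_equal(filter_diameters(c(30, 50, 51, 400)), c(51, 400))
  expect_equal(filter_diameters(numeric(0)), numeric(0))
  set.seed(14)
  x <- runif(200, 0, 120)
  expect_length(filter_diameters(x), sum(x > 50))
  expect_equal(filter_diameters(x), x[x > 50])
})

test_that("two-sample KS statistic matches its definition", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2), c(5, 6))$D, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1, 3))$D, 0.5)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
  # invariant under strictly monotone transforms of both samples
  set.seed(8)
  x <- rlnorm(40, log(120), 0.4); y <- rlnorm(35, log(150), 0.3)
  expect_equal(ks_two_sample(log(x), log(y))$D, ks_two_sample(x, y)$D)
})

test_that("Bonferroni alpha reproduces figure-legend display conventions", {
  expect_equal(bonferroni_alpha(0.05, 3)$display, 0.0167)
  expect_equal(bonferroni_alpha(0.05, 4)$display, 0.0125)
  expect_equal(bonferroni_alpha(0.05, 12)$display, 0.004)
  expect_equal(bonferroni_alpha(0.05, 2)$display, 0.025)
  expect_equal(bonferroni_alpha(0.05, 1)$alpha, 0.05)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
  # monotone decreasing in the number of comparisons
  alphas <- vapply(1:12, function(m) bonferroni_alpha(0.05, m)$alpha, numeric(1))
  expect_true(all(diff(alphas) < 0))
})

test_that("organoid type proportions sum to 100 and handle edge cases", {
  p <- organoid_type_proportions(c(SPC_pos = 6, ACT_pos = 2, dual = 1, neg = 1))
  expect_equal(unname(p), c(60, 20, 10, 10))
  expect_equal(unname(organoid_type_proportions(c(a = 0, b = 5))), c(0, 100))
  expect_error(organoid_type_proportions(c(a = 0, b = 0)), "> 0")
  set.seed(3)
  for (i in 1:10) {
    cts <- rpois(4, 20)
    if (sum(cts) == 0) next
    expect_equal(sum(organoid_type_proportions(cts)), 100, tolerance = 1e-9)
  }
})

test_that("Dunnett comparisons behave across degenerate and extreme designs", {
  # identical constants: nothing significant, adjusted p = 1
  same <- list(ctl = rep(2, 5), a = rep(2, 5), b = rep(2, 5))
  r0 <- anova_dunnett(same, "ctl")
  expect_true(all(r0$p_adjusted == 1))
  # extreme separation
  set.seed(99)
  r1 <- anova_dunnett(list(ctl = rnorm(6, 0, 0.01), hi = rnorm(6, 10, 0.01)), "ctl")
  expect_lt(r1$p_adjusted, 1e-4)
  # single comparison: Dunnett adjustment collapses to a plain t-test
  set.seed(100)
  x <- rnorm(8); y <- rnorm(8, 0.8)
  r2 <- anova_dunnett(list(ctl = x, trt = y), "ctl")
  t_p <- t.test(y, x, var.equal = TRUE)$p.value
  expect_equal(r2$p_adjusted, t_p, tolerance = 0.1 * t_p)
  # errors
  expect_error(anova_dunnett(list(a = 1:3, b = 1:3), "ctl"), "not present")
  expect_error(anova_dunnett(list(ctl = 1:3, a = 1:4), "ctl", paired = TRUE),
               "equal group lengths")
})

test_that("paired Dunnett absorbs replicate effects", {
  set.seed(42)
  block <- rnorm(6, 0, 5)                 # large animal-to-animal spread
  ctl <- block + rnorm(6, 0, 0.1)
  trt <- block + 1 + rnorm(6, 0, 0.1)     # constant within-pair shift
  unp <- anova_dunnett(list(ctl = ctl, trt = trt), "ctl", paired = FALSE)
  par <- anova_dunnett(list(ctl = ctl, trt = trt), "ctl", paired = TRUE)
  expect_lt(par$p_adjusted, 0.001)
  expect_gt(unp$p_adjusted, par$p_adjusted)
})

test_that("effect estimation recovers exact and planted treatment ratios", {
  mk <- function(n_org, ids = paste0("m", seq_along(n_org)), n_seeded = 10000) {
    data.frame(replicate_id = ids, n_organoids = n_org, n_seeded = n_seeded)
  }
  # exact 1.75x on every pair: +75% with a zero-width interval
  ctl <- mk(c(100, 120, 80))
  trt <- mk(c(175, 210, 140))
  r <- effect_estimate(trt, ctl)
  expect_equal(r$estimate, 75)
  expect_equal(unname(diff(r$ci)), 0)
  # identical experiments: 0%
  expect_equal(effect_estimate(ctl, ctl)$estimate, 0)
  # zero-control pairs are excluded with a warning; all-zero errors
  expect_warning(r2 <- effect_estimate(mk(c(175, 140)), mk(c(100, 0))),
                 "zero control CFE")
  expect_equal(r2$n_pairs, 1)
  expect_error(suppressWarnings(effect_estimate(mk(10), mk(0))), "all pairs")
  expect_error(effect_estimate(mk(10, ids = "a"), mk(10, ids = "b")), "matched")
})
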