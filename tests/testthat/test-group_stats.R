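test_that("activity quartile bins close boundaries downward except the last", {
  b <- bin_scores(c(0, 24.9, 25, 49.9, 50, 74.9, 75, 99.9, 100),
                  "activity_quartiles")
  expect_equal(as.integer(b), c(2, 2, 2, 3))   # 25 -> second bin, 100 -> last
  expect_equal(attr(b, "labels"), c("0-25%", "25-50%", "50-75%", "75-100%"))
  expect_error(bin_scores(c(50, 101), "activity_quartiles"), "domain error")
  expect_error(bin_scores(c(50, NA), "activity_quartiles"), "domain error")
})

test_that("E-O terciles place 0 and 10 in the middle bin", {
  b <- bin_scores(c(-5, -0.01, 0, 5, 10, 10.01, 60), "eo_terciles")
  expect_equal(as.integer(b), c(2, 3, 2))
  expect_equal(attr(b, "labels"), c("<0%", "0-10%", ">10%"))
})

test_that("sign binning counts an exact zero as non-positive", {
  b <- bin_scores(c(-1, 0, 0.001, 5), "sign")
  expect_equal(as.integer(b), c(2, 2))
})

test_that("homogeneity test matches the hand-computed 2x2 example", {
  cmp <- chi2_homogeneity(c(10, 0), c(0, 10))
  # expected counts are all 5: chi2 = 4 * (5^2/5) = 20 on 1 dof
  expect_equal(cmp$chi2, 20)
  expect_equal(cmp$dof, 1)
  expect_equal(cmp$p, pchisq(20, 1, lower.tail = FALSE))
  expect_lt(abs(cmp$p - 7.7e-6), 5e-7)
})

test_that("chi-squared equals the brute-force sum((O-E)^2/E) oracle", {
  set.seed(42)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    a <- rpois(k, 5); b <- rpois(k, 5)
    keep <- (a + b) > 0
    if (sum(keep) < 2 || sum(a) == 0 || sum(b) == 0) next
    a2 <- a[keep]; b2 <- b[keep]
    # independent oracle: pooled-margin expected counts, explicit loops
    tot <- sum(a2) + sum(b2)
    chi2 <- 0
    for (j in seq_along(a2)) {
      ea <- sum(a2) * (a2[j] + b2[j]) / tot
      eb <- sum(b2) * (a2[j] + b2[j]) / tot
      chi2 <- chi2 + (a2[j] - ea)^2 / ea + (b2[j] - eb)^2 / eb
    }
    cmp <- chi2_homogeneity(a, b)
    expect_equal(cmp$chi2, chi2, tolerance = 1e-12)
    expect_equal(cmp$dof, sum(keep) - 1)
    expect_equal(cmp$p, pchisq(chi2, sum(keep) - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("identical distributions give chi2 0 and p 1", {
  cmp <- chi2_homogeneity(c(5, 10, 5), c(5, 10, 5))
  expect_equal(cmp$chi2, 0)
  expect_equal(cmp$p, 1)
  expect_error(chi2_homogeneity(c(0, 0), c(1, 2)), "zero total")
})

test_that("bins empty in both groups are pruned, one-sided zeros are kept", {
  with_zero <- chi2_homogeneity(c(5, 0, 7), c(3, 0, 9))
  pruned <- chi2_homogeneity(c(5, 7), c(3, 9))
  expect_equal(with_zero$chi2, pruned$chi2)
  expect_equal(with_zero$dof, 1)
  asym <- chi2_homogeneity(c(5, 0), c(3, 4))   # zero in one group only: signal
  expect_equal(asym$dof, 1)
  expect_gt(asym$chi2, 0)
})

test_that("the 50-50 test scores sign counts against equal expectation", {
  cmp <- chi2_5050(c(rep(1, 10), rep(-1, 10)))
  expect_equal(cmp$chi2, 0)
  expect_equal(cmp$p, 1)
  cmp <- chi2_5050(rep(2, 20))      # 20 positive, 0 non-positive
  expect_equal(cmp$chi2, 20)        # (20-10)^2/10 + (0-10)^2/10
  expect_equal(cmp$dof, 1)
  # zero counts as non-positive
  cmp0 <- chi2_5050(c(0, 0, 1, 1))
  expect_equal(cmp0$chi2, 0)
  expect_error(chi2_5050(numeric(0)), "no valid")
})

test_that("Bonferroni thresholds divide alpha by the comparison count", {
  expect_equal(bonferroni(0.05, 6), 0.05 / 6)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.01, 5), 0.002)
  expect_error(bonferroni(0.05, 0), "domain error")
  expect_error(bonferroni(0, 3), "domain error")
})

test_that("significance stars honor the adjusted thresholds", {
  cmp <- chi2_5050(rep(1, 20), n_comparisons = 5)
  expect_equal(cmp$significant_at, "0.01/n")
  expect_equal(cmp$bonferroni_alpha, 0.01)
  weak <- chi2_homogeneity(c(6, 4), c(4, 6), n_comparisons = 5)
  expect_equal(weak$significant_at, "none")
})

test_that("median p-value reproduces the repeat-experiment convention", {
  expect_equal(median_p(c(9e-4, 9e-6, 0.04)), 9e-4)
  expect_equal(median_p(c(2e-11, 0.002, 5e-4)), 5e-4)
  expect_equal(median_p(0.03), 0.03)
  expect_equal(median_p(c(0.01, NA, 0.03)), 0.02)   # even count after dropping
  expect_true(is.na(median_p(c(NA_real_, NA_real_))))
})

test_that("mass-to-molar conversion reproduces the tricaine concentrations", {
  expect_equal(round(molar_from_mass(160, 261.3)), 612)
  expect_equal(round(molar_from_mass(80, 261.3)), 306)
  expect_equal(molar_from_mass(261.3, 261.3), 1000)  # 1 g/L of itself is 1 mM
  expect_error(molar_from_mass(-1, 100), "domain error")
})

test_that("type-I error of the homogeneity test is near nominal", {
  # both groups drawn from identical behavioral parameters; quartile-binned
  # activity contrast at alpha = 0.05 should reject in about 5% of replicates
  sched <- period_schedule(period_length = 60)
  p <- larva_params(p_move = 0.5, optomotor_gain = 0)
  n_rep <- 200
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    sc <- simulate_scores(72, p, sched, seed = 1000 + r)
    a <- bin_scores(sc$activity[1:48], "activity_quartiles")
    b <- bin_scores(sc$activity[49:72], "activity_quartiles")
    cmp <- chi2_homogeneity(a, b)
    if (cmp$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.015)
  expect_lte(rate, 0.085)
})

test_that("rejection frequency is non-decreasing in the simulated effect", {
  sched <- period_schedule(period_length = 60)
  n_rep <- 60
  reject_rate <- function(delta) {
    hits <- 0L
    for (r in seq_len(n_rep)) {
      ctrl <- simulate_scores(48, larva_params(p_move = 0.5), sched,
                              seed = 2000 + r)
      trt <- simulate_scores(24, larva_params(p_move = 0.5 - delta), sched,
                             seed = 5000 + r)
      cmp <- chi2_homogeneity(bin_scores(trt$activity, "activity_quartiles"),
                              bin_scores(ctrl$activity, "activity_quartiles"))
      if (cmp$p < 0.05) hits <- hits + 1L
    }
    hits / n_rep
  }
  rates <- c(reject_rate(0), reject_rate(0.15), reject_rate(0.3))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)              # a 30-point activity drop is obvious
})

test_that("stats_report runs the contrast battery against the control", {
  sched <- period_schedule(period_length = 60)
  ctrl <- simulate_scores(24, larva_params(p_move = 0.5, optomotor_gain = 0.8),
                          sched, seed = 31)
  trt <- simulate_scores(24, larva_params(p_move = 0.05, optomotor_gain = 0.8),
                         sched, seed = 32)
  scores <- rbind(cbind(ctrl, plate = 1, row = 1, col = ctrl$id),
                  cbind(trt, plate = 1, row = 2, col = trt$id))
  gm <- data.frame(plate = 1, row = 1:2, group = c("control", "treated"))
  rep <- stats_report(scores, gm, control = "control", metric = "overall")
  expect_setequal(rep$contrast[rep$group == "treated"],
                  c("activity", "eo", "eo_5050"))
  act <- rep[rep$group == "treated" & rep$contrast == "activity", ]
  expect_lt(act$p, 0.01)                # near-immotile vs active: clear signal
})

test_that("experiment sets summarize to per-contrast median p", {
  r1 <- data.frame(group = "t", contrast = "activity", chi2 = 1, dof = 1,
                   p = 0.002, n_comparisons = 1, bonferroni_alpha = 0.05,
                   significant_at = "0.05/n")
  r2 <- r1; r2$p <- 5e-4
  r3 <- r1; r3$p <- 2e-11
  s <- experiment_set_summary(list(r1, r2, r3))
  expect_equal(s$median_p, 5e-4)
  expect_equal(s$n_experiments, 3)
})
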