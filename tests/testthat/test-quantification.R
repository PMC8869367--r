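test_that("comparative-Ct relative quantities follow the closed form", {
  vals <- rbind(target = c(25, 24, 23), ref = c(20, 20, 19))
  colnames(vals) <- c("C1", "C2", "C3")
  m <- ct_matrix(vals)
  rq <- relative_expression(m, "target", "ref", milestone = "C1")
  expect_identical(rq$rq[rq$sample_id == "C1"], 1)
  # C2: ddCt = (24-20) - (25-20) = -1 -> RQ 2
  expect_equal(rq$rq[rq$sample_id == "C2"], 2)
  # C3: ddCt = (23-19) - 5 = -1 -> RQ 2
  expect_equal(rq$rq[rq$sample_id == "C3"], 2)

  # a reference tracking the target exactly gives RQ 1 everywhere
  tracker <- ct_matrix(rbind(target = c(25, 24, 23), ref = c(22, 21, 20)),
                       condition = setNames(rep("CTRL", 3), c("C1", "C2", "C3")))
  rq2 <- relative_expression(tracker, "target", "ref", "C1")
  expect_equal(rq2$rq, rep(1, 3))

  expect_error(relative_expression(m, "target", "target", "C1"),
               class = "rgstab_error_BAD_GENE")
  expect_error(relative_expression(m, "target", "ref", "Z9"),
               class = "rgstab_error_BAD_SAMPLE")
})

test_that("per-donor fold changes cancel the milestone and are antisymmetric", {
  vals <- rbind(target = c(25, 24.5, 23, 24, 23.2, 22.4),
                ref = c(20, 20.1, 19.8, 20.2, 19.9, 20))
  colnames(vals) <- c("C1", "C2", "C3", "S1", "S2", "S3")
  m <- ct_matrix(vals)
  rq <- relative_expression(m, "target", "ref", "C1")
  pairs <- data.frame(donor = paste0("D", 1:3),
                      treated = c("S1", "S2", "S3"),
                      control = c("C1", "C2", "C3"))
  cr <- condition_ratio(rq, rq, pairs)
  # identical to direct within-donor 2^-ddCt
  direct <- vapply(1:3, function(i) {
    2^-((vals["target", pairs$treated[i]] - vals["ref", pairs$treated[i]]) -
          (vals["target", pairs$control[i]] - vals["ref", pairs$control[i]]))
  }, 0)
  expect_equal(cr$ratio, direct, tolerance = 1e-12)

  swapped <- condition_ratio(rq, rq,
                             data.frame(donor = pairs$donor,
                                        treated = pairs$control,
                                        control = pairs$treated))
  expect_equal(cr$ratio * swapped$ratio, rep(1, 3), tolerance = 1e-12)

  expect_error(condition_ratio(rq, rq,
                               data.frame(donor = "D9", treated = "S9",
                                          control = "C1")),
               "D9", class = "rgstab_error_UNPAIRED_DONOR")
})

test_that("identical treated and control samples give unit ratios", {
  vals <- rbind(target = c(25, 24, 23), ref = c(20, 21, 22))
  colnames(vals) <- c("C1", "C2", "C3")
  m <- ct_matrix(vals)
  rq <- relative_expression(m, "target", "ref", "C1")
  cr <- condition_ratio(rq, rq, data.frame(donor = 1:3,
                                           treated = c("C1", "C2", "C3"),
                                           control = c("C1", "C2", "C3")))
  expect_equal(cr$ratio, rep(1, 3))
})

test_that("one-sample t-test matches the closed form and applies the compound rule", {
  res <- one_sample_t_test(c(2.2, 2.0, 1.8), mu = 1)
  expect_equal(res$statistic, (2 - 1) / (0.2 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$statistic, 8.660254, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * stats::pt(-res$statistic, df = 2), tolerance = 1e-12)
  expect_equal(res$p_value, 0.01307, tolerance = 1e-3)
  expect_true(res$significant)  # mean 2 >= 2 and p <= 0.05

  res2 <- one_sample_t_test(c(1.1, 0.9, 1.0), mu = 1)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  expect_false(res2$significant)

  # significant p alone is not enough under the compound rule
  res3 <- one_sample_t_test(c(1.6, 1.5, 1.55), mu = 1)
  expect_lt(res3$p_value, 0.05)
  expect_false(res3$significant)
  expect_true(one_sample_t_test(c(1.6, 1.5, 1.55), mu = 1,
                                compound = FALSE)$significant)

  expect_error(one_sample_t_test(c(1, 1, 1)), class = "rgstab_error_DEGENERATE")
})

test_that("Grubbs test uses the closed-form critical value and flags one outlier", {
  g0 <- grubbs_test(c(-1, 0, 1))
  expect_equal(g0$critical, 1.1543, tolerance = 1e-4)
  expect_equal(g0$statistic, 1)
  expect_false(g0$significant)
  expect_true(is.na(g0$outlier_index))

  g1 <- grubbs_test(c(1, 1.02, 5))
  expect_true(g1$significant)
  expect_equal(g1$outlier_index, 3L)
  expect_equal(g1$outlier_value, 5)

  expect_error(grubbs_test(c(1, 2)), class = "rgstab_error_TOO_FEW_SAMPLES")
})

test_that("a noisy reference inflates between-donor spread of log fold changes", {
  # noiseless target, reference noise SD 0.5: the per-donor fold change uses
  # two independent reference draws, so SD of log2 ratio -> sqrt(2) * 0.5
  sigma_r <- 0.5
  sp <- synthetic_spec(n_genes = 3, n_donors = 300, conditions = c("CTRL", "SF"),
                       baseline = c(24, 20, 16),
                       noise_sd = c(0, sigma_r, 0.1), treatment_effect = 0,
                       sample_offset_sd = 0, spike_offset_sd = 0)
  m <- generate_panel(sp, seed = 4)$matrix
  rq <- relative_expression(m, "RG01", "RG02", milestone = "C1")
  pairs <- data.frame(donor = 1:300, treated = paste0("S", 1:300),
                      control = paste0("C", 1:300))
  cr <- condition_ratio(rq, rq, pairs)
  expect_equal(stats::sd(log2(cr$ratio)), sqrt(2) * sigma_r, tolerance = 0.1)
})
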