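test_that("coefficient of variation", {
  expect_equal(coefficient_of_variation(c(9, 10, 11)), 10)
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(0.40, 0.44, 0.42)), 4.7619, tolerance = 1e-4)
  expect_error(coefficient_of_variation(1), "at least 2")
})

test_that("paired t test matches hand decomposition and is antisymmetric", {
  r <- paired_t_test(c(1, 2, 3), c(2, 2, 4))
  expect_equal(r$t, -2)
  expect_equal(r$df, 2)
  r2 <- paired_t_test(c(2, 2, 4), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_equal(paired_t_test(c(1, 3), c(0, 0))$t, 2)
  deg <- paired_t_test(c(1, 2), c(1, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$t, 0)
})

test_that("Pearson r and OLS fit", {
  expect_equal(linear_fit(c(1, 2, 3), c(2, 4, 6)),
               list(slope = 2, intercept = 0, r = 1))
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  f <- linear_fit(c(1, 2, 3), c(1, 3, 4))
  expect_equal(f$slope, 1.5)
  expect_equal(f$intercept, -1 / 3)
  expect_equal(f$r, 0.981981, tolerance = 1e-6)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("one-way ANOVA with hand-checked decomposition", {
  a <- one_way_anova(list(c(1, 2, 3), c(11, 12, 13)))
  expect_equal(a$F, 150)
  expect_equal(c(a$df1, a$df2), c(1, 4))
  same <- one_way_anova(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$F, 0)
  # two-group ANOVA F equals the squared unpaired t statistic
  x <- c(3.1, 4.2, 5.0, 4.4); y <- c(5.3, 6.1, 5.8, 7.0)
  a2 <- one_way_anova(list(x, y))
  t2 <- stats::t.test(x, y, var.equal = TRUE)$statistic^2
  expect_equal(a2$F, unname(t2), tolerance = 1e-12)
})

test_that("Scheffe flags only genuinely shifted pairs", {
  set.seed(5)
  g1 <- rnorm(8); g2 <- rnorm(8); g3 <- rnorm(8) + 6
  s <- scheffe_posthoc(list(a = g1, b = g2, c = g3))
  sig <- s$significant
  names(sig) <- paste(s$group_i, s$group_j)
  expect_false(sig[["a b"]])
  expect_true(sig[["a c"]])
  expect_true(sig[["b c"]])
  none <- scheffe_posthoc(list(c(1, 2, 3), c(1, 2, 3)))
  expect_false(any(none$significant))
})

test_that("cohort report: identical sessions give zero SD, single session no tests", {
  rec <- make_session()
  m <- do.call(rbind, lapply(1:3, function(i) session_metrics(rec)))
  rep3 <- build_report(m)
  sds <- rep3$summary$sd[!is.na(rep3$summary$sd)]
  expect_true(all(sds == 0))
  expect_true(all(is.na(rep3$paired$p)))  # zero-variance differences flagged
  rep1 <- build_report(session_metrics(rec))
  expect_true(all(is.na(rep1$summary$sd)))
  expect_null(rep1$paired)
})

test_that("report on a disequilibrium cohort shows Kt_inst above Kt_bal", {
  co <- generate_cohort(list(BHD_hf = default_arm_configs()$BHD_hf),
                        n_per_arm = 6, seed = 3)
  cm <- cohort_metrics(co)
  rep <- build_report(cm$metrics, cm$urea)
  urea_kt <- rep$paired[rep$paired$solute == "urea" &
                        rep$paired$comparison == "kt_inst_l vs kt_bal_l", ]
  expect_gt(urea_kt$t, 0)
  expect_lt(urea_kt$p, 0.05)
  s <- rep$summary
  mi <- s$mean[s$metric == "kt_inst_l" & s$solute == "urea"]
  mb <- s$mean[s$metric == "kt_bal_l" & s$solute == "urea" & s$arm == "BHD_hf"]
  expect_gt(mi, mb)
})
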