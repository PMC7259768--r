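# Expected values below were frozen from direct independent evaluation
# of the closed-form expressions (see the corresponding formulas in the
# function documentation).

test_that("Colton plasma-water conversion divides by the water fraction", {
  expect_equal(to_plasma_water(1000, 7.0), 1080.964, tolerance = 1e-6)
  expect_equal(to_plasma_water(1000, 6.0), 1068.604, tolerance = 1e-6)
  expect_equal(to_plasma_water(500, 0), 500)
  expect_gt(to_plasma_water(123, 8), 123)
  expect_error(to_plasma_water(1000, 95), "water fraction")
  expect_error(to_plasma_water(-1, 7))
})

test_that("Bergstrom-Wehle hemoconcentration correction", {
  expect_equal(correct_hemoconcentration(400, 3, 70), 329.4117647, tolerance = 1e-9)
  expect_equal(correct_hemoconcentration(400, 0, 70), 400)
  expect_equal(correct_hemoconcentration(100, 2, 50), 100 / 1.2)
  expect_error(correct_hemoconcentration(400, 3, 0))
})

test_that("Tattersall rebound equilibration", {
  expect_equal(equilibrate_rebound(1000, 300, 240, 35), 349.6789, tolerance = 1e-6)
  expect_equal(equilibrate_rebound(1000, 1000, 240, 35), 1000)
  expect_equal(equilibrate_rebound(1000, 300, 240, 0), 300)
  # monotone increasing in tx when concentration fell
  peq <- vapply(c(0, 35, 50, 60, 110), function(tx)
    equilibrate_rebound(1000, 300, 240, tx), 0)
  expect_true(all(diff(peq) > 0))
})

test_that("logarithmic-mean TAC and its continuous limit", {
  expect_equal(tac_logmean(1000, 349.6789), 618.9167, tolerance = 1e-4)
  expect_equal(tac_logmean(800, 800), 800)
  expect_equal(tac_logmean(800, 800 * (1 + 1e-12)), 800)
  expect_equal(tac_logmean(100, 35), 61.91525, tolerance = 1e-6)
  x <- tac_logmean(700, 400)
  expect_true(x > 400 && x < 700)
  expect_error(tac_logmean(-1, 5))
})

test_that("balance TAC runs the full correction chain", {
  rec <- make_session(uf_l = 3)  # pre 1000 mg/L TP 7, post 400 mg/L TP 7.5
  pre_pw <- 1000 / (1 - 0.0107 * 7.0)
  post_pw <- 400 / (1 - 0.0107 * 7.5)
  p_cor <- post_pw / (1 + 3 / (0.2 * 70))
  p_eq <- pre_pw * (p_cor / pre_pw)^(240 / 275)
  expect_equal(tac_balance(rec, "urea"),
               (pre_pw - p_eq) / log(pre_pw / p_eq), tolerance = 1e-12)
  expect_equal(tac_balance(rec, "urea"), 693.6799, tolerance = 1e-4)
  # beta-2-microglobulin: same numbers, longer equilibration time
  p_eq_b <- pre_pw * (p_cor / pre_pw)^(240 / 350)
  rec_b <- make_session(solute = "b2m", uf_l = 3)
  expect_equal(tac_balance(rec_b, "b2m"),
               (pre_pw - p_eq_b) / log(pre_pw / p_eq_b), tolerance = 1e-12)
  expect_equal(tac_balance(rec_b, "b2m"), 757.9870, tolerance = 1e-4)
  # no removal and no UF collapses to the pre plasma-water value
  rec0 <- make_session(uf_l = 0, post = 100, tp_post = 7)
  expect_equal(tac_balance(rec0, "urea"), pre_pw, tolerance = 1e-9)
})

test_that("instant TAC uses uncorrected plasma-water values", {
  expect_equal(tac_instant(700, 400), 536.0821, tolerance = 1e-4)
  expect_equal(tac_instant(500, 500), 500)
  expect_equal(tac_instant(600, 300), 300 / log(2))
})

test_that("balance TAC is monotone in the pre-dialysis level and ordered", {
  base <- tac_balance(make_session(), "urea")
  up <- tac_balance(make_session(pre = 110), "urea")
  expect_gt(up, base)
  # ordering p_cor <= p_eq <= pre_pw for a falling session
  rec <- make_session()
  pre_pw <- 1000 / (1 - 0.0107 * 7)
  post_pw <- 400 / (1 - 0.0107 * 7.5)
  p_cor <- correct_hemoconcentration(post_pw, rec$uf_l, rec$bw_post_kg)
  p_eq <- equilibrate_rebound(pre_pw, p_cor, 240, 35)
  expect_true(p_cor <= p_eq && p_eq <= pre_pw)
})

test_that("missing per-sample total protein falls back with a warning", {
  rec <- make_session(tp_instant = NA_real_)
  w <- capture_warnings(m <- session_metrics(rec))
  expect_true(any(grepl("fallback", w)))
  expect_true(is.finite(m$dp_inst_mean))
})
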