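# Frozen expected values from direct evaluation of the closed forms.

test_that("Daugirdas second-generation spKt/V", {
  expect_equal(sp_ktv_daugirdas(1000, 350, 4, 3, 70), 1.264632, tolerance = 1e-6)
  expect_equal(sp_ktv_daugirdas(1000, 500, 4, 0, 70), -log(0.468), tolerance = 1e-12)
  # no-removal limit approaches -ln(1 - 0.008 t)
  eps <- 1e-9
  expect_equal(sp_ktv_daugirdas(1000, 1000 - eps, 4, 0, 70),
               -log(1 - 0.032), tolerance = 1e-6)
  expect_error(sp_ktv_daugirdas(1000, 30, 4.9, 0, 70), "implausible")
  expect_error(sp_ktv_daugirdas(1000, 1100, 4, 0, 70))
})

test_that("equilibrated Kt/V rate equation", {
  expect_equal(e_ktv(1.264632, 4), 1.104938, tolerance = 1e-6)
  expect_equal(e_ktv(0, 4), 0.03)
  expect_equal(e_ktv(1.5, 2.5), 1.17)
  expect_lt(e_ktv(1.2, 4), 1.2)
})

test_that("Leypoldt standardized weekly Kt/V", {
  expect_equal(std_ktv_leypoldt(1.52, 240, 3), 2.428155, tolerance = 1e-6)
  expect_equal(std_ktv_leypoldt(1.2, 240, 3), 2.160883, tolerance = 1e-6)
  # small-dose linear limit: stdKt/V ~ N * eKt/V
  expect_equal(std_ktv_leypoldt(0.001, 240, 3), 3 * 0.001, tolerance = 1e-3)
  # increasing in frequency and in per-session dose
  s <- vapply(1:7, function(n) std_ktv_leypoldt(1.3, 240, n), 0)
  expect_true(all(diff(s) > 0))
  e <- vapply(seq(0.2, 2, by = 0.2), function(x) std_ktv_leypoldt(x, 240, 3), 0)
  expect_true(all(diff(e) > 0))
})

test_that("Watson total body water", {
  expect_equal(watson_tbw("male", 60, 170, 70), 38.7454, tolerance = 1e-6)
  expect_equal(watson_tbw("female", 60, 160, 60), 29.803, tolerance = 1e-6)
  expect_error(watson_tbw("male", 0, 170, 70))
})

test_that("distribution volume from dialysate balance", {
  expect_equal(v_from_balance(24000, 1000, 350, 3), 32.30769, tolerance = 1e-6)
  expect_equal(v_from_balance(24000, 1000, 350, 0), 36.92308, tolerance = 1e-6)
  expect_error(v_from_balance(24000, 350, 1000, 3), "exceed")
  # algebraic inverse round-trip
  for (v in c(25, 32, 40)) {
    q <- v * (1000 - 350) + 1000 * 3
    expect_equal(v_from_balance(q, 1000, 350, 3), v, tolerance = 1e-12)
  }
})

test_that("Kt from eKt/V and the NSO dialysate prescription", {
  expect_equal(kt_from_ektv(1.41, 32), 45.12)
  expect_equal(kt_from_ektv(1, 30), 30)
  expect_equal(nso_dialysate_volume(38.7454), 22.791, tolerance = 1e-3)
  expect_equal(nso_dialysate_volume(34), 20, tolerance = 1e-12)
  expect_equal(nso_dialysate_volume(34, 0), 0)
})

test_that("urea_kinetics runs the chain on raw plasma values", {
  rec <- make_session()  # pre 100 mg/dl, post 40, t 4 h, UF 3, BW 70
  uk <- urea_kinetics(rec)
  sp <- sp_ktv_daugirdas(1000, 400, 4, 3, 70)
  expect_equal(uk$sp_ktv, sp)
  expect_equal(uk$e_ktv, e_ktv(sp, 4))
  expect_equal(uk$std_ktv, std_ktv_leypoldt(uk$e_ktv, 240, 3))
  # V from raw pre and the rebound-equilibrated raw post
  p_cor <- correct_hemoconcentration(400, 3, 70)
  p_eq <- equilibrate_rebound(1000, p_cor, 240, 35)
  expect_equal(uk$v_l, v_from_balance(24000, 1000, p_eq, 3))
  expect_equal(uk$kt_daug_l, uk$e_ktv * uk$v_l)
  expect_equal(uk$e_ktv_bal, uk$kt_bal_l / uk$v_l)
  expect_equal(uk$tbw_l, watson_tbw("male", 60, 170, 73))
})
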