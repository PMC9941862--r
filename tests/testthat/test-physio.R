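# Frozen expected values below were computed by direct independent
# evaluation of the closed forms (oxygen-transport chain evaluated step by
# step by hand / in a scratch session).

test_that("Severinghaus saturation matches the closed form and its limits", {
  expect_equal(severinghaus_saturation(100), 0.9774653, tolerance = 1e-6)
  expect_equal(severinghaus_saturation(450), 0.9997435, tolerance = 1e-6)
  expect_gt(severinghaus_saturation(1e6), 1 - 1e-9) # asymptote
  p <- seq(10, 600, by = 5)
  s <- severinghaus_saturation(p)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
  expect_error(severinghaus_saturation(0), "po2")
  expect_error(severinghaus_saturation(-10), "po2")
})

test_that("arterial O2 content combines bound and dissolved oxygen", {
  expect_equal(arterial_o2_content(100), 19.957, tolerance = 1e-4)
  # dissolved term only when hemoglobin is (nearly) absent
  p_nohb <- calib_params(hb = 1e-12)
  expect_equal(arterial_o2_content(200, p_nohb), 0.0031 * 200,
               tolerance = 1e-6)
  expect_true(all(diff(arterial_o2_content(seq(50, 500, 10))) > 0))
})

test_that("hyperoxic dHb ratio follows the constant-extraction chain", {
  expect_equal(hyperoxia_dhb_ratio(100, 100), 1)
  expect_equal(hyperoxia_dhb_ratio(100, 450), 0.74996, tolerance = 1e-4)
  # strictly decreasing in hyperoxic tension until saturation caps
  r <- vapply(seq(100, 500, 25), hyperoxia_dhb_ratio, numeric(1),
              po2_baseline = 100)
  expect_true(all(diff(r) < 0))
  expect_error(hyperoxia_dhb_ratio(100, 50), ">=")
  # fully saturated venous baseline is degenerate
  p_sat <- calib_params(oef0 = 1e-6)
  expect_error(hyperoxia_dhb_ratio(5000, 5000, p_sat), "degenerate|satur")
})

test_that("dHb ratio is invariant to consistent rescaling of Hb constants", {
  # doubling hb while halving phi leaves carrying capacity phi*hb and hence
  # the whole saturation chain unchanged
  a <- hyperoxia_dhb_ratio(100, 450, calib_params(hb = 15, phi = 1.34))
  b <- hyperoxia_dhb_ratio(100, 450, calib_params(hb = 30, phi = 0.67))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("M-value estimation is exact arithmetic and scale-linear", {
  expect_equal(m_value(0, 0.8), 0)
  expect_equal(m_value(0.02, 0.8), 0.10)
  for (k in c(0.5, 2, 7))
    expect_equal(m_value(k * 0.013, 0.71), k * m_value(0.013, 0.71))
  expect_error(m_value(0.02, 1), "dhb_ratio")
  # round trip through the hyperoxia forward model
  m <- 0.17
  r <- hyperoxia_dhb_ratio(100, 450)
  dbold <- m * (1 - r)
  expect_equal(m_value(dbold, r), m, tolerance = 1e-12)
})

test_that("Grubb coupling is the stated power law", {
  expect_equal(grubb_cbv_ratio(1), 1)
  expect_equal(grubb_cbv_ratio(1.9), 1.9^0.2, tolerance = 1e-12)
  expect_error(grubb_cbv_ratio(0), "cbf_ratio")
})

test_that("Davis forward model and its inversion are exact inverses", {
  expect_equal(forward_bold_hypercapnia(1, 1, 0.14), 0)
  expect_equal(forward_bold_hypercapnia(1.1, 0.95, 0.14), 0.049159,
               tolerance = 1e-5)
  expect_equal(invert_cbv(0, 0.14, 1), 1)
  expect_equal(invert_cbv(0.0491592, 0.14, 0.95), 1.1, tolerance = 1e-5)
  # monotone in volume for beta/alpha > 1
  v <- seq(0.9, 1.4, 0.05)
  expect_true(all(diff(forward_bold_hypercapnia(v, 0.95, 0.14)) > 0))
  expect_error(invert_cbv(0.2, 0.14, 0.95), "saturated")
  expect_error(invert_cbv(0.01, -0.1, 0.95), "m must")
})

test_that("inversion recovers volume on a parameter grid to 1e-9", {
  params <- calib_params()
  grid <- expand.grid(v = seq(0.8, 1.5, 0.05),
                      m = seq(0.05, 0.25, 0.05),
                      q = c(0.90, 0.92, 0.95, 0.97))
  db <- forward_bold_hypercapnia(grid$v, grid$q, grid$m, params)
  v_back <- invert_cbv(db, grid$m, grid$q, params)
  expect_lt(max(abs(v_back - grid$v)), 1e-9)
})

test_that("with beta = 1 and no volume change the Davis model reduces to the hyperoxia form", {
  # general model at v = 1: dBOLD = M (1 - q^beta); with beta = 1 this is
  # the same algebra as the hyperoxia simplification with ratio q
  m <- 0.12
  for (q in c(0.9, 0.95, 0.97)) {
    expect_equal(forward_bold_hypercapnia(1, q, m), m * (1 - q),
                 tolerance = 1e-14)
    expect_equal(m_value(m * (1 - q), q), m, tolerance = 1e-12)
  }
})

test_that("parameter validation and JSON round trip", {
  expect_error(calib_params(alpha = 0), "alpha")
  expect_error(calib_params(alpha = 1), "alpha")
  expect_error(calib_params(beta = -1), "beta")
  expect_error(calib_params(oef0 = 1.2), "oef0")
  expect_error(calib_params(cmro2_ratio = c("+5" = 1.3)), "CMRO2")
  p <- calib_params(oef0 = 0.35, cmro2_ratio = c("+5" = 0.94, "+10" = 0.89))
  expect_error(cmro2_ratio_for(p, "+3"), "no CMRO2")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  params_to_json(p, path)
  q <- params_from_json(path)
  expect_equal(unclass(q), unclass(p))
})
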