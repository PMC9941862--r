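test_that("slab labels tile the grid as specified", {
  lab <- make_slab(c(12, 9, 22))
  expect_equal(sort(unique(as.vector(lab$depth))), 0:20)
  # 20 in-cortex layers, one out-of-cortex slice on each side
  expect_equal(sum(lab$depth == 0), 2 * 12 * 9)
  counts <- table(lab$depth[lab$depth > 0])
  expect_true(all(counts == 12 * 9)) # equal voxel count per layer
  # ROI stripes partition the in-cortex voxels
  expect_true(all(lab$roi[lab$depth > 0] %in% 1:3))
  expect_true(all(lab$roi[lab$depth == 0] == 0))
  # veins concentrate at the superficial face
  expect_true(all(lab$depth[lab$vein] >= 19))
  expect_error(make_slab(c(5, 5, 10)), "too small")
})

test_that("ground truth interpolates the depth anchors", {
  lab <- small_slab()
  ge <- make_ground_truth(lab, "GE", jitter_sd = 0)
  se <- make_ground_truth(lab, "SE", jitter_sd = 0)
  expect_equal(unique(ge$m_true[lab$depth == 2]), 0.09)
  expect_equal(unique(ge$m_true[lab$depth == 19]), 0.21)
  expect_equal(unique(se$m_true[lab$depth == 19]), 0.16)
  expect_equal(unique(ge$cvr_true[lab$depth == 2]), 0.39)
  expect_equal(unique(ge$cvr_true[lab$depth == 19]), 0.64)
  expect_equal(unique(se$cvr_true[lab$depth == 2]), 0.18)
  # +10 volume change is depth-constant at the anchor
  expect_equal(unique(ge$dcbv10_true[lab$depth > 0]), 12.5)
  expect_equal(unique(se$dcbv10_true[lab$depth > 0]), 8.5)
  in_ctx <- lab$depth > 0
  expect_true(all(ge$m_true[in_ctx] >= 0))
  for (lev in names(ge$cbv_ratio_true))
    expect_true(all(ge$cbv_ratio_true[[lev]][in_ctx] >= 1))
})

test_that("per-condition volume ratios are Davis-consistent with CVR", {
  lab <- small_slab()
  ge <- make_ground_truth(lab, "GE", jitter_sd = 0)
  params <- calib_params()
  i <- which(lab$depth == 10)[1]
  m <- ge$m_true[i]
  b <- vapply(c("+3", "+5", "+8", "+10"), function(lev)
    forward_bold_hypercapnia(ge$cbv_ratio_true[[lev]][i],
                             cmro2_ratio_for(params, lev), m, params),
    numeric(1))
  # plateaus fall on a straight line in the CO2 step with slope cvr_true
  fit <- stats::lm(I(100 * b) ~ c(3, 5, 8, 10))
  expect_equal(unname(stats::coef(fit)[2]), ge$cvr_true[i],
               tolerance = 1e-10)
  # volume change grows monotonically with the CO2 step
  v <- vapply(c("+3", "+5", "+8", "+10"),
              function(lev) ge$cbv_ratio_true[[lev]][i], numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("jitter is multiplicative, seeded, and off when sd = 0", {
  lab <- small_slab()
  t0 <- make_ground_truth(lab, "GE", jitter_sd = 0)
  ta <- make_ground_truth(lab, "GE", jitter_sd = 0.05, seed = 9)
  tb <- make_ground_truth(lab, "GE", jitter_sd = 0.05, seed = 9)
  tc <- make_ground_truth(lab, "GE", jitter_sd = 0.05, seed = 10)
  expect_identical(ta, tb)
  expect_false(identical(ta$m_true, tc$m_true))
  # depth-deterministic without jitter: one value per layer
  expect_length(unique(t0$m_true[lab$depth == 5]), 1L)
  expect_gt(length(unique(ta$m_true[lab$depth == 5])), 1L)
})

test_that("simulated plateaus match the forward model in the clean limit", {
  b <- noiseless_session(c(6, 6, 22))
  blk <- volume_blocks(b$protocol)
  params <- calib_params()
  i <- which(b$labels$depth == 15 & b$labels$roi == 2)[1]
  ai <- arrayInd(i, dim(b$labels$depth))
  sig <- b$series$data[ai[1], ai[2], ai[3], ]
  s0 <- b$truth$s0
  base <- mean(sig[blk == "baseline"]) - s0 # drift-only offset at baseline
  for (lev in c("+5", "+10")) {
    expected <- forward_bold_hypercapnia(
      b$truth$cbv_ratio_true[[lev]][i], cmro2_ratio_for(params, lev),
      b$truth$m_true[i], params)
    got <- mean(sig[blk == paste0("hc", lev)] / s0 - 1)
    # drift contributes < 1% of s0; compare at the stated absolute level
    expect_lt(abs(got - expected), 1e-4 + 0.012)
  }
  # with drift disabled the block mean is exact to < 0.01% absolute
  b2 <- simulate_session(b$labels, "GE", tsnr = Inf, transition_tau = 0,
                         gas_noise_sd = 0, jitter_sd = 0, drift_amp = 0,
                         seed = 5)
  sig2 <- b2$series$data[ai[1], ai[2], ai[3], ]
  for (lev in c("+5", "+10")) {
    expected <- forward_bold_hypercapnia(
      b2$truth$cbv_ratio_true[[lev]][i], cmro2_ratio_for(params, lev),
      b2$truth$m_true[i], params)
    got <- mean(sig2[blk == paste0("hc", lev)] / b2$truth$s0 - 1)
    expect_lt(abs(got - expected), 1e-4)
  }
  ho <- mean(sig2[blk == "ho+350"] / b2$truth$s0 - 1)
  expect_lt(abs(ho - b2$truth$m_true[i] * (1 - hyperoxia_dhb_ratio(100, 450))),
            1e-4)
})

test_that("zero ground truth yields pure noise plus drift", {
  lab <- small_slab(c(6, 6, 22))
  tr <- make_ground_truth(lab, "GE", jitter_sd = 0)
  in_ctx <- lab$depth > 0
  tr$m_true[in_ctx] <- 0
  tr$cvr_true[in_ctx] <- 0
  for (lev in names(tr$cbv_ratio_true)) tr$cbv_ratio_true[[lev]][in_ctx] <- 1
  p <- make_protocol()
  g <- make_gas_traces(p, 0, 0)
  ser <- simulate_bold(tr, g, p, tsnr = Inf, drift_amp = 0, seed = 1)
  expect_true(all(ser$data == tr$s0))
  ser2 <- simulate_bold(tr, g, p, tsnr = 100, drift_amp = 0, seed = 1)
  resid <- ser2$data - tr$s0
  expect_equal(stats::sd(resid), tr$s0 / 100, tolerance = 0.01)
})

test_that("simulation is bit-identical under a fixed seed", {
  lab <- small_slab(c(5, 5, 22))
  tr <- make_ground_truth(lab, "GE", seed = 2)
  p <- make_protocol()
  g <- make_gas_traces(p, seed = 3)
  a <- simulate_bold(tr, g, p, tsnr = 40, seed = 7)
  b <- simulate_bold(tr, g, p, tsnr = 40, seed = 7)
  expect_identical(a, b)
  c_ <- simulate_bold(tr, g, p, tsnr = 40, seed = 8)
  expect_false(identical(a$data, c_$data))
  expect_error(simulate_bold(tr, g, p, tsnr = 0), "tsnr")
})

test_that("physio traces support rate extraction and motion is 6-column", {
  p <- make_protocol()
  ph <- make_physio_traces(p, seed = 4)
  expect_named(ph, c("respiration", "pulse"))
  expect_equal(attr(ph, "fs"), 50)
  vt <- volume_times(p)
  r <- rvt(ph$respiration, 50, vt)
  bb <- bpm(ph$pulse, 50, vt)
  expect_length(r, p$n_volumes)
  expect_true(all(bb > 55 & bb < 80)) # around the 66 bpm design rate
  mot <- make_motion_params(p$n_volumes, seed = 4)
  expect_equal(dim(mot), c(820L, 6L))
  expect_identical(mot, make_motion_params(p$n_volumes, seed = 4))
})
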