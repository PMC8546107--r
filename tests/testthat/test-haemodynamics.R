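test_that("average_phase averages whole pulse cycles", {
  expect_equal(average_phase(rep(0.5, 100), duration_s = 2), 0.5)

  # zero-mean oscillation over exactly 2 cycles
  t <- seq(0, 2, length.out = 401)[-401]
  expect_equal(average_phase(0.5 + 0.2 * sin(2 * pi * t), duration_s = 2,
                             pulse_period_s = 1),
               0.5, tolerance = 1e-10)

  # sampled pulse waveform: mean over whole cycles matches a direct
  # sum/count over the retained samples
  set.seed(4)
  period <- 0.9
  dur <- 2.5  # 2 whole cycles + a partial one
  tt <- seq(0, dur, length.out = 250)
  wave <- 0.4 + 0.15 * sin(2 * pi * tt / period) + rnorm(250, 0, 0.01)
  n_keep <- floor(250 * 2 * period / dur)
  expect_equal(average_phase(wave, dur, period),
               sum(wave[1:n_keep]) / n_keep)

  expect_error(average_phase(numeric(0), 1), "empty")
  expect_error(average_phase(c(0.4, 0.5), duration_s = 0.5,
                             pulse_period_s = 0.9), "one pulse cycle")
})

test_that("doppler_velocity matches direct evaluation of the phase equation", {
  k <- doct_constants(wavelength_m = 8e-7, tau_s = 1e-4, n_blood = 1.35,
                      dalpha_rad = 0.01, beta_deg = 0)
  expect_equal(doppler_velocity(0, k), 0)
  expect_equal(doppler_velocity(0.5, k), 0.02357851, tolerance = 1e-6)
  # halving cos(beta) doubles velocity
  expect_equal(doppler_velocity(0.5, k, beta_deg = 60),
               2 * doppler_velocity(0.5, k), tolerance = 1e-12)

  # oracle equivalence over random constants
  set.seed(10)
  for (i in 1:50) {
    lam <- runif(1, 6e-7, 1.1e-6); tau <- runif(1, 1e-5, 2e-4)
    n <- runif(1, 1.3, 1.45); da <- runif(1, 0.002, 0.03)
    beta <- runif(1, 0, 80); dphi <- runif(1, -2, 2)
    kk <- doct_constants(lam, tau, n, da, beta)
    expect_equal(doppler_velocity(dphi, kk),
                 oracle_velocity(dphi, lam, n, tau, da, beta * pi / 180),
                 tolerance = 1e-12)
  }
})

test_that("doppler_velocity is homogeneous in its arguments", {
  set.seed(11)
  base <- doct_constants(8.4e-7, 2.5e-5, 1.38, 0.0095, 30)
  v0 <- doppler_velocity(0.7, base)
  for (i in 1:20) {
    s <- runif(1, 0.5, 2)
    expect_equal(doppler_velocity(0.7 * s, base), v0 * s)
    expect_equal(
      doppler_velocity(0.7, doct_constants(8.4e-7 * s, 2.5e-5, 1.38,
                                           0.0095, 30)), v0 * s)
    expect_equal(
      doppler_velocity(0.7, doct_constants(8.4e-7, 2.5e-5 * s, 1.38,
                                           0.0095, 30)), v0 / s)
    expect_equal(
      doppler_velocity(0.7, doct_constants(8.4e-7, 2.5e-5, 1.38,
                                           0.0095 * s, 30)), v0 / s)
  }
})

test_that("degenerate Doppler angle raises an error", {
  expect_error(doct_constants(beta_deg = 89.9), "ill-conditioned")
  k <- doct_constants(beta_deg = 0)
  expect_error(doppler_velocity(0.5, k, beta_deg = 90), "floor")
})

test_that("vessel_flow is the circular-lumen cross-section times velocity", {
  expect_equal(vessel_flow(100, 0), 0)
  expect_equal(vessel_flow(100, 0.02358), 11.11181, tolerance = 1e-5)
  expect_equal(vessel_flow(40, 0.010), 0.7539822, tolerance = 1e-6)
  # quadratic in D
  set.seed(12)
  for (i in 1:20) {
    d <- runif(1, 40, 200); v <- runif(1, 0, 0.05)
    expect_equal(vessel_flow(d, v), 4 * vessel_flow(d / 2, v),
                 tolerance = 1e-12)
    expect_equal(vessel_flow(d, v), oracle_flow_ul_min(d, v),
                 tolerance = 1e-12)
  }
  expect_error(vessel_flow(0, 0.01), "positive")
  expect_error(vessel_flow(-10, 0.01), "positive")
})

test_that("total flow sums per-vessel flows by kind and averages the totals", {
  v <- fixture_vessel_table()
  res <- total_retinal_blood_flow(v)
  # brute-force per-vessel loop
  qa <- 0; qv <- 0
  for (i in seq_len(nrow(v))) {
    q <- oracle_flow_ul_min(v$diameter_um[i], v$velocity_m_s[i])
    if (v$kind[i] == "A") qa <- qa + q else qv <- qv + q
  }
  expect_equal(res$trbf_arterial, qa)
  expect_equal(res$trbf_venous, qv)
  expect_equal(res$trbf, (qa + qv) / 2)
  expect_equal(nrow(res$per_vessel), 6)
})

test_that("the caliper filter excludes strictly-below-threshold vessels", {
  v <- fixture_vessel_table()
  v$diameter_um[2] <- 39.9   # just below
  v$diameter_um[3] <- 40.0   # exactly at: kept
  res <- total_retinal_blood_flow(v)
  expect_equal(res$n_excluded, 1)
  expect_false(res$per_vessel$included[2])
  expect_true(res$per_vessel$included[3])
  kept <- res$per_vessel[res$per_vessel$included &
                           res$per_vessel$kind == "A", ]
  expect_equal(res$trbf_arterial, sum(kept$flow_ul_min))

  # losing all veins to the filter is an incomplete circulation
  v2 <- fixture_vessel_table()
  v2$diameter_um[v2$kind == "V"] <- 35
  expect_error(total_retinal_blood_flow(v2), "incomplete circulation")
})

test_that("phase input and per-vessel beta overrides reach the velocity", {
  k <- doct_constants(beta_deg = 0)
  v <- fixture_vessel_table()
  v$velocity_m_s <- NULL
  v$dphi_rad <- c(0.03, -0.025, 0.02, 0.018, 0.015, 0.012)
  v$beta_deg <- c(NA, NA, 60, NA, NA, NA)
  res <- total_retinal_blood_flow(v, k)
  expect_equal(res$per_vessel$velocity_m_s[1],
               doppler_velocity(0.03, k))
  # negative phase folds to positive velocity
  expect_equal(res$per_vessel$velocity_m_s[2],
               doppler_velocity(0.025, k))
  expect_equal(res$per_vessel$velocity_m_s[3],
               doppler_velocity(0.02, k, beta_deg = 60))
  expect_error(total_retinal_blood_flow(v, const = NULL), "required")
})
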