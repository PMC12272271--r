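test_that("phantom spec validates its geometry and parameters", {
  expect_error(phantom_spec(), "seed is mandatory")
  expect_error(phantom_spec(seed = 1, dim = 32), "r_wm < r_csf")
  expect_error(small_spec(kappa = 1.2), "kappa")
  expect_error(small_spec(beta_resp = -1), "amplitudes")
  # vessel volume cap
  expect_error(make_phantom_anatomy(small_spec(n_pial = 200, pial_radius = 3)),
               "20%")
})

test_that("anatomy partitions the grid and plants vessels at the interface", {
  truth <- small_truth()
  lab <- truth$labels$labels
  expect_true(all(lab %in% 0:3))
  expect_equal(sum(lab == 0) + sum(lab == 1) + sum(lab == 2) + sum(lab == 3),
               prod(dim(lab)))
  # vessels live in GM or the interface shell just outside it
  r <- truth$radius
  sp <- truth$spec
  expect_true(all(r[truth$vessel_mask] > sp$r_wm &
                    r[truth$vessel_mask] <= sp$r_csf + 1.5))
  # coupling is positive at vessels and decays with distance
  expect_true(all(truth$coupling[truth$vessel_mask] == sp$beta_resp))
  far <- truth$brain_mask & truth$dist_vessel > 5
  expect_true(all(truth$coupling[far] < sp$beta_resp * exp(-5 / sp$lambda_vox) + 1e-9))
  # analytic depth closed form
  gm <- lab == 2
  expect_equal(truth$depth_true[gm],
               (sp$r_csf^3 - r[gm]^3) / (sp$r_csf^3 - sp$r_wm^3))
  expect_true(all(truth$depth_true[gm] >= 0 & truth$depth_true[gm] <= 1))
})

test_that("respiratory trace: sampling rate, determinism, deep-breath timing", {
  sp <- small_spec()
  tr1 <- make_resp_trace(sp, "natural", n_vol = 10)
  expect_equal(nrow(tr1$trace), round(10 * sp$tr_s * 500))
  tr2 <- make_resp_trace(sp, "natural", n_vol = 10)
  expect_identical(tr1$trace, tr2$trace)

  db <- make_resp_trace(sp, "deep_breath", n_trials = 2)
  expect_equal(db$n_vol, 6 + 2 * 12)
  ev <- db$events
  expect_equal(ev$duration, rep(3 * 2 * sp$tr_s, 2))
  # within a task block, belt maxima are one 12.164 s cycle apart
  seg <- db$trace[db$trace$time_s >= ev$onset[1] &
                    db$trace$time_s < ev$onset[1] + ev$duration[1], ]
  P <- 2 * sp$tr_s
  pk <- sapply(0:2, function(cyc) {
    w <- seg[seg$time_s >= ev$onset[1] + cyc * P &
               seg$time_s < ev$onset[1] + (cyc + 1) * P, ]
    w$time_s[which.max(w$amplitude)]
  })
  expect_equal(diff(pk), rep(P, 2), tolerance = 0.05)

  bh <- make_resp_trace(sp, "breath_hold", n_trials = 2)
  expect_equal(nrow(bh$events), 2)
  expect_equal(bh$events$duration, rep(5 * sp$tr_s, 2))
  expect_error(make_resp_trace(sp, "deep_breath", n_trials = 0),
               "shorter than one trial")
})

test_that("time series generator is exactly reproducible from (spec, seed)", {
  sp <- small_spec(n_vol = 20)
  truth <- make_phantom_anatomy(sp)
  resp <- make_resp_trace(sp, "natural")
  a <- make_phantom_timeseries(truth, resp)
  b <- make_phantom_timeseries(truth, resp)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$motion, b$motion)
  # different run offset gives a different realisation
  c_ <- make_phantom_timeseries(truth, resp, seed_offset = 99)
  expect_false(identical(a$series$data, c_$series$data))
})

test_that("noiseless generative algebra: corrected VAPER recovers the planted response", {
  sp <- small_spec(noise_sd_pct = 0, motion_spike_vols = integer(0),
                   outlier_spike_vols = integer(0), beta_resp = 0,
                   macro_amp_bold = 0, macro_amp_vaper = 0, n_vol = 48)
  truth <- make_phantom_anatomy(sp)
  resp <- make_resp_trace(sp, "natural")
  sim <- make_phantom_timeseries(truth, resp)
  st <- split_conditions(sim$series)
  v <- compute_vaper(st$control, st$nulled, corrected = TRUE)
  g <- task_regressor(sim$design, v$time_s)
  # voxel with beta_bold = 0 (outside sector, but give it a known beta_cbv):
  # at mid depth inside the sector, beta_bold = beta_cbv = neural amplitude,
  # and (C - N)/C = 1 - kappa*(1 - a g)/(1 + a g)
  idx <- which(truth$roi_sector & abs(truth$depth_true - sp$neural_peak_depth) < 0.02,
               arr.ind = TRUE)[1, ]
  a <- sim$truth_betas$beta_cbv[idx[1], idx[2], idx[3]] / 100
  ts_v <- v$data[idx[1], idx[2], idx[3], ]
  # control = B (1 + a g), nulled = B kappa (1 + (a - a) g) = B kappa, so
  # (C - N)/C = 1 - kappa / (1 + a g)
  pred <- 1 - sp$kappa / (1 + a * g)
  expect_equal(ts_v, pred, tolerance = 1e-12)
  # with kappa = 0.5 the percent change relative to baseline is a*g up to the
  # control-division attenuation 1/(1 + a g)
  base <- 1 - sp$kappa
  pct <- (ts_v - base) / base * 100
  expect_equal(pct, 100 * a * g / (1 + a * g), tolerance = 1e-10)

  # null coupling + noiseless: respiration map on rest volumes is zero
  rest <- v$time_index[g == 0]
  m <- respiration_effect_map(v, variation_idx = rest[1:3], truth$brain_mask,
                              units = "raw", stable_idx = rest[-(1:3)])
  expect_lt(max(m$map), 1e-10)
})

test_that("MT phantom reproduces the planted GM/WM ratio contrast", {
  sp <- small_spec(noise_sd_pct = 0)
  truth <- make_phantom_anatomy(sp)
  mt <- make_phantom_mt_series(truth, n_vol = 8)
  st <- split_conditions(mt, c("control", "mt"))
  anat <- compute_mt_anat(st$control, st$mt)
  gm <- truth$labels$labels == 2
  wm <- truth$labels$labels == 1
  # closed form (1 - m)/m from the generator's MT ratios
  expect_equal(unique(round(anat$data[, , , 1][gm], 10)), (1 - 0.75) / 0.75)
  expect_equal(unique(round(anat$data[, , , 1][wm], 10)), (1 - 0.55) / 0.55)
  # with noise, the contrast holds within tolerance
  sp2 <- small_spec()
  truth2 <- make_phantom_anatomy(sp2)
  mt2 <- make_phantom_mt_series(truth2, n_vol = 20)
  st2 <- split_conditions(mt2, c("control", "mt"))
  anat2 <- compute_mt_anat(st2$control, st2$mt)
  expect_equal(mean(anat2$data[, , , 1][gm]), 1 / 3, tolerance = 0.02)
  expect_gt(mean(anat2$data[, , , 1][wm]), mean(anat2$data[, , , 1][gm]))
})

test_that("respiration regressor reflects belt deviations per volume", {
  sp <- small_spec()
  tr <- sp$tr_s
  trace <- tibble::tibble(time_s = seq(0, 10 * tr - 1 / 500, by = 1 / 500),
                          amplitude = 50)
  trace$amplitude[trace$time_s >= 2 * tr & trace$time_s < 3 * tr] <- 80
  h <- resp_regressor(trace, tr, 10)
  expect_equal(h[3], 30 / 50, tolerance = 0.01)
  expect_equal(h[5], 0, tolerance = 1e-6)
  # lag shifts the window
  h2 <- resp_regressor(trace, tr, 10, lag_s = tr)
  expect_equal(h2[4], 30 / 50, tolerance = 0.01)
})
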