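make_boxcar_series <- function(amp_pct, d = c(3, 3, 1), n_vol = 24, tr = 1,
                               base = 100, noise = 0, seed = 31) {
  des <- block_design(data.frame(onset = c(6, 18), duration = 6, label = "task"),
                      tr_s = tr, n_vol = n_vol)
  g <- task_regressor(des, (seq_len(n_vol) - 1) * tr)
  set.seed(seed)
  dat <- array(0, c(d, n_vol))
  for (v in seq_len(n_vol))
    dat[, , , v] <- base * (1 + amp_pct / 100 * g[v]) +
      rnorm(prod(d), sd = noise)
  list(series = volume_series(dat, tr_s = tr), design = des, g = g)
}

test_that("GLM recovers the boxcar amplitude exactly on noiseless data", {
  bx <- make_boxcar_series(2)
  mask <- array(TRUE, c(3, 3, 1))
  act <- fit_block_glm(bx$series, bx$design, mask, hrf = "none")
  expect_equal(unique(round(as.vector(act$beta), 10)), 2)
  # scale invariance of the percent units
  bx2 <- bx
  bx2$series$data <- bx2$series$data * 7.3
  act2 <- fit_block_glm(bx2$series, bx$design, mask, hrf = "none")
  expect_equal(act2$beta, act$beta, tolerance = 1e-10)
})

test_that("GLM null case: drift-only series gives near-zero beta and small |t|", {
  d <- c(3, 3, 1)
  n_vol <- 40
  des <- block_design(data.frame(onset = c(8, 24), duration = 8, label = "task"),
                      tr_s = 1, n_vol = n_vol)
  set.seed(32)
  tt <- seq_len(n_vol) - 1
  drift <- 100 + 0.05 * tt + 0.002 * tt^2
  dat <- array(rep(drift, each = prod(d)), c(d, n_vol)) +
    array(rnorm(prod(d) * n_vol, sd = 0.2), c(d, n_vol))
  s <- volume_series(dat, tr_s = 1)
  act <- fit_block_glm(s, des, array(TRUE, d), drift_order = 2)
  expect_lt(max(abs(act$beta), na.rm = TRUE), 0.5)
  expect_lt(median(abs(act$t), na.rm = TRUE), 2.5)
})

test_that("GLM errors on a rank-deficient design and drops censored rows", {
  d <- c(2, 2, 1)
  n_vol <- 20
  # task spanning the whole run is collinear with the intercept
  des_bad <- block_design(data.frame(onset = 0, duration = 20, label = "task"),
                          tr_s = 1, n_vol = n_vol)
  s <- volume_series(array(100, c(d, n_vol)), tr_s = 1)
  expect_error(fit_block_glm(s, des_bad, array(TRUE, d), drift_order = 0),
               "rank-deficient")

  # censored rows excluded: corrupt a volume, censor it, estimate unaffected
  bx <- make_boxcar_series(2)
  bx$series$data[, , , 5] <- 5000
  bx$series$censored[5] <- TRUE
  act <- fit_block_glm(bx$series, bx$design, array(TRUE, c(3, 3, 1)))
  expect_equal(unique(round(as.vector(act$beta), 8)), 2)
})

test_that("double-gamma regressor has unit peak and delays the boxcar", {
  des <- block_design(data.frame(onset = 12, duration = 12, label = "task"),
                      tr_s = 2, n_vol = 30)
  tt <- (0:29) * 2
  h <- laminaresp:::make_task_regressor(des, tt, "double_gamma")
  expect_gt(max(h), 0.95) # unit-peak normalisation, sampled near the plateau
  expect_lt(h[7], 0.5)       # t = 12 s, onset: response not yet up
  expect_true(all(diff(h[7:11]) > 0)) # haemodynamic rise through the block
  expect_gt(which.max(h), 9) # peak delayed well past the onset
})

test_that("top-fraction exclusion mask follows order statistics and ties", {
  d <- c(10, 10, 1)
  mask <- array(TRUE, d)
  vals <- array(1:100, d)
  ex <- exclusion_mask_topfrac(vals, mask, 0.10)
  expect_equal(sort(vals[ex]), 91:100)
  expect_equal(sum(ex), 10)

  # constant map: everything ties at the threshold -> all masked + warning
  cst <- array(5, d)
  expect_warning(ex2 <- exclusion_mask_topfrac(cst, mask, 0.10), "tie")
  expect_true(all(ex2[mask]))

  expect_error(exclusion_mask_topfrac(vals, mask, 0), "fraction")
  expect_error(exclusion_mask_topfrac(vals, mask, 1), "fraction")
  # mask size bound: |excluded| / |mask| >= fraction
  set.seed(33)
  vals2 <- array(rnorm(100), d)
  ex3 <- exclusion_mask_topfrac(vals2, mask, 0.25)
  expect_gte(sum(ex3) / sum(mask), 0.25)
})

test_that("laminar profile: constant field, oracle equality, order invariance", {
  set.seed(34)
  d <- c(8, 8, 8)
  depth <- array(runif(prod(d)), d)
  roi <- array(runif(prod(d)) > 0.3, d)
  vals <- array(1, d)
  p <- extract_laminar_profile(vals, depth, roi, n_bins = 10)
  expect_true(all(p$mean_pct == 1))
  expect_true(all(p$sem_pct[p$n_vox >= 2] == 0))

  vals2 <- array(rnorm(prod(d), 2), d)
  p2 <- extract_laminar_profile(vals2, depth, roi, n_bins = 10)
  o <- oracle_profile(vals2, depth, roi, 10)
  expect_equal(p2$depth_bin, o$depth_bin)
  expect_equal(p2$mean_pct, o$mean_pct, tolerance = 1e-12)
  expect_equal(p2$sem_pct, o$sem_pct, tolerance = 1e-12)
  expect_equal(p2$n_vox, o$n_vox)
  expect_equal(sum(p2$n_vox), sum(roi))

  # voxel-order invariance: permuting the array layout does not change bins
  perm <- aperm(vals2, c(2, 3, 1))
  p3 <- extract_laminar_profile(perm, aperm(depth, c(2, 3, 1)),
                                aperm(roi, c(2, 3, 1)), n_bins = 10)
  expect_equal(p3$mean_pct, p2$mean_pct, tolerance = 1e-12)

  # exclusion produces the after-curve; fully excluded ROI errors
  excl <- array(TRUE, d)
  expect_error(extract_laminar_profile(vals2, depth, roi, 10, excl),
               "entirely inside")
  excl2 <- array(runif(prod(d)) > 0.5, d)
  p4 <- extract_laminar_profile(vals2, depth, roi, 10, excl2)
  expect_setequal(unique(p4$excluded), c(TRUE, FALSE))
  after <- p4[p4$excluded, ]
  expect_equal(sum(after$n_vox), sum(roi & !excl2))
})

test_that("superficial-bias metrics: argmax, flat profile, peak shift", {
  mkprof <- function(means, excluded = FALSE) {
    tibble::tibble(depth_bin = (seq_along(means) - 0.5) / length(means),
                   mean_pct = means, sem_pct = 0.1,
                   n_vox = 10L, excluded = excluded)
  }
  # monotone decreasing from CSF: peak at most superficial bin
  p <- mkprof(seq(2, 0.1, length.out = 10))
  class(p) <- c("laminar_profile", class(p))
  b <- superficial_bias(p)
  expect_equal(b$peak_depth, 0.05)
  # flat profile: surface/mid ratio 1
  pf <- mkprof(rep(1.5, 10))
  class(pf) <- c("laminar_profile", class(pf))
  expect_equal(superficial_bias(pf)$surface_mid_ratio, 1)
  # before/after pair: signed peak shift
  pair <- rbind(mkprof(c(3, 2.5, 2, 1, 1.2, 1.3, 1.1, 1, 0.9, 0.8), FALSE),
                mkprof(c(0.5, 0.6, 0.8, 1, 1.6, 1.7, 1.2, 1, 0.9, 0.8), TRUE))
  class(pair) <- c("laminar_profile", class(pair))
  bb <- superficial_bias(pair)
  expect_equal(nrow(bb), 2)
  expect_gt(attr(bb, "peak_shift"), 0)
  expect_lt(bb$surface_mid_ratio[bb$excluded],
            bb$surface_mid_ratio[!bb$excluded])
  # too few bins
  short <- mkprof(c(1, 2, 3))
  class(short) <- c("laminar_profile", class(short))
  expect_error(superficial_bias(short), "at least 5")
})
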