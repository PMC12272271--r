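test_that("outlier fraction is zero on constant series and invariant to affine maps", {
  d <- c(4, 4, 2)
  mask <- array(TRUE, d)
  s <- volume_series(array(100, c(d, 12)), tr_s = 1)
  of <- outlier_fraction(s, mask)
  expect_true(all(of$fraction == 0))

  set.seed(11)
  s2 <- volume_series(array(rnorm(prod(d) * 20, 100), c(d, 20)), tr_s = 1)
  of2 <- outlier_fraction(s2, mask)
  expect_true(all(of2$fraction >= 0 & of2$fraction <= 1))
  # per-voxel affine rescaling leaves fractions unchanged (order >= 1 trend)
  a <- array(runif(prod(d), 0.5, 3), d)
  b <- array(runif(prod(d), -5, 5), d)
  s3 <- s2
  s3$data <- sweep(sweep(s2$data, 1:3, a, "*"), 1:3, b, "+")
  of3 <- outlier_fraction(s3, mask)
  expect_equal(of3$fraction, of2$fraction, tolerance = 1e-12)

  expect_error(outlier_fraction(s2, array(FALSE, d)), "empty")
  short <- volume_series(array(1, c(d, 3)), tr_s = 1)
  expect_error(outlier_fraction(short, mask), "fewer volumes")
})

test_that("outlier fraction detects planted spikes and matches the brute-force oracle", {
  set.seed(12)
  d <- c(5, 5, 4) # 100 voxels
  nt <- 30
  mask <- array(TRUE, d)
  dat <- array(rnorm(prod(d) * nt, mean = 100, sd = 1), c(d, nt))
  spiked <- sample(prod(d), 5)
  for (v in spiked) {
    idx <- arrayInd(v, d)
    dat[idx[1], idx[2], idx[3], 7] <- dat[idx[1], idx[2], idx[3], 7] + 20
  }
  s <- volume_series(dat, tr_s = 1)
  of <- outlier_fraction(s, mask)
  expect_gte(of$fraction[7], 0.05)
  expect_lt(max(of$fraction[-7]), of$fraction[7])
  oracle <- oracle_outlier_fraction(dat, mask, s$time_s)
  expect_equal(of$fraction, oracle, tolerance = 1e-10)
})

test_that("variation-point selection counts, tie-breaks and bounds", {
  frac <- tibble::tibble(volume = 1:40, fraction = seq(0.001, 0.04, length.out = 40))
  sel <- select_variation_points(frac, 0.15)
  expect_length(sel, 6) # round(0.15 * 40)
  expect_equal(sort(sel), 35:40)
  expect_equal(sort(c(sel, attr(sel, "stable"))), 1:40)

  # ties broken toward earlier time indices
  frac2 <- tibble::tibble(volume = 1:10, fraction = rep(0.5, 10))
  sel2 <- select_variation_points(frac2, 0.2)
  expect_equal(sort(sel2), 1:2)

  # minimum of one point
  frac3 <- tibble::tibble(volume = 1:5, fraction = runif(5))
  expect_length(select_variation_points(frac3, 0.15), 1)

  expect_error(select_variation_points(frac, 0), "top_fraction")
  expect_error(select_variation_points(frac, 1), "top_fraction")
})

test_that("respiration-effect map: hand values, identity, oracle equality", {
  d <- c(2, 2, 1)
  mask <- array(TRUE, d)
  # stable volumes at 100; variation volumes at 110 and 94 -> raw 8, pct 8
  dat <- array(100, c(d, 6))
  dat[, , , 5] <- 110
  dat[, , , 6] <- 94
  s <- volume_series(dat, tr_s = 1)
  m_raw <- respiration_effect_map(s, variation_idx = 5:6, mask, units = "raw")
  m_pct <- respiration_effect_map(s, variation_idx = 5:6, mask, units = "percent")
  expect_equal(unique(as.vector(m_raw$map)), 8)
  expect_equal(unique(as.vector(m_pct$map)), 8)
  expect_equal(m_raw$n_variation, 2)

  # variation points identical to stable mean -> all-zero map
  dat2 <- array(55, c(d, 6))
  s2 <- volume_series(dat2, tr_s = 1)
  expect_true(all(respiration_effect_map(s2, 5:6, mask, "raw")$map == 0))

  # exact equality with the two-loop oracle on random arrays
  set.seed(13)
  d3 <- c(8, 8, 8)
  nt <- 40
  dat3 <- array(rnorm(prod(d3) * nt, 100, 5), c(d3, nt))
  mask3 <- array(runif(prod(d3)) > 0.2, d3)
  s3 <- volume_series(dat3, tr_s = 1)
  var_idx <- sort(sample(nt, 6))
  got <- respiration_effect_map(s3, var_idx, mask3, units = "raw")
  exp_map <- oracle_resp_map(dat3, var_idx, setdiff(1:nt, var_idx), mask3, "raw")
  expect_equal(got$map, exp_map, tolerance = 1e-12)
  expect_true(all(got$map >= 0))
  expect_true(all(got$map[!mask3] == 0))

  expect_error(respiration_effect_map(s, 1:6, mask), "stable set is empty")
  expect_error(respiration_effect_map(s, 5:6, mask, stable_idx = 4:6),
               "overlap")
})

test_that("block signal change applies the breathing-challenge window rules", {
  d <- c(2, 2, 1)
  tr <- 1
  nt <- 30
  # deep-breath trial at volumes 7..12 (onset 6 s, 6 volumes); analysis must
  # use volumes 9..12 (skip 2) and rest volumes 15..18
  dat <- array(100, c(d, nt))
  dat[, , , 7:8] <- 300 # transient, must be skipped
  dat[, , , 9:12] <- 102
  dat[, , , 13:14] <- 300 # post-task transient, must be skipped
  s <- volume_series(dat, tr_s = tr)
  des <- block_design(data.frame(onset = 6, duration = 6, label = "deep_breath"),
                      tr_s = tr, n_vol = nt)
  chg <- block_signal_change(s, des, "deep_breath")
  expect_equal(unique(round(as.vector(chg), 10)), 2)

  # constant series -> 0% everywhere
  s0 <- volume_series(array(70, c(d, nt)), tr_s = tr)
  expect_true(all(block_signal_change(s0, des, "deep_breath") == 0))

  # breath-hold: task = 5 hold volumes, rest = volumes 3..8 after hold end
  nt2 <- 30
  dat2 <- array(100, c(d, nt2))
  dat2[, , , 10:14] <- 103   # hold volumes (onset 9 s, 5 vols)
  dat2[, , , 15:16] <- 300   # recovery, excluded
  s2 <- volume_series(dat2, tr_s = tr)
  des2 <- block_design(data.frame(onset = 9, duration = 5, label = "breath_hold"),
                       tr_s = tr, n_vol = nt2)
  chg2 <- block_signal_change(s2, des2, "breath_hold")
  expect_equal(unique(round(as.vector(chg2), 10)), 3)

  # censored task volumes are excluded; fully censored trials are dropped
  s3 <- s
  s3$censored[9:12] <- TRUE
  expect_error(block_signal_change(s3, des, "deep_breath"), "no usable trials")
})

test_that("phase-response analysis recovers exact cosines and the quarter-cycle shift", {
  d <- c(4, 4, 1)
  mask <- array(TRUE, d)
  mk <- function(vals_by_vox) {
    # vals_by_vox: 16 x 4 matrix of changes per phase
    lapply(1:4, function(p) array(vals_by_vox[, p], d))
  }
  vb <- matrix(0, 16, 4)
  vb[1, ] <- c(2, 0, -2, 0)   # peaks at phase 0 -> ROI1, A=2, phi=0
  vb[2, ] <- c(0, 2, 0, -2)   # quarter-cycle shift -> ROI2, phi=90
  vb[3, ] <- c(-1.5, 0, 1.5, 0) # ROI3, phi=180
  vb[4, ] <- c(0, -1, 0, 1)   # ROI4, phi=270
  pr <- phase_response_analysis(mk(vb), mask, response_threshold = 0.5)
  fits <- pr$fits
  expect_true(all(fits$present))
  expect_equal(fits$peak_phase_deg, c(0, 90, 180, 270))
  expect_equal(fits$amplitude, c(2, 2, 1.5, 1), tolerance = 1e-12)
  t1 <- pr$table[pr$table$roi == 1, ]
  expect_equal(t1$mean_change_pct, c(2, 0, -2, 0))

  # all-zero maps: nothing survives a positive threshold; ROIs flagged absent
  pr0 <- phase_response_analysis(mk(matrix(0, 16, 4)), mask,
                                 response_threshold = 0.1)
  expect_true(all(!pr0$fits$present))
  expect_true(all(is.na(pr0$fits$amplitude)))
})

test_that("task regressor and block design validate events", {
  expect_error(block_design(data.frame(onset = c(0, 5), duration = c(6, 6),
                                       label = "a"), tr_s = 1),
               "overlap")
  des <- block_design(data.frame(onset = c(2, 10), duration = c(4, 4),
                                 label = c("a", "b")), tr_s = 1, n_vol = 20)
  g <- task_regressor(des, 0:19, label = "a")
  expect_equal(which(g == 1), 3:6)
  g2 <- task_regressor(des, 0:19)
  expect_equal(sum(g2), 8)
})
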