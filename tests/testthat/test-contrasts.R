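test_that("split_conditions partitions labels, preserves indices, drops censored", {
  dat <- array(seq_len(2 * 2 * 1 * 6), c(2, 2, 1, 6))
  s <- volume_series(dat, tr_s = 2,
                     condition = c("control", "nulled", "control",
                                   "nulled", "control", "nulled"))
  st <- split_conditions(s)
  expect_equal(st$control$time_index, c(1L, 3L, 5L))
  expect_equal(st$nulled$time_index, c(2L, 4L, 6L))
  expect_equal(st$control$time_s, c(0, 4, 8))

  # censored volume excluded from its stream
  s$censored[3] <- TRUE
  st <- split_conditions(s)
  expect_equal(st$control$time_index, c(1L, 5L))
  expect_equal(st$nulled$time_index, c(2L, 4L, 6L))

  # all-control series has no nulled volumes
  s2 <- volume_series(dat[, , , 1:3, drop = FALSE], tr_s = 2,
                      condition = "control")
  expect_error(split_conditions(s2), "insufficient condition volumes")
})

test_that("VAPER raw and corrected reproduce hand-computed values", {
  s <- toy_series(ctrl_vals = c(100, 100, 100), null_vals = c(80, 80, 80))
  st <- split_conditions(s)
  raw <- compute_vaper(st$control, st$nulled, corrected = FALSE)
  cor_ <- compute_vaper(st$control, st$nulled, corrected = TRUE)
  expect_equal(unique(as.vector(raw$data)), 20)
  expect_equal(unique(as.vector(cor_$data)), 0.2)
  expect_equal(raw$time_index, c(2L, 4L, 6L))

  # perfect blood suppression absent: C == N -> corrected 0 everywhere
  s2 <- toy_series(c(50, 50), c(50, 50))
  st2 <- split_conditions(s2)
  expect_true(all(compute_vaper(st2$control, st2$nulled)$data == 0))
})

test_that("corrected VAPER is invariant to joint rescaling; raw scales", {
  set.seed(7)
  base <- toy_series(runif(4, 90, 110), runif(4, 60, 80))
  st <- split_conditions(base)
  ref_raw <- compute_vaper(st$control, st$nulled, corrected = FALSE)
  ref_cor <- compute_vaper(st$control, st$nulled, corrected = TRUE)
  for (f in runif(5, 0.1, 10)) {
    sc <- base
    sc$data <- sc$data * f
    sts <- split_conditions(sc)
    expect_equal(compute_vaper(sts$control, sts$nulled, corrected = TRUE)$data,
                 ref_cor$data, tolerance = 1e-12)
    expect_equal(compute_vaper(sts$control, sts$nulled, corrected = FALSE)$data,
                 ref_raw$data * f, tolerance = 1e-12)
  }
})

test_that("raw VAPER is antisymmetric under stream swap", {
  # on time-constant streams the pairing is exact in both directions, so
  # swapping the roles of the streams negates the output
  set.seed(8)
  v <- array(runif(4, 60, 110), c(2, 2, 1))
  cs <- toy_series(c(1, 1), c(1, 1))
  cs$data <- array(0, c(2, 2, 1, 4))
  cs$data[, , , c(1, 3)] <- v + 20
  cs$data[, , , c(2, 4)] <- v
  stc <- split_conditions(cs)
  fwd <- compute_vaper(stc$control, stc$nulled, corrected = FALSE)
  rev_ <- compute_vaper(stc$nulled, stc$control, corrected = FALSE)
  expect_equal(as.vector(fwd$data), -as.vector(rev_$data))
  expect_equal(unique(round(as.vector(fwd$data), 10)), 20)
})

test_that("corrected VAPER flags voxels with non-positive control", {
  s <- toy_series(c(100, 100), c(80, 80))
  s$data[1, 1, 1, c(1, 3)] <- 0 # control voxel dead
  st <- split_conditions(s)
  mask <- array(TRUE, c(2, 2, 1))
  v <- compute_vaper(st$control, st$nulled, corrected = TRUE, mask = mask)
  expect_false(v$valid[1, 1, 1])
  expect_true(all(is.nan(v$data[1, 1, 1, ])))
  expect_true(all(is.finite(v$data[2, , , ])))
})

test_that("MT anatomical contrast: formula, identity, scale invariance", {
  mk <- function(cv, mv) {
    dat <- array(0, c(2, 2, 1, 4))
    dat[, , , c(1, 3)] <- cv
    dat[, , , c(2, 4)] <- mv
    volume_series(dat, tr_s = 1, condition = rep(c("control", "mt"), 2))
  }
  s <- mk(120, 100)
  st <- split_conditions(s, c("control", "mt"))
  expect_equal(unique(as.vector(compute_mt_anat(st$control, st$mt)$data)), 0.2)
  s2 <- mk(77, 77)
  st2 <- split_conditions(s2, c("control", "mt"))
  expect_true(all(compute_mt_anat(st2$control, st2$mt)$data == 0))
  s3 <- mk(360, 300) # everything x3
  st3 <- split_conditions(s3, c("control", "mt"))
  expect_equal(unique(as.vector(compute_mt_anat(st3$control, st3$mt)$data)), 0.2)
})

test_that("MT averaging uses only uncensored volumes and flags bad voxels", {
  dat <- array(100, c(2, 2, 1, 6))
  dat[, , , c(2, 4)] <- 80
  dat[, , , 6] <- 120 # corrupted MT volume to be censored
  s <- volume_series(dat, tr_s = 1, condition = rep(c("control", "mt"), 3),
                     censored = c(rep(FALSE, 5), TRUE))
  st <- split_conditions(s, c("control", "mt"))
  expect_equal(unique(as.vector(compute_mt_anat(st$control, st$mt)$data)),
               (100 - 80) / 80)
  # non-positive MT mean flagged invalid
  datc <- array(100, c(2, 2, 1, 2))
  datm <- array(80, c(2, 2, 1, 2))
  datm[1, 1, 1, ] <- -5
  ctrl <- volume_series(datc, tr_s = 1, condition = "control")
  mts <- volume_series(datm, tr_s = 1, condition = "mt")
  mt <- compute_mt_anat(ctrl, mts, mask = array(TRUE, c(2, 2, 1)))
  expect_false(mt$valid[1, 1, 1])
  expect_true(is.nan(mt$data[1, 1, 1, 1]))
})

test_that("censor_frames applies motion and outlier rules with stickiness", {
  dat <- array(100, c(2, 2, 1, 10))
  s <- volume_series(dat, tr_s = 1, condition = "none")
  motion <- data.frame(trans_x = 0, trans_y = 0, trans_z = 0,
                       rot_x = 0, rot_y = 0, rot_z = 0)[rep(1, 10), ]
  motion$trans_x[7:10] <- 0.5 # step at t=7: derivative enorm 0.5 only there
  out <- censor_frames(s, motion)
  expect_equal(which(out$censored), 7L)
  expect_equal(out$meta$censor_log$n_new, 1L)

  # outlier fraction >= 10% censors; 0.12 >= 0.10
  of <- rep(0, 10); of[3] <- 0.12
  out2 <- censor_frames(s, motion = NULL, outfrac = of)
  expect_equal(which(out2$censored), 3L)

  # clean data: nothing censored
  motion0 <- motion
  motion0$trans_x <- 0
  out3 <- censor_frames(s, motion0, outfrac = rep(0.05, 10))
  expect_equal(sum(out3$censored), 0L)

  # idempotent and sticky
  out4 <- censor_frames(out2, motion, outfrac = of)
  expect_equal(which(out4$censored), sort(c(3L, 7L)))
  out5 <- censor_frames(out4, motion, outfrac = of)
  expect_equal(out5$censored, out4$censored)

  # monotone: raising outfrac values never un-censors
  of_hi <- of + 0.05
  out6 <- censor_frames(s, motion = NULL, outfrac = of_hi)
  expect_true(all(which(out2$censored) %in% which(out6$censored)))

  expect_error(censor_frames(s, motion, enorm_limit = 0), "positive")
})

test_that("rotations are converted to arc length at the head radius", {
  dat <- array(100, c(2, 2, 1, 3))
  s <- volume_series(dat, tr_s = 1)
  motion <- data.frame(trans_x = 0, trans_y = 0, trans_z = 0,
                       rot_x = c(0, 0.5, 0.5), rot_y = 0, rot_z = 0)
  # 0.5 deg at 50 mm radius = 0.436 mm > 0.4
  out <- censor_frames(s, motion)
  expect_equal(which(out$censored), 2L)
  # raw-degrees mode: 0.3 "mm" < 0.4, and 0.3 deg at 50 mm = 0.26 mm < 0.4
  motion$rot_x <- c(0, 0.3, 0.3)
  expect_equal(sum(censor_frames(s, motion, rot_radius_mm = NA)$censored), 0L)
  expect_equal(sum(censor_frames(s, motion)$censored), 0L)
})
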