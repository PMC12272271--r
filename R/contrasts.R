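#' Split an interleaved series into its condition streams
#'
#' An interleaved acquisition alternates blood-nulled and control volumes (or
#' control and MT-prepared volumes for the anatomical run). This partitions
#' the series by condition label, dropping censored volumes, while preserving
#' the original time indices of each stream. The control stream doubles as
#' the conventional BOLD series.
#'
#' @param series A [volume_series()] with at least two distinct condition
#'   labels among its uncensored volumes.
#' @param conditions Character vector of the two labels to extract
#'   (default `c("control", "nulled")`).
#' @return Named list of two [volume_series()] streams.
#' @export
split_conditions <- function(series, conditions = c("control", "nulled")) {
  stopifnot(inherits(series, "volume_series"), length(conditions) == 2)
  keep <- !series$censored
  out <- lapply(conditions, function(cond) {
    idx <- which(keep & series$condition == cond)
    if (length(idx) < 2)
      stop_param("insufficient condition volumes: fewer than 2 uncensored '",
                 cond, "' volumes")
    subset_volumes(series, idx)
  })
  names(out) <- conditions
  out
}

#' Compute the VAPER contrast from paired condition streams
#'
#' Dynamic subtraction of the blood-nulled signal from the control signal,
#' with the control stream interpolated to each nulled volume's acquisition
#' time. In `corrected` mode the difference is further divided by the
#' interpolated control signal, which removes the shared T2*-weighting of the
#' EPI readout and with it residual BOLD contamination; the corrected value
#' is therefore invariant under joint rescaling of both streams. The sign
#' convention makes a task-evoked CBV increase positive: greater blood
#' suppression lowers the nulled signal, so the difference rises.
#'
#' @param control,nulled Condition streams from [split_conditions()], sharing
#'   grid and affine.
#' @param corrected If `TRUE` (default) return `(C - N)/C`; otherwise the raw
#'   difference `C - N`.
#' @param pairing `"nearest_preceding"` (default): the closest control
#'   volume at or before the nulled time — for interleaved acquisition, the
#'   partner volume of the same pair (the following control before the first
#'   control volume); `"two_neighbor"`: the mean of the two temporally
#'   adjacent control volumes (single neighbor at the series ends).
#'   Symmetric interpolation minimises breathing-phase bias between the
#'   streams but smears sharp block transitions, biasing block-design betas
#'   downward, so pairing within the acquired pair is the default.
#' @param mask Optional 3D analysis mask; in corrected mode voxels where the
#'   interpolated control is not positive are flagged invalid (`NaN` in the
#'   data, `FALSE` in the validity mask) rather than silently zeroed.
#' @return A `contrast_series`: list with 4D `data` (one sample per nulled
#'   volume), `kind` (`"vaper_corrected"` or `"vaper_raw"`), `time_index` and
#'   `time_s` of the nulled volumes, `tr_s`, and 3D logical `valid`.
#' @export
compute_vaper <- function(control, nulled, corrected = TRUE,
                          pairing = c("nearest_preceding", "two_neighbor"),
                          mask = NULL) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(control, "volume_series"), inherits(nulled, "volume_series"))
  if (!all(dim(control$data)[1:3] == dim(nulled$data)[1:3]))
    stop_param("control and nulled streams are on different grids")
  tc <- control$time_s
  tn <- nulled$time_s
  nt <- length(tn)
  d3 <- dim(nulled$data)[1:3]
  ctil <- array(0, c(d3, nt))
  for (i in seq_len(nt)) {
    if (pairing == "two_neighbor") {
      before <- which(tc <= tn[i])
      after <- which(tc > tn[i])
      picks <- c(if (length(before)) max(before), if (length(after)) min(after))
    } else {
      before <- which(tc <= tn[i])
      picks <- if (length(before)) max(before) else which.min(tc)
    }
    ctil[, , , i] <- if (length(picks) == 1) control$data[, , , picks] else
      (control$data[, , , picks[1]] + control$data[, , , picks[2]]) / 2
  }
  diff <- ctil - nulled$data
  valid <- array(TRUE, d3)
  if (corrected) {
    nonpos <- array(rowSums(matrix(ctil <= 0, prod(d3), nt)) > 0, d3)
    if (!is.null(mask)) nonpos <- nonpos & mask
    valid <- !nonpos
    diff <- diff / ctil
    diff[!is.finite(diff)] <- NaN
    bad4 <- array(rep(nonpos, nt), c(d3, nt))
    diff[bad4] <- NaN
  }
  structure(list(
    data = diff,
    kind = if (corrected) "vaper_corrected" else "vaper_raw",
    time_index = nulled$time_index,
    time_s = tn,
    tr_s = nulled$tr_s,
    affine = nulled$affine,
    valid = valid,
    meta = nulled$meta
  ), class = "contrast_series")
}

#' @export
print.contrast_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<contrast_series> kind=%s, %dx%dx%d, %d samples\n",
              x$kind, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' MT anatomical contrast from interleaved control/MT streams
#'
#' `(mean S_CTRL - mean S_MT) / mean S_MT` on time-averaged uncensored
#' volumes: the MT-saturated signal with the shared T2* weighting of the EPI
#' readout divided out, giving GM/WM anatomical contrast in native fMRI
#' space.
#'
#' @param control,mt Condition streams sharing a grid; only uncensored
#'   volumes enter the means.
#' @param mask Optional 3D mask restricting where a non-positive mean MT
#'   signal is treated as an error (flagged invalid).
#' @return A `contrast_series` of kind `"mt_anat"` whose `data` is a single
#'   3D volume.
#' @export
compute_mt_anat <- function(control, mt, mask = NULL) {
  stopifnot(inherits(control, "volume_series"), inherits(mt, "volume_series"))
  if (!all(dim(control$data)[1:3] == dim(mt$data)[1:3]))
    stop_param("control and MT streams are on different grids")
  mean_over <- function(s) {
    idx <- which(!s$censored)
    if (length(idx) == 0) stop_param("no uncensored volumes to average")
    d3 <- dim(s$data)[1:3]
    array(rowMeans(matrix(s$data[, , , idx, drop = FALSE],
                          prod(d3), length(idx))), d3)
  }
  mc <- mean_over(control)
  mm <- mean_over(mt)
  nonpos <- mm <= 0
  if (!is.null(mask)) nonpos <- nonpos & mask
  out <- (mc - mm) / mm
  out[nonpos | !is.finite(out)] <- NaN
  structure(list(
    data = array(out, c(dim(out), 1)),
    kind = "mt_anat",
    time_index = NA_integer_,
    time_s = NA_real_,
    tr_s = control$tr_s,
    affine = control$affine,
    valid = !(nonpos | !is.finite(out)),
    meta = control$meta
  ), class = "contrast_series")
}

#' Censor corrupted volumes by motion and outlier fraction
#'
#' Flags a volume whenever the Euclidean norm of the backward-difference
#' motion derivatives exceeds `enorm_limit` (default 0.4 mm) or the fraction
#' of outlier voxels is at least `outfrac_limit` (default 10%). Rotations are
#' converted to mm-equivalent arc length at `rot_radius_mm` before the norm.
#' Flags are sticky: volumes already censored stay censored. The count of
#' newly and totally censored volumes is recorded in `meta$censor_log`.
#'
#' @param series A [volume_series()].
#' @param motion Data frame with per-volume columns `trans_x/y/z` (mm) and
#'   `rot_x/y/z` (degrees); row count must equal the volume count.
#' @param outfrac Optional numeric vector of per-volume outlier fractions
#'   (see [outlier_fraction()]); `NA` entries are treated as 0.
#' @param enorm_limit Motion-derivative Euclidean-norm limit in mm (> 0).
#' @param outfrac_limit Outlier-fraction limit (> 0); censoring uses
#'   `outfrac >= outfrac_limit`.
#' @param rot_radius_mm Head radius for the degrees-to-mm conversion
#'   (default 50 mm); set `NA` to treat raw degrees as mm.
#' @return The series with updated `censored` flags and a `censor_log` entry
#'   in `meta` (fields `n_new`, `n_total`, `enorm`, `indices`).
#' @export
censor_frames <- function(series, motion = NULL, outfrac = NULL,
                          enorm_limit = 0.4, outfrac_limit = 0.10,
                          rot_radius_mm = 50) {
  stopifnot(inherits(series, "volume_series"))
  if (enorm_limit <= 0 || outfrac_limit <= 0)
    stop_param("censoring limits must be positive")
  nt <- n_volumes(series)
  flag <- rep(FALSE, nt)
  enorm <- rep(0, nt)
  if (!is.null(motion)) {
    motion <- as.data.frame(motion)
    if (nrow(motion) != nt)
      stop_param("motion table rows (", nrow(motion),
                 ") do not match volume count (", nt, ")")
    m <- as.matrix(motion[, c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z")])
    if (!is.na(rot_radius_mm))
      m[, 4:6] <- m[, 4:6] * pi / 180 * rot_radius_mm
    dm <- rbind(0, diff(m)) # first volume derivative defined as 0
    enorm <- sqrt(rowSums(dm^2))
    flag <- flag | (enorm > enorm_limit)
  }
  if (!is.null(outfrac)) {
    of <- rep(0, nt)
    of[seq_along(outfrac)] <- ifelse(is.na(outfrac), 0, outfrac)
    flag <- flag | (of >= outfrac_limit)
  }
  flag <- unname(flag)
  newly <- flag & !series$censored
  series$censored <- series$censored | flag
  series$meta$censor_log <- list(
    n_new = sum(newly),
    n_total = sum(series$censored),
    enorm = enorm,
    indices = series$time_index[series$censored]
  )
  series
}
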