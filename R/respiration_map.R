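#' Per-volume outlier fraction
#'
#' For each voxel the time series is detrended with an ordinary polynomial of
#' order `detrend_order` (least squares); a residual is an outlier when its
#' magnitude exceeds `k * MAD`, where `MAD = median(|residual|)` per voxel and
#' `k = qnorm(1 - qthr/2) * sqrt(pi/2)` rescales the MAD to a Gaussian-tail
#' threshold at two-sided level `qthr`. The statistic per volume is the
#' fraction of mask voxels flagged. Voxels with `MAD = 0` flag any nonzero
#' residual. Only uncensored volumes enter the trend fit and the output.
#'
#' @param series A [volume_series()] or `contrast_series`.
#' @param mask 3D logical analysis mask (non-empty).
#' @param detrend_order Polynomial trend order (default 2).
#' @param qthr Two-sided Gaussian tail probability defining the outlier
#'   threshold (default 0.001).
#' @return A tibble of class `outlier_fraction_series` with columns `volume`
#'   (original time index) and `fraction` in `[0, 1]`; attributes
#'   `detrend_order`, `qthr`, `k`, `n_mask`.
#' @export
outlier_fraction <- function(series, mask, detrend_order = 2, qthr = 0.001) {
  if (is.null(mask) || sum(mask) == 0) stop_param("mask is empty")
  dat <- series$data
  keep <- if (!is.null(series$censored)) which(!series$censored) else
    seq_len(dim(dat)[4])
  if (length(keep) < detrend_order + 2)
    stop_param("fewer volumes than detrend_order + 2")
  tt <- series$time_s[keep]
  y <- mat_from_4d(dat[, , , keep, drop = FALSE], mask) # T x V
  r <- detrend_poly(y, detrend_order, tt)
  madv <- apply(abs(r), 2, median)
  k <- qnorm(1 - qthr / 2) * sqrt(pi / 2)
  thr <- k * madv
  zero <- thr == 0
  out <- abs(r) > rep(thr, each = nrow(r))
  if (any(zero)) out[, zero] <- abs(r[, zero, drop = FALSE]) > 0
  frac <- rowMeans(out)
  res <- tibble::tibble(volume = series$time_index[keep], fraction = frac)
  attr(res, "detrend_order") <- detrend_order
  attr(res, "qthr") <- qthr
  attr(res, "k") <- k
  attr(res, "n_mask") <- sum(mask)
  class(res) <- c("outlier_fraction_series", class(res))
  res
}

#' Select respiration-variation time points
#'
#' The `top_fraction` of (uncensored) time points with the highest outlier
#' fraction are flagged as respiration-variation points; the complement is
#' the stable-respiration set. The count is `round(top_fraction * T)` with a
#' minimum of 1; ties are broken in favour of earlier time indices.
#'
#' @param frac An [outlier_fraction()] result (or any data frame with
#'   `volume` and `fraction` columns).
#' @param top_fraction Fraction of time points to select, in (0, 1);
#'   default 0.15.
#' @return Integer vector of selected volume indices (ascending), with the
#'   complement as attribute `stable` and the selection size as `n_sel`.
#' @export
select_variation_points <- function(frac, top_fraction = 0.15) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1)
    stop_param("top_fraction must be in (0, 1)")
  n <- nrow(frac)
  n_sel <- max(1L, round(top_fraction * n))
  ord <- order(-frac$fraction, frac$volume)
  sel <- sort(frac$volume[ord[seq_len(n_sel)]])
  structure(sel, stable = sort(setdiff(frac$volume, sel)), n_sel = n_sel)
}

#' Respiration-effect map
#'
#' Mean absolute signal deviation at the respiration-variation time points,
#' relative to the mean image over the stable-respiration time points. In
#' `"percent"` units (the default, suited to cross-subject pooling) the
#' deviation is expressed as percent of the stable mean.
#'
#' @param series A [volume_series()] or `contrast_series`.
#' @param variation_idx Volume indices (in `series$time_index` terms) of the
#'   respiration-variation points, e.g. from [select_variation_points()].
#' @param mask 3D logical analysis mask; the map is zero outside it.
#' @param units `"percent"` (default) or `"raw"`.
#' @param stable_idx Stable time points; default: uncensored volumes not in
#'   `variation_idx`. Must be disjoint from `variation_idx` and non-empty.
#' @return A `respiration_effect_map`: list with 3D `map` (non-negative,
#'   `NaN` where invalid), `stable_mean`, `n_variation`, `units`, `mask`.
#' @export
respiration_effect_map <- function(series, variation_idx, mask,
                                   units = c("percent", "raw"),
                                   stable_idx = NULL) {
  units <- match.arg(units)
  avail <- series$time_index[!(series$censored %||% FALSE)]
  variation_idx <- intersect(variation_idx, avail)
  stable_idx <- stable_idx %||% setdiff(avail, variation_idx)
  if (length(intersect(stable_idx, variation_idx)) > 0)
    stop_param("variation and stable sets overlap")
  if (length(stable_idx) == 0) stop_param("stable set is empty")
  if (length(variation_idx) == 0) stop_param("variation set is empty")
  d3 <- dim(series$data)[1:3]
  pos_var <- match(variation_idx, series$time_index)
  pos_sta <- match(stable_idx, series$time_index)
  nvox <- prod(d3)
  m <- matrix(series$data, nvox, dim(series$data)[4])
  stable_mean <- rowMeans(m[, pos_sta, drop = FALSE])
  dev <- abs(m[, pos_var, drop = FALSE] - stable_mean)
  mapv <- rowMeans(dev)
  if (units == "percent") {
    bad <- stable_mean <= 0
    mapv <- mapv / stable_mean * 100
    mapv[bad] <- NaN
  }
  mapv[!as.vector(mask)] <- 0
  structure(list(
    map = array(mapv, d3),
    stable_mean = array(stable_mean, d3),
    n_variation = length(variation_idx),
    units = units,
    mask = mask
  ), class = "respiration_effect_map")
}

#' @export
print.respiration_effect_map <- function(x, ...) {
  cat(sprintf("<respiration_effect_map> %s units, %d variation points, %d mask voxels\n",
              x$units, x$n_variation, sum(x$mask)))
  invisible(x)
}

#' Block design for breathing and task paradigms
#'
#' @param events Data frame with columns `onset` (s), `duration` (s),
#'   `label`; events must not overlap.
#' @param tr_s Repetition time of the acquisition grid in seconds.
#' @param n_vol Number of volumes in the run (optional; used for validation).
#' @return A `block_design` object.
#' @export
block_design <- function(events, tr_s, n_vol = NULL) {
  events <- tibble::as_tibble(as.data.frame(events))
  stopifnot(all(c("onset", "duration", "label") %in% names(events)))
  ev <- events[order(events$onset), ]
  if (nrow(ev) > 1 &&
      any(ev$onset[-1] < (ev$onset + ev$duration)[-nrow(ev)] - 1e-9))
    stop_param("events overlap")
  if (!is.null(n_vol) && max(ev$onset + ev$duration) > n_vol * tr_s + 1e-9)
    stop_param("events extend past the run duration")
  structure(list(events = ev, tr_s = tr_s, n_vol = n_vol),
            class = "block_design")
}

#' Boxcar task regressor sampled at volume times
#'
#' @param design A [block_design()].
#' @param times_s Volume acquisition start times.
#' @param label Event label to include (default: all events).
#' @return Numeric 0/1 vector, 1 where the volume starts inside an event.
#' @export
task_regressor <- function(design, times_s, label = NULL) {
  ev <- design$events
  if (!is.null(label)) ev <- ev[ev$label %in% label, ]
  g <- numeric(length(times_s))
  for (i in seq_len(nrow(ev)))
    g[times_s >= ev$onset[i] - 1e-9 &
        times_s < ev$onset[i] + ev$duration[i] - 1e-9] <- 1
  g
}

#' Block signal-change map for breathing challenges
#'
#' Percent signal change of the task window against the rest window, with the
#' window rules used for cerebrovascular-reactivity blocks:
#' \describe{
#'   \item{`deep_breath`}{the first 2 of 6 task volumes (12.164 s at the
#'     default TR) are skipped to avoid the transient, keeping the latter 2/3
#'     (4 volumes); the rest window likewise skips the first 2 post-task
#'     volumes and keeps the next 4.}
#'   \item{`breath_hold`}{the task window is the 5 breath-hold volumes (the
#'     cued breath-in/out period is not part of the event); the rest window
#'     skips 2 volumes after the hold ends and keeps the following 6 (the
#'     later 3/4 of the 8-volume rest).}
#'   \item{`custom`}{explicit windows via `task_skip/task_len/rest_skip/`
#'     `rest_len`, in volumes of the design grid.}
#' }
#' Windows are defined in seconds on the design's acquisition grid and then
#' intersected with the actual sample times of `series`, so the same rule
#' applies to full interleaved runs and to single-condition or contrast
#' streams. Trial means are averaged across trials before the task/rest
#' contrast; censored volumes are excluded, and trials whose task or rest
#' window is fully censored are dropped (counted in the `dropped_trials`
#' attribute).
#'
#' @param series A [volume_series()] or `contrast_series`.
#' @param design A [block_design()] whose events mark the task blocks (deep
#'   breath: the 6-volume breathing block; breath hold: the 5-volume hold).
#' @param window_rule `"deep_breath"`, `"breath_hold"` or `"custom"`.
#' @param label Event label of the task blocks (default: all events).
#' @param task_skip,task_len,rest_skip,rest_len Window description in design
#'   volumes, used when `window_rule = "custom"` (skips counted from event
#'   onset and event end respectively).
#' @param mask Optional 3D mask; outside it the map is 0.
#' @return 3D array of percent signal change, with attributes `n_trials` and
#'   `dropped_trials`.
#' @export
block_signal_change <- function(series, design,
                                window_rule = c("deep_breath", "breath_hold",
                                                "custom"),
                                label = NULL, task_skip = NULL,
                                task_len = NULL, rest_skip = NULL,
                                rest_len = NULL, mask = NULL) {
  window_rule <- match.arg(window_rule)
  tr <- design$tr_s
  w <- switch(window_rule,
    deep_breath = list(task_skip = 2, task_len = 4, rest_skip = 2, rest_len = 4),
    breath_hold = list(task_skip = 0, task_len = 5, rest_skip = 2, rest_len = 6),
    custom = list(task_skip = task_skip, task_len = task_len,
                  rest_skip = rest_skip, rest_len = rest_len))
  if (any(vapply(w, is.null, logical(1))))
    stop_param("custom window rule requires task/rest skip and length")
  ev <- design$events
  if (!is.null(label)) ev <- ev[ev$label %in% label, ]
  if (nrow(ev) == 0) stop_param("no matching events in design")

  keep <- !(series$censored %||% rep(FALSE, dim(series$data)[4]))
  times <- series$time_s
  d3 <- dim(series$data)[1:3]
  nvox <- prod(d3)
  m <- matrix(series$data, nvox, dim(series$data)[4])

  in_window <- function(a, b) which(keep & times >= a - 1e-9 & times < b - 1e-9)
  task_sum <- rest_sum <- numeric(nvox)
  n_used <- 0L
  dropped <- 0L
  for (i in seq_len(nrow(ev))) {
    on <- ev$onset[i]
    end <- ev$onset[i] + ev$duration[i]
    it <- in_window(on + w$task_skip * tr, on + (w$task_skip + w$task_len) * tr)
    ir <- in_window(end + w$rest_skip * tr, end + (w$rest_skip + w$rest_len) * tr)
    if (length(it) == 0 || length(ir) == 0) {
      dropped <- dropped + 1L
      next
    }
    task_sum <- task_sum + rowMeans(m[, it, drop = FALSE])
    rest_sum <- rest_sum + rowMeans(m[, ir, drop = FALSE])
    n_used <- n_used + 1L
  }
  if (n_used == 0) stop_param("no usable trials")
  task_mean <- task_sum / n_used
  rest_mean <- rest_sum / n_used
  chg <- (task_mean - rest_mean) / rest_mean * 100
  chg[!is.finite(chg)] <- NaN
  if (!is.null(mask)) chg[!as.vector(mask)] <- 0
  structure(array(chg, d3), n_trials = n_used, dropped_trials = dropped)
}

#' Breath-phase ROI analysis
#'
#' Given one signal-change map per acquisition breath phase (0, 90, 180,
#' 270 degrees), voxels surviving a response threshold are grouped into four
#' ROIs by the phase of their maximum positive change; each ROI's mean change
#' per phase is then fit with a least-squares sinusoid `A * cos(theta - phi0)`
#' (`A >= 0`, `phi0` in `[0, 360)`), the model expected when respiration-
#' coupled signal follows the breathing cycle with a voxel-specific lag.
#'
#' @param change_maps List of four co-registered 3D arrays, named (or
#'   ordered) as phases 0, 90, 180, 270.
#' @param mask 3D logical mask of analysis voxels.
#' @param response_threshold Minimum of the voxelwise maximum positive change
#'   for a voxel to enter an ROI; default: the 80th percentile of that
#'   maximum over the mask.
#' @return A `phase_response`: list with `table` (tibble: roi, phase_deg,
#'   mean_change_pct), `fits` (tibble: roi, present, n_voxels, amplitude,
#'   peak_phase_deg) and `threshold`.
#' @export
phase_response_analysis <- function(change_maps, mask,
                                    response_threshold = NULL) {
  stopifnot(length(change_maps) == 4)
  phases <- c(0, 90, 180, 270)
  v <- vapply(change_maps, function(a) as.vector(a)[as.vector(mask)],
              numeric(sum(mask)))       # n x 4
  ok <- rowSums(!is.finite(v)) == 0
  vmax <- apply(v, 1, max)
  response_threshold <- response_threshold %||%
    quantile(vmax[ok], 0.8, names = FALSE, na.rm = TRUE)
  surv <- ok & vmax >= response_threshold & vmax > 0
  argmax <- max.col(v, ties.method = "first")
  rows <- list()
  fits <- list()
  for (k in 1:4) {
    idx <- which(surv & argmax == k)
    present <- length(idx) > 0
    mc <- if (present) colMeans(v[idx, , drop = FALSE]) else rep(NA_real_, 4)
    rows[[k]] <- tibble::tibble(roi = k, phase_deg = phases,
                                mean_change_pct = mc)
    if (present) {
      # least-squares A*cos(theta - phi0) on 4 equally spaced phases
      a <- (mc[1] - mc[3]) / 2
      b <- (mc[2] - mc[4]) / 2
      amp <- sqrt(a^2 + b^2)
      phi <- (atan2(b, a) * 180 / pi) %% 360
    } else {
      amp <- NA_real_
      phi <- NA_real_
    }
    fits[[k]] <- tibble::tibble(roi = k, present = present,
                                n_voxels = length(idx),
                                amplitude = amp, peak_phase_deg = phi)
  }
  structure(list(table = do.call(rbind, rows),
                 fits = do.call(rbind, fits),
                 threshold = response_threshold),
            class = "phase_response")
}

#' @export
print.phase_response <- function(x, ...) {
  cat("<phase_response>\n")
  print(x$fits)
  invisible(x)
}

#' Write a phase response as TSV
#'
#' Columns: roi, phase_deg, mean_change_pct, fit_amplitude, fit_phase_deg.
#' @param x A `phase_response`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_phase_response <- function(x, path) {
  tab <- merge(as.data.frame(x$table), as.data.frame(x$fits), by = "roi")
  tab <- tab[, c("roi", "phase_deg", "mean_change_pct",
                 "amplitude", "peak_phase_deg")]
  names(tab)[4:5] <- c("fit_amplitude", "fit_phase_deg")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
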