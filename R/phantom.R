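# Synthetic laminar-fMRI phantom: spherical-shell cortex, planted vessels
# with respiration-coupled fluctuations, mid-depth neural plus superficial
# macrovascular task responses, and interleaved nulled/control acquisition.

BREATH_CYCLE_S <- 12.164 # one deep-breath cycle = 2 volume TRs

#' Phantom specification
#'
#' Defines the synthetic subject: a WM ball inside a GM shell inside a CSF
#' shell; pial vessels as tangential tubes on the GM/CSF interface and
#' penetrating vessels as radial segments, planted with an azimuthally
#' varying density; respiration-coupled signal fluctuations concentrated at
#' (and decaying away from) vessels; a mid-depth-peaked neural response plus
#' a superficial macrovascular response inside a sector ROI; AR(1) noise,
#' motion/outlier spikes, and interleaved blood-nulled/control acquisition.
#'
#' @param seed RNG seed (mandatory; every generated series is exactly
#'   reproducible from the spec and seed).
#' @param dim Grid size in voxels (length 1 or 3), default 64.
#' @param voxel_mm Isotropic voxel size in mm, default 0.8.
#' @param r_wm,r_csf WM-ball and GM/CSF-interface radii in voxels (defaults
#'   14 and 24; the GM shell is `r_wm < r <= r_csf`).
#' @param csf_thickness CSF shell thickness in voxels beyond `r_csf`.
#' @param roi_polar_deg Half-angle of the sector ROI about +z (default 45).
#' @param n_pial,pial_radius,pial_arc_deg Pial vessels: count, tube radius
#'   (voxels), angular arc length (degrees).
#' @param n_penetrating,pen_radius Penetrating vessels: count and radius.
#' @param beta_resp Vessel-coupling amplitude in percent of baseline at the
#'   vessel (default 5, of the order of the respiratory fluctuations seen at
#'   macrovessels in sub-millimetre 7T data); decays as `exp(-d/lambda_vox)` with distance `d` to
#'   the nearest vessel, emulating the extravascular spread of macrovascular
#'   effects.
#' @param lambda_vox Extravascular decay constant in voxels (default 1.5).
#' @param neural_amp,neural_peak_depth,neural_sigma Laminar neural response:
#'   amplitude (percent), peak equi-volume depth, Gaussian width in depth.
#' @param macro_amp_bold,macro_amp_vaper Superficial macrovascular task
#'   amplitudes (percent, at a pial vessel) for the BOLD-weighted and the
#'   CBV-weighted response (defaults 10 and 3; the CBV term is small but
#'   nonzero — blood-volume imaging retains residual large-vessel bias).
#' @param kappa Nulled-stream suppression factor in (0, 1) (default 0.5:
#'   the blood-nulling preparation also attenuates tissue signal; at 0.5 the
#'   corrected VAPER gain kappa/(1-kappa) is 1, so the recovered percent
#'   signal change equals the planted CBV amplitude).
#' @param noise_sd_pct AR(1) noise standard deviation in percent of baseline
#'   (default 0.6).
#' @param ar1 AR(1) coefficient of the noise (default 0.3).
#' @param tr_s Volume repetition time in seconds (default 6.082).
#' @param n_vol Run length in volumes (default 120, interleaved).
#' @param motion_spike_vols,outlier_spike_vols Volume indices receiving a
#'   motion spike (with matching motion-table jump) or an intensity-only
#'   outlier spike.
#' @param spike_enorm_mm Motion-derivative Euclidean norm of a motion spike.
#' @param spike_intensity_pct Global intensity perturbation of spike volumes.
#' @param motion_walk_sd_mm Per-volume sd of the baseline motion random walk.
#' @param f_breath_hz Natural breathing rate (default 0.27 Hz).
#' @param natural_amp Natural belt oscillation amplitude (a.u., belt
#'   baseline is 50).
#' @param deep_amp Deep-breath excursion amplitude (a.u., symmetric about
#'   the baseline).
#' @param event_interval_s Mean interval between spontaneous deep-breath
#'   events (sighs) in natural mode (default 60 s).
#' @param first_condition First volume's condition (default `"control"`).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(seed,
                         dim = 64, voxel_mm = 0.8,
                         r_wm = 14, r_csf = 24, csf_thickness = 3,
                         roi_polar_deg = 45,
                         n_pial = 24, pial_radius = 1.4, pial_arc_deg = 80,
                         n_penetrating = 40, pen_radius = 0.8,
                         beta_resp = 5, lambda_vox = 1.5,
                         neural_amp = 2, neural_peak_depth = 0.5,
                         neural_sigma = 0.15,
                         macro_amp_bold = 10, macro_amp_vaper = 3,
                         kappa = 0.5,
                         noise_sd_pct = 0.6, ar1 = 0.3,
                         tr_s = 6.082, n_vol = 120,
                         motion_spike_vols = c(37, 83),
                         outlier_spike_vols = 55,
                         spike_enorm_mm = 0.6,
                         spike_intensity_pct = 3,
                         motion_walk_sd_mm = 0.015,
                         f_breath_hz = 0.27, natural_amp = 10,
                         deep_amp = 40, event_interval_s = 60,
                         first_condition = "control") {
  if (missing(seed)) stop_param("a seed is mandatory for the phantom")
  if (length(dim) == 1) dim <- rep(dim, 3)
  if (!(r_wm < r_csf && r_csf < min(dim) / 2))
    stop_param("need r_wm < r_csf < dim/2")
  amps <- c(beta_resp, neural_amp, macro_amp_bold, macro_amp_vaper)
  if (any(amps < 0)) stop_param("amplitudes must be >= 0")
  if (kappa <= 0 || kappa >= 1) stop_param("kappa must be in (0, 1)")
  spec <- as.list(environment())
  class(spec) <- "phantom_spec"
  spec
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Static phantom anatomy and ground truth
#'
#' Builds the tissue labels, vessel masks with lag-group assignment, the
#' vessel-coupling amplitude field, the analytic equi-volume depth of the
#' spherical shell, the sector ROI, and the baseline/MT-ratio fields.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_truth` list: `spec`, `labels` ([seg_labels()]),
#'   `vessel_mask`, `pial_mask`, `dist_vessel` (voxels), `coupling`
#'   (percent), `coupling_by_lag` (list of 4 fields; vessels carry a
#'   quarter-cycle respiratory lag 0-3 assigned by azimuthal sector,
#'   emulating regionally varying vascular transit delays), `w_pial`
#'   (macrovascular proximity weight), `depth_true`
#'   (analytic depth from the CSF side), `roi_sector`, `baseline`,
#'   `mt_ratio`, `brain_mask`.
#' @export
make_phantom_anatomy <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  ctr <- (d + 1) / 2
  ax <- lapply(1:3, function(i) seq_len(d[i]) - ctr[i])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  r <- sqrt(r2)
  labels <- array(LBL_BG, d)
  labels[r <= spec$r_wm] <- LBL_WM
  labels[r > spec$r_wm & r <= spec$r_csf] <- LBL_GM
  labels[r > spec$r_csf & r <= spec$r_csf + spec$csf_thickness] <- LBL_CSF
  gm <- labels == LBL_GM

  # analytic equi-volume depth, 0 at the CSF side
  depth_true <- array(NA_real_, d)
  depth_true[gm] <- (spec$r_csf^3 - r[gm]^3) / (spec$r_csf^3 - spec$r_wm^3)

  # sector ROI about +z
  zc <- slice.index(r, 3) - ctr[3]
  polar <- acos(pmin(pmax(zc / pmax(r, 1e-9), -1), 1)) * 180 / pi
  roi_sector <- gm & polar <= spec$roi_polar_deg

  vess <- with_seed(spec$seed, plant_vessels(spec, ctr))
  vessel_mask <- array(FALSE, d)
  for (i in seq_along(vess)) {
    keep <- r[vess[[i]]$voxels] > spec$r_wm &
      r[vess[[i]]$voxels] <= spec$r_csf + 1.5 # GM + interface shell
    vessel_mask[vess[[i]]$voxels[keep]] <- TRUE
  }
  # respiratory transit-delay lag varies regionally: quarter-cycle lag by
  # azimuthal sector, so neighbouring vessels share a delay
  xc <- slice.index(r, 1) - ctr[1]
  yc <- slice.index(r, 2) - ctr[2]
  azim <- atan2(yc, xc) # (-pi, pi]
  lag_group <- array((floor((azim + pi) / (pi / 2)) %% 4L), d)
  lag_group[!vessel_mask] <- NA_integer_
  pial_mask <- vessel_mask & r > spec$r_csf - 2.5
  if (sum(vessel_mask) > 0.2 * sum(gm))
    stop_param("vessel volume exceeds 20% of GM: unrealistic spec")

  ftv <- .edt3d_ft_cpp(vessel_mask, as.integer(d), c(1, 1, 1))
  dist_vessel <- ftv$distance
  coupling <- spec$beta_resp * exp(-dist_vessel / spec$lambda_vox)
  coupling[labels == LBL_BG] <- 0
  # each voxel inherits the transit-delay lag of its nearest vessel, so the
  # extravascular spread carries a single, well-defined phase
  voxel_lag <- array(lag_group[ftv$index], d)
  coupling_by_lag <- lapply(0:3, function(q) {
    cq <- coupling
    cq[is.na(voxel_lag) | voxel_lag != q] <- 0
    cq
  })
  dp <- edt3d(pial_mask)
  w_pial <- exp(-dp / spec$lambda_vox)

  baseline <- array(0, d)
  baseline[labels == LBL_WM] <- 800
  baseline[gm] <- 1000
  baseline[labels == LBL_CSF] <- 1400
  mt_ratio <- array(1, d)
  mt_ratio[labels == LBL_WM] <- 0.55
  mt_ratio[gm] <- 0.75
  mt_ratio[labels == LBL_CSF] <- 0.95

  structure(list(
    spec = spec,
    labels = seg_labels(labels, voxel_mm = spec$voxel_mm),
    vessel_mask = vessel_mask,
    pial_mask = pial_mask,
    lag_group = lag_group,
    dist_vessel = dist_vessel,
    coupling = coupling,
    coupling_by_lag = coupling_by_lag,
    w_pial = w_pial,
    depth_true = depth_true,
    roi_sector = roi_sector,
    baseline = baseline,
    mt_ratio = mt_ratio,
    brain_mask = labels != LBL_BG,
    radius = r
  ), class = "phantom_truth")
}

# Sample vessel centrelines and stamp tube voxels. Pial vessels are
# great-circle arcs on the GM/CSF interface, penetrating vessels radial
# segments; sampling density varies with azimuth (denser near azimuth 0).
plant_vessels <- function(spec, ctr) {
  d <- spec$dim
  sample_dir <- function() {
    # rejection sampling: density proportional to 0.05 + 0.95*(1+cos(az))/2
    repeat {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      az <- atan2(u[2], u[1])
      w <- 0.05 + 0.95 * (1 + cos(az)) / 2
      if (stats::runif(1) < w) return(u)
    }
  }
  stamp <- function(pts, radius) {
    rr <- ceiling(radius)
    offs <- as.matrix(expand.grid(-rr:rr, -rr:rr, -rr:rr))
    vox <- integer(0)
    for (p in seq_len(nrow(pts))) {
      cand <- sweep(offs, 2, round(pts[p, ]), "+")
      dd <- sqrt(rowSums((cand - rep(pts[p, ], each = nrow(cand)))^2))
      ok <- dd <= radius &
        cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      if (any(ok))
        vox <- c(vox, cand[ok, 1] + (cand[ok, 2] - 1) * d[1] +
                   (cand[ok, 3] - 1) * d[1] * d[2])
    }
    unique(vox)
  }
  vessels <- list()
  for (i in seq_len(spec$n_pial)) {
    u <- sample_dir()
    tvec <- stats::rnorm(3)
    tvec <- tvec - sum(tvec * u) * u
    tvec <- tvec / sqrt(sum(tvec^2))
    half <- spec$pial_arc_deg / 2 * pi / 180
    s <- seq(-half, half, by = 0.4 / spec$r_csf)
    pts <- t(vapply(s, function(a)
      ctr + spec$r_csf * (u * cos(a) + tvec * sin(a)), numeric(3)))
    vessels[[length(vessels) + 1]] <-
      list(voxels = stamp(pts, spec$pial_radius), type = "pial")
  }
  for (i in seq_len(spec$n_penetrating)) {
    u <- sample_dir()
    rs <- seq(spec$r_wm + 1, spec$r_csf, by = 0.4)
    pts <- t(vapply(rs, function(rad) ctr + rad * u, numeric(3)))
    vessels[[length(vessels) + 1]] <-
      list(voxels = stamp(pts, spec$pen_radius), type = "penetrating")
  }
  vessels
}

#' Respiratory belt trace and paradigm events
#'
#' Generates the 500 Hz pneumatic-belt trace for one run together with the
#' event table of the paradigm. Modes:
#' \describe{
#'   \item{`natural`}{baseline sinusoidal breathing (~0.27 Hz) with seeded
#'     amplitude/rate jitter and occasional spontaneous deep-breath events —
#'     single symmetric deep cycles about the belt median.}
#'   \item{`deep_breath`}{seven trials of three 12.164-s deep-breath cycles
#'     (breath in over one volume TR, out over the next) followed by
#'     36.492 s of rest; `phase_deg` shifts the cycle relative to the
#'     acquisition grid in quarter-cycle units.}
#'   \item{`breath_hold`}{blocks of 48.656 s rest, a 6.082-s cued
#'     breath-in/out, and a 30.41-s end-expiration hold.}
#' }
#'
#' @param spec A [phantom_spec()].
#' @param mode `"natural"`, `"deep_breath"` or `"breath_hold"`.
#' @param n_vol Run length in volumes (default `spec$n_vol`; for structured
#'   modes the run is sized to fit whole trials and a lead-in rest).
#' @param phase_deg Breath phase of the acquisition in deep-breath mode
#'   (0, 90, 180 or 270).
#' @param n_trials Trials (deep breath, default 7) or blocks (breath hold,
#'   default 12).
#' @param seed_offset Added to the spec seed so that separate runs get
#'   independent traces while staying reproducible.
#' @return List with `trace` (tibble `time_s`, `amplitude` at 500 Hz),
#'   `events` (tibble `onset`, `duration`, `label`), `design`
#'   ([block_design()]), `mode`, `n_vol`, `fs` = 500.
#' @export
make_resp_trace <- function(spec, mode = c("natural", "deep_breath",
                                           "breath_hold"),
                            n_vol = NULL, phase_deg = 0, n_trials = NULL,
                            seed_offset = 1) {
  mode <- match.arg(mode)
  tr <- spec$tr_s
  fs <- 500
  P <- 2 * tr # deep-breath cycle period
  if (mode == "deep_breath") {
    n_trials <- n_trials %||% 7
    n_vol <- 6 + n_trials * 12
  } else if (mode == "breath_hold") {
    n_trials <- n_trials %||% 12
    n_vol <- n_trials * 14
  } else {
    n_vol <- n_vol %||% spec$n_vol
  }
  dur <- n_vol * tr
  if (mode != "natural" && n_vol < (if (mode == "deep_breath") 18 else 14))
    stop_param("duration shorter than one trial")
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)

  with_seed(spec$seed + seed_offset, {
    f <- spec$f_breath_hz * (1 + 0.1 * sin(2 * pi * tt / 97))
    amp_env <- spec$natural_amp * (1 + 0.2 * sin(2 * pi * tt / 131 + runif(1) * 2 * pi))
    natural <- 50 + amp_env * sin(2 * pi * cumsum(f) / fs + runif(1) * 2 * pi)
    amplitude <- natural
    events <- NULL
    if (mode == "natural") {
      n_ev <- max(1, floor(dur / spec$event_interval_s))
      # jittered regular grid keeps sighs well separated across the run
      grid <- seq(2 * tr, dur - P - 2 * tr, length.out = n_ev + 1)[-(n_ev + 1)]
      t0s <- grid + runif(n_ev, 0, 0.6 * spec$event_interval_s)
      t0s <- pmin(t0s, dur - P - 2 * tr)
      for (t0 in t0s) {
        seg <- tt >= t0 & tt < t0 + P
        amplitude[seg] <- amplitude[seg] +
          spec$deep_amp * sin(2 * pi * (tt[seg] - t0) / P)
      }
      events <- tibble::tibble(onset = t0s, duration = P,
                               label = "deep_event")
    } else if (mode == "deep_breath") {
      onsets <- 6 * tr + (seq_len(n_trials) - 1) * 12 * tr
      shift <- phase_deg / 360 * P
      for (on in onsets) {
        seg <- tt >= on & tt < on + 3 * P
        amplitude[seg] <- 50 - 50 * cos(2 * pi * (tt[seg] - on - shift) / P)
      }
      events <- tibble::tibble(onset = onsets, duration = 3 * P,
                               label = "deep_breath")
    } else { # breath_hold
      onsets <- numeric(n_trials)
      for (b in seq_len(n_trials)) {
        b0 <- (b - 1) * 14 * tr
        cue0 <- b0 + 8 * tr
        hold0 <- cue0 + tr
        onsets[b] <- hold0
        seg_in <- tt >= cue0 & tt < cue0 + tr / 2
        amplitude[seg_in] <- 50 + 50 * (tt[seg_in] - cue0) / (tr / 2)
        seg_out <- tt >= cue0 + tr / 2 & tt < cue0 + tr
        amplitude[seg_out] <- 100 - 85 * (tt[seg_out] - cue0 - tr / 2) / (tr / 2)
        seg_hold <- tt >= hold0 & tt < hold0 + 5 * tr
        amplitude[seg_hold] <- 15
      }
      events <- tibble::tibble(onset = onsets, duration = 5 * tr,
                               label = "breath_hold")
    }
    amplitude <- amplitude + stats::rnorm(length(tt), sd = 0.5)
    list(trace = tibble::tibble(time_s = tt, amplitude = amplitude),
         events = events,
         design = block_design(events, tr_s = tr, n_vol = n_vol),
         mode = mode, n_vol = n_vol, phase_deg = phase_deg, fs = fs)
  })
}

#' Per-volume respiration regressor from a belt trace
#'
#' The windowed belt-amplitude deviation from the run median, in units of the
#' belt half-range (50 a.u.): for each volume, the mean amplitude over the
#' acquisition window of the trace delayed by `lag_s`, minus the run median,
#' divided by 50.
#'
#' @param trace Tibble with `time_s`, `amplitude` (500 Hz).
#' @param tr_s Volume TR in seconds.
#' @param n_vol Number of volumes.
#' @param lag_s Temporal lag applied to the trace (default 0).
#' @return Numeric vector of length `n_vol`.
#' @export
resp_regressor <- function(trace, tr_s, n_vol, lag_s = 0) {
  med <- median(trace$amplitude)
  shifted_t <- trace$time_s + lag_s # amplitude(t - lag) sampled at t
  h <- numeric(n_vol)
  idx_all <- findInterval(shifted_t, (seq_len(n_vol + 1) - 1) * tr_s)
  ok <- idx_all >= 1 & idx_all <= n_vol
  sums <- tapply(trace$amplitude[ok], idx_all[ok], mean)
  h[as.integer(names(sums))] <- as.numeric(sums) - med
  h / 50
}

#' Visual block design for the phantom
#'
#' Alternating six-volume task and rest blocks after a six-volume lead-in
#' rest, filling the run.
#'
#' @param spec A [phantom_spec()].
#' @param n_vol Run length in volumes (default `spec$n_vol`).
#' @return A [block_design()] with events labelled `"visual"`.
#' @export
visual_block_design <- function(spec, n_vol = NULL) {
  n_vol <- n_vol %||% spec$n_vol
  tr <- spec$tr_s
  n_trials <- floor((n_vol - 6) / 12)
  if (n_trials < 1) stop_param("run too short for one task block")
  onsets <- (6 + (seq_len(n_trials) - 1) * 12) * tr
  block_design(tibble::tibble(onset = onsets, duration = 6 * tr,
                              label = "visual"),
               tr_s = tr, n_vol = n_vol)
}

#' Simulate an interleaved phantom run
#'
#' Generates the interleaved blood-nulled/control series following the
#' generative model: the control stream is
#' `B(x) * (1 + beta_bold(x) g(t) + sum_q c_q(x) h_q(t) + eps)` and the
#' nulled stream
#' `B(x) * kappa * (1 + (beta_bold(x) - beta_cbv(x)) g(t) + sum_q c_q(x)
#' h_q(t) + eps)`, where `g` is the task boxcar, `h_q` the per-volume
#' respiration regressor at quarter-cycle lag `q`, `c_q` the vessel-coupling
#' field of lag group `q`, and `eps` AR(1) Gaussian noise. `beta_bold` is the
#' mid-depth neural Gaussian plus the superficial macrovascular term;
#' `beta_cbv` is the neural term plus a smaller macrovascular residual.
#' Motion spikes inject a global intensity perturbation and matching
#' motion-table jumps; outlier spikes perturb intensity only.
#'
#' @param truth A [make_phantom_anatomy()] result.
#' @param resp A [make_resp_trace()] result for the run.
#' @param design Optional [block_design()] of the task (default: the visual
#'   design in natural mode, none otherwise).
#' @param seed_offset Added to the spec seed for the run's noise stream.
#' @return List with `series` (a [volume_series()]), `motion` (tibble),
#'   `design`, `truth_betas` (list `beta_bold`, `beta_cbv`), and
#'   `spike_vols`.
#' @export
make_phantom_timeseries <- function(truth, resp, design = NULL,
                                    seed_offset = 2) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  if (spec$kappa <= 0 || spec$kappa >= 1) stop_param("kappa must be in (0, 1)")
  n_vol <- resp$n_vol
  tr <- spec$tr_s
  times <- (seq_len(n_vol) - 1) * tr
  d <- spec$dim
  nvox <- prod(d)

  if (is.null(design) && resp$mode == "natural")
    design <- visual_block_design(spec, n_vol)
  g <- if (!is.null(design) && resp$mode == "natural")
    task_regressor(design, times, label = "visual") else numeric(n_vol)

  # laminar task fields (restricted to the activated sector)
  dep <- truth$depth_true
  neural <- spec$neural_amp *
    exp(-(dep - spec$neural_peak_depth)^2 / (2 * spec$neural_sigma^2))
  neural[is.na(neural)] <- 0
  neural[!truth$roi_sector] <- 0
  macro <- truth$w_pial
  macro[!truth$roi_sector] <- 0
  macro[is.na(dep)] <- 0 # macrovascular task response within GM only
  beta_bold <- (neural + spec$macro_amp_bold * macro) / 100
  beta_cbv <- (neural + spec$macro_amp_vaper * macro) / 100

  # respiration coupling, per lag group (quarter-cycle transit delays)
  P <- 2 * tr
  hq <- lapply(0:3, function(q)
    resp_regressor(resp$trace, tr, n_vol, lag_s = q * P / 4))

  condition <- rep(c("control", "nulled"), length.out = n_vol)
  if (spec$first_condition == "nulled") condition <- rev(condition)[seq_len(n_vol)]
  is_nulled <- condition == "nulled"

  spikes <- sort(unique(c(spec$motion_spike_vols, spec$outlier_spike_vols)))
  spikes <- spikes[spikes <= n_vol]

  sim <- with_seed(spec$seed + seed_offset, {
    m <- matrix(0, nvox, n_vol)
    for (q in 1:4) {
      cq <- as.vector(truth$coupling_by_lag[[q]]) / 100
      if (any(cq > 0)) m <- m + outer(cq, hq[[q]])
    }
    if (spec$noise_sd_pct > 0) {
      innov <- matrix(stats::rnorm(nvox * n_vol,
                                   sd = spec$noise_sd_pct / 100 *
                                     sqrt(1 - spec$ar1^2)),
                      n_vol, nvox)
      eps <- stats::filter(innov, spec$ar1, method = "recursive")
      m <- m + t(matrix(as.numeric(eps), n_vol, nvox))
    }
    m <- m + outer(as.vector(beta_bold), g)
    if (any(is_nulled) && any(g != 0))
      m[, is_nulled] <- m[, is_nulled] -
        outer(as.vector(beta_cbv), g[is_nulled])
    s <- 1 + m
    rm(m)
    if (any(is_nulled)) s[, is_nulled] <- s[, is_nulled] * spec$kappa
    s <- s * as.vector(truth$baseline)
    if (length(spikes) > 0)
      s[, spikes] <- s[, spikes] * (1 + spec$spike_intensity_pct / 100)

    # motion: slow random walk plus step jumps at motion-spike volumes
    walk <- matrix(stats::rnorm(n_vol * 6, sd = spec$motion_walk_sd_mm),
                   n_vol, 6)
    motion <- apply(walk, 2, cumsum)
    jump <- spec$spike_enorm_mm / sqrt(2)
    for (v in intersect(spec$motion_spike_vols, seq_len(n_vol)))
      motion[v:n_vol, 1:2] <- motion[v:n_vol, 1:2] + jump
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    list(s = s, motion = tibble::as_tibble(as.data.frame(motion)))
  })

  series <- volume_series(array(sim$s, c(d, n_vol)), tr_s = tr,
                          condition = condition,
                          voxel_mm = spec$voxel_mm,
                          meta = list(mode = resp$mode,
                                      phase_deg = resp$phase_deg))
  list(series = series, motion = sim$motion, design = design,
       truth_betas = list(beta_bold = array(beta_bold * 100, d),
                          beta_cbv = array(beta_cbv * 100, d)),
       spike_vols = list(motion = intersect(spec$motion_spike_vols,
                                            seq_len(n_vol)),
                         outlier = intersect(spec$outlier_spike_vols,
                                             seq_len(n_vol)),
                         all = spikes))
}

#' Simulate an interleaved control/MT anatomical run
#'
#' @param truth A [make_phantom_anatomy()] result.
#' @param n_vol Number of volumes (default 20, interleaved control/MT).
#' @param seed_offset Added to the spec seed for the noise stream.
#' @return A [volume_series()] with condition labels `control`/`mt`.
#' @export
make_phantom_mt_series <- function(truth, n_vol = 20, seed_offset = 9) {
  spec <- truth$spec
  d <- spec$dim
  nvox <- prod(d)
  condition <- rep(c("control", "mt"), length.out = n_vol)
  is_mt <- condition == "mt"
  s <- with_seed(spec$seed + seed_offset, {
    eps <- matrix(stats::rnorm(nvox * n_vol, sd = spec$noise_sd_pct / 100),
                  nvox, n_vol)
    s <- (1 + eps) * as.vector(truth$baseline)
    s[, is_mt] <- s[, is_mt] * as.vector(truth$mt_ratio)
    s
  })
  volume_series(array(s, c(d, n_vol)), tr_s = spec$tr_s,
                condition = condition, voxel_mm = spec$voxel_mm)
}
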