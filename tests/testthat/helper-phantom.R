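# Shared small-phantom fixtures, built once per test run.

small_spec <- function(seed = 101, ...) {
  args <- utils::modifyList(
    list(seed = seed, dim = 32, r_wm = 7, r_csf = 13, csf_thickness = 2,
         n_pial = 10, n_penetrating = 14, n_vol = 120,
         motion_spike_vols = c(37, 83), outlier_spike_vols = 55),
    list(...))
  do.call(phantom_spec, args)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

small_truth <- function() fixture("small_truth", function() {
  make_phantom_anatomy(small_spec())
})

small_run <- function() fixture("small_run", function() {
  truth <- small_truth()
  resp <- make_resp_trace(truth$spec, "natural")
  sim <- make_phantom_timeseries(truth, resp)
  ofv <- rep(NA_real_, truth$spec$n_vol)
  for (s in split_conditions(sim$series)) {
    of <- outlier_fraction(s, truth$brain_mask)
    ofv[of$volume] <- of$fraction
  }
  series <- censor_frames(sim$series, sim$motion, outfrac = ofv)
  streams <- split_conditions(series)
  list(truth = truth, resp = resp, sim = sim, series = series,
       streams = streams,
       vaper_raw = compute_vaper(streams$control, streams$nulled,
                                 corrected = FALSE),
       vaper_cor = compute_vaper(streams$control, streams$nulled,
                                 corrected = TRUE,
                                 mask = truth$brain_mask))
})

small_depth <- function() fixture("small_depth", function() {
  equivolume_depth(small_truth()$labels, seed = 1)
})

# toy interleaved series with hand-set values, for formula tests
toy_series <- function(ctrl_vals, null_vals, d3 = c(2, 2, 1), tr_s = 1) {
  nt <- 2 * length(ctrl_vals)
  dat <- array(0, c(d3, nt))
  for (i in seq_along(ctrl_vals)) {
    dat[, , , 2 * i - 1] <- ctrl_vals[i]
    dat[, , , 2 * i] <- null_vals[i]
  }
  volume_series(dat, tr_s = tr_s,
                condition = rep(c("control", "nulled"), length(ctrl_vals)))
}
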