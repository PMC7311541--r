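#' Promoter and transcript kinetic parameters
#'
#' The promoter is modelled as a single irreversible switch per stress
#' episode: a repressed locus turns ON with hazard
#' `activation_rate_scale * max(activity(t - chromatin_delay) -
#' chromatin_threshold, 0)`, so activation concentrates in the early
#' high-MAPK-activity window and a tightly repressed locus (high threshold,
#' long delay) responds later and less often. Once ON, convoys of RNA PolII
#' load every `convoy_interval` minutes (gamma-distributed gaps) until the
#' gating activity falls below threshold plus `shutoff_lag`. Each transcript's
#' fluorescence ramps linearly while the stem-loop cassette is transcribed
#' (`cassette_length / elongation_speed`) and then stays constant until the
#' polymerase terminates at `transcript_length / elongation_speed` — 400 s
#' (6.7 min) at the default 8 kb / 20 bp/s, which sets the expected lifetime
#' of one transcript at the transcription site. `basal_rate > 0` adds
#' stimulus-independent convoy firing, visible as pre-stimulus transcription
#' sites.
#'
#' @param activation_rate_scale 1/min of hazard per unit gated activity.
#' @param chromatin_threshold activity level the MAPK must exceed.
#' @param chromatin_delay minutes of remodeling lag before the locus can fire.
#' @param basal_rate 1/min rate of stimulus-independent convoy firing.
#' @param convoy_size_mean mean polymerases per convoy (min 1).
#' @param convoy_interval mean minutes between convoys while loading.
#' @param convoy_interval_shape gamma shape of the convoy gaps.
#' @param loading_duration minutes over which one convoy's polymerases load.
#' @param elongation_speed bp/s.
#' @param cassette_length bp of the stem-loop array (1.5 kb for the 24x
#'   array).
#' @param orf_length bp of the ORF downstream of the cassette (6.5 kb for
#'   the GLT1 integration locus).
#' @param transcript_length bp; defaults to `cassette_length + orf_length`
#'   (8 kb).
#' @param shutoff_lag minutes of residual loading after activity gates off.
#' @return a `promoter_params` list.
#' @export
promoter_params <- function(activation_rate_scale = 0.19,
                            chromatin_threshold = 0.3,
                            chromatin_delay = 1.5,
                            basal_rate = 0,
                            convoy_size_mean = 8,
                            convoy_interval = 1.5,
                            convoy_interval_shape = 4,
                            loading_duration = 0.25,
                            elongation_speed = 20,
                            cassette_length = 1500,
                            orf_length = 6500,
                            transcript_length = cassette_length + orf_length,
                            shutoff_lag = 1) {
  stopifnot(activation_rate_scale >= 0, basal_rate >= 0,
            chromatin_threshold >= 0, chromatin_delay >= 0,
            convoy_size_mean >= 1, convoy_interval > 0,
            convoy_interval_shape > 0, loading_duration > 0,
            elongation_speed > 0,
            transcript_length > cassette_length, cassette_length > 0,
            shutoff_lag >= 0)
  structure(
    list(activation_rate_scale = activation_rate_scale,
         chromatin_threshold = chromatin_threshold,
         chromatin_delay = chromatin_delay,
         basal_rate = basal_rate,
         convoy_size_mean = convoy_size_mean,
         convoy_interval = convoy_interval,
         convoy_interval_shape = convoy_interval_shape,
         loading_duration = loading_duration,
         elongation_speed = elongation_speed,
         cassette_length = cassette_length,
         orf_length = orf_length,
         transcript_length = transcript_length,
         shutoff_lag = shutoff_lag),
    class = "promoter_params"
  )
}

#' Promoter presets
#'
#' Two qualitative promoter regimes: a tightly repressed stress promoter
#' (`"repressed"`, STL1-like: no basal firing, slow noisy activation, ~60%
#' responders at 0.2 M) and a permissive one (`"permissive"`, GPD1-like:
#' basal firing, fast near-uniform activation).
#'
#' @param which preset name.
#' @param ... overrides passed to [promoter_params()].
#' @export
promoter_preset <- function(which = c("repressed", "permissive"), ...) {
  which <- match.arg(which)
  base <- switch(which,
    repressed  = list(),
    permissive = list(activation_rate_scale = 1.6,
                      chromatin_threshold = 0.1,
                      chromatin_delay = 0.3,
                      basal_rate = 0.02)
  )
  do.call(promoter_params, utils::modifyList(base, list(...)))
}

# residence time of one transcript at the TS, minutes
transcript_residence_min <- function(params) {
  params$transcript_length / params$elongation_speed / 60
}

#' Simulate nascent transcription for one cell
#'
#' Draws the promoter ON time from the gated inhomogeneous hazard, lays down
#' PolII convoys, and tabulates the ground-truth transcription-site intensity
#' (in units of fully loaded transcripts) on the frame grid, together with
#' the per-cell ground-truth event record.
#'
#' @param activity gated MAPK activity on the frame grid (see
#'   [hog1_activity()]); a zero vector with `basal_rate = 0` yields no
#'   transcription.
#' @param grid the [frame_grid()].
#' @param params a [promoter_params()].
#' @param seed optional integer seed.
#' @return list with `intensity` (numeric per frame, transcript units) and
#'   `truth` (event record: frame-grid `true_start_time` / `true_end_time`,
#'   continuous `first_init_time` / `last_termination_time` /
#'   `stress_on_time`, `convoy_times`, `init_times`, `is_basal`,
#'   `true_peak_count`, `n_transcripts`).
#' @export
simulate_transcription <- function(activity, grid, params = promoter_params(),
                                   seed = NULL) {
  stopifnot(length(activity) == grid$n_frames)
  if (!is.null(seed)) set.seed(seed)
  t <- grid$time_min
  dt <- grid$interval_min
  resid <- transcript_residence_min(params)
  t_cass <- params$cassette_length / params$elongation_speed / 60

  # gated hazard, chromatin delay as a shift of the activity trace
  shift <- round(params$chromatin_delay / dt)
  act_shift <- if (shift > 0) c(rep(0, shift), activity)[seq_along(activity)]
               else activity
  haz <- params$activation_rate_scale * pmax(act_shift - params$chromatin_threshold, 0)

  # stress-driven ON switch: inverse-transform on the piecewise-constant
  # hazard; haz[i] applies on the interval [t[i], t[i] + dt)
  t_on <- NA_real_
  if (any(haz > 0)) {
    target <- stats::rexp(1)
    ch <- cumsum(haz * dt)
    hit <- which(ch >= target)[1]
    if (!is.na(hit)) {
      prev <- if (hit > 1) ch[hit - 1] else 0
      t_on <- t[hit] + (target - prev) / haz[hit]
    }
  }

  convoy_times <- numeric(0)
  if (!is.na(t_on)) {
    gate_on <- which(haz > 0)
    t_off <- t[max(gate_on)] + params$shutoff_lag
    tc <- t_on
    while (tc <= min(t_off, t[length(t)])) {
      convoy_times <- c(convoy_times, tc)
      sh <- params$convoy_interval_shape
      tc <- tc + stats::rgamma(1, shape = sh, rate = sh / params$convoy_interval)
    }
  }

  # basal firing, including transcripts initiated before the movie that are
  # still resident at frame 1
  basal_times <- numeric(0)
  if (params$basal_rate > 0) {
    span_from <- t[1] - resid
    span <- t[length(t)] - span_from
    n_b <- stats::rpois(1, params$basal_rate * span)
    if (n_b > 0) basal_times <- sort(stats::runif(n_b, span_from, t[length(t)]))
  }

  all_convoys <- sort(c(convoy_times, basal_times))
  init_times <- numeric(0)
  for (tc in all_convoys) {
    n_pol <- 1 + stats::rpois(1, params$convoy_size_mean - 1)
    init_times <- c(init_times, tc + sort(stats::runif(n_pol, 0, params$loading_duration)))
  }
  init_times <- sort(init_times)

  intensity <- numeric(grid$n_frames)
  for (s in init_times) {
    live <- t >= s & t < s + resid
    if (any(live)) intensity[live] <- intensity[live] + pmin((t[live] - s) / t_cass, 1)
  }

  eps <- 1e-9
  pre <- t < 0
  pos <- intensity > eps
  pos_runs <- rle(pos)
  # Start/End ground truth lives on the frame grid, like the measurement:
  # the first and last frames at which the site carries nascent signal.
  # The continuous event times are kept alongside.
  truth <- list(
    true_start_time = if (any(pos)) t[which(pos)[1]] else NA_real_,
    true_end_time = if (any(pos)) t[which(pos)[sum(pos)]] else NA_real_,
    first_init_time = if (length(init_times)) min(init_times) else NA_real_,
    last_termination_time =
      if (length(init_times)) max(init_times) + resid else NA_real_,
    convoy_times = all_convoys,
    init_times = init_times,
    is_basal = any(pre & pos),
    true_peak_count = sum(pos_runs$values),
    stress_on_time = t_on,
    n_transcripts = length(init_times)
  )
  list(intensity = intensity, truth = truth)
}

#' Simulate a population of cells
#'
#' One master seed; each cell's Hog1 trace and transcription kinetics use a
#' deterministically derived per-cell stream, so the simulation is
#' reproducible and individual cells can be regenerated in isolation.
#'
#' @param n_cells number of cells.
#' @param profile stimulus profile.
#' @param hog1 [hog1_params()].
#' @param promoter [promoter_params()].
#' @param seed master integer seed.
#' @return list with `hog1_traces` (cells x frames), `intensity` (cells x
#'   frames, transcript units), `truth` (list per cell), `grid`, and the
#'   parameter sets used.
#' @export
simulate_cells <- function(n_cells, profile,
                           hog1 = hog1_params(),
                           promoter = promoter_params(),
                           seed = 1) {
  grid <- profile$grid
  hog1_traces <- matrix(NA_real_, n_cells, grid$n_frames)
  intensity <- matrix(NA_real_, n_cells, grid$n_frames)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    tr <- simulate_hog1_trace(profile, hog1, seed = derive_seed(seed, 2L * i))
    act <- hog1_activity(tr, hog1)
    sim <- simulate_transcription(act, grid, promoter,
                                  seed = derive_seed(seed, 2L * i + 1L))
    hog1_traces[i, ] <- tr
    intensity[i, ] <- sim$intensity
    truth[[i]] <- c(list(cell_id = i), sim$truth)
  }
  list(hog1_traces = hog1_traces, intensity = intensity, truth = truth,
       grid = grid, profile = profile, hog1 = hog1, promoter = promoter,
       seed = seed)
}

#' Ground truth as a data frame
#'
#' @param sim result of [simulate_cells()].
#' @return one row per cell with the scalar truth fields.
#' @export
truth_table <- function(sim) {
  do.call(rbind, lapply(sim$truth, function(tr) {
    data.frame(cell_id = tr$cell_id,
               is_basal = tr$is_basal,
               true_start_time = tr$true_start_time,
               true_end_time = tr$true_end_time,
               first_init_time = tr$first_init_time,
               last_termination_time = tr$last_termination_time,
               true_peak_count = tr$true_peak_count,
               n_transcripts = tr$n_transcripts,
               stress_on_time = tr$stress_on_time)
  }))
}

#' Trace-level observation model
#'
#' Emulates the measured HiPix/ConnectedHiPix traces without rendering
#' images: the HiPix observation is the truth intensity scaled to camera
#' counts plus Gaussian measurement noise, and a ConnectedHiPix detection is
#' recorded whenever at least `detect_min` transcript equivalents are
#' resident (the image-based detector needs a spot bright enough for its
#' brightest-pixel set to cluster). Used for fast statistical tests; the
#' rendering route exercises the full image pipeline.
#'
#' @param intensity cells x frames truth matrix (transcript units).
#' @param counts_per_mRNA HiPix counts contributed per resident transcript.
#' @param noise_sd Gaussian noise sd of the HiPix statistic, counts.
#' @param detect_min detection threshold in transcript units.
#' @param seed integer seed.
#' @return list of matrices `hipix` and `connected_hipix` (NA when
#'   undetected).
#' @export
observe_traces <- function(intensity, counts_per_mRNA = 12, noise_sd = 3,
                           detect_min = 1.5, seed = 1) {
  set.seed(seed)
  hip <- counts_per_mRNA * intensity +
    matrix(stats::rnorm(length(intensity), 0, noise_sd),
           nrow(intensity), ncol(intensity))
  ch <- hip
  ch[intensity < detect_min] <- NA_real_
  list(hipix = hip, connected_hipix = ch)
}
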