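#' Parameters of the MAPK nuclear-relocation model
#'
#' The Hog1 nuclear-enrichment trace is modelled piecewise: a linear rise from
#' `baseline` to the stress-scaled peak over `rise_time`, a plateau, then an
#' exponential return towards baseline timed so that the cell has adapted
#' (returned to within ~5% of baseline amplitude) at its adaptation time.
#' `adaptation_time` is the population value at the reference stress
#' `ref_amplitude` (0.2 M); it scales linearly with the effective stress
#' amplitude, so milder stresses adapt faster and stronger or rising stresses
#' later. A pulse that returns the medium to 0 M truncates the trace with a
#' fast nuclear-exit exponential (`exit_tau`), since the kinase leaves the
#' nucleus as soon as the osmotic imbalance is gone.
#'
#' @param rise_time minutes from stimulus to maximal enrichment.
#' @param peak_enrichment nuclear/cytoplasmic enrichment ratio at the
#'   reference amplitude.
#' @param adaptation_time minutes to essentially complete (~95%) return to
#'   baseline at `ref_amplitude`; with the default decay shape the measured
#'   adaptation feature (crossing 20% of amplitude) sits near 14 min and the
#'   decay feature (80% of maximum) near 7 min at 0.2 M, the reference
#'   values for this pathway.
#' @param baseline resting enrichment ratio.
#' @param cell_to_cell_cv lognormal coefficient of variation applied per cell
#'   to the peak and the adaptation time.
#' @param plateau_frac fraction of the (adaptation - rise) interval spent at
#'   the plateau before decay starts.
#' @param exit_tau minutes; nuclear-exit time constant after a pulse ends.
#' @param ref_amplitude mol/L; stress at which the nominal parameters apply.
#' @param max_amp_factor cap on the amplitude scaling of the peak.
#' @return a `hog1_params` list.
#' @export
hog1_params <- function(rise_time = 1,
                        peak_enrichment = 2,
                        adaptation_time = 20,
                        baseline = 1,
                        cell_to_cell_cv = 0.15,
                        plateau_frac = 0.25,
                        exit_tau = 0.3,
                        ref_amplitude = 0.2,
                        max_amp_factor = 2) {
  stopifnot(peak_enrichment > baseline,
            adaptation_time > rise_time,
            cell_to_cell_cv >= 0,
            rise_time > 0, exit_tau > 0, ref_amplitude > 0,
            plateau_frac >= 0, plateau_frac < 1)
  structure(
    list(rise_time = rise_time, peak_enrichment = peak_enrichment,
         adaptation_time = adaptation_time, baseline = baseline,
         cell_to_cell_cv = cell_to_cell_cv, plateau_frac = plateau_frac,
         exit_tau = exit_tau, ref_amplitude = ref_amplitude,
         max_amp_factor = max_amp_factor),
    class = "hog1_params"
  )
}

#' Simulate one cell's Hog1 nuclear-enrichment trace
#'
#' Deterministic piecewise shape with per-cell lognormal variability on peak
#' and adaptation time. A null stimulus gives a trace identically at baseline.
#'
#' @param profile a [make_stimulus_profile()].
#' @param params a [hog1_params()].
#' @param seed optional integer seed for the per-cell variability draws.
#' @return numeric enrichment trace on the profile's frame grid.
#' @export
simulate_hog1_trace <- function(profile, params = hog1_params(), seed = NULL) {
  grid <- profile$grid
  t <- grid$time_min
  conc <- profile$conc
  amp_eff <- max(conc)
  if (amp_eff == 0) return(rep(params$baseline, grid$n_frames))

  if (!is.null(seed)) set.seed(seed)
  cv <- params$cell_to_cell_cv
  m_peak  <- if (cv > 0) stats::rlnorm(1, -cv^2 / 2, cv) else 1
  m_adapt <- if (cv > 0) stats::rlnorm(1, -cv^2 / 2, cv) else 1
  m_exit  <- if (cv > 0) stats::rlnorm(1, -cv^2 / 2, cv) else 1

  amp_factor <- min(amp_eff / params$ref_amplitude, params$max_amp_factor)
  peak <- params$baseline +
    (params$peak_enrichment - params$baseline) * amp_factor * m_peak
  adapt <- params$adaptation_time * (amp_eff / params$ref_amplitude) * m_adapt
  adapt <- max(adapt, params$rise_time + 0.5)

  rise <- params$rise_time
  # adaptation is clocked from the last increase of the stimulus: while a
  # ramp keeps rising the cells cannot catch up osmotically, so the decay
  # schedule is deferred to the time the concentration peaks
  t_conc_peak <- grid$time_min[which(conc >= amp_eff - 1e-12)[1]]
  t_conc_peak <- max(t_conc_peak, 0)
  decay_start <- t_conc_peak + rise + params$plateau_frac * (adapt - rise)
  tau <- max((adapt - rise - params$plateau_frac * (adapt - rise)) / 3, 0.1)

  a <- numeric(length(t))
  pre <- t < 0
  a[pre] <- params$baseline
  up <- !pre & t < rise
  a[up] <- params$baseline + (peak - params$baseline) * t[up] / rise
  plat <- t >= rise & t < decay_start
  a[plat] <- peak
  dec <- t >= decay_start
  a[dec] <- params$baseline +
    (peak - params$baseline) * exp(-(t[dec] - decay_start) / tau)

  if (profile$kind == "pulse") {
    pe <- profile$pulse_end
    after <- t >= pe
    if (any(after)) {
      # value the shape would have right at pulse end
      a_pe <- if (pe < rise) {
        params$baseline + (peak - params$baseline) * pe / rise
      } else if (pe < decay_start) peak else {
        params$baseline + (peak - params$baseline) *
          exp(-(pe - decay_start) / tau)
      }
      a[after] <- params$baseline +
        (a_pe - params$baseline) *
          exp(-(t[after] - pe) / (params$exit_tau * m_exit))
    }
  }
  a
}

#' Normalized Hog1 activity
#'
#' Rescales an enrichment trace to the nominal dynamic range, so that 1 is
#' the population-typical peak at the reference stress. This is the quantity
#' that gates promoter activation in [simulate_transcription()].
#'
#' @param trace enrichment trace from [simulate_hog1_trace()].
#' @param params the [hog1_params()] used to simulate it.
#' @return non-negative activity trace.
#' @export
hog1_activity <- function(trace, params = hog1_params()) {
  pmax(trace - params$baseline, 0) /
    (params$peak_enrichment - params$baseline)
}
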