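#' Osmolyte stimulus profiles
#'
#' Builds the extracellular NaCl concentration profile sampled on the
#' acquisition grid. Three dynamic regimes are supported besides the null
#' control:
#' \describe{
#'   \item{step}{concentration jumps to `amplitude` at time zero and stays
#'     there (the standard well experiment).}
#'   \item{pulse}{as step, but the medium is switched back to 0 M at
#'     `pulse_end` minutes after time zero.}
#'   \item{ramp}{initial step to `amplitude`, then a linear increase up to
#'     `ramp_end_conc` over `ramp_duration` minutes.}
#' }
#' Profiles are deterministic: no randomness enters here.
#'
#' @param kind one of `"step"`, `"pulse"`, `"ramp"`, `"none"`.
#' @param amplitude initial concentration step in mol/L.
#' @param pulse_end minutes after time zero at which a pulse returns to 0 M.
#' @param ramp_end_conc final concentration of a ramp, mol/L.
#' @param ramp_duration minutes over which the ramp rises.
#' @param grid a [frame_grid()].
#' @return a `stimulus_profile` with the concentration tabulated per frame.
#' @export
make_stimulus_profile <- function(kind = c("step", "pulse", "ramp", "none"),
                                  amplitude = 0.2,
                                  pulse_end = 7,
                                  ramp_end_conc = 0.6,
                                  ramp_duration = 20,
                                  grid = frame_grid()) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (kind == "pulse" && pulse_end <= 0) stop("pulse_end must be > 0")
  if (kind == "ramp") {
    if (ramp_duration <= 0) stop("ramp_duration must be > 0")
    if (ramp_end_conc < amplitude)
      stop("ramp_end_conc must be >= amplitude (ramps are non-decreasing)")
  }
  prof <- structure(
    list(kind = kind, amplitude = amplitude, pulse_end = pulse_end,
         ramp_end_conc = ramp_end_conc, ramp_duration = ramp_duration,
         grid = grid),
    class = "stimulus_profile"
  )
  prof$conc <- stimulus_concentration(prof, grid$time_min)
  prof
}

#' Evaluate a stimulus profile
#'
#' @param profile a `stimulus_profile`.
#' @param t_min times in minutes relative to time zero.
#' @return concentrations in mol/L.
#' @export
stimulus_concentration <- function(profile, t_min) {
  a <- profile$amplitude
  c_t <- switch(profile$kind,
    none  = rep(0, length(t_min)),
    step  = ifelse(t_min >= 0, a, 0),
    pulse = ifelse(t_min >= 0 & t_min < profile$pulse_end, a, 0),
    ramp  = ifelse(t_min < 0, 0,
              pmin(a + (profile$ramp_end_conc - a) *
                     pmax(t_min, 0) / profile$ramp_duration,
                   profile$ramp_end_conc))
  )
  stopifnot(all(c_t >= 0))
  c_t
}

#' @export
print.stimulus_profile <- function(x, ...) {
  cat(sprintf("stimulus_profile: %s, amplitude %g M", x$kind, x$amplitude))
  if (x$kind == "pulse") cat(sprintf(", back to 0 M at %g min", x$pulse_end))
  if (x$kind == "ramp")
    cat(sprintf(", to %g M over %g min", x$ramp_end_conc, x$ramp_duration))
  cat("\n")
  invisible(x)
}
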