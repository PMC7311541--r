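#' Remove single-timepoint detections
#'
#' A ConnectedHiPix detection whose previous and next frames are both
#' missing is discarded (set to missing): an isolated one-frame detection is
#' most likely noise, whereas a real transcription site persists over
#' consecutive frames. Boundary frames use their single existing neighbour.
#' The operation is idempotent.
#'
#' @param connected_hipix numeric vector with `NA` for missing.
#' @return the vector with isolated detections removed.
#' @export
remove_isolated_detections <- function(connected_hipix) {
  det <- !is.na(connected_hipix)
  n <- length(det)
  if (n <= 1) return(connected_hipix)
  prev <- c(FALSE, det[-n])
  nxt <- c(det[-1], FALSE)
  isolated <- det & !prev & !nxt
  connected_hipix[isolated] <- NA_real_
  connected_hipix
}

#' Transcription Start and End times
#'
#' The first and last timepoints with a surviving ConnectedHiPix detection
#' define transcription initiation (Start Time) and shutoff (End Time).
#' Isolated detections must have been removed first.
#'
#' @param connected_hipix cleaned detection vector.
#' @param time_min frame times, minutes relative to time zero.
#' @return list with `start`, `end` (minutes, `NA` if never detected).
#' @export
start_end_times <- function(connected_hipix, time_min) {
  det <- which(!is.na(connected_hipix))
  if (!length(det)) return(list(start = NA_real_, end = NA_real_))
  list(start = time_min[det[1]], end = time_min[det[length(det)]])
}

#' Responder classification
#'
#' `basal` if any detection occurs strictly before time zero, `responder` if
#' the first detection is at or after time zero, `non_responder` if the cell
#' is never detected.
#'
#' @param connected_hipix cleaned detection vector.
#' @param time_min frame times.
#' @return one of `"basal"`, `"responder"`, `"non_responder"`.
#' @export
classify_responder <- function(connected_hipix, time_min) {
  det <- !is.na(connected_hipix)
  if (!any(det)) return("non_responder")
  if (any(det & time_min < 0)) return("basal")
  "responder"
}

#' Centered moving average
#'
#' Window of `window` frames (default 3, i.e. 45 s at 15 s sampling);
#' missing values are ignored within the window and the edges use the
#' available part of the window.
#'
#' @param x numeric vector.
#' @param window odd window length in frames.
#' @export
moving_average <- function(x, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- max(1, i - half):min(n, i + half)
    v <- x[w]
    out[i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

trapezoid <- function(t, y) {
  ok <- !is.na(y) & !is.na(t)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 2) return(0)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Per-cell trace features
#'
#' Turns one cell's HiPix/ConnectedHiPix trace into the quantitative
#' features: Start/End Time, transcription period, responder class, trace
#' maximum and integral. The raw HiPix trace is normalized by subtracting
#' its value at the first post-stimulus frame; the maximum and the
#' (trapezoidal) integral are taken over the normalized trace restricted to
#' the `[start, end]` window, so they are invariant to anything outside the
#' transcription period. Cells without a transcription period get zero
#' maximum and integral plus a flag.
#'
#' @param hipix,connected_hipix one cell's traces on the frame grid.
#' @param grid the [frame_grid()].
#' @param smooth_window moving-average window in frames.
#' @param cell_id optional id copied to the output.
#' @return one-row data.frame of features.
#' @export
compute_trace_features <- function(hipix, connected_hipix, grid,
                                   smooth_window = 3, cell_id = NA_integer_) {
  t <- grid$time_min
  ch <- remove_isolated_detections(connected_hipix)
  se <- start_end_times(ch, t)
  cls <- classify_responder(ch, t)
  base <- hipix[grid$time_zero_frame]
  norm <- hipix - base
  smooth <- moving_average(norm, smooth_window)
  has_period <- !is.na(se$start)
  any_post <- any(!is.na(ch) & t >= 0)
  if (has_period) {
    win <- t >= se$start & t <= se$end
    trace_max <- max(norm[win], na.rm = TRUE)
    integral <- trapezoid(t[win], norm[win])
    period <- se$end - se$start
  } else {
    trace_max <- 0
    integral <- 0
    period <- NA_real_
  }
  data.frame(cell_id = cell_id,
             responder_class = cls,
             start_time = se$start, end_time = se$end,
             transcription_period = period,
             trace_max = trace_max, integral = integral,
             n_detections = sum(!is.na(ch)),
             any_post_detection = any_post,
             no_period = !has_period)
}

#' Features for every cell of a trace table
#'
#' @param traces tidy trace table from [quantify_traces()] (columns
#'   `cell_id`, `frame`, `hipix`, `connected_hipix`).
#' @param grid the [frame_grid()].
#' @param smooth_window moving-average window.
#' @return data.frame, one row per cell.
#' @export
trace_features_table <- function(traces, grid, smooth_window = 3) {
  out <- lapply(split(traces, traces$cell_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    compute_trace_features(tr$hipix, tr$connected_hipix, grid,
                           smooth_window, cell_id = tr$cell_id[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cell_id), ]
}

#' MAPK nuclear-relocation features
#'
#' From a nuclear-enrichment trace: entry time (first post-stimulus time
#' exceeding baseline plus `entry_frac` of the amplitude), time of maximal
#' enrichment, decay time (first time after the maximum below 80% of the
#' maximum), and adaptation time (first time after the maximum below
#' baseline plus `adapt_frac` of the amplitude). A cell that has not adapted
#' by the end of the movie gets its adaptation time censored to
#' `censor` minutes and a censored flag. A flat trace yields all-missing
#' features.
#'
#' @param trace enrichment trace on the frame grid.
#' @param grid the [frame_grid()].
#' @param entry_frac,adapt_frac fractions of the amplitude defining entry and
#'   adaptation.
#' @param decay_frac fraction of the maximum defining the decay time.
#' @param censor censoring value in minutes.
#' @param flat_tol amplitude below which the trace counts as flat.
#' @param cell_id optional id.
#' @return one-row data.frame: `entry_time`, `max_time`, `decay_time`,
#'   `adaptation_time`, `censored`.
#' @export
hog1_features <- function(trace, grid, entry_frac = 0.2, adapt_frac = 0.2,
                          decay_frac = 0.8, censor = 35, flat_tol = 0.05,
                          cell_id = NA_integer_) {
  t <- grid$time_min
  baseline <- mean(trace[t < 0])
  if (!any(t < 0)) baseline <- trace[1]
  amp <- max(trace) - baseline
  if (!is.finite(amp) || amp <= flat_tol) {
    return(data.frame(cell_id = cell_id, entry_time = NA_real_,
                      max_time = NA_real_, decay_time = NA_real_,
                      adaptation_time = NA_real_, censored = NA))
  }
  post <- which(t >= 0)
  entry_i <- post[which(trace[post] > baseline + entry_frac * amp)[1]]
  max_i <- which.max(trace)
  peak <- trace[max_i]
  after <- which(seq_along(t) > max_i)
  decay_i <- after[which(trace[after] < decay_frac * peak)[1]]
  adapt_i <- after[which(trace[after] < baseline + adapt_frac * amp)[1]]
  censored <- is.na(adapt_i)
  data.frame(
    cell_id = cell_id,
    entry_time = if (length(entry_i) && !is.na(entry_i)) t[entry_i] else NA_real_,
    max_time = t[max_i],
    decay_time = if (length(decay_i) && !is.na(decay_i)) t[decay_i] else NA_real_,
    adaptation_time = if (censored) censor else t[adapt_i],
    censored = censored
  )
}

#' Hog1 features for a population
#'
#' @param traces cells x frames enrichment matrix.
#' @param grid the [frame_grid()].
#' @param ... passed to [hog1_features()].
#' @return data.frame, one row per cell.
#' @export
hog1_features_table <- function(traces, grid, ...) {
  res <- do.call(rbind, lapply(seq_len(nrow(traces)), function(i) {
    hog1_features(traces[i, ], grid, cell_id = i, ...)
  }))
  rownames(res) <- NULL
  res
}
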