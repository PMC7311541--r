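#' Acquisition time grid
#'
#' The default grid mirrors the live-imaging protocol used throughout the
#' package: one GFP acquisition every 15 s for 25 min (100 frames), with the
#' osmotic stimulus added just before frame 4, which therefore defines time
#' zero. Frame times are reported in minutes relative to time zero, so the
#' three pre-stimulus frames carry negative times.
#'
#' @param n_frames number of timepoints.
#' @param interval_s acquisition interval in seconds.
#' @param time_zero_frame 1-based index of the first post-stimulus frame.
#' @return an object of class `frame_grid` with the frame times in minutes.
#' @export
frame_grid <- function(n_frames = 100, interval_s = 15, time_zero_frame = 4) {
  stopifnot(n_frames >= 1, interval_s > 0,
            time_zero_frame >= 1, time_zero_frame <= n_frames)
  structure(
    list(
      n_frames = as.integer(n_frames),
      interval_s = interval_s,
      interval_min = interval_s / 60,
      time_zero_frame = as.integer(time_zero_frame),
      time_min = (seq_len(n_frames) - time_zero_frame) * interval_s / 60
    ),
    class = "frame_grid"
  )
}

#' @export
print.frame_grid <- function(x, ...) {
  cat(sprintf("frame_grid: %d frames, %g s interval, time zero at frame %d\n",
              x$n_frames, x$interval_s, x$time_zero_frame))
  invisible(x)
}

# deterministic per-cell seed stream derived from one master seed
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + as.numeric(i) * 9973) %% 2147483399) + 1L
}
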