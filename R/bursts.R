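#' Candidate peaks in a transcription-site trace
#'
#' Local maxima of the smoothed, normalized trace, strictly inside the
#' `[start, end]` transcription window, with value strictly above the count
#' threshold. Plateaus are represented by their leftmost index.
#'
#' @param y smoothed normalized trace on the frame grid.
#' @param time_min frame times, minutes.
#' @param start,end transcription window in minutes ([start_end_times()]);
#'   if either is missing the candidate list is empty.
#' @param threshold minimum peak value, counts (strict).
#' @return data.frame `idx` (frame index), `time`, `value`.
#' @export
find_candidate_peaks <- function(y, time_min, start, end, threshold = 7) {
  empty <- data.frame(idx = integer(), time = numeric(), value = numeric())
  if (is.na(start) || is.na(end)) return(empty)
  win <- which(time_min >= start & time_min <= end)
  if (length(win) < 3) return(empty)
  yw <- y[win]
  # collapse runs of equal values; a run is a local max if both neighbouring
  # run values are lower; boundary runs are excluded (strictly inside)
  r <- rle(yw)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nr <- length(r$values)
  cand <- integer()
  if (nr >= 3) {
    for (j in 2:(nr - 1)) {
      v <- r$values[j]
      if (!is.na(v) && v > threshold &&
          !is.na(r$values[j - 1]) && !is.na(r$values[j + 1]) &&
          r$values[j - 1] < v && r$values[j + 1] < v) {
        cand <- c(cand, starts[j])
      }
    }
  }
  idx <- win[cand]
  data.frame(idx = idx, time = time_min[idx], value = y[idx])
}

# trough value and index between two frame indices a < b on trace y
trough_between <- function(y, a, b) {
  if (b - a >= 2) {
    interior <- (a + 1):(b - 1)
    i <- interior[which.min(y[interior])]
  } else {
    i <- c(a, b)[which.min(y[c(a, b)])]
  }
  list(idx = i, value = y[i])
}

#' Four-rule burst (peak) filter
#'
#' Refines the candidate peaks with the trough conditions, left to right,
#' recomputing after every merge: the boundary between two neighbouring
#' peaks is kept only if the drop after the left peak exceeds a quarter of
#' that peak's intensity AND the rise to the right peak exceeds a third of
#' the trough value; otherwise the pair is merged, retaining the higher peak
#' (tie: the earlier). Finally any peak below one-fifth of the trace maximum
#' is discarded, and the cell is classified by the surviving peak count
#' (`1P`, `2P`, `3P_plus`; `0P` when nothing survives).
#'
#' @param candidates data.frame from [find_candidate_peaks()].
#' @param y the same smoothed normalized trace.
#' @param time_min frame times.
#' @param start,end transcription window, minutes.
#' @return a `peak_set`: list with `peaks` (data.frame `idx`, `time`,
#'   `value`, `left_bound`, `right_bound`, `duration`), `n_peaks`, `class`.
#' @export
filter_peaks <- function(candidates, y, time_min, start, end) {
  idx <- candidates$idx
  # pairwise trough merging, restart after each merge (left to right)
  repeat {
    if (length(idx) < 2) break
    merged <- FALSE
    for (i in seq_len(length(idx) - 1)) {
      a <- idx[i]; b <- idx[i + 1]
      tr <- trough_between(y, a, b)$value
      drop_ok <- (y[a] - tr) > y[a] / 4
      rise_ok <- (y[b] - tr) > tr / 3
      if (!(drop_ok && rise_ok)) {
        keep <- if (y[b] > y[a]) b else a   # tie keeps the earlier (a)
        idx <- c(idx[seq_len(i - 1)], keep,
                 if (i + 2 <= length(idx)) idx[(i + 2):length(idx)])
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # fifth-of-max pruning over the transcription window
  if (length(idx)) {
    win <- which(time_min >= start & time_min <= end)
    ymax <- max(y[win], na.rm = TRUE)
    idx <- idx[y[idx] >= ymax / 5]
  }
  peaks <- peak_durations(idx, y, time_min, start, end)
  n <- nrow(peaks)
  cls <- if (n == 0) "0P" else if (n == 1) "1P" else if (n == 2) "2P" else "3P_plus"
  structure(list(peaks = peaks, n_peaks = n, class = cls), class = "peak_set")
}

#' Peak boundaries and durations
#'
#' Interior boundaries between retained peaks sit at the trough positions;
#' the outermost boundaries are the Start and End detections, so a
#' single-peak trace has duration equal to the transcription period.
#'
#' @param idx frame indices of the retained peaks, increasing.
#' @param y trace, `time_min` frame times, `start`/`end` window in minutes.
#' @param time_min,start,end as in [filter_peaks()].
#' @return data.frame, one row per peak.
#' @export
peak_durations <- function(idx, y, time_min, start, end) {
  if (!length(idx))
    return(data.frame(idx = integer(), time = numeric(), value = numeric(),
                      left_bound = numeric(), right_bound = numeric(),
                      duration = numeric()))
  n <- length(idx)
  bounds <- numeric(n + 1)
  bounds[1] <- start
  bounds[n + 1] <- end
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      bounds[i + 1] <- time_min[trough_between(y, idx[i], idx[i + 1])$idx]
    }
  }
  data.frame(idx = idx, time = time_min[idx], value = y[idx],
             left_bound = bounds[seq_len(n)],
             right_bound = bounds[seq_len(n) + 1],
             duration = bounds[seq_len(n) + 1] - bounds[seq_len(n)])
}

#' Detect bursts in one cell's trace
#'
#' Orchestration: clean the detection trace, locate the transcription
#' window, smooth and normalize the HiPix trace, then apply the threshold
#' and the four-rule filter.
#'
#' @param hipix,connected_hipix one cell's traces.
#' @param grid the [frame_grid()].
#' @param threshold findpeak count threshold.
#' @param smooth_window moving-average window in frames.
#' @return a `peak_set`.
#' @export
detect_bursts <- function(hipix, connected_hipix, grid, threshold = 7,
                          smooth_window = 3) {
  t <- grid$time_min
  ch <- remove_isolated_detections(connected_hipix)
  se <- start_end_times(ch, t)
  norm <- hipix - hipix[grid$time_zero_frame]
  y <- moving_average(norm, smooth_window)
  cand <- find_candidate_peaks(y, t, se$start, se$end, threshold)
  filter_peaks(cand, y, t, se$start, se$end)
}

#' Bursts for every cell of a trace table
#'
#' @param traces tidy trace table ([quantify_traces()]).
#' @param grid the [frame_grid()].
#' @param ... passed to [detect_bursts()].
#' @return list with `peaks` (tidy data.frame over all cells) and `classes`
#'   (per-cell peak-count class).
#' @export
burst_table <- function(traces, grid, ...) {
  sets <- lapply(split(traces, traces$cell_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    detect_bursts(tr$hipix, tr$connected_hipix, grid, ...)
  })
  ids <- as.integer(names(sets))
  peaks <- do.call(rbind, lapply(seq_along(sets), function(i) {
    p <- sets[[i]]$peaks
    if (!nrow(p)) return(NULL)
    cbind(cell_id = ids[i], p)
  }))
  if (is.null(peaks))
    peaks <- data.frame(cell_id = integer(), idx = integer(), time = numeric(),
                        value = numeric(), left_bound = numeric(),
                        right_bound = numeric(), duration = numeric())
  classes <- data.frame(cell_id = ids,
                        n_peaks = vapply(sets, `[[`, 0, "n_peaks"),
                        peak_class = vapply(sets, `[[`, "", "class"))
  rownames(classes) <- NULL
  list(peaks = peaks, classes = classes)
}
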