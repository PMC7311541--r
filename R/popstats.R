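#' Empirical CDF of Start Times
#'
#' Over responders only by default: cells with basal (pre-stimulus)
#' detections and cells that never respond are excluded, so the curve shows
#' when stimulus-induced transcription begins.
#'
#' @param features per-cell feature table ([trace_features_table()]).
#' @param responders_only exclude basal and non-responding cells.
#' @return data.frame `time` (sorted unique Start Times, minutes) and
#'   `fraction` (non-decreasing, ending at 1); attribute `empty` flags a
#'   zero-responder input.
#' @export
start_time_cdf <- function(features, responders_only = TRUE) {
  x <- if (responders_only)
    features$start_time[features$responder_class == "responder"]
  else features$start_time[!is.na(features$start_time)]
  x <- x[!is.na(x)]
  if (!length(x))
    return(structure(data.frame(time = numeric(), fraction = numeric()),
                     empty = TRUE))
  tt <- sort(unique(x))
  structure(data.frame(time = tt, fraction = stats::ecdf(x)(tt)),
            empty = FALSE)
}

#' Survival curve of End Times
#'
#' One minus the empirical CDF of the responders' End Times: the fraction of
#' cells still transcribing at each time.
#'
#' @param features per-cell feature table.
#' @return data.frame `time`, `fraction` (non-increasing from 1); attribute
#'   `empty` flags a zero-responder input.
#' @export
end_time_survival <- function(features) {
  x <- features$end_time[features$responder_class == "responder"]
  x <- x[!is.na(x)]
  if (!length(x))
    return(structure(data.frame(time = numeric(), fraction = numeric()),
                     empty = TRUE))
  tt <- sort(unique(x))
  structure(data.frame(time = tt, fraction = 1 - stats::ecdf(x)(tt)),
            empty = FALSE)
}

#' Basal and responding fractions
#'
#' The basal fraction is the share of valid cells with a detection in the
#' pre-stimulus frames; the responding fraction is the share with any
#' post-stimulus detection (basal cells that keep transcribing count in
#' both).
#'
#' @param features per-cell feature table.
#' @return list `fraction_basal`, `fraction_responding`, `n_cells`.
#' @export
fractions <- function(features) {
  n <- nrow(features)
  if (!n) return(list(fraction_basal = 0, fraction_responding = 0, n_cells = 0))
  list(
    fraction_basal = mean(features$responder_class == "basal"),
    fraction_responding = mean(features$any_post_detection),
    n_cells = n
  )
}

#' Start-time percentiles
#'
#' @param features per-cell feature table.
#' @param probs percentile levels.
#' @return named numeric; linear-interpolation percentiles of the
#'   responders' Start Times.
#' @export
start_percentiles <- function(features, probs = c(0.1, 0.5, 0.9)) {
  x <- features$start_time[features$responder_class == "responder"]
  stats::quantile(x[!is.na(x)], probs = probs, type = 7, names = TRUE)
}

#' Transcriptional output by Start-Time quartile
#'
#' Responders are ranked by Start Time (ties broken by cell id, remainder
#' cells assigned to the earlier quartiles) and split into four groups; per
#' quartile the median and the 25th/75th percentiles of the trace integral
#' are reported. Requires at least 8 responders.
#'
#' @param features per-cell feature table.
#' @return data.frame, one row per quartile (`quartile`, `n`, `median`,
#'   `q25`, `q75`), or `NULL` with a warning if under 8 responders.
#' @export
start_quartile_output <- function(features) {
  r <- features[features$responder_class == "responder" &
                  !is.na(features$start_time), ]
  if (nrow(r) < 8) {
    warning("fewer than 8 responders; quartile analysis not computed")
    return(NULL)
  }
  r <- r[order(r$start_time, r$cell_id), ]
  n <- nrow(r)
  base <- n %/% 4
  extra <- n %% 4
  sizes <- base + (seq_len(4) <= extra)
  q <- rep(seq_len(4), times = sizes)
  out <- do.call(rbind, lapply(seq_len(4), function(i) {
    v <- r$integral[q == i]
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
    data.frame(quartile = i, n = length(v),
               median = qs[2], q25 = qs[1], q75 = qs[3])
  }))
  rownames(out) <- NULL
  out
}

#' Correlation between MAPK adaptation time and transcription End Time
#'
#' Pearson correlation over cells measured in both channels; censored
#' adaptation times enter at the censoring value (35 min by convention) and
#' their count is reported.
#'
#' @param hog1_features per-cell table from [hog1_features_table()].
#' @param trace_features per-cell table from [trace_features_table()].
#' @return list `r`, `n`, `n_censored`, `flag` (`"ok"`, `"too_few"`,
#'   `"degenerate"`).
#' @export
adaptation_endtime_correlation <- function(hog1_features, trace_features) {
  m <- merge(hog1_features, trace_features, by = "cell_id")
  m <- m[!is.na(m$adaptation_time) & !is.na(m$end_time), ]
  n <- nrow(m)
  n_cens <- sum(m$censored, na.rm = TRUE)
  if (n < 3)
    return(list(r = NA_real_, n = n, n_censored = n_cens, flag = "too_few"))
  if (stats::sd(m$adaptation_time) == 0 || stats::sd(m$end_time) == 0)
    return(list(r = NA_real_, n = n, n_censored = n_cens, flag = "degenerate"))
  list(r = stats::cor(m$adaptation_time, m$end_time), n = n,
       n_censored = n_cens, flag = "ok")
}

#' Expected lifetime of one transcript at the transcription site
#'
#' The time a single transcript stays visible at the locus: the transcript
#' length divided by the PolII elongation speed. At the default reporter
#' geometry (1.5 kb stem-loop cassette + 6.5 kb downstream ORF = 8 kb) and
#' 20 bp/s this is 400 s, i.e. 6.7 min to the reported 0.1-min precision.
#'
#' @param transcript_length_bp transcript length in bp.
#' @param elongation_speed_bp_per_s elongation speed in bp/s.
#' @return list `seconds` (exact) and `minutes` (rounded to 0.1 min).
#' @export
expected_ts_lifetime <- function(transcript_length_bp = 8000,
                                 elongation_speed_bp_per_s = 20) {
  if (transcript_length_bp <= 0 || elongation_speed_bp_per_s <= 0)
    stop("transcript length and elongation speed must be positive")
  s <- transcript_length_bp / elongation_speed_bp_per_s
  list(seconds = s, minutes = round(s / 60, 1))
}

#' Population summary bundle
#'
#' Convenience aggregation of the population-level analyses.
#'
#' @param features per-cell trace feature table.
#' @param hog1_features optional Hog1 feature table for the correlation.
#' @return list of the individual summaries.
#' @export
population_summary <- function(features, hog1_features = NULL) {
  out <- list(
    fractions = fractions(features),
    start_time_cdf = start_time_cdf(features),
    end_time_survival = end_time_survival(features),
    start_percentiles = tryCatch(start_percentiles(features),
                                 error = function(e) NULL),
    quartile_output = tryCatch(
      suppressWarnings(start_quartile_output(features)),
      error = function(e) NULL)
  )
  if (!is.null(hog1_features))
    out$adaptation_endtime <- adaptation_endtime_correlation(hog1_features,
                                                             features)
  out
}
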