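#' Pipeline configuration
#'
#' One flat configuration object holding every module's parameters with
#' their documented defaults; it round-trips losslessly through JSON
#' ([save_config()] / [load_config()]) so a single file plus the master seed
#' reproduces any run. Overrides are given as named nested lists.
#'
#' @param ... nested overrides, e.g. `stimulus = list(kind = "pulse")`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    grid = list(n_frames = 100, interval_s = 15, time_zero_frame = 4),
    stimulus = list(kind = "step", amplitude = 0.2, pulse_end = 7,
                    ramp_end_conc = 0.6, ramp_duration = 20),
    hog1 = unclass(hog1_params()),
    promoter = unclass(promoter_params()),
    simulate = list(n_cells = 100, mode = "movie"),
    observe = list(counts_per_mRNA = 12, noise_sd = 3, detect_min = 1.5),
    render = list(),
    segmentation = list(bypass = FALSE, expand_px = 5, min_area = 20,
                        ecc_max = 0.95, area_range = c(40, Inf),
                        intensity_range = c(0, Inf), max_disp = 10),
    quantify = list(k = 20, se = "cross"),
    features = list(smooth_window = 3),
    bursts = list(threshold = 7),
    hog1_features = list(entry_frac = 0.2, adapt_frac = 0.2,
                         decay_frac = 0.8, censor = 35)
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  cfg <- utils::modifyList(cfg, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(raw)
}

config_grid <- function(config) do.call(frame_grid, config$grid)

config_profile <- function(config) {
  do.call(make_stimulus_profile,
          c(config$stimulus, list(grid = config_grid(config))))
}

# match recovered track positions to simulated cell positions
match_tracks_to_truth <- function(tracks, layout_cells, max_dist) {
  agg_x <- tapply(tracks$x, tracks$cell_id, stats::median)
  agg_y <- tapply(tracks$y, tracks$cell_id, stats::median)
  ids <- as.integer(names(agg_x))
  map <- rep(NA_integer_, length(ids))
  for (i in seq_along(ids)) {
    d2 <- (layout_cells$x - agg_x[i])^2 + (layout_cells$y - agg_y[i])^2
    j <- which.min(d2)
    if (length(j) && d2[j] <= max_dist^2) map[i] <- layout_cells$cell_id[j]
  }
  stats::setNames(map, ids)
}

# analyze one rendered field; returns the tidy trace table with cell ids
# remapped to the simulator's ground-truth ids (unmatched tracks dropped,
# counted in attr "n_unmatched")
analyze_field <- function(rf, cells, grid, config) {
  seg_cfg <- config$segmentation
  proj <- max_project(rf$gfp)
  if (isTRUE(seg_cfg$bypass)) {
    seg <- segment_from_truth(rf$cell_mask, rf$nucleus_mask,
                              gfp_frame = proj[, , 1],
                              expand_px = seg_cfg$expand_px)
    frames <- list(seg)
    fe <- seg$features
    tracks <- data.frame(cell_id = fe$label, frame = 1L, label = fe$label,
                         x = fe$x, y = fe$y)
    tracks <- filter_cells(tracks, frames, ecc_max = seg_cfg$ecc_max,
                           area_range = seg_cfg$area_range,
                           intensity_range = seg_cfg$intensity_range)
    traces <- quantify_traces(proj, frames, tracks, grid,
                              k = config$quantify$k, se = config$quantify$se)
    attr(traces, "n_unmatched") <- 0L
    return(traces)
  }
  frames <- lapply(seq_len(grid$n_frames), function(f) {
    segment_frame(rf$nuc[, , f], rf$proxy[, , f], proj[, , f],
                  expand_px = seg_cfg$expand_px, min_area = seg_cfg$min_area)
  })
  tracks <- track_cells(frames, max_disp = seg_cfg$max_disp)
  tracks <- filter_cells(tracks, frames, ecc_max = seg_cfg$ecc_max,
                         area_range = seg_cfg$area_range,
                         intensity_range = seg_cfg$intensity_range)
  traces <- quantify_traces(proj, frames, tracks, grid,
                            k = config$quantify$k, se = config$quantify$se)
  map <- match_tracks_to_truth(tracks, cells,
                               max_dist = config$render$cell_radius %||% 10)
  mapped <- map[as.character(traces$cell_id)]
  n_unmatched <- length(unique(traces$cell_id[is.na(mapped)]))
  traces <- traces[!is.na(mapped), ]
  traces$cell_id <- mapped[!is.na(mapped)]
  # if two tracks map to one truth cell keep the first
  traces <- traces[!duplicated(paste(traces$cell_id, traces$frame)), ]
  attr(traces, "n_unmatched") <- n_unmatched
  traces
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Simulate, render (or use the trace-level observation model), segment (or
#' bypass with truth masks), quantify, extract features, detect bursts and
#' summarize — all from one configuration and one master seed, field by
#' field so memory stays bounded. With `out_dir` set, per-stage CSV/JSON
#' outputs and a reproducibility manifest are written.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress stage messages.
#' @return list with `truth`, `traces`, `features`, `hog1_features`,
#'   `bursts`, `summary`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  grid <- config_grid(config)
  profile <- config_profile(config)
  hog1 <- do.call(hog1_params, config$hog1)
  promoter <- do.call(promoter_params, config$promoter)
  n_cells <- config$simulate$n_cells

  say("simulate: %d cells, %s stimulus (%g M)", n_cells,
      profile$kind, profile$amplitude)
  sim <- simulate_cells(n_cells, profile, hog1, promoter, seed = config$seed)
  truth <- truth_table(sim)

  if (identical(config$simulate$mode, "trace")) {
    ob <- do.call(observe_traces,
                  c(list(intensity = sim$intensity), config$observe,
                    list(seed = derive_seed(config$seed, 999L))))
    traces <- data.frame(
      cell_id = rep(seq_len(n_cells), each = grid$n_frames),
      frame = rep(seq_len(grid$n_frames), n_cells),
      time_min = rep(grid$time_min, n_cells),
      hipix = as.vector(t(ob$hipix)),
      connected_hipix = as.vector(t(ob$connected_hipix)),
      valid = TRUE
    )
  } else {
    rcfg <- do.call(render_config, config$render)
    lay <- layout_cells(n_cells, rcfg, seed = derive_seed(config$seed, 0L))
    fields <- split(seq_len(nrow(lay)), lay$field)
    say("render + analyze: %d fields (%s segmentation)", length(fields),
        if (isTRUE(config$segmentation$bypass)) "bypass" else "seeded-watershed")
    trace_parts <- vector("list", length(fields))
    n_unmatched <- 0L
    for (fi in seq_along(fields)) {
      ix <- fields[[fi]]
      cells <- lay[ix, , drop = FALSE]
      attr(cells, "field_size") <- attr(lay, "field_size")
      rf <- render_field(cells, sim$intensity[ix, , drop = FALSE], grid,
                         rcfg, seed = derive_seed(config$seed, 100L + fi))
      tr <- analyze_field(rf, cells, grid, config)
      n_unmatched <- n_unmatched + attr(tr, "n_unmatched")
      trace_parts[[fi]] <- tr
    }
    traces <- do.call(rbind, trace_parts)
    say("tracking: %d tracks could not be matched to a simulated cell",
        n_unmatched)
  }

  say("features: extracting per-cell trace features")
  feats <- trace_features_table(traces, grid,
                                smooth_window = config$features$smooth_window)
  hfeats <- hog1_features_table(sim$hog1_traces, grid,
                                entry_frac = config$hog1_features$entry_frac,
                                adapt_frac = config$hog1_features$adapt_frac,
                                decay_frac = config$hog1_features$decay_frac,
                                censor = config$hog1_features$censor)
  say("bursts: four-rule peak filter, threshold %g counts",
      config$bursts$threshold)
  bursts <- burst_table(traces, grid, threshold = config$bursts$threshold,
                        smooth_window = config$features$smooth_window)
  feats <- merge(feats, bursts$classes, by = "cell_id", all.x = TRUE)
  summary <- population_summary(feats, hfeats)
  say("population: %d/%d cells responding (%.0f%%)",
      sum(feats$any_post_detection), nrow(feats),
      100 * summary$fractions$fraction_responding)

  res <- list(truth = truth, traces = traces, features = feats,
              hog1_features = hfeats, bursts = bursts, summary = summary,
              config = config, sim = sim)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(res$truth, file.path(out_dir, "cell_truth.csv"))
  write_table_csv(res$traces, file.path(out_dir, "ts_traces.csv"))
  write_table_csv(res$features, file.path(out_dir, "trace_features.csv"))
  write_table_csv(res$hog1_features, file.path(out_dir, "hog1_features.csv"))
  write_table_csv(res$bursts$peaks, file.path(out_dir, "peaks.csv"))
  s <- res$summary
  jsonlite::write_json(
    list(fractions = s$fractions,
         start_percentiles = as.list(s$start_percentiles),
         adaptation_endtime = s$adaptation_endtime),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  write_table_csv(s$start_time_cdf, file.path(out_dir, "start_time_cdf.csv"))
  write_table_csv(s$end_time_survival,
                  file.path(out_dir, "end_time_survival.csv"))
  if (!is.null(s$quartile_output))
    write_table_csv(s$quartile_output,
                    file.path(out_dir, "start_quartiles.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("tsburst")),
    seed = res$config$seed,
    n_cells = nrow(res$truth),
    config = unclass(res$config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
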