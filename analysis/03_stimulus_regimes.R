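#!/usr/bin/env Rscript
# Step / pulse / ramp comparison: how the shape of the osmolyte input sets
# the MAPK activity window and, through it, the start and shutoff of
# transcription. Trace-level simulation (300 cells per regime) for speed;
# writes start-time CDFs, end-time survival curves, and the adaptation vs
# end-time correlation (censored at 35 min) under results/regimes/.

library(tsburst)

out <- "results/regimes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
g <- frame_grid()
n <- 300
seed0 <- 10

regimes <- list(
  step  = make_stimulus_profile("step", 0.2, grid = g),
  pulse = make_stimulus_profile("pulse", 0.2, pulse_end = 7, grid = g),
  ramp  = make_stimulus_profile("ramp", 0.2, ramp_end_conc = 0.6,
                                ramp_duration = 20, grid = g)
)

summaries <- list()
for (nm in names(regimes)) {
  sim <- simulate_cells(n, regimes[[nm]], seed = seed0)
  ob <- observe_traces(sim$intensity, seed = seed0 + 1)
  traces <- data.frame(
    cell_id = rep(seq_len(n), each = g$n_frames),
    frame = rep(seq_len(g$n_frames), n),
    time_min = rep(g$time_min, n),
    hipix = as.vector(t(ob$hipix)),
    connected_hipix = as.vector(t(ob$connected_hipix)), valid = TRUE)
  fe <- trace_features_table(traces, g)
  hf <- hog1_features_table(sim$hog1_traces, g, censor = 35)
  write_table_csv(start_time_cdf(fe),
                  file.path(out, paste0(nm, "_start_cdf.csv")))
  write_table_csv(end_time_survival(fe),
                  file.path(out, paste0(nm, "_end_survival.csv")))
  corr <- adaptation_endtime_correlation(hf, fe)
  summaries[[nm]] <- data.frame(
    regime = nm,
    frac_responding = fractions(fe)$fraction_responding,
    median_end = median(fe$end_time, na.rm = TRUE),
    adaptation_endtime_r = corr$r,
    n_censored = corr$n_censored)
  message(sprintf(
    "%-5s: %.0f%% responding, median end %.1f min, r(adapt, end) = %.2f (%d censored)",
    nm, 100 * summaries[[nm]]$frac_responding, summaries[[nm]]$median_end,
    corr$r, corr$n_censored))
}
tab <- do.call(rbind, summaries)
write_table_csv(tab, file.path(out, "regime_summary.csv"))

stopifnot(tab["pulse", "median_end"] < tab["step", "median_end"],
          tab["step", "median_end"] < tab["ramp", "median_end"])
message("pulse shuts transcription off earliest, the ramp extends it — the ",
        "MAPK window bounds the transcription period")
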