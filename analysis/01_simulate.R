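#!/usr/bin/env Rscript
# Simulate the reference experiment: 100 cells carrying a repressed
# stress-promoter reporter under a 0.2 M NaCl step, rendered as noisy
# multi-channel Z-stack movies with ground truth. Writes the movie of the
# first field plus the truth tables under results/simulation/.
#
# The full pipeline over these images is run by 02_analyze_movie.R; this
# script materializes the raw data products (TIFF + sidecar + truth CSV).

library(tsburst)

out <- "results/simulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

grid <- frame_grid()                        # 100 frames, 15 s, t0 = frame 4
profile <- make_stimulus_profile("step", amplitude = 0.2, grid = grid)
sim <- simulate_cells(100, profile, seed = seed)
write_table_csv(truth_table(sim), file.path(out, "cell_truth.csv"))

rcfg <- render_config()
lay <- layout_cells(100, rcfg, seed = seed)
write_table_csv(lay, file.path(out, "layout.csv"))

# one field as a browsable TIFF product (the analysis scripts re-render all
# fields in memory; images are bulky, so only field 1 is materialized)
ix <- which(lay$field == 1)
cells <- lay[ix, , drop = FALSE]
attr(cells, "field_size") <- attr(lay, "field_size")
rf <- render_field(cells, sim$intensity[ix, , drop = FALSE], grid, rcfg,
                   seed = seed + 100)
write_image_tiff(rf$gfp, file.path(out, "field1_gfp.tif"))
write_image_tiff(rf$nuc, file.path(out, "field1_nuclear.tif"))
write_label_tiff(rf$cell_mask, file.path(out, "field1_truth_cells.tif"))
write_label_tiff(rf$nucleus_mask, file.path(out, "field1_truth_nuclei.tif"))

tt <- truth_table(sim)
message(sprintf("simulated %d cells: %.0f%% activate, median truth start %.2f min",
                nrow(tt), 100 * mean(!is.na(tt$stress_on_time)),
                median(tt$true_start_time, na.rm = TRUE)))
message("wrote ", out)
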