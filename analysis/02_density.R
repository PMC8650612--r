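#!/usr/bin/env Rscript
# Step 2 -- reduce the rendered time-lapses to density representations:
# adaptive binarization, radial profiles (the corona appears as a travelling
# peripheral peak) and a tile-count density grid of one frame.

suppressPackageStartupMessages(library(coronakit))
out <- "results/analysis"

for (name in c("confined", "mechanistic", "unconfined")) {
  agents <- read.csv(file.path(out, paste0(name, "_agents.csv")))
  preset <- switch(name,
    confined = colony_preset("AX2-confined", seed = 1, duration = 6),
    mechanistic = colony_preset("AX2-confined", seed = 1,
                                mode = "mechanistic", duration = 2.5),
    unconfined = colony_preset("NC-spreading", seed = 1))
  sim <- simulate_colony(preset,
                         frame_times = sort(unique(agents$t_min)))
  profs <- profile_series(sim)
  write_profiles_csv(profs, file.path(out, paste0(name, "_profiles.csv")))
  cat(sprintf("%-12s %3d profiles, centre (%.1f, %.1f) um\n", name,
              length(profs), attr(profs, "center")[1],
              attr(profs, "center")[2]))
}

# tile-count density grid of the uniform run's first frame
p <- colony_preset("uniform-motility", seed = 1)
sim <- simulate_colony(p, frame_times = 0)
fr <- render_frames(sim)$frames[[1]]
grid <- count_cells_grid(fr, tile = 200, pixel_size = p$pixel_size, time = 0)
write.csv(grid$counts, file.path(out, "uniform_grid_counts.csv"),
          row.names = FALSE)
cat(sprintf("uniform frame: %d detections over %d occupied tiles (true cells: %d)\n",
            sum(grid$counts$count), nrow(grid$counts), p$n_cells))
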