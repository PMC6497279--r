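#!/usr/bin/env Rscript
# Stage 1: generate the synthetic survey inputs.
#
# Two streams are produced under results/sim/:
#   * testset/   -- a 9155-frame consecutive (5 fps) stream emulating the
#     fully annotated camera test set: test-set taxon composition, ~339
#     organisms arriving with the transect-calibrated patchiness, each
#     persisting in 3-5 overlapping frames;
#   * transects/ -- a 4393-frame record emulating the every-30th-frame
#     production annotation, calibrated so that per-frame counts average
#     3035/4393 organisms and 33.3% of frames are occupied.

suppressPackageStartupMessages(library(towcam))

seed <- 1L
out <- "results/sim"

message("-- every-30th-frame production record (calibrated NB arrivals) --")
cfg <- read_pipeline_config()
cfg$seed <- seed
cfg$paths$out_dir <- file.path(out, "transects")
stream <- run_simulate(cfg)
occ <- mean(rowSums(stream$records[taxon_columns(stream$records)]) > 0)
message(sprintf("occupied frames: %.1f%% (surveyed: 33.3%%)", 100 * occ))

message("-- consecutive 5 fps test-set stream with 3-5 frame persistence --")
base <- calibrate(3035, 4393, 1463 / 4393)
ts_cfg <- sim_config(9155, organism_rate = 339 / 9155, theta = base$theta,
                     persistence_range = c(3, 5), seed = seed,
                     transect_id = "TestSet")
ts <- generate_frame_stream(ts_cfg)
dir.create(file.path(out, "testset"), recursive = TRUE, showWarnings = FALSE)
write_frame_annotations(ts$records, file.path(out, "testset/annotations.csv"))
jsonlite::write_json(ts$truth[c("proportions", "H", "N2")],
                     file.path(out, "testset/truth.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("%d frames, %d organisms, true N2 = %.3f",
                nrow(ts$records), nrow(ts$truth$organisms), ts$truth$N2))
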