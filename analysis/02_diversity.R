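#!/usr/bin/env Rscript
# Stage 2: diversity tables from the published count table and the
# synthetic streams.
#
# Writes results/diversity/:
#   published_columns.csv -- H and N2 for each published survey column
#     (beam trawl, camera test set, pooled transects) at taxon, order and
#     class rank;
#   simulated_transects.csv -- per-transect diversity of the stage-1
#     synthetic record.

suppressPackageStartupMessages(library(towcam))
library(dplyr)

dir.create("results/diversity", recursive = TRUE, showWarnings = FALSE)

sc <- survey_counts()
tax <- read_taxonomy()
cols <- c("beam_trawl", "test_set", "transects_1_7")
tabs <- bind_rows(lapply(cols, function(cl) {
  v <- setNames(sc[[cl]], sc$common_name)
  bind_rows(lapply(c("taxon", "order", "class"), function(rk) {
    bind_cols(tibble::tibble(column = cl, rank = rk),
              diversity_summary(aggregate_counts(v, tax, rk)))
  }))
}))
readr::write_csv(tabs, "results/diversity/published_columns.csv")
message("published columns:")
print(as.data.frame(tabs[tabs$rank == "taxon", c("column", "n", "S", "H", "N2")]),
      row.names = FALSE, digits = 4)

ann <- "results/sim/transects/annotations.csv"
if (file.exists(ann)) {
  rec <- read_frame_annotations(ann)
  div <- diversity_by_group(rec, tax, rank = "taxon")
  readr::write_csv(div, "results/diversity/simulated_transects.csv")
} else {
  message("run analysis/01_simulate.R first for the simulated table")
}
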