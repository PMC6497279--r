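#!/usr/bin/env Rscript
# Stage 3: how many frames are enough?
#
# Replicates the subsampling study on the stage-1 synthetic test set:
# 40 systematic intervals (5-300 frames, random starts) and 36
# log-spaced random sizes (31-1778 frames), 10 replicates each, then
# LOWESS plateau detection and the 25% CV rule on the random curve.
# Writes results/sufficiency/{systematic,random}_curve.csv and
# sufficiency.json.

suppressPackageStartupMessages(library(towcam))

ann <- "results/sim/testset/annotations.csv"
if (!file.exists(ann)) stop("run analysis/01_simulate.R first")
rec <- read_frame_annotations(ann)
N <- nrow(rec)
dir.create("results/sufficiency", recursive = TRUE, showWarnings = FALSE)

set.seed(1)
sys_curve <- run_design(rec, subsample_design("systematic", n_reps = 10))
rnd_curve <- run_design(rec, subsample_design("random", n_reps = 10))
readr::write_csv(sys_curve, "results/sufficiency/systematic_curve.csv")
readr::write_csv(rnd_curve, "results/sufficiency/random_curve.csv")

rep <- suppressWarnings(sufficiency_report(rnd_curve, n_total = N))
print(rep)
write_sufficiency_report(rep, "results/sufficiency/sufficiency.json")

# the two halves of the test set, as in the original 15-minute-segment check
halves <- split_halves(rec)
for (h in names(halves)) {
  set.seed(2)
  cv <- run_design(halves[[h]],
                   subsample_design("random",
                                    sizes = log_spaced_sizes(31, 1778, 36),
                                    n_reps = 10))
  hrep <- suppressWarnings(sufficiency_report(cv, n_total = nrow(halves[[h]])))
  message(h, " half: n* = ", hrep$n_star, " frames")
}
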