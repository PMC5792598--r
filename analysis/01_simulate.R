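#!/usr/bin/env Rscript
# Stage 1: generate the synthetic drought experiment.
# Emulates the field campaign: 10/10/4 trees in the irrigated/ambient/
# droughted plots, one measured branch per tree (three on droughted trees),
# 2007-2013 climate anchored on the site's yearly record, a ~45% rainfall
# exclusion and scheduled ~19 mm irrigation events. Writes the pipeline's
# input CSVs plus the generating truth.

library(pinonbranch)

outdir <- "results/data"
seed <- 42L
cfg <- sim_config()
d <- generate_dataset(cfg, seed = seed, outdir = outdir)

cat("Wrote synthetic experiment to", outdir, "\n")
cat(sprintf("  needles: %d rows over %d branches\n",
            nrow(d$needles), length(unique(d$needles$branch_id))))
cat(sprintf("  rings:   %d rows (%d flagged missing)\n",
            nrow(d$rings), sum(d$rings$missing)))
cat(sprintf("  segments:%d rows\n", nrow(d$segments)))
collapse_years <- d$truth$collapse$droughted$year[d$truth$collapse$droughted$collapse]
cat("  collapse year(s) for the droughted plot:",
    paste(collapse_years, collapse = ", "), "\n")
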