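#!/usr/bin/env Rscript
# Stage 2: daily climate -> per-hydro-year predictors.
# Premonsoon (Nov-Jun) and monsoon (Jul-Oct) precipitation, counts of days
# with maximum VPD > 4.5 kPa in the MAMJ and JASO windows, and the
# experimental-period summary statistics per treatment.

library(pinonbranch)

indir <- "results/data"
for (tr in c("ambient", "irrigated", "droughted")) {
  daily <- read_daily_climate(file.path(indir, sprintf("climate_daily_%s.csv", tr)))
  seas <- summarize_seasons(daily)
  write.csv(seas, sprintf("results/climate_seasonal_%s.csv", tr), row.names = FALSE)
  p <- period_stats(seas)
  cat(sprintf(
    "%-10s premonsoon %6.1f mm (SD %5.1f) | monsoon %6.1f mm (SD %5.1f) | VPD>4.5 days (JASO) %4.1f\n",
    tr, p$ppt_premonsoon[1], p$ppt_premonsoon[2],
    p$ppt_monsoon[1], p$ppt_monsoon[2], p$vpd_days_monsoon[1]))
}
cat("Seasonal tables written to results/climate_seasonal_<treatment>.csv\n")
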