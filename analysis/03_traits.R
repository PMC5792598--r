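#!/usr/bin/env Rscript
# Stage 3: needle evaporative-structure traits.
# Fits the adaxial-area allometry A_ad = gamma + alpha*l*w on the measured
# subset, fills the unmeasured needles, and summarizes each branch-year
# cohort: mean length, total area, stomata per needle, stomatal density,
# stomatal diameter, and one maximal anatomical stomatal conductance per
# branch-year from the cohort means.

library(pinonbranch)

needles <- read_needles("results/data/needles.csv")
am <- fit_area_model(needles)
print(am)

traits <- summarize_traits(needles, am)
write.csv(traits, "results/traits_by_branch_year.csv", row.names = FALSE)

cat(sprintf("%d branch-year cohorts\n", nrow(traits)))
for (tr in c("irrigated", "ambient", "droughted")) {
  s <- traits[traits$treatment == tr, ]
  cat(sprintf("%-10s l = %4.1f mm | D_s = %5.1f mm-2 | d_S = %4.1f um | g_smax = %5.3f mol m-2 s-1\n",
              tr, mean(s$mean_length_mm), mean(s$stomatal_density_mm2, na.rm = TRUE),
              mean(s$stomatal_diameter_um, na.rm = TRUE),
              mean(s$gsmax_mol_m2_s, na.rm = TRUE)))
}
cat("Traits written to results/traits_by_branch_year.csv\n")
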