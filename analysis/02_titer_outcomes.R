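#!/usr/bin/env Rscript
# Stage 2: titer QC and outcome construction. Removes >3 SD outliers per
# (antigen, timepoint), classifies LVR/NVR by the four-or-more
# sub-threshold rule at year 1, min-max normalizes and builds the three
# median composite outcomes.

library(vaxbiome)

titers <- read_tsv_file("results/cohort/titers.tsv")
st <- titer_outcomes(titers)
dir.create("results", showWarnings = FALSE)
write_tsv_file(st$outcomes, "results/outcomes.tsv")
write_tsv_file(st$outlier_log, "results/outlier_log.tsv")

n_out <- sum(st$outlier_log$reason != "group size 1: untestable, retained")
cat(sprintf("Titer QC: %d of %d measurements removed as >3 SD outliers\n",
            n_out, nrow(titers)))
tab <- table(st$outcomes$category)
known <- sum(tab[c("LVR", "NVR")])
cat(sprintf("Responder status at year 1: %d LVR / %d classified (%.1f%%), %d unknown\n",
            tab[["LVR"]], known, 100 * tab[["LVR"]] / known,
            if ("unknown" %in% names(tab)) tab[["unknown"]] else 0))
cat("Composite outcome summary (classified subjects):\n")
print(summary(st$outcomes[st$outcomes$category %in% c("LVR", "NVR"),
                          c("median_cross", "median_dtap_hib", "median_pcv")]))
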