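#!/usr/bin/env Rscript
# Stage 4: community metrics. Rarefies each count table to its configured
# depth, computes per-sample richness / Shannon (bits) / Pielou evenness,
# and Bray-Curtis distances for the stool genus table.

library(vaxbiome)

dir.create("scratch", showWarnings = FALSE)
depths <- c(stool_ko = 10000, stool_genus = 10000, nasal_otu = 5000)
cohort <- read_cohort("results/cohort")
div_all <- list()
for (assay in names(cohort$features)) {
  rar <- rarefy(cohort$features[[assay]], depths[[assay]],
                seed = 401 + match(assay, names(cohort$features)))
  cat(sprintf("%s: %d samples at depth %d (%d dropped below depth)\n",
              assay, nrow(rar$table), depths[[assay]], length(rar$dropped)))
  div <- alpha_diversity(rar$table)
  div$assay <- assay
  div_all[[assay]] <- div
  saveRDS(rar$table, file.path("scratch",
                               paste0("rarefied_", assay, ".rds")))
  if (assay == "stool_genus") {
    d <- bray_curtis(rar$table)
    write_tsv_file(cbind(data.frame(sample_id = rownames(d)),
                         as.data.frame(d)),
                   "results/distances_stool_genus.tsv")
  }
}
diversity <- do.call(rbind, div_all)
write_tsv_file(diversity, "results/diversity.tsv")
cat("\nAlpha diversity summary by assay:\n")
for (assay in unique(diversity$assay)) {
  d <- diversity[diversity$assay == assay, ]
  cat(sprintf("  %-12s median richness %g, Shannon %.2f bits, evenness %.2f\n",
              assay, median(d$richness), median(d$shannon),
              median(d$evenness, na.rm = TRUE)))
}
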