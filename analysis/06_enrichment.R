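#!/usr/bin/env Rscript
# Stage 6: KEGG-module over-representation. For each 2-month stool-KO
# association family, takes the nominally significant KOs (raw p < 0.05)
# and tests each module (>= 5 detected KOs) against the detected-KO
# universe with a one-sided Fisher exact test, BH-corrected across
# modules. Checks the result against the generator's planted module.

library(vaxbiome)

cohort <- read_cohort("results/cohort")
associations <- read_tsv_file("results/associations.tsv")
truth <- jsonlite::read_json("results/cohort/ground_truth.json",
                             simplifyVector = TRUE)

rar <- readRDS("scratch/rarefied_stool_ko.rds")
detected <- colnames(rar)[colSums(rar) > 0]
ko <- associations[associations$assay == "stool_ko" &
                     associations$timepoint == "2mo", ]
enr <- list()
for (fam in unique(ko$family)) {
  sig <- select_nominal(ko[ko$family == fam, ], alpha = 0.05)
  er <- module_enrichment(sig, detected, cohort$module_map)
  er$family <- fam
  enr[[fam]] <- er
  hits <- er$module_id[er$adjusted_p < 0.05]
  cat(sprintf("%-28s %3d nominal KOs -> enriched modules: %s\n",
              fam, length(sig),
              if (length(hits)) paste(hits, collapse = ", ") else "none"))
}
enrichment <- do.call(rbind, enr)
rownames(enrichment) <- NULL
write_tsv_file(enrichment, "results/enrichment.tsv")

planted <- truth$planted_module
found <- enrichment[enrichment$module_id == planted &
                      enrichment$adjusted_p < 0.05, ]
cat(sprintf("\nPlanted module %s recovered in %d of %d families tested\n",
            planted, length(unique(found$family)),
            length(unique(enrichment$family))))
if (nrow(found)) {
  print(found[, c("family", "k", "K", "n", "N", "p", "adjusted_p",
                  "gene_ratio")], row.names = FALSE, digits = 3)
}
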