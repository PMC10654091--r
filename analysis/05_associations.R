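#!/usr/bin/env Rscript
# Stage 5: cross-sectional association screens. Tests every rarefied
# feature, every metabolite and the per-sample diversity metrics against
# the categorical (Mann-Whitney U) and continuous (Spearman) vaccine
# outcomes, with BH correction inside each (timepoint x outcome x assay)
# family.

library(vaxbiome)

cohort <- read_cohort("results/cohort")
outcomes <- read_tsv_file("results/outcomes.tsv")
diversity <- read_tsv_file("results/diversity.tsv")

assoc <- list()
for (assay in names(cohort$features)) {
  rar <- readRDS(file.path("scratch", paste0("rarefied_", assay, ".rds")))
  assoc[[assay]] <- run_association_screen(rar, cohort$samples, outcomes,
                                           assay = assay)
  dm <- as.matrix(diversity[diversity$assay == assay,
                            c("richness", "shannon", "evenness")])
  rownames(dm) <- diversity$sample_id[diversity$assay == assay]
  colnames(dm) <- paste(assay, colnames(dm), sep = "_")
  assoc[[paste0(assay, "_div")]] <- run_association_screen(
    dm, cohort$samples, outcomes, assay = paste0(assay, "_diversity"))
}
assoc$metabolite <- run_association_screen(cohort$metabolites,
                                           cohort$samples, outcomes,
                                           assay = "metabolite")
associations <- do.call(rbind, assoc)
rownames(associations) <- NULL
write_tsv_file(associations, "results/associations.tsv")

cat(sprintf("%d association tests in %d BH families\n",
            nrow(associations), length(unique(associations$family))))
nom <- associations[associations$p_raw < 0.05, ]
cat("Nominally significant features (raw p < 0.05) per 2-month family:\n")
two <- nom[nom$timepoint == "2mo", ]
print(table(two$assay, two$outcome))
sig <- associations[associations$p_adjusted < 0.05, ]
cat(sprintf("\nBH-significant at q < 0.05: %d records across %d features\n",
            nrow(sig), length(unique(sig$feature_id))))
if (nrow(sig)) {
  print(utils::head(sig[order(sig$p_adjusted),
                        c("feature_id", "assay", "timepoint", "outcome",
                          "rho", "p_adjusted")], 10), row.names = FALSE)
}
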