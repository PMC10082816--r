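#!/usr/bin/env Rscript
# UMAP embedding of one-hot phenotype profiles (AD phenotype excluded) and
# rank-test comparisons of the two components by AD status and by stratum.
# Writes results/embedding/.

suppressPackageStartupMessages(library(adcomorbid))

seed <- 20240924L
inp <- read_omop_lite("results/cohort")
asg <- read.csv("results/matching/phenotype_assignments.csv",
                stringsAsFactors = FALSE)
links <- read.csv("results/matching/matched_pairs.csv", stringsAsFactors = FALSE)
cohort_ids <- unique(c(links$case_id, links$control_id))
mat <- build_phenotype_matrix(asg[asg$person_id %in% cohort_ids, ], cohort_ids)

emb <- embed_2d(mat, seed = seed)
pats <- inp$patients
rownames(pats) <- pats$person_id
ad <- setNames(ifelse(pats[rownames(mat), "is_case"], "AD", "control"),
               rownames(mat))
stratum <- setNames(pats[rownames(mat), "race_ethnicity"], rownames(mat))

cmp_ad <- compare_embedding(emb, ad)
cmp_st <- compare_embedding(emb, stratum)
for (comp in c("comp1", "comp2")) {
  cat(sprintf("%s | AD status: MWU p = %.3g | stratum: KW p = %.3g\n",
              comp, cmp_ad[[comp]]$p_value, cmp_st[[comp]]$p_value))
}
cat("Dunn post hoc (stratum, comp1):\n")
print(cmp_st$comp1$posthoc, digits = 3)

dir.create("results/embedding", showWarnings = FALSE, recursive = TRUE)
coords <- emb$coords
coords$ad_status <- ad[coords$person_id]
coords$stratum <- stratum[coords$person_id]
write.csv(coords, "results/embedding/umap_coordinates.csv", row.names = FALSE)
jsonlite::write_json(list(AD_status = cmp_ad, stratum = cmp_st),
                     "results/embedding/component_comparisons.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat("wrote results/embedding/{umap_coordinates.csv,component_comparisons.json}\n")
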