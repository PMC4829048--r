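# Stage 3 — pairwise Lynch-Ritland relatedness from consensus genotypes,
# with plug-in allele frequencies estimated from the identified
# individuals. The pairwise table feeds both pedigree verification
# (stage 4) and full-sibling screening of dyads (stage 5).

source("analysis/00_config.R")

for (area in names(study_configs)) {
  inds <- read_individuals_csv(res_path(paste0(area, "_individuals.csv")))
  rel <- lr_matrix(inds$geno)
  write_relatedness_csv(rel, res_path(paste0(area, "_relatedness.csv")))
  cat(sprintf(
    "%s: %d pairs; mean r %.3f (sd %.3f); %d pairs flagged low-confidence\n",
    area, nrow(rel$pairs), mean(rel$pairs$r, na.rm = TRUE),
    sd(rel$pairs$r, na.rm = TRUE), sum(rel$pairs$low_confidence)))
}
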