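# Stage 2 — QC, genotype matching and sex assignment.
# Samples with more than 70 called assays are clustered into individuals
# (single linkage, <=2 mismatches over >=40 shared loci); consensus
# genotypes, sexes and median centers are written per area.

source("analysis/00_config.R")

for (area in names(study_configs)) {
  smp <- read_samples_csv(res_path(paste0(area, "_samples.csv")))
  keep <- qc_samples(smp, min_loci = 70)
  smp_qc <- filter_samples(smp, keep)
  inds <- match_samples(smp_qc, max_mismatch = 2, min_overlap = 40)
  write_individuals_csv(inds, res_path(paste0(area, "_individuals.csv")))
  # clustering fidelity against the latent truth carried by the simulator
  pure <- mean(!grepl("|", inds$info$true_id, fixed = TRUE))
  cat(sprintf(
    "%s: %d/%d samples passed QC -> %d individuals (%d F / %d M / %d unknown); %.1f%% pure clusters; %d sex conflicts\n",
    area, sum(keep), length(keep), nrow(inds$info),
    sum(inds$info$sex == "F"), sum(inds$info$sex == "M"),
    sum(inds$info$sex == "UNKNOWN"), 100 * pure,
    sum(inds$info$sex_conflict)))
}
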