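# Stage 1 — simulate the two study populations and their fecal samples.
# Writes per-area sample tables (with the latent truth column retained
# for later validation) and the true pedigrees.

source("analysis/00_config.R")

for (area in names(study_configs)) {
  cfg <- study_configs[[area]]
  pop <- simulate_population(cfg)
  smp <- collect_samples(pop, cfg)
  write_pedigree_csv(pop, res_path(paste0(area, "_true_pedigree.csv")))
  write_samples_csv(smp, res_path(paste0(area, "_samples.csv")))
  sampled <- unique(smp$meta$individual_id)
  cat(sprintf(
    "%s: %d individuals alive, %d fecal samples from %d individuals (%.0f%% coverage), max recaptures %d\n",
    area, n_alive(pop), nrow(smp$meta), length(sampled),
    100 * length(sampled) / n_alive(pop),
    max(table(smp$meta$individual_id))))
}
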