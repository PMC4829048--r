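# Shared configuration for the analysis workflow: two synthetic study
# populations emulating the central (CS) and northern (NS) monitoring
# areas — CS larger with curated low-error genotypes, NS smaller with the
# all-sample error rate and higher sampling coverage.

library(pedpop)

RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

study_configs <- list(
  CS = sim_config(
    n_founders = 400, n_years = 12,
    typing_error = 1.538e-4,        # curated best-quality extracts
    sampling_zero_prob = 0.40,      # ~55% of the population sampled
    seed = 2012
  ),
  NS = sim_config(
    n_founders = 220, n_years = 12,
    typing_error = 0.01,            # all samples passing amplification
    sampling_zero_prob = 0.20,      # ~73% sampled
    seed = 2014
  )
)

res_path <- function(...) file.path(RESULTS, ...)
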