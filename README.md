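# pedpop

Population-size estimation from pedigrees reconstructed out of
noninvasively collected SNP genotypes.

Wildlife managers often need the *actual* size of an elusive population
— brown bears are the motivating case — but can only collect fecal
samples opportunistically. Each sample genotyped on a 96-assay SNP panel
(85 autosomal + 4 mtDNA + 4 Y + 3 X) becomes a molecular tag; unique
genotypes give a minimum count. `pedpop` implements the
pedigree-based (Creel–Rosenblatt) estimator, which goes further:
parents that were never sampled are inferred from their sampled
offspring, so the estimate is

```
N̂ = N_s + N_in + N_un
```

with `N_s` the unique-genotype count, `N_in` the inferred missing
parents (full-sibling screening of single-parent dyads, dam:sire-ratio
inference of the rest, then sex-specific mortality correction — 7.2%/yr
for dams, 11.6%/yr for sires), and `N_un` the estimated unsampled
non-breeders. A rarefaction (accumulation-curve) estimator fitting the
Kohn model `y = ax/(b+x)` provides an independent comparison, and
Lynch–Ritland pairwise relatedness (expectation 0.5 for first-order
pairs) verifies the reconstructed pedigree.

The package contains every stage as tested functions:

| stage | functions |
| --- | --- |
| synthetic populations & fecal samples | `sim_config()`, `simulate_population()`, `collect_samples()` |
| QC, sex assignment, genotype matching | `qc_samples()`, `assign_species_sex()`, `match_samples()` |
| relatedness | `lr_pair()`, `lr_matrix()` |
| parentage | `reconstruct_pedigree()`, `trio_loglik()`, `mendelian_incompatibilities()` |
| population estimates | `cre_estimate()`, `mortality_correct()`, `rarefaction_estimate()`, `fit_saturation()` |
| experiments | `sampling_intensity_sweep()`, `edge_subsets()`, `dyad_completeness()`, `prp()` |
| end to end | `run_pipeline()` |

Because the original fecal-sample genotypes are not public, the
simulator is a first-class module: it generates polygynandrous,
female-philopatric populations with overlapping generations, Mendelian
genotypes, allelic dropout and per-call typing error, at the study's
magnitudes, so every estimator is exercised against a known truth.

## Worked example

```r
library(pedpop)
rep <- run_pipeline(list(seed = 11))
```

The pipeline simulates a population, collects samples, identifies
individuals, reconstructs the pedigree and estimates size. With seed 11
it prints/returns:

```
rep$true_n_alive        # 207   true living population (latent truth)
rep$n_individuals       # 166   unique genotypes identified (N_s)
rep$pedigree
#> n_s 166 | triads 31 | dyads 50 | no parent 85 | B_s 69 | dam:sire 0.97
rep$cre
#> N_in 39 | N_un 23 | N_hat 228 | bounds [166, 245]
rep$rarefaction$mean_a  # 212.2 rarefaction estimate
```

Read: 166 unique genotypes were found; 31 individuals had both parents
identified, 50 one parent, 85 none; 69 sampled individuals are breeders.
From the 50 dyads, 39 missing parents survive the mortality correction
and 23 unsampled non-breeders are added, for a point estimate of 228
against a true living population of 207 (the genotype count alone would
have undercounted by 20%). The rarefaction estimate (212) agrees.

The `analysis/` directory holds the full study-scale workflow as
numbered scripts (`01_simulate.R` … `06_experiments.R`): two synthetic
areas at the published magnitudes, Table-1-style pedigree summaries,
CRE + rarefaction estimates with bounds, the sampling-intensity sweep
(CV and accuracy improve with coverage; low coverage underestimates
badly) and the edge-effect analysis (mother–daughter dyads outnumber
father–son dyads along borders — female philopatry). Run them in order
from the repository root; outputs land in `results/`.

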