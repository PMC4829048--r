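# Stage 6 — evaluation experiments.
# (a) breeder-proportion comparison between the two areas;
# (b) sampling-intensity sweep of the CRE on the higher-coverage area;
# (c) edge-effect analysis: pedigree completeness in core vs border
#     subsets, overall and sex-separated (female philopatry signal).

source("analysis/00_config.R")

summ <- read.csv(res_path("pedigree_summary.csv"), stringsAsFactors = FALSE)

## (a) proportions of breeders
cs <- summ[summ$area == "CS", ]; ns <- summ[summ$area == "NS", ]
zt <- two_prop_ztest(cs$b_s, cs$n_s, ns$b_s, ns$n_s)
cat(sprintf(
  "Breeder proportions %.2f (CS) vs %.2f (NS): z = %.2f, P = %.2f\n",
  zt$p1, zt$p2, zt$z, zt$p))

## (b) sampling-intensity sweep (NS: higher coverage)
cfg <- study_configs$NS
truth <- read.csv(res_path("NS_true_pedigree.csv"), stringsAsFactors = FALSE)
true_n <- sum(is.na(truth$death_year))
inds <- read_individuals_csv(res_path("NS_individuals.csv"))
sweep <- sampling_intensity_sweep(
  inds, n_ref = true_n, levels = seq(0.1, 0.6, by = 0.1), n_reps = 10,
  cfg = parentage_config(typing_error = cfg$typing_error,
                         nf_max = summ$nf_max[summ$area == "NS"],
                         nm_max = summ$nm_max[summ$area == "NS"]),
  seed = 77)
write.csv(sweep, res_path("intensity_sweep.csv"), row.names = FALSE)
cat("\nSampling-intensity sweep (NS, reference N =", true_n, "):\n")
print(transform(sweep, cv = round(cv, 3), pct_diff = round(pct_diff, 1),
                mean_nhat = round(mean_nhat, 1)), row.names = FALSE)

## (c) edge effects on pedigree completeness
for (area in c("CS", "NS")) {
  n_sub <- if (area == "CS") 100 else 70
  n_sex <- if (area == "CS") 50 else 30
  inds_a <- read_individuals_csv(res_path(paste0(area, "_individuals.csv")))
  ped_csv <- read.csv(res_path(paste0(area, "_pedigree.csv")),
                      stringsAsFactors = FALSE)
  ped <- pedpop:::finalize_pedigree(ped_csv, inds_a$info$individual_id)
  info <- inds_a$info[, c("individual_id", "x_median", "y_median")]
  es <- edge_subsets(info, n = n_sub)
  comp <- vapply(es$subsets, dyad_completeness, 0, ped = ped)
  counts <- round(comp * n_sub)
  ct <- chisq_homogeneity(counts, rep(n_sub, 5))
  cat(sprintf(
    "\n%s edge effects (n = %d): pairs in core/N/S/E/W = %s; chi2(%d) = %.2f, P = %.2f\n",
    area, n_sub, paste(counts, collapse = "/"), ct$df, ct$chisq, ct$p))

  # sex-separated: mother-daughter vs father-son dyads per border
  sexes <- stats::setNames(inds_a$info$sex, inds_a$info$individual_id)
  md <- fs <- c()
  for (sx in c("F", "M")) {
    sel <- inds_a$info$sex == sx
    ess <- edge_subsets(info[sel, ], n = min(n_sex, sum(sel)))
    flt <- if (sx == "F") "mother_daughter" else "father_son"
    v <- vapply(ess$subsets, dyad_completeness, 0, ped = ped,
                sex_filter = flt, sexes = sexes)
    if (sx == "F") md <- v else fs <- v
  }
  cat(sprintf("    mother-daughter per subset: %s\n",
              paste(sprintf("%.2f", md), collapse = " ")))
  cat(sprintf("    father-son     per subset: %s\n",
              paste(sprintf("%.2f", fs), collapse = " ")))
  cat(sprintf("    border totals: mother-daughter %.2f vs father-son %.2f\n",
              sum(md[-1]), sum(fs[-1])))
}
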