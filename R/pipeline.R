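#' Pipeline configuration
#'
#' Assembles the per-stage parameter blocks into one validated list, with
#' every stochastic stage's seed derived deterministically from a single
#' master seed. Accepts a YAML file path or a list with (all optional)
#' blocks `sim`, `genotyping`, `parentage`, `estimator`, `rarefaction`,
#' `experiments`, `paths`, and `seed`.
#'
#' @param config list or path to a YAML file
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  cfg <- list(
    seed = seed,
    sim = do.call(sim_config, c(config$sim %||% list(),
                                if (is.null(config$sim$seed)) list(seed = seed))),
    genotyping = utils::modifyList(
      list(min_loci = 70L, max_mismatch = 2L, min_overlap = 40L),
      config$genotyping %||% list()),
    parentage = do.call(parentage_config, config$parentage %||% list()),
    # when the user gives no candidate ceilings they are derived at run
    # time from the rarefaction estimate and the sampled sex ratio
    auto_ceilings = is.null(config$parentage$nf_max) &&
      is.null(config$parentage$nm_max),
    estimator = utils::modifyList(
      list(strategy = "nonbreeder_fraction", m_f = 0.072, m_m = 0.116,
           fs_threshold = 0.375),
      config$estimator %||% list()),
    rarefaction = utils::modifyList(list(n_iter = 100L),
                                    config$rarefaction %||% list()),
    experiments = utils::modifyList(
      list(run = FALSE, levels = seq(0.1, 0.6, by = 0.1), n_reps = 10L,
           edge_n = 30L),
      config$experiments %||% list()),
    paths = config$paths %||% list(),
    samples_csv = config$samples_csv %||% NULL
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the full estimation pipeline
#'
#' Simulate (or ingest) noninvasive samples, QC and identify individuals,
#' compute pairwise relatedness, reconstruct the pedigree, and produce
#' the Creel-Rosenblatt and rarefaction population estimates, optionally
#' followed by the sampling-intensity and edge-effect experiments. The
#' run is fully reproducible from the master seed; when `paths$out_dir`
#' is set, stage CSVs and a JSON report are written there.
#'
#' @param config a [pipeline_config()] (or anything it accepts)
#' @return the report list (invisibly written as JSON when configured)
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  report <- list(schema_version = "1.0", seed = config$seed,
                 parameters = list(
                   genotyping = config$genotyping,
                   parentage = unclass(config$parentage),
                   estimator = config$estimator))

  panel <- marker_panel()
  if (!is.null(config$samples_csv)) {
    samples <- read_samples_csv(config$samples_csv, panel)
    report$source <- config$samples_csv
  } else {
    pop <- simulate_population(config$sim, panel)
    samples <- collect_samples(pop, config$sim)
    report$source <- "synthetic"
    report$true_n_alive <- n_alive(pop)
  }
  report$n_samples_collected <- nrow(samples$meta)

  keep <- qc_samples(samples, min_loci = config$genotyping$min_loci)
  samples_qc <- filter_samples(samples, keep)
  report$n_samples_qc_passed <- nrow(samples_qc$meta)
  if (nrow(samples_qc$meta) == 0L) stop("pipeline: no sample passed QC")

  inds <- match_samples(samples_qc,
                        max_mismatch = config$genotyping$max_mismatch,
                        min_overlap = config$genotyping$min_overlap)
  report$n_individuals <- nrow(inds$info)
  report$n_females <- sum(inds$info$sex == "F")
  report$n_males <- sum(inds$info$sex == "M")
  report$max_recaptures <- max(inds$info$n_samples)

  seq_ids <- samples_qc$meta$individual_id
  if (all(is.na(seq_ids))) {
    seq_ids <- ind_of_samples(inds)[samples_qc$meta$sample_id]
  }
  raref <- rarefaction_estimate(seq_ids,
                                n_iter = config$rarefaction$n_iter,
                                seed = derive_seed(config$seed, 7L))
  report$rarefaction <- list(mean_a = raref$mean_a,
                             n_converged = raref$n_converged,
                             n_distinct = raref$n_distinct)

  par_cfg <- config$parentage
  if (config$auto_ceilings) {
    # candidate-pool ceilings from the rarefaction estimate and the
    # sampled sex ratio (unknown-sex individuals split evenly)
    n_fm <- max(report$n_females + report$n_males, 1L)
    frac_f <- if (n_fm > 0) report$n_females / n_fm else 0.5
    par_cfg$nf_max <- max(1L, as.integer(ceiling(raref$mean_a * frac_f)))
    par_cfg$nm_max <- max(1L, as.integer(ceiling(raref$mean_a * (1 - frac_f))))
  }
  report$parameters$parentage <- unclass(par_cfg)

  freqs <- allele_freqs_from_genotypes(inds$geno)
  rel <- lr_matrix(inds$geno, freqs = freqs)
  ped <- reconstruct_pedigree(inds, freqs = freqs, cfg = par_cfg)
  report$pedigree <- list(
    n_s = ped$n_s, n_triads = ped$n_triads, n_dyads = ped$n_dyads,
    n_unassigned = ped$n_unassigned, b_s = ped$b_s,
    breeder_proportion = ped$b_s / ped$n_s,
    dam_sire_ratio = ped$dam_sire_ratio)

  est <- config$estimator
  rho <- ped$dam_sire_ratio
  if (!is.finite(rho) || rho <= 0) rho <- 1
  inp <- cre_inputs(ped, rel, m_f = est$m_f, m_m = est$m_m,
                    fs_threshold = est$fs_threshold)
  inp$rho <- rho
  cre <- if (ped$b_s > 0) cre_estimate(inp, est$strategy) else NULL
  report$cre <- if (is.null(cre)) NULL else unclass(cre)[
    c("n_s", "b_s", "n_dyads", "fs_inferred_sires", "fs_inferred_dams",
      "ratio_inferred_sires", "ratio_inferred_dams", "n_in", "n_un",
      "n_hat", "lower_bound", "upper_bound", "strategy")]

  if (isTRUE(config$experiments$run) && !is.null(cre)) {
    sweep <- sampling_intensity_sweep(
      inds, n_ref = report$true_n_alive %||% nrow(inds$info),
      levels = config$experiments$levels,
      n_reps = config$experiments$n_reps,
      cfg = par_cfg, strategy = est$strategy,
      seed = derive_seed(config$seed, 8L))
    report$intensity_sweep <- sweep
  }

  out_dir <- config$paths$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_samples_csv(samples_qc, file.path(out_dir, "samples.csv"))
    write_individuals_csv(inds, file.path(out_dir, "individuals.csv"))
    write_relatedness_csv(rel, file.path(out_dir, "relatedness.csv"))
    write_pedigree_result_csv(ped, file.path(out_dir, "pedigree.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}

# sample-id -> individual-id map from the clustering itself (used when
# no latent truth column is carried)
ind_of_samples <- function(inds) {
  stats::setNames(rep(names(inds$members), lengths(inds$members)),
                  unlist(inds$members, use.names = FALSE))
}
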