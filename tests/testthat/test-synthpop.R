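test_that("panel and config invariants reject boundary values", {
  expect_error(marker_panel(rep(1.0, 85)), "strictly inside")
  expect_error(marker_panel(rep(0.5, 40)), "85 autosomal")
  pan <- marker_panel()
  expect_length(panel_assays <- c(pan$auto_loci, pan$mt_loci, pan$y_loci,
                                  pan$x_loci), 96L)
  expect_true(all(pan$auto_freq > 0 & pan$auto_freq < 1))

  expect_error(sim_config(dropout_prob = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(philopatry_sd_f = 30, dispersal_sd_m = 10),
               "philopatry")
  expect_error(sim_config(n_founders = 1), "at least 2")
})

test_that("founders are Hardy-Weinberg at the panel frequencies", {
  pan <- marker_panel(rep(0.5, 85))
  pop <- init_population(sim_config(n_founders = 100, seed = 3), pan)
  het_per_locus <- colMeans(pop$geno == 1L)
  expect_equal(mean(het_per_locus), 0.5, tolerance = 0.05)
  expect_true(all(pop$geno %in% 0:2))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_founders = 40, n_years = 4, seed = 7)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$ped, p2$ped)
  expect_identical(p1$geno, p2$geno)
  s1 <- collect_samples(p1, cfg)
  s2 <- collect_samples(p2, cfg)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$meta, s2$meta)
})

test_that("advance_year respects mortality and breeding switches", {
  cfg <- sim_config(n_founders = 30, breeding_prob = 0,
                    adult_mortality_f = 0, adult_mortality_m = 0,
                    cub_mortality = 0, seed = 2)
  pop <- init_population(cfg)
  adv <- advance_year(pop, cfg)
  expect_identical(adv$ped$id, pop$ped$id)         # nobody born or died
  expect_true(all(is.na(adv$ped$death_year)))
  expect_equal(adv$year, pop$year + 1L)

  cfg2 <- sim_config(n_founders = 30, breeding_prob = 0,
                     adult_mortality_f = 1, seed = 2)
  adv2 <- advance_year(init_population(cfg2), cfg2)
  fem <- adv2$ped$sex == "F"
  expect_true(all(!is.na(adv2$ped$death_year[fem])))
})

test_that("offspring genotypes are Mendelian", {
  pan <- marker_panel()
  set.seed(1)
  expect_identical(mendelian_offspring_genotype(rep(0L, 85), rep(0L, 85)),
                   rep(0L, 85))
  expect_error(mendelian_offspring_genotype(c(NA, rep(1L, 84)), rep(1L, 85)),
               "complete")
  # AB x AB segregates 1:2:1
  draws <- replicate(4000, mendelian_offspring_genotype(1L, 1L)[1])
  frac <- tabulate(draws + 1L, 3L) / 4000
  expect_equal(frac, c(0.25, 0.5, 0.25), tolerance = 0.05)
  # transmission preserves allele frequency: 1e4 offspring at one locus
  p <- 0.3
  dam <- stats::rbinom(1e4, 2, p); sire <- stats::rbinom(1e4, 2, p)
  off <- stats::rbinom(1e4, 1, dam / 2) + stats::rbinom(1e4, 1, sire / 2)
  parental_p <- mean(c(dam, sire)) / 2
  se3 <- 3 * sqrt(parental_p * (1 - parental_p) / (2 * 1e4))
  expect_lt(abs(mean(off) / 2 - parental_p), se3)
})

test_that("sample calls follow the dropout and typing-error model", {
  cfg0 <- sim_config(n_founders = 40, n_years = 0, dropout_prob = 0,
                     typing_error = 0, sampling_zero_prob = 0, seed = 4)
  pop <- init_population(cfg0)
  smp <- collect_samples(pop, cfg0)
  truth <- pedpop:::true_calls(pop, alive_ids <- pop$ped$id)
  expect_true(all(smp$calls == truth[smp$meta$individual_id, ]))

  cfg1 <- sim_config(n_founders = 40, n_years = 0, dropout_prob = 1,
                     sampling_zero_prob = 0, seed = 4)
  smp1 <- collect_samples(pop, cfg1)
  expect_true(all(smp1$calls %in% c("NN", "-")))

  cfg2 <- sim_config(n_founders = 200, n_years = 0, dropout_prob = 0,
                     typing_error = 0.01, sampling_zero_prob = 0,
                     samples_per_individual_mean = 3, seed = 9)
  pop2 <- init_population(cfg2)
  smp2 <- collect_samples(pop2, cfg2)
  truth2 <- pedpop:::true_calls(pop2, pop2$ped$id)[smp2$meta$individual_id, ]
  auto <- pop2$panel$auto_loci
  n_err <- mean(rowSums(smp2$calls[, auto] != truth2[, auto]))
  expect_equal(n_err, 0.85, tolerance = 0.2)  # binomial mean 85 * 0.01
})

test_that("pedigree structure, matriline and philopatry hold on seeded runs", {
  cfg <- sim_config(seed = 12)
  pop <- simulate_population(cfg)
  ped <- pop$ped
  nonf <- !is.na(ped$dam_id)
  # every non-founder has both parents on record, sexes correct
  expect_true(all(!is.na(ped$sire_id[nonf])))
  sex_of <- stats::setNames(ped$sex, ped$id)
  expect_true(all(sex_of[ped$dam_id[nonf]] == "F"))
  expect_true(all(sex_of[ped$sire_id[nonf]] == "M"))
  # parents born before offspring
  by <- stats::setNames(ped$birth_year, ped$id)
  expect_true(all(by[ped$dam_id[nonf]] < ped$birth_year[nonf]))
  # acyclic
  g <- igraph::graph_from_edgelist(cbind(
    c(ped$dam_id[nonf], ped$sire_id[nonf]), rep(ped$id[nonf], 2)))
  expect_true(igraph::is_dag(g))
  # matrilineal haplotypes
  expect_identical(unname(pop$mt_hap[ped$id[nonf]]),
                   unname(pop$mt_hap[ped$dam_id[nonf]]))
  # daughters settle nearer their dam than sons their sire
  xy <- ped[match(ped$id, ped$id), c("x", "y")]
  dist_to <- function(kid_rows, par_ids) {
    pr <- match(par_ids, ped$id)
    sqrt((ped$x[kid_rows] - ped$x[pr])^2 + (ped$y[kid_rows] - ped$y[pr])^2)
  }
  dg <- which(nonf & ped$sex == "F")
  sn <- which(nonf & ped$sex == "M")
  expect_lt(mean(dist_to(dg, ped$dam_id[dg])),
            mean(dist_to(sn, ped$sire_id[sn])))
})
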