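test_that("percentage relative precision matches its definition and scales", {
  expect_equal(prp(362, 310, 459), 21L)
  expect_equal(prp(793, 621, 1179), 35L)
  expect_equal(prp(100, 100, 100), 0L)
  # scale invariance
  for (k in c(0.5, 2, 10)) {
    expect_equal(prp(k * 362, k * 310, k * 459), prp(362, 310, 459))
  }
  expect_error(prp(0, -1, 1), "positive")
  expect_error(prp(100, 150, 200), "bracket")
})

test_that("pooled z test for proportions matches hand computation", {
  expect_equal(two_prop_ztest(10, 20, 10, 20)$z, 0)
  expect_equal(two_prop_ztest(10, 20, 5, 20)$z, 1.633, tolerance = 1e-3)
  # the study-sized comparison under the pooled formula
  res <- two_prop_ztest(159, 433, 112, 265)
  expect_equal(res$z, -1.457, tolerance = 1e-3)
  expect_gt(res$p, 0.1)
  expect_error(two_prop_ztest(5, 0, 1, 2), "positive")
})

test_that("chi-square homogeneity equals the brute-force Pearson sum", {
  same <- chisq_homogeneity(c(10, 20, 30, 40, 50), c(100, 200, 300, 400, 500))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$df, 4L)
  two <- chisq_homogeneity(c(10, 20), c(50, 50))
  expect_equal(two$chisq, 4.762, tolerance = 1e-3)
  # random tables against sum((O-E)^2 / E)
  set.seed(8)
  for (rep in 1:5) {
    ns <- sample(30:80, 4)
    ks <- vapply(ns, function(n) rbinom(1, n, runif(1, 0.2, 0.8)), 0L)
    got <- chisq_homogeneity(ks, ns)
    tab <- cbind(ks, ns - ks)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$chisq, sum((tab - E)^2 / E), tolerance = 1e-10)
    expect_equal(got$df, 3L)
  }
})

test_that("edge subsets pick nearest-to-center and nearest-to-border members", {
  gr <- expand.grid(x = 0:9, y = 0:9)
  info <- data.frame(individual_id = sprintf("g%03d", seq_len(nrow(gr))),
                     x_median = gr$x, y_median = gr$y,
                     stringsAsFactors = FALSE)
  es <- edge_subsets(info, n = 10)
  expect_false(es$degenerate)
  expect_setequal(es$subsets$west, info$individual_id[info$x_median == 0])
  expect_setequal(es$subsets$east, info$individual_id[info$x_median == 9])
  expect_setequal(es$subsets$south, info$individual_id[info$y_median == 0])
  expect_setequal(es$subsets$north, info$individual_id[info$y_median == 9])
  expect_equal(es$center, c(4.5, 4.5))
  expect_error(edge_subsets(info, n = 101), "exceeds")
  # degenerate geometries flagged
  info2 <- info; info2$x_median <- 1; info2$y_median <- 1
  expect_true(edge_subsets(info2, 5)$degenerate)
  expect_true(edge_subsets(info, 100)$degenerate)
})

fake_ped <- function(offspring, dam = NA, sire = NA) {
  asn <- data.frame(offspring_id = offspring,
                    dam_id = rep_len(dam, length(offspring)),
                    sire_id = rep_len(sire, length(offspring)),
                    category = "dyad_dam", log_odds = 1, ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  pedpop:::finalize_pedigree(asn, offspring)
}

test_that("dyad completeness counts pairs fully inside the subset", {
  ped <- fake_ped(c("k1", "k2"), dam = "m1")
  expect_equal(dyad_completeness(c("k1", "k2", "m1"), ped), 2 / 3)
  expect_equal(dyad_completeness(c("k1", "k2"), ped), 0)  # dam outside
  sexes <- c(k1 = "F", k2 = "M", m1 = "F")
  expect_equal(dyad_completeness(c("k1", "k2", "m1"), ped,
                                 sex_filter = "mother_daughter",
                                 sexes = sexes), 1 / 3)
  expect_equal(dyad_completeness(c("k1", "k2", "m1"), ped,
                                 sex_filter = "father_son",
                                 sexes = sexes), 0)
  expect_error(dyad_completeness(character(), ped), "empty")
})

test_that("one-sample t matches hand computation and degenerate cases", {
  res <- one_sample_t(c(0.4, 0.6, 0.8), 0.5)
  expect_equal(res$t, 0.866, tolerance = 1e-3)
  expect_equal(res$df, 2L)
  expect_equal(one_sample_t(c(0.5, 0.5, 0.5), 0.5)$t, 0)
  zv <- one_sample_t(c(0.7, 0.7), 0.5)
  expect_true(zv$zero_variance)
  expect_true(is.infinite(zv$t))
  expect_error(one_sample_t(0.4, 0.5), "at least 2")
})

test_that("parent-offspring relatedness is consistent with 0.5 in most
           seeded runs", {
  # clean simulated PO pairs: the t test against 0.5 should reject at
  # the 5% level only at the nominal rate
  p_vals <- vapply(1:10, function(s) {
    set.seed(100 + s)
    p <- runif(85, 0.1, 0.9)
    po <- related_pairs(200, p, "PO")
    rv <- vapply(seq_len(200), function(i)
      lr_pair(po$a[i, ], po$b[i, ], p)$r, 0)
    one_sample_t(rv, 0.5)$p
  }, 0)
  expect_gte(mean(p_vals > 0.05), 0.9)

  # relatedness of reconstruction-assigned first-order pairs stays close
  # to 0.5 even with typing error in the genotypes
  cfg <- sim_config(n_founders = 60, n_years = 8, seed = 17)
  pop <- simulate_population(cfg)
  inds <- individuals_from_truth(pop, eps = 0.01, seed = 18)
  nf <- sum(inds$info$sex == "F"); nm <- sum(inds$info$sex == "M")
  ped <- reconstruct_pedigree(inds, cfg = parentage_config(
    typing_error = 0.01, nf_max = nf, nm_max = nm))
  freqs <- allele_freqs_from_genotypes(inds$geno)
  a <- ped$assignments
  rvals <- c()
  for (i in seq_len(nrow(a))) {
    for (par in c(a$dam_id[i], a$sire_id[i])) {
      if (!is.na(par)) {
        rvals <- c(rvals, lr_pair(inds$geno[a$offspring_id[i], ],
                                  inds$geno[par, ], freqs)$r)
      }
    }
  }
  expect_lt(abs(mean(rvals) - 0.5), 0.05)
})

test_that("intensity sweep validates its inputs", {
  cfg <- sim_config(n_founders = 40, n_years = 4, seed = 19)
  pop <- simulate_population(cfg)
  inds <- individuals_from_truth(pop, eps = 0,
                                 who = pop$ped$id[is.na(pop$ped$death_year)])
  expect_error(sampling_intensity_sweep(inds, n_ref = 50, levels = 0.5,
                                        n_reps = 1), "at least 2")
  expect_error(sampling_intensity_sweep(inds, n_ref = 50, levels = 0,
                                        n_reps = 3), "\\(0, 1\\]")
  expect_error(sampling_intensity_sweep(inds, n_ref = 0, levels = 0.5,
                                        n_reps = 3), "positive")
  expect_error(sampling_intensity_sweep(inds, n_ref = 10 * nrow(inds$geno),
                                        levels = 1, n_reps = 3), "requests")
})
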