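make_rel <- function(ids, rvals) {
  # symmetric relatedness matrix from a named list "a|b" -> r
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (nm in names(rvals)) {
    ab <- strsplit(nm, "|", fixed = TRUE)[[1]]
    m[ab[1], ab[2]] <- m[ab[2], ab[1]] <- rvals[[nm]]
  }
  m
}

test_that("full-sibling screening infers one parent per sib group", {
  dyads <- data.frame(offspring_id = c("o1", "o2"),
                      known_parent_id = "d1", known_parent_sex = "F",
                      stringsAsFactors = FALSE)
  rel <- make_rel(c("o1", "o2"), list("o1|o2" = 0.5))
  scr <- screen_fullsib_dyads(dyads, rel, fs_threshold = 0.375)
  expect_equal(scr$inferred_sires, 1L)
  expect_equal(scr$inferred_dams, 0L)
  expect_equal(nrow(scr$remaining), 0L)

  rel2 <- make_rel(c("o1", "o2"), list("o1|o2" = 0.25))
  scr2 <- screen_fullsib_dyads(dyads, rel2, fs_threshold = 0.375)
  expect_equal(scr2$inferred_sires, 0L)
  expect_equal(nrow(scr2$remaining), 2L)

  # sire-side group infers a dam; singleton groups never infer
  dy3 <- data.frame(offspring_id = c("o1", "o2", "o3"),
                    known_parent_id = c("s1", "s1", "s2"),
                    known_parent_sex = "M", stringsAsFactors = FALSE)
  rel3 <- make_rel(c("o1", "o2", "o3"), list("o1|o2" = 0.55))
  scr3 <- screen_fullsib_dyads(dy3, rel3)
  expect_equal(scr3$inferred_dams, 1L)
  expect_equal(scr3$remaining$offspring_id, "o3")
})

test_that("ratio inference preserves the dam:sire ratio", {
  dy <- function(n_dams, n_sires) {
    data.frame(
      offspring_id = sprintf("o%d", seq_len(n_dams + n_sires)),
      known_parent_id = c(sprintf("d%d", seq_len(n_dams)),
                          sprintf("s%d", seq_len(n_sires))),
      known_parent_sex = c(rep("F", n_dams), rep("M", n_sires)),
      stringsAsFactors = FALSE)
  }
  r1 <- infer_by_ratio(dy(10, 10), rho = 1)
  expect_equal(r1$inferred_sires, 10L)
  expect_equal(r1$inferred_dams, 10L)
  r2 <- infer_by_ratio(dy(6, 4), rho = 1.5)
  expect_equal(r2$inferred_sires, 4L)   # 6 / 1.5
  expect_equal(r2$inferred_dams, 6L)    # 4 * 1.5
  # distinct parents, not dyads, drive the counts
  rep_dy <- dy(3, 0)
  rep_dy <- rbind(rep_dy, rep_dy)       # each dam appears twice
  expect_equal(infer_by_ratio(rep_dy, 1)$inferred_sires, 3L)
  expect_error(infer_by_ratio(dy(1, 1), rho = 0), "positive")
})

test_that("mortality correction rounds per sex and is monotone", {
  expect_equal(mortality_correct(58, 69), 115L)
  expect_equal(mortality_correct(45, 48), 85L)
  expect_equal(mortality_correct(0, 0), 0L)
  expect_equal(mortality_correct(10, 10, m_m = 0, m_f = 0), 20L)
  expect_error(mortality_correct(-1, 5), "non-negative")
  vals <- vapply(0:60, function(s) mortality_correct(s, 40), 0L)
  expect_true(all(diff(vals) >= 0))
})

test_that("unsampled non-breeder strategies follow their closed forms", {
  expect_equal(estimate_unsampled(115, 433, 159, "nonbreeder_fraction"), 73L)
  expect_equal(estimate_unsampled(85, 265, 112, "nonbreeder_fraction"), 49L)
  expect_equal(estimate_unsampled(100, 200, 200, "nonbreeder_fraction"), 0L)
  expect_equal(estimate_unsampled(100, 200, 200, "breeder_ratio"), 0L)
  expect_equal(estimate_unsampled(0, 433, 159, "nonbreeder_fraction"), 0L)
  expect_equal(estimate_unsampled(10, 100, 50, "none"), 0L)
  expect_error(estimate_unsampled(10, 100, 50, "bogus"))
  expect_error(estimate_unsampled(10, 100, 0, "breeder_ratio"), "positive")
})

test_that("the estimator pipeline composes its stages and bounds", {
  # two dyads are full sibs via dam d1 (one inferred sire); two dyads with
  # known sires s1, s2 remain for the ratio method at rho = 1
  dyads <- data.frame(
    offspring_id = c("o1", "o2", "o3", "o4"),
    known_parent_id = c("d1", "d1", "s1", "s2"),
    known_parent_sex = c("F", "F", "M", "M"), stringsAsFactors = FALSE)
  rel <- make_rel(c("o1", "o2", "o3", "o4"), list("o1|o2" = 0.5))
  inputs <- list(n_s = 50, b_s = 20, dyads = dyads, rho = 1,
                 relatedness = rel, m_f = 0, m_m = 0)
  res <- cre_estimate(inputs, strategy = "nonbreeder_fraction")
  expect_equal(res$fs_inferred_sires, 1L)
  expect_equal(res$ratio_inferred_dams, 2L)  # s_d = 2 distinct sires
  expect_equal(res$ratio_inferred_sires, 0L) # no dam-known dyads remain
  expect_equal(res$n_in, 3L)
  expect_equal(res$n_un, as.integer(round(3 * 30 / 50)))
  expect_equal(res$n_hat, res$n_s + res$n_in + res$n_un)
  expect_equal(res$lower_bound, 50)
  expect_equal(res$upper_bound, 50 + 4 + as.integer(round(4 * 30 / 50)))
  expect_true(res$lower_bound <= res$n_hat && res$n_hat <= res$upper_bound)
  # no dyads -> estimate collapses to the genotype count
  empty <- list(n_s = 50, b_s = 20,
                dyads = dyads[0, ], rho = 1, relatedness = rel)
  expect_equal(cre_estimate(empty)$n_hat, 50)
})

test_that("accumulation counts track distinct individuals", {
  expect_equal(accumulation_counts(c("A", "A", "A")), c(1, 1, 1))
  expect_equal(accumulation_counts(c("A", "B", "A", "C")), c(1, 2, 2, 3))
  expect_equal(accumulation_counts(letters[1:5]), 1:5)
  expect_error(accumulation_counts(character()), "empty")
})

test_that("saturation fit recovers exact curves and matches a grid oracle", {
  xs <- c(10, 50, 100, 200, 400)
  ys_exact <- 100 * xs / (50 + xs)
  f <- fit_saturation(xs, ys_exact)
  expect_true(f$converged)
  expect_equal(f$a, 100, tolerance = 1e-6)
  expect_equal(f$b, 50, tolerance = 1e-6)
  # noisy 5-point dataset against the brute-force grid oracle
  set.seed(77)
  ys <- ys_exact + round(rnorm(5, 0, 1))
  f2 <- fit_saturation(xs, ys)
  oracle <- grid_fit_oracle(xs, ys, step = 1e-3)
  expect_equal(f2$a, unname(oracle["a"]), tolerance = 1e-3)
  expect_equal(f2$b, unname(oracle["b"]), tolerance = 1e-3)
  # degenerate inputs are flagged, not estimated
  expect_false(fit_saturation(xs, rep(5, 5))$converged)
  expect_error(fit_saturation(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_saturation(c(3, 2, 1), c(1, 2, 3)), "increasing")
})

test_that("rarefaction is deterministic, bounded below by the observed count
           and overestimates at high coverage", {
  set.seed(41)
  seq1 <- sample(sprintf("i%03d", 1:100), 1000, replace = TRUE)
  r1 <- rarefaction_estimate(seq1, n_iter = 30, seed = 5)
  r2 <- rarefaction_estimate(seq1, n_iter = 30, seed = 5)
  expect_identical(r1$mean_a, r2$mean_a)
  # equally catchable individuals, heavy sampling: the Kohn model
  # overshoots the true 100
  expect_gte(r1$mean_a, 100)
  expect_false(r1$flag_below_observed)
  # mean asymptote at least the observed distinct count across seeds
  for (s in 1:5) {
    seqs <- sample(sprintf("i%02d", 1:40), 200, replace = TRUE)
    rr <- rarefaction_estimate(seqs, n_iter = 10, seed = s)
    expect_gte(rr$mean_a, rr$n_distinct * 0.999)
  }
  expect_error(rarefaction_estimate(rep("a", 5)), "2 distinct")
})
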