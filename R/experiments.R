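#' Sampling-intensity sweep of the pedigree-based estimator
#'
#' Evaluates estimator precision and accuracy against sampling coverage:
#' at each intensity level, `round(level * n_ref)` identified individuals
#' are drawn uniformly without replacement, the pedigree is reconstructed
#' on the subsample, the Creel-Rosenblatt estimate recomputed, and across
#' `n_reps` replicates the coefficient of variation (sd/mean of the
#' estimates) and the percentage difference to the reference size
#' (`100 * |n_ref - mean| / mean`) are reported.
#'
#' @param individuals an `individual_set`
#' @param n_ref reference population size the levels refer to
#' @param levels sampling intensities in (0, 1]
#' @param n_reps replicates per level (>= 2 for a defined CV)
#' @param cfg a [parentage_config()]
#' @param strategy N_un strategy for [cre_estimate()]
#' @param seed RNG seed
#' @return data.frame per level: level, n_drawn, mean_nhat, sd_nhat, cv,
#'   pct_diff, plus a `replicates` attribute with all estimates
#' @export
sampling_intensity_sweep <- function(individuals, n_ref, levels,
                                     n_reps = 10L,
                                     cfg = parentage_config(),
                                     strategy = "nonbreeder_fraction",
                                     seed = 1L) {
  if (n_ref <= 0) stop("n_ref must be positive")
  if (any(levels <= 0 | levels > 1)) stop("levels must lie in (0, 1]")
  if (n_reps < 2L) stop("need at least 2 replicates for a CV")
  n_avail <- nrow(individuals$geno)
  freqs <- allele_freqs_from_genotypes(individuals$geno)
  set.seed(seed)
  reps <- list()
  out <- data.frame()
  for (lev in levels) {
    n_draw <- as.integer(round_half_up(lev * n_ref))
    if (n_draw > n_avail) {
      stop("level ", lev, " requests ", n_draw, " of ", n_avail,
           " available individuals")
    }
    if (n_draw < 2L) stop("level ", lev, " draws fewer than 2 individuals")
    nhat <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      take <- sample.int(n_avail, n_draw)
      sub <- structure(list(
        info = individuals$info[take, , drop = FALSE],
        geno = individuals$geno[take, , drop = FALSE],
        members = NULL, panel = individuals$panel),
        class = "individual_set")
      ped <- reconstruct_pedigree(sub, freqs = freqs, cfg = cfg)
      rel <- lr_matrix(sub$geno, freqs = freqs)
      rho <- ped$dam_sire_ratio
      if (!is.finite(rho) || rho <= 0) rho <- 1
      inp <- cre_inputs(ped, rel)
      inp$rho <- rho
      est <- if (ped$b_s > 0) cre_estimate(inp, strategy)$n_hat else ped$n_s
      nhat[r] <- est
    }
    m <- mean(nhat)
    out <- rbind(out, data.frame(
      level = lev, n_drawn = n_draw, mean_nhat = m, sd_nhat = stats::sd(nhat),
      cv = stats::sd(nhat) / m,
      pct_diff = 100 * abs(n_ref - m) / m))
    reps[[as.character(lev)]] <- nhat
  }
  attr(out, "replicates") <- reps
  out
}

#' Percentage relative precision
#'
#' Relates a population estimate to its 95% confidence limits:
#' `100 * ((ci_high - ci_low) / 2) / estimate`, rounded to the nearest
#' integer percent.
#'
#' @param estimate point estimate (> 0)
#' @param ci_low,ci_high confidence limits with
#'   `ci_low <= estimate <= ci_high`
#' @return integer percent
#' @examples
#' prp(362, 310, 459)   # 21
#' prp(793, 621, 1179)  # 35
#' @export
prp <- function(estimate, ci_low, ci_high) {
  if (estimate <= 0) stop("estimate must be positive")
  if (ci_low > estimate || ci_high < estimate) {
    stop("confidence limits must bracket the estimate")
  }
  as.integer(round_half_up(100 * ((ci_high - ci_low) / 2) / estimate))
}

#' Two-sample z-test for proportions (pooled)
#'
#' Standard pooled-variance z statistic for comparing k1/n1 with k2/n2,
#' with a two-sided normal p-value.
#'
#' @param k1,n1,k2,n2 successes and trials per group
#' @return list: `z`, `p`, and the two proportions
#' @export
two_prop_ztest <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("trial counts must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("invalid success counts")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Pearson chi-square test of homogeneity of proportions
#'
#' Tests whether the per-group proportions (e.g. parent-offspring pairs
#' per sampled individuals in different spatial subsets) are homogeneous,
#' on the groups x (event, no event) contingency table without continuity
#' correction.
#'
#' @param counts events per group
#' @param ns group sizes (all positive, `counts <= ns`)
#' @return list: `chisq`, `df`, `p`, `low_expected` flag (some expected
#'   cell below 1)
#' @export
chisq_homogeneity <- function(counts, ns) {
  if (any(ns <= 0)) stop("group sizes must be positive")
  if (any(counts < 0 | counts > ns)) stop("counts must lie in [0, ns]")
  tab <- cbind(counts, ns - counts)
  if (sum(counts) == 0 || sum(ns - counts) == 0) {
    return(list(chisq = 0, df = length(ns) - 1L, p = 1, low_expected = TRUE))
  }
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), low_expected = any(exp_tab < 1))
}

#' Core and border subsets of individuals
#'
#' The sampling-area center point is the median center of the individual
#' median centers. The core subset holds the `n` individuals nearest that
#' point; each border subset holds the `n` individuals nearest the
#' corresponding edge of the bounding rectangle of all centers (west =
#' smallest x, east = largest x, south = smallest y, north = largest y).
#' Ties are broken by individual id.
#'
#' @param info data.frame with individual_id, x_median, y_median (an
#'   `individual_set$info` works directly)
#' @param n subset size (<= number of individuals)
#' @return an `edge_subsets` list: `center`, named list `subsets` of
#'   individual-id vectors (core, north, south, east, west), `n`,
#'   `degenerate` flag (all points identical or n equals the population)
#' @export
edge_subsets <- function(info, n) {
  m <- nrow(info)
  if (n > m) stop("subset size exceeds the population")
  ids <- info$individual_id
  x <- info$x_median; y <- info$y_median
  ctr <- c(stats::median(x), stats::median(y))
  take <- function(key) ids[order(key, ids)[seq_len(n)]]
  subsets <- list(
    core = take(sqrt((x - ctr[1])^2 + (y - ctr[2])^2)),
    north = take(max(y) - y),
    south = take(y - min(y)),
    east = take(max(x) - x),
    west = take(x - min(x))
  )
  degenerate <- (stats::var(x) == 0 && stats::var(y) == 0) || n == m
  structure(list(center = ctr, subsets = subsets, n = n,
                 degenerate = degenerate),
            class = "edge_subsets")
}

#' Pedigree completeness of a subset
#'
#' Number of parent-offspring pairs with both members inside the subset,
#' divided by the subset size. Optionally restricted to mother-daughter
#' or father-son pairs for the sex-separated edge analysis.
#'
#' @param subset_ids individual ids in the subset
#' @param ped a `pedigree_result`
#' @param sex_filter NULL, "mother_daughter" or "father_son"
#' @param sexes named sex vector (id -> "F"/"M"), required for the
#'   sex-filtered variants
#' @return proportion (pairs / subset size)
#' @export
dyad_completeness <- function(subset_ids, ped, sex_filter = NULL,
                              sexes = NULL) {
  if (length(subset_ids) == 0L) stop("subset is empty")
  a <- ped$assignments
  links <- rbind(
    data.frame(off = a$offspring_id, par = a$dam_id, par_sex = "F",
               stringsAsFactors = FALSE),
    data.frame(off = a$offspring_id, par = a$sire_id, par_sex = "M",
               stringsAsFactors = FALSE))
  links <- links[!is.na(links$par), , drop = FALSE]
  if (!is.null(sex_filter)) {
    if (is.null(sexes)) stop("sexes required for sex-filtered completeness")
    off_sex <- sexes[links$off]
    links <- switch(sex_filter,
      mother_daughter = links[links$par_sex == "F" & off_sex %in% "F", ],
      father_son = links[links$par_sex == "M" & off_sex %in% "M", ],
      stop("unknown sex_filter: ", sex_filter))
  }
  inside <- links$off %in% subset_ids & links$par %in% subset_ids
  sum(inside) / length(subset_ids)
}

#' One-sample t test
#'
#' Tests whether the mean of `values` differs from `mu` (e.g. whether
#' parent-offspring relatedness differs from the first-order expectation
#' of 0.5).
#'
#' @param values numeric vector (length >= 2)
#' @param mu null mean
#' @return list: `t`, `df`, `p`, `mean`, `zero_variance` flag
#' @export
one_sample_t <- function(values, mu) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  if (stats::sd(values) == 0) {
    if (mean(values) == mu) {
      return(list(t = 0, df = length(values) - 1L, p = 1,
                  mean = mean(values), zero_variance = TRUE))
    }
    return(list(t = Inf * sign(mean(values) - mu),
                df = length(values) - 1L, p = 0,
                mean = mean(values), zero_variance = TRUE))
  }
  tt <- stats::t.test(values, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(values), zero_variance = FALSE)
}
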