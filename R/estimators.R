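#' Screen parent-offspring dyads for full siblings
#'
#' Dyad offspring sharing the same known parent are compared pairwise;
#' where their Lynch-Ritland relatedness reaches `fs_threshold`
#' (full sibs expect r ~ 0.5, half sibs ~ 0.25) they are linked, and each
#' connected component of two or more offspring is taken to share a
#' single missing parent of the opposite sex to the known parent. Those
#' dyads therefore contribute exactly one inferred individual and are
#' removed from the pool passed on to the ratio method.
#'
#' @param dyads data.frame: offspring_id, known_parent_id,
#'   known_parent_sex ("F"/"M")
#' @param relatedness a `relatedness_matrix` (or a plain symmetric matrix
#'   with id dimnames)
#' @param fs_threshold minimum r for a full-sibling call (default 0.375,
#'   midway between half-sib and full-sib expectations)
#' @return list: `inferred_sires`, `inferred_dams` (counts),
#'   `fs_groups` (list of offspring-id groups), `remaining` (dyads not
#'   consumed by a full-sib group)
#' @export
screen_fullsib_dyads <- function(dyads, relatedness, fs_threshold = 0.375) {
  rmat <- if (inherits(relatedness, "relatedness_matrix")) relatedness$r
          else relatedness
  inferred_sires <- 0L
  inferred_dams <- 0L
  fs_groups <- list()
  consumed <- rep(FALSE, nrow(dyads))
  if (nrow(dyads) > 0L) {
    for (par in unique(dyads$known_parent_id)) {
      rows <- which(dyads$known_parent_id == par)
      if (length(rows) < 2L) next
      offs <- dyads$offspring_id[rows]
      have <- offs %in% rownames(rmat)
      adj <- matrix(FALSE, length(offs), length(offs))
      if (any(have)) {
        sub <- rmat[offs[have], offs[have], drop = FALSE]
        adj[have, have] <- !is.na(sub) & sub >= fs_threshold
      }
      diag(adj) <- FALSE
      gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comp <- igraph::components(gr)$membership
      for (cc in unique(comp)) {
        mem <- which(comp == cc)
        if (length(mem) < 2L) next
        # one missing parent, opposite sex to the known parent
        if (dyads$known_parent_sex[rows[1]] == "F") {
          inferred_sires <- inferred_sires + 1L
        } else {
          inferred_dams <- inferred_dams + 1L
        }
        fs_groups[[length(fs_groups) + 1L]] <- offs[mem]
        consumed[rows[mem]] <- TRUE
      }
    }
  }
  list(inferred_sires = inferred_sires, inferred_dams = inferred_dams,
       fs_groups = fs_groups,
       remaining = dyads[!consumed, , drop = FALSE])
}

#' Infer missing parents from the dam:sire ratio
#'
#' For dyads not explained by full siblings, missing counterparts are
#' inferred so that the pedigree's dam:sire ratio `rho` is preserved:
#' with `D_d` distinct known dams among the missing-sire dyads and `S_d`
#' distinct known sires among the missing-dam dyads, the method infers
#' `x = round(D_d / rho)` sires and `y = round(S_d * rho)` dams.
#'
#' @param remaining_dyads data.frame as in [screen_fullsib_dyads()]
#' @param rho dam:sire ratio (> 0)
#' @return list: `inferred_sires`, `inferred_dams`, plus the distinct
#'   known-parent counts `d_d` and `s_d`
#' @export
infer_by_ratio <- function(remaining_dyads, rho) {
  if (!is.finite(rho) || rho <= 0) stop("dam:sire ratio must be positive")
  dd <- length(unique(remaining_dyads$known_parent_id[
    remaining_dyads$known_parent_sex == "F"]))
  sd_ <- length(unique(remaining_dyads$known_parent_id[
    remaining_dyads$known_parent_sex == "M"]))
  list(inferred_sires = as.integer(round_half_up(dd / rho)),
       inferred_dams = as.integer(round_half_up(sd_ * rho)),
       d_d = dd, s_d = sd_)
}

#' Mortality correction of inferred parents
#'
#' Inferred individuals are assumed to be at typical breeding age, and
#' one year of sex-specific annual mortality is applied: 11.6% to
#' inferred sires and 7.2% to inferred dams by default. Rounding is per
#' sex, then summed.
#'
#' @param sires,dams inferred counts (non-negative)
#' @param m_m,m_f annual mortality of sires / dams
#' @return integer N_in, the mortality-corrected number of inferred
#'   individuals
#' @examples
#' mortality_correct(58, 69)  # 51 + 64 = 115
#' mortality_correct(45, 48)  # 40 + 45 = 85
#' @export
mortality_correct <- function(sires, dams, m_m = 0.116, m_f = 0.072) {
  if (sires < 0 || dams < 0) stop("counts must be non-negative")
  as.integer(round_half_up(sires * (1 - m_m)) +
             round_half_up(dams * (1 - m_f)))
}

#' Estimate unsampled non-breeders
#'
#' The individuals that neither bred nor were sampled are invisible to
#' pedigree reconstruction; their number is approximated from the
#' composition of the sample. Strategies: `"nonbreeder_fraction"`
#' (default) scales the inferred individuals by the sampled non-breeder
#' fraction, `N_un = round(N_in * (N_s - B_s) / N_s)`;
#' `"breeder_ratio"` uses the non-breeder:breeder ratio,
#' `N_un = round(N_in * (N_s - B_s) / B_s)`; `"none"` returns 0.
#'
#' @param n_in mortality-corrected inferred individuals
#' @param n_s sampled individuals
#' @param b_s sampled breeders (> 0 for the ratio strategies)
#' @param strategy one of "nonbreeder_fraction", "breeder_ratio", "none"
#' @return integer N_un
#' @export
estimate_unsampled <- function(n_in, n_s, b_s,
                               strategy = c("nonbreeder_fraction",
                                            "breeder_ratio", "none")) {
  strategy <- match.arg(strategy)
  if (strategy == "none") return(0L)
  if (b_s <= 0) stop("b_s must be positive for the ratio strategies")
  denom <- if (strategy == "nonbreeder_fraction") n_s else b_s
  as.integer(round_half_up(n_in * (n_s - b_s) / denom))
}

#' Creel-Rosenblatt population estimate
#'
#' Full pipeline over a reconstructed pedigree: full-sibling screening of
#' the dyads, ratio-based inference of the remaining missing parents,
#' sex-specific mortality correction (N_in), estimation of unsampled
#' non-breeders (N_un), and the point estimate
#' `N_hat = N_s + N_in + N_un`. The lower bound is the genotype count
#' N_s; the upper bound treats every dyad as a distinct missing parent
#' with zero mortality.
#'
#' @param inputs list with `n_s`, `b_s`, `dyads` (data.frame), `rho`
#'   (dam:sire ratio), `relatedness`, and optionally `m_f`, `m_m`,
#'   `fs_threshold` — as produced by [cre_inputs()]
#' @param strategy N_un strategy, see [estimate_unsampled()]
#' @return a `cre_result` with every component and the bounds
#' @export
cre_estimate <- function(inputs, strategy = "nonbreeder_fraction") {
  m_f <- inputs$m_f %||% 0.072
  m_m <- inputs$m_m %||% 0.116
  fs_thr <- inputs$fs_threshold %||% 0.375
  scr <- screen_fullsib_dyads(inputs$dyads, inputs$relatedness, fs_thr)
  rat <- infer_by_ratio(scr$remaining, inputs$rho)
  sires <- scr$inferred_sires + rat$inferred_sires
  dams <- scr$inferred_dams + rat$inferred_dams
  n_in <- mortality_correct(sires, dams, m_m = m_m, m_f = m_f)
  n_un <- estimate_unsampled(n_in, inputs$n_s, inputs$b_s, strategy)
  n_hat <- inputs$n_s + n_in + n_un
  n_dyads <- nrow(inputs$dyads)
  upper <- inputs$n_s + n_dyads +
    estimate_unsampled(n_dyads, inputs$n_s, inputs$b_s, strategy)
  structure(list(
    n_s = inputs$n_s, b_s = inputs$b_s, n_dyads = n_dyads,
    fs_inferred_sires = scr$inferred_sires,
    fs_inferred_dams = scr$inferred_dams,
    ratio_inferred_sires = rat$inferred_sires,
    ratio_inferred_dams = rat$inferred_dams,
    inferred_sires = sires, inferred_dams = dams,
    n_in = n_in, n_un = n_un, n_hat = n_hat,
    lower_bound = inputs$n_s, upper_bound = upper,
    strategy = strategy, rho = inputs$rho
  ), class = "cre_result")
}

#' Assemble Creel-Rosenblatt inputs from pipeline stages
#'
#' @param ped a `pedigree_result`
#' @param relatedness a `relatedness_matrix`
#' @param m_f,m_m annual mortality of dams / sires
#' @param fs_threshold full-sibling relatedness cutoff
#' @return list suitable for [cre_estimate()]
#' @export
cre_inputs <- function(ped, relatedness, m_f = 0.072, m_m = 0.116,
                       fs_threshold = 0.375) {
  list(n_s = ped$n_s, b_s = ped$b_s, dyads = pedigree_dyads(ped),
       rho = ped$dam_sire_ratio, relatedness = relatedness,
       m_f = m_f, m_m = m_m, fs_threshold = fs_threshold)
}

#' @export
print.cre_result <- function(x, ...) {
  cat("cre_result: N_s =", x$n_s, "| B_s =", x$b_s,
      "| N_in =", x$n_in, "| N_un =", x$n_un,
      "| N_hat =", x$n_hat,
      sprintf("[%d, %d]\n", x$lower_bound, x$upper_bound))
  invisible(x)
}

#' Cumulative unique-individual counts
#'
#' Accumulation curve of a genotyping campaign: for each prefix of the
#' sample sequence, the number of distinct individuals seen so far.
#'
#' @param individual_seq vector of individual ids in sampling order
#' @return integer vector `y` with `y[i]` = distinct individuals among
#'   the first i samples
#' @export
accumulation_counts <- function(individual_seq) {
  if (length(individual_seq) == 0L) stop("empty sample sequence")
  cumsum(!duplicated(individual_seq))
}

#' Fit the saturating accumulation model y = a x / (b + x)
#'
#' Nonlinear least squares (Levenberg-Marquardt) with the asymptote `a`
#' interpreted as the estimated population size and `b` the rate of
#' decline of the slope. Initialization a0 = max(y), b0 = median(x);
#' convergence declared at a parameter change below 1e-8 within 500
#' iterations. Degenerate inputs (constant y) and non-converged fits are
#' flagged rather than returned as estimates.
#'
#' @param xs increasing sample counts (length >= 3)
#' @param ys unique-individual counts
#' @return list: `a`, `b`, `converged` (logical)
#' @export
fit_saturation <- function(xs, ys) {
  if (length(xs) < 3L || length(xs) != length(ys)) {
    stop("need at least 3 (x, y) points")
  }
  if (is.unsorted(xs, strictly = TRUE)) stop("xs must be increasing")
  if (stats::var(ys) == 0) {
    return(list(a = NA_real_, b = NA_real_, converged = FALSE))
  }
  df <- data.frame(x = xs, y = ys)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x / (b + x), data = df,
                      start = list(a = max(ys), b = stats::median(xs)),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ptol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(a = NA_real_, b = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  conv <- is.finite(cf[["a"]]) && is.finite(cf[["b"]]) && cf[["b"]] > 0
  list(a = unname(cf[["a"]]), b = unname(cf[["b"]]), converged = conv)
}

#' Rarefaction population estimate
#'
#' Repeats the accumulation-curve fit over random permutations of the
#' sample order (the curve, and hence the fitted asymptote, depends on
#' the order in which genotypes are drawn) and reports the mean asymptote
#' of the converged fits as the population estimate.
#'
#' @param individual_seq vector of individual ids, one per sample
#' @param n_iter number of random sampling orders (default 100)
#' @param seed RNG seed for the permutations
#' @return a `rarefaction_fit`: `mean_a`, per-iteration `a` values,
#'   `n_converged`, `n_distinct` observed, `flag_below_observed`
#' @export
rarefaction_estimate <- function(individual_seq, n_iter = 100L, seed = 1L) {
  n <- length(individual_seq)
  n_distinct <- length(unique(individual_seq))
  if (n_distinct < 2L) stop("need at least 2 distinct individuals")
  set.seed(seed)
  a_vals <- rep(NA_real_, n_iter)
  xs <- seq_len(n)
  for (it in seq_len(n_iter)) {
    ys <- accumulation_counts(individual_seq[sample.int(n)])
    f <- fit_saturation(xs, ys)
    if (f$converged) a_vals[it] <- f$a
  }
  conv <- !is.na(a_vals)
  if (!any(conv)) stop("no rarefaction fit converged")
  mean_a <- mean(a_vals[conv])
  structure(list(mean_a = mean_a, a = a_vals,
                 n_converged = sum(conv), n_distinct = n_distinct,
                 flag_below_observed = mean_a < n_distinct),
            class = "rarefaction_fit")
}

#' @export
print.rarefaction_fit <- function(x, ...) {
  cat("rarefaction_fit: mean asymptote =", round(x$mean_a, 1),
      "from", x$n_converged, "converged fits (",
      x$n_distinct, "distinct individuals observed )\n")
  invisible(x)
}
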