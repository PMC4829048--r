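#' Parentage engine configuration
#'
#' @param typing_error per-call genotyping error rate used by the
#'   likelihood model; 0.01 matches an all-sample error rate, with
#'   1.538e-4 available as the low-error preset for curated extracts.
#' @param nf_max,nm_max ceilings on the candidate dam / sire pool sizes
#'   (approximate numbers of females and males in the population).
#' @param min_posterior_odds posterior odds against the both-parents-
#'   unsampled null required to accept an assignment.
#' @param use_sex restrict candidate dams to females and sires to males?
#' @param use_age use birth-year constraints when available (off by
#'   default: noninvasive data typically carry no ages).
#' @return object of class `parentage_config`
#' @export
parentage_config <- function(typing_error = 0.01,
                             nf_max = 500L, nm_max = 500L,
                             min_posterior_odds = 10,
                             use_sex = TRUE, use_age = FALSE) {
  if (typing_error < 0 || typing_error >= 0.5) {
    stop("typing_error must lie in [0, 0.5)")
  }
  if (nf_max < 1L || nm_max < 1L) stop("candidate ceilings must be positive")
  structure(list(typing_error = typing_error,
                 nf_max = as.integer(nf_max), nm_max = as.integer(nm_max),
                 min_posterior_odds = min_posterior_odds,
                 use_sex = use_sex, use_age = use_age),
            class = "parentage_config")
}

#' Count Mendelian incompatibilities between a candidate parent and an
#' offspring
#'
#' A co-called locus is incompatible when parent and offspring share no
#' allele — with dose coding, exactly the opposing-homozygote pattern
#' (0 vs 2). Used as a fast exclusion screen before likelihood scoring.
#'
#' @param off_g,parent_g dose vectors (0/1/2, NA missing)
#' @return integer incompatibility count
#' @export
mendelian_incompatibilities <- function(off_g, parent_g) {
  ok <- !is.na(off_g) & !is.na(parent_g)
  sum(abs(off_g[ok] - parent_g[ok]) == 2L)
}

# P(observed dose | true-dose distribution T, error e):
# an observed call is correct with probability 1-e, otherwise uniform over
# the other two calls. T is a length-3 vector (per locus: columns).
obs_prob <- function(T_mat, obs, eps) {
  t_obs <- T_mat[cbind(obs + 1L, seq_along(obs))]
  (1 - eps) * t_obs + (eps / 2) * (1 - t_obs)
}

# offspring true-dose distribution given transmission probabilities of the
# alternate allele from each side; returns 3 x L matrix
trans_dist <- function(pd, ps) {
  rbind((1 - pd) * (1 - ps),
        pd * (1 - ps) + (1 - pd) * ps,
        pd * ps)
}

#' Trio log-likelihood
#'
#' Log-probability of the offspring's observed calls given both putative
#' parents, under Mendelian transmission with a per-call error rate
#' `eps` applied to the offspring's observed call. Loci where the
#' offspring call is missing are skipped; a missing parental call at a
#' locus integrates that parent's transmitted allele over the population
#' frequency, so trio, dyad and null likelihoods stay comparable on one
#' locus set.
#'
#' @param off_g,dam_g,sire_g dose vectors (0/1/2, NA missing)
#' @param freqs alternate-allele frequencies
#' @param eps per-call error rate in [0, 0.5)
#' @return log-likelihood (can be -Inf when eps = 0 and an exclusion exists)
#' @export
trio_loglik <- function(off_g, dam_g, sire_g, freqs, eps = 0.01) {
  if (eps < 0 || eps >= 0.5) stop("eps must lie in [0, 0.5)")
  ok <- !is.na(off_g)
  if (!any(ok)) return(0)
  pd <- ifelse(is.na(dam_g[ok]), freqs[ok], dam_g[ok] / 2)
  ps <- ifelse(is.na(sire_g[ok]), freqs[ok], sire_g[ok] / 2)
  sum(log(obs_prob(trans_dist(pd, ps), off_g[ok], eps)))
}

#' Single-parent (dyad) log-likelihood
#'
#' As [trio_loglik()], with the missing parent's transmitted allele
#' integrated over the population allele frequencies.
#'
#' @param off_g,parent_g dose vectors
#' @param freqs alternate-allele frequencies
#' @param eps per-call error rate
#' @return log-likelihood
#' @export
single_parent_loglik <- function(off_g, parent_g, freqs, eps = 0.01) {
  if (eps < 0 || eps >= 0.5) stop("eps must lie in [0, 0.5)")
  ok <- !is.na(off_g)
  if (!any(ok)) return(0)
  pp <- ifelse(is.na(parent_g[ok]), freqs[ok], parent_g[ok] / 2)
  sum(log(obs_prob(trans_dist(pp, freqs[ok]), off_g[ok], eps)))
}

# both parents unsampled: Hardy-Weinberg draw with observation error
null_loglik <- function(off_g, freqs, eps = 0.01) {
  ok <- !is.na(off_g)
  if (!any(ok)) return(0)
  sum(log(obs_prob(trans_dist(freqs[ok], freqs[ok]), off_g[ok], eps)))
}

# pairwise exclusion counts between offspring rows and candidate rows:
# opposing homozygotes via indicator cross-products
exclusion_matrix <- function(g_off, g_cand) {
  h0o <- (!is.na(g_off) & g_off == 0L) * 1
  h2o <- (!is.na(g_off) & g_off == 2L) * 1
  h0c <- (!is.na(g_cand) & g_cand == 0L) * 1
  h2c <- (!is.na(g_cand) & g_cand == 2L) * 1
  h0o %*% t(h2c) + h2o %*% t(h0c)
}

#' Reconstruct a sampled pedigree by maximum-likelihood parentage
#'
#' For each focal individual, candidate parents of the appropriate sex
#' are screened by Mendelian exclusion count (allowing
#' `ceiling(2 * eps * L)` incompatibilities over the pair's L co-called
#' loci), then the best-supported triad, dam-only or sire-only dyad is
#' accepted when its posterior odds against the both-parents-unsampled
#' null exceed the configured threshold. Prior odds penalize the
#' assignment by the candidate ceilings (`1/nf_max` per assigned dam,
#' `1/nm_max` per assigned sire). Accepted links are made globally
#' consistent: assignments are added in decreasing order of odds and any
#' link that would close a directed cycle (an individual becoming its own
#' ancestor) is dropped.
#'
#' @param individuals an `individual_set` (consensus genotypes + sexes),
#'   or a list with `geno` and `info$individual_id`/`info$sex`
#' @param freqs alternate-allele frequencies (defaults to plug-in from
#'   the consensus genotypes)
#' @param cfg a [parentage_config()]
#' @return a `pedigree_result`: `assignments` (offspring_id, dam_id,
#'   sire_id, category, log_odds, ambiguous), counts `n_triads`,
#'   `n_dyads`, `n_unassigned`, `n_s`, breeder set `breeders`, `b_s`,
#'   `dam_sire_ratio`
#' @export
reconstruct_pedigree <- function(individuals, freqs = NULL,
                                 cfg = parentage_config()) {
  geno <- individuals$geno
  info <- individuals$info
  ids <- info$individual_id
  n <- nrow(geno)
  if (is.null(freqs)) freqs <- allele_freqs_from_genotypes(geno)
  eps <- cfg$typing_error
  # likelihood evaluation needs a strictly positive error rate; an exact
  # eps = 0 keeps exclusions infinitely penalized via a tiny floor
  eps_ll <- max(eps, 1e-9)

  sex <- if (cfg$use_sex) info$sex else rep("UNKNOWN", n)
  dam_pool_all <- which(sex == "F")
  sire_pool_all <- which(sex == "M")
  if (!cfg$use_sex) {
    dam_pool_all <- sire_pool_all <- seq_len(n)
  }

  excl <- exclusion_matrix(geno, geno)
  called <- !is.na(geno)
  overlap <- (called * 1) %*% t(called * 1)
  max_excl <- ceiling(2 * eps * overlap)

  cand <- list()
  warn_trunc <- FALSE
  for (i in seq_len(n)) {
    okd <- dam_pool_all[dam_pool_all != i &
                          excl[i, dam_pool_all] <= max_excl[i, dam_pool_all]]
    oks <- sire_pool_all[sire_pool_all != i &
                           excl[i, sire_pool_all] <= max_excl[i, sire_pool_all]]
    lls_d <- vapply(okd, function(j)
      single_parent_loglik(geno[i, ], geno[j, ], freqs, eps_ll), 0)
    lls_s <- vapply(oks, function(j)
      single_parent_loglik(geno[i, ], geno[j, ], freqs, eps_ll), 0)
    if (length(okd) > cfg$nf_max) {
      warn_trunc <- TRUE
      keep <- order(lls_d, decreasing = TRUE)[seq_len(cfg$nf_max)]
      okd <- okd[keep]; lls_d <- lls_d[keep]
    }
    if (length(oks) > cfg$nm_max) {
      warn_trunc <- TRUE
      keep <- order(lls_s, decreasing = TRUE)[seq_len(cfg$nm_max)]
      oks <- oks[keep]; lls_s <- lls_s[keep]
    }
    cand[[i]] <- list(dams = okd, sires = oks, ll_d = lls_d, ll_s = lls_s)
  }
  if (warn_trunc) {
    warning("candidate pool exceeded nf_max/nm_max; truncated by likelihood")
  }

  log_prior_dam <- -log(cfg$nf_max)
  log_prior_sire <- -log(cfg$nm_max)
  min_log_odds <- log(cfg$min_posterior_odds)

  asn <- data.frame(offspring_id = ids, dam_id = NA_character_,
                    sire_id = NA_character_, category = "none",
                    log_odds = NA_real_, ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ll0 <- null_loglik(geno[i, ], freqs, eps_ll)
    cd <- cand[[i]]
    best <- list(odds = -Inf, dam = NA_integer_, sire = NA_integer_,
                 category = "none", tie = FALSE)
    consider <- function(odds, dam, sire, category) {
      if (odds > best$odds + 1e-9) {
        best <<- list(odds = odds, dam = dam, sire = sire,
                      category = category, tie = FALSE)
      } else if (abs(odds - best$odds) <= 1e-9 && is.finite(odds)) {
        # equal-likelihood tie: keep the lexicographically first ids,
        # flag the ambiguity
        cur <- c(best$dam, best$sire); new <- c(dam, sire)
        cur_key <- paste(ids[cur[!is.na(cur)]], collapse = "|")
        new_key <- paste(ids[new[!is.na(new)]], collapse = "|")
        if (new_key < cur_key) {
          best <<- list(odds = odds, dam = dam, sire = sire,
                        category = category, tie = TRUE)
        } else {
          best$tie <<- TRUE
        }
      }
    }
    for (k in seq_along(cd$dams)) {
      consider(cd$ll_d[k] + log_prior_dam - ll0, cd$dams[k], NA_integer_,
               "dyad_dam")
    }
    for (k in seq_along(cd$sires)) {
      consider(cd$ll_s[k] + log_prior_sire - ll0, NA_integer_, cd$sires[k],
               "dyad_sire")
    }
    if (length(cd$dams) > 0L && length(cd$sires) > 0L) {
      for (kd in seq_along(cd$dams)) {
        for (ks in seq_along(cd$sires)) {
          ll <- trio_loglik(geno[i, ], geno[cd$dams[kd], ],
                            geno[cd$sires[ks], ], freqs, eps_ll)
          consider(ll + log_prior_dam + log_prior_sire - ll0,
                   cd$dams[kd], cd$sires[ks], "triad")
        }
      }
    }
    if (is.finite(best$odds) && best$odds > min_log_odds) {
      asn$dam_id[i] <- if (is.na(best$dam)) NA_character_ else ids[best$dam]
      asn$sire_id[i] <- if (is.na(best$sire)) NA_character_ else ids[best$sire]
      asn$category[i] <- best$category
      asn$log_odds[i] <- best$odds
      asn$ambiguous[i] <- best$tie
    }
  }

  asn <- enforce_acyclic(asn)
  finalize_pedigree(asn, ids)
}

# drop parent links that would make an individual its own ancestor,
# keeping higher-odds assignments; parent -> offspring edges are added
# greedily in decreasing order of assignment odds
enforce_acyclic <- function(asn) {
  ids <- asn$offspring_id
  idx <- stats::setNames(seq_along(ids), ids)
  children <- vector("list", length(ids))  # adjacency parent -> offspring
  reaches <- function(from, to) {          # is `to` reachable from `from`?
    seen <- logical(length(ids))
    stack <- from
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v == to) return(TRUE)
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, children[[v]])
    }
    FALSE
  }
  ord <- order(-ifelse(is.na(asn$log_odds), -Inf, asn$log_odds))
  for (i in ord) {
    if (asn$category[i] == "none") next
    o <- idx[[asn$offspring_id[i]]]
    for (side in c("dam_id", "sire_id")) {
      p_id <- asn[[side]][i]
      if (is.na(p_id)) next
      p <- idx[[p_id]]
      if (reaches(o, p)) {
        asn[[side]][i] <- NA_character_   # would close a cycle
      } else {
        children[[p]] <- c(children[[p]], o)
      }
    }
    asn$category[i] <- category_of(asn$dam_id[i], asn$sire_id[i])
  }
  asn
}

category_of <- function(dam, sire) {
  if (!is.na(dam) && !is.na(sire)) "triad"
  else if (!is.na(dam)) "dyad_dam"
  else if (!is.na(sire)) "dyad_sire"
  else "none"
}

finalize_pedigree <- function(asn, ids) {
  n_triads <- sum(asn$category == "triad")
  n_dyads <- sum(asn$category %in% c("dyad_dam", "dyad_sire"))
  n_un <- sum(asn$category == "none")
  dams <- unique(stats::na.omit(asn$dam_id))
  sires <- unique(stats::na.omit(asn$sire_id))
  breeders <- union(dams, sires)
  structure(list(
    assignments = asn,
    n_s = length(ids), n_triads = n_triads, n_dyads = n_dyads,
    n_unassigned = n_un,
    breeders = breeders, b_s = length(breeders),
    n_dams = length(dams), n_sires = length(sires),
    dam_sire_ratio = if (length(sires) > 0L) length(dams) / length(sires)
                     else NA_real_
  ), class = "pedigree_result")
}

#' @export
print.pedigree_result <- function(x, ...) {
  cat("pedigree_result: N_s =", x$n_s, "| triads", x$n_triads,
      "| dyads", x$n_dyads, "| no parent", x$n_unassigned,
      "| B_s =", x$b_s, "| dam:sire =",
      round(x$dam_sire_ratio, 2), "\n")
  invisible(x)
}

#' Parent-offspring dyads of a reconstructed pedigree
#'
#' The single-parent (dyad) assignments, i.e. offspring with exactly one
#' identified parent — the records from which missing parents are
#' inferred.
#'
#' @param ped a `pedigree_result`
#' @return data.frame: offspring_id, known_parent_id, known_parent_sex
#' @export
pedigree_dyads <- function(ped) {
  a <- ped$assignments
  d <- a[a$category %in% c("dyad_dam", "dyad_sire"), , drop = FALSE]
  data.frame(
    offspring_id = d$offspring_id,
    known_parent_id = ifelse(d$category == "dyad_dam", d$dam_id, d$sire_id),
    known_parent_sex = ifelse(d$category == "dyad_dam", "F", "M"),
    stringsAsFactors = FALSE
  )
}

#' Write a reconstructed pedigree to CSV
#' @param ped a `pedigree_result`
#' @param path output file
#' @export
write_pedigree_result_csv <- function(ped, path) {
  utils::write.csv(ped$assignments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
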