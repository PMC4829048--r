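#' Subset a sample set
#' @param samples a `sample_set`
#' @param keep logical or index vector over samples
#' @return the subset `sample_set`
#' @export
filter_samples <- function(samples, keep) {
  structure(list(meta = samples$meta[keep, , drop = FALSE],
                 calls = samples$calls[keep, , drop = FALSE],
                 panel = samples$panel),
            class = "sample_set")
}

#' Plug-in allele frequencies from consensus genotypes
#'
#' Alternate-allele frequency per locus estimated from identified
#' individuals (not from raw samples, which would weight individuals by
#' their resampling frequency). Frequencies are clamped away from 0 and 1
#' so that downstream estimators stay defined at loci that happen to be
#' monomorphic in the sample.
#'
#' @param geno dose matrix (0/1/2, NA missing), individuals x loci
#' @param clamp minimum distance from the 0/1 boundary
#' @return numeric vector of alternate-allele frequencies per locus
#' @export
allele_freqs_from_genotypes <- function(geno, clamp = 0.005) {
  n2 <- 2 * colSums(!is.na(geno))
  f <- colSums(geno, na.rm = TRUE) / pmax(n2, 1)
  pmin(pmax(f, clamp), 1 - clamp)
}

# Per-locus Lynch-Ritland components for reference genotype gx against
# proband genotype gy, at alternate-allele ("B") frequency p.
# Reference hom A: num = 2*pA*nA(y) - 4*pA^2,      den = 4*pA*(1-pA)
# Reference het:   num = pB*nA(y) + pA*nB(y) - 4*pA*pB, den = 1 - 4*pA*pB
# Reference hom B: num = 2*pB*nB(y) - 4*pB^2,      den = 4*pB*(1-pB)
# where nA(y), nB(y) count the proband's A/B alleles.
lr_components <- function(gx, gy, p) {
  pA <- 1 - p; pB <- p
  nA <- 2 - gy; nB <- gy
  num <- ifelse(gx == 0L, 2 * pA * nA - 4 * pA^2,
         ifelse(gx == 1L, pB * nA + pA * nB - 4 * pA * pB,
                          2 * pB * nB - 4 * pB^2))
  den <- ifelse(gx == 0L, 4 * pA * (1 - pA),
         ifelse(gx == 1L, 1 - 4 * pA * pB,
                          4 * pB * (1 - pB)))
  list(num = num, den = den)
}

#' Lynch-Ritland pairwise relatedness
#'
#' Regression-based relatedness estimator for a pair of multilocus
#' genotypes given population allele frequencies. Loci are combined in
#' the weighted (ratio-of-sums) form — the sum of per-locus numerators
#' over the sum of per-locus denominators — which keeps the estimator
#' defined at biallelic loci where a heterozygous reference at p = 0.5
#' has zero denominator. The final value is the arithmetic mean of the
#' two directed estimates (each genotype taken once as reference); if
#' only one direction has informative loci that direction is returned,
#' and if neither does the estimate is NA.
#'
#' Expectation is 0.5 for parent-offspring and full-sib pairs, 0.25 for
#' half-sibs, 0 for unrelated pairs.
#'
#' @param gx,gy integer dose vectors (0/1/2, NA missing) on the same loci
#' @param freqs alternate-allele frequencies, strictly inside (0, 1)
#' @return list with `r` (estimate, NA when undefined) and `n_loci`
#'   (co-called informative loci)
#' @export
lr_pair <- function(gx, gy, freqs) {
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("allele frequencies must lie strictly inside (0, 1)")
  }
  ok <- !is.na(gx) & !is.na(gy)
  if (!any(ok)) return(list(r = NA_real_, n_loci = 0L))
  gx <- gx[ok]; gy <- gy[ok]; p <- freqs[ok]
  fwd <- lr_components(gx, gy, p)
  rev <- lr_components(gy, gx, p)
  r_fwd <- if (sum(fwd$den) > 0) sum(fwd$num) / sum(fwd$den) else NA_real_
  r_rev <- if (sum(rev$den) > 0) sum(rev$num) / sum(rev$den) else NA_real_
  r <- mean(c(r_fwd, r_rev), na.rm = TRUE)
  if (is.nan(r)) r <- NA_real_
  n_inf <- sum(fwd$den != 0 | rev$den != 0)
  list(r = r, n_loci = n_inf)
}

#' Pairwise Lynch-Ritland relatedness matrix
#'
#' Evaluates [lr_pair()] for every unordered pair of individuals, using
#' indicator-matrix cross-products so the cost is a handful of matrix
#' multiplications rather than a loop over pairs. Pairs with fewer than
#' `min_informative` informative loci are flagged low-confidence.
#'
#' @param geno dose matrix, individuals x loci; rownames are ids
#' @param freqs alternate-allele frequencies; defaults to the plug-in
#'   estimate from `geno` itself
#' @param min_informative flag threshold for the informative-locus count
#' @return a `relatedness_matrix`: list with symmetric matrix `r`,
#'   matrix `n_loci`, and `pairs` (data.frame id1, id2, r,
#'   n_informative_loci, low_confidence)
#' @export
lr_matrix <- function(geno, freqs = NULL, min_informative = 20L) {
  if (nrow(geno) < 2L) stop("need at least 2 individuals")
  if (is.null(freqs)) freqs <- allele_freqs_from_genotypes(geno)
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("allele frequencies must lie strictly inside (0, 1)")
  }
  pA <- 1 - freqs; pB <- freqs
  called <- !is.na(geno)
  g0 <- ifelse(called, geno, 0L)

  # reference-side per-locus coefficients: num = a*nA(y) + b*nB(y) + c
  is0 <- called & geno == 0L; is1 <- called & geno == 1L; is2 <- called & geno == 2L
  A <- sweep(is0, 2, 2 * pA, "*") + sweep(is1, 2, pB, "*")
  B <- sweep(is1, 2, pA, "*") + sweep(is2, 2, 2 * pB, "*")
  C <- sweep(is0, 2, -4 * pA^2, "*") + sweep(is1, 2, -4 * pA * pB, "*") +
       sweep(is2, 2, -4 * pB^2, "*")
  denx <- sweep(is0, 2, 4 * pA * (1 - pA), "*") +
          sweep(is1, 2, 1 - 4 * pA * pB, "*") +
          sweep(is2, 2, 4 * pB * (1 - pB), "*")

  nAy <- (2 - g0) * called
  nBy <- g0 * called
  cl <- called * 1

  num <- A %*% t(nAy) + B %*% t(nBy) + C %*% t(cl)
  den <- denx %*% t(cl)

  r_dir <- ifelse(den > 1e-12, num / den, NA_real_)
  r <- (r_dir + t(r_dir)) / 2
  only_fwd <- is.na(t(r_dir)) & !is.na(r_dir)
  r[only_fwd] <- r_dir[only_fwd]
  r[t(only_fwd)] <- t(r_dir)[t(only_fwd)]
  diag(r) <- NA_real_

  # informative loci for a pair: co-called loci where at least one
  # direction has a nonzero denominator
  zero_x <- (called & denx == 0) * 1
  n_loci <- cl %*% t(cl) - zero_x %*% t(zero_x)
  dimnames(r) <- dimnames(n_loci) <- list(rownames(geno), rownames(geno))

  ut <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- data.frame(
    id1 = rownames(geno)[ut[, 1]], id2 = rownames(geno)[ut[, 2]],
    r = r[ut], n_informative_loci = as.integer(n_loci[ut]),
    stringsAsFactors = FALSE
  )
  pairs$low_confidence <- pairs$n_informative_loci < min_informative
  structure(list(r = r, n_loci = n_loci, pairs = pairs, freqs = freqs),
            class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat("relatedness_matrix:", nrow(x$r), "individuals,",
      nrow(x$pairs), "pairs\n")
  invisible(x)
}

#' Write pairwise relatedness to CSV
#' @param rel a `relatedness_matrix`
#' @param path output file
#' @export
write_relatedness_csv <- function(rel, path) {
  utils::write.csv(rel$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
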