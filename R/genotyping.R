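#' Per-sample QC on call completeness
#'
#' A sample passes quality control when strictly more than `min_loci` of
#' its assays produced a call. By default the count runs over all 96
#' assays; set `autosomal_only = TRUE` to count the 85 identity SNPs only.
#'
#' @param samples a `sample_set`
#' @param min_loci QC threshold (pass requires called > min_loci)
#' @param autosomal_only count autosomal assays only?
#' @return logical vector, one element per sample
#' @export
qc_samples <- function(samples, min_loci = 70L, autosomal_only = FALSE) {
  calls <- samples$calls
  if (autosomal_only) calls <- calls[, samples$panel$auto_loci, drop = FALSE]
  called <- rowSums(calls != "NN" & calls != "-")
  stats::setNames(called > min_loci, rownames(calls))
}

#' Species and sex assignment from marker call counts
#'
#' Applies the assignment rules used with the 96-assay panel: a sample is
#' confirmed as bear when at least 3 of 4 mtDNA assays call; a confirmed
#' sample is male when at least 3 of 4 Y assays call, and female when no
#' Y assay calls and at least 2 of 3 X assays call. Anything else
#' (including 1-2 Y calls, consistent with partial male amplification) is
#' left UNKNOWN rather than risk calling a poorly amplified male a female.
#'
#' @param mt_calls,y_calls,x_calls counts of called mtDNA / Y / X assays
#' @return data.frame with `species_confirmed` (logical) and `sex`
#'   ("F", "M" or "UNKNOWN"); vectors recycle to a common length
#' @export
assign_species_sex <- function(mt_calls, y_calls, x_calls) {
  n <- max(length(mt_calls), length(y_calls), length(x_calls))
  mt_calls <- rep_len(mt_calls, n)
  y_calls <- rep_len(y_calls, n)
  x_calls <- rep_len(x_calls, n)
  species <- mt_calls >= 3L
  sex <- ifelse(!species, "UNKNOWN",
         ifelse(y_calls >= 3L, "M",
         ifelse(y_calls == 0L & x_calls >= 2L, "F", "UNKNOWN")))
  data.frame(species_confirmed = species, sex = sex,
             stringsAsFactors = FALSE)
}

# integer dose matrix (0/1/2, NA missing) from autosomal call strings
calls_to_dose <- function(calls) {
  g <- matrix(NA_integer_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  g[calls == "AA"] <- 0L
  g[calls == "AB"] <- 1L
  g[calls == "BB"] <- 2L
  g
}

dose_to_calls <- function(g) {
  out <- matrix("NN", nrow(g), ncol(g), dimnames = dimnames(g))
  out[!is.na(g)] <- c("AA", "AB", "BB")[g[!is.na(g)] + 1L]
  out
}

# pairwise co-called locus counts and mismatch counts between the rows of
# two dose matrices; returns list(overlap, mismatch) of n1 x n2 matrices.
# Computed with indicator cross-products, no per-pair loops.
pairwise_mismatch <- function(g1, g2 = g1) {
  c1 <- !is.na(g1); c2 <- !is.na(g2)
  overlap <- (c1 * 1) %*% t(c2 * 1)
  agree <- matrix(0, nrow(g1), nrow(g2))
  for (k in 0:2) {
    m1 <- (!is.na(g1) & g1 == k) * 1
    m2 <- (!is.na(g2) & g2 == k) * 1
    agree <- agree + m1 %*% t(m2)
  }
  list(overlap = overlap, mismatch = overlap - agree)
}

#' Match samples into individuals
#'
#' Single-linkage clustering of QC-passed samples on their autosomal
#' calls: two samples link when they share at least `min_overlap`
#' co-called loci and disagree at no more than `max_mismatch` of them.
#' Each cluster becomes one identified individual with a per-locus
#' majority-rule consensus genotype (ties yield a missing call), a sex
#' assignment from consensus marker presence, and a componentwise median
#' spatial center. Clusters whose member samples carry conflicting
#' definite sex assignments (both F and M) are flagged, not silently
#' merged away.
#'
#' @param samples a `sample_set` (QC-passed; see [qc_samples()])
#' @param max_mismatch maximum tolerated disagreeing loci within a link
#' @param min_overlap minimum co-called loci for a link to be assessable
#' @return an `individual_set`: list with `info` (individual_id,
#'   n_samples, sex, x_median, y_median, n_loci_called, sex_conflict),
#'   `geno` consensus dose matrix, `members` (list of sample ids), and the
#'   latent truth map when the input carried one
#' @export
match_samples <- function(samples, max_mismatch = 2L, min_overlap = 40L) {
  panel <- samples$panel
  calls <- samples$calls
  if (nrow(calls) == 0L) stop("no samples to match")
  g <- calls_to_dose(calls[, panel$auto_loci, drop = FALSE])
  pm <- pairwise_mismatch(g)
  link <- pm$overlap >= min_overlap & pm$mismatch <= max_mismatch
  diag(link) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(link, mode = "undirected")
  comp <- igraph::components(gr)$membership

  per_sample_sex <- assign_species_sex(
    rowSums(calls[, panel$mt_loci, drop = FALSE] == "1"),
    rowSums(calls[, panel$y_loci, drop = FALSE] == "1"),
    rowSums(calls[, panel$x_loci, drop = FALSE] == "1"))$sex

  n_ind <- max(comp)
  ids <- sprintf("G%04d", seq_len(n_ind))
  members <- split(rownames(calls), comp)
  names(members) <- ids

  cons_geno <- matrix(NA_integer_, n_ind, length(panel$auto_loci),
                      dimnames = list(ids, panel$auto_loci))
  info <- data.frame(individual_id = ids,
                     n_samples = lengths(members),
                     sex = NA_character_, x_median = NA_real_,
                     y_median = NA_real_, n_loci_called = NA_integer_,
                     sex_conflict = FALSE, stringsAsFactors = FALSE)
  truth <- rep(NA_character_, n_ind)
  has_truth <- !all(is.na(samples$meta$individual_id))

  for (i in seq_len(n_ind)) {
    rows <- match(members[[i]], rownames(calls))
    cons_geno[i, ] <- consensus_dose(g[rows, , drop = FALSE])
    # haploid consensus: an assay is present when called in a strict
    # majority of the member samples
    hcount <- function(loci) {
      pres <- colSums(calls[rows, loci, drop = FALSE] == "1")
      sum(pres > length(rows) / 2)
    }
    sx <- assign_species_sex(hcount(panel$mt_loci), hcount(panel$y_loci),
                             hcount(panel$x_loci))
    info$sex[i] <- sx$sex
    ss <- per_sample_sex[rows]
    info$sex_conflict[i] <- all(c("F", "M") %in% ss)
    ctr <- median_center(samples$meta$x[rows], samples$meta$y[rows])
    info$x_median[i] <- ctr[1]; info$y_median[i] <- ctr[2]
    info$n_loci_called[i] <- sum(!is.na(cons_geno[i, ]))
    if (has_truth) {
      tt <- unique(samples$meta$individual_id[rows])
      truth[i] <- if (length(tt) == 1L) tt else paste(sort(tt), collapse = "|")
    }
  }
  info$true_id <- truth
  structure(list(info = info, geno = cons_geno, members = members,
                 panel = panel),
            class = "individual_set")
}

# majority call per column; 1-1 ties give NA, never an arbitrary pick
consensus_dose <- function(g) {
  if (nrow(g) == 1L) return(g[1L, ])
  apply(g, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0L) return(NA_integer_)
    tab <- tabulate(col + 1L, nbins = 3L)
    top <- which(tab == max(tab))
    if (length(top) > 1L) NA_integer_ else top - 1L
  })
}

#' @export
print.individual_set <- function(x, ...) {
  cat("individual_set:", nrow(x$info), "identified individuals (",
      sum(x$info$sex == "F"), "F /", sum(x$info$sex == "M"), "M )\n")
  invisible(x)
}

#' Componentwise median center
#'
#' The median center of a set of planar locations: the coordinatewise
#' median, with even counts using the midpoint of the two central order
#' statistics. Preferred over the mean for its insensitivity to outlying
#' sample locations.
#'
#' @param x,y coordinate vectors (equal length, non-empty)
#' @return numeric length-2 vector (x, y)
#' @export
median_center <- function(x, y) {
  if (length(x) == 0L || length(x) != length(y)) {
    stop("median_center needs at least one (x, y) location")
  }
  c(stats::median(x), stats::median(y))
}

#' Write identified individuals to CSV
#' @param individuals an `individual_set`
#' @param path output file
#' @export
write_individuals_csv <- function(individuals, path) {
  df <- cbind(individuals$info,
              as.data.frame(dose_to_calls(individuals$geno),
                            stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read identified individuals from CSV
#' @param path CSV written by [write_individuals_csv()]
#' @param panel the marker panel
#' @return an `individual_set` (without member sample lists)
#' @export
read_individuals_csv <- function(path, panel = marker_panel()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  geno <- calls_to_dose(as.matrix(df[panel$auto_loci]))
  rownames(geno) <- df$individual_id
  info <- df[setdiff(names(df), panel$auto_loci)]
  structure(list(info = info, geno = geno, members = NULL, panel = panel),
            class = "individual_set")
}
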