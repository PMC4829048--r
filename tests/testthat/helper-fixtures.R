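# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no data files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hardy-Weinberg genotype matrix (n individuals x length(p) loci)
hw_geno <- function(n, p) {
  g <- sapply(p, function(pb) stats::rbinom(n, 2L, pb))
  if (n == 1L) g <- matrix(g, nrow = 1L)
  g
}

# pairs of genotype matrices under a fixed relationship:
# "PO" parent-offspring, "FS" full sibs, "HS" half sibs, "UN" unrelated
related_pairs <- function(n, p, relationship) {
  L <- length(p)
  child_of <- function(gd, gs) {
    t(vapply(seq_len(nrow(gd)), function(i)
      stats::rbinom(L, 1L, gd[i, ] / 2) + stats::rbinom(L, 1L, gs[i, ] / 2),
      integer(L)))
  }
  pop_child <- function(gp) {  # one parent known, other from the population
    t(vapply(seq_len(nrow(gp)), function(i)
      stats::rbinom(L, 1L, gp[i, ] / 2) + stats::rbinom(L, 1L, p),
      integer(L)))
  }
  switch(relationship,
    PO = { a <- hw_geno(n, p); list(a = a, b = pop_child(a)) },
    FS = { d <- hw_geno(n, p); s <- hw_geno(n, p)
           list(a = child_of(d, s), b = child_of(d, s)) },
    HS = { sh <- hw_geno(n, p)
           list(a = pop_child(sh), b = pop_child(sh)) },
    UN = list(a = hw_geno(n, p), b = hw_geno(n, p)),
    stop("unknown relationship"))
}

mean_pair_r <- function(pairs, p) {
  mean(vapply(seq_len(nrow(pairs$a)), function(i)
    lr_pair(pairs$a[i, ], pairs$b[i, ], p)$r, 0))
}

# individual_set straight from a simulated population's true genotypes,
# with optional per-call typing error; `who` selects ids (default: all
# individuals ever, i.e. every parent sampled)
individuals_from_truth <- function(pop, eps = 0, seed = 1L, who = NULL) {
  ids <- who %||% pop$ped$id
  g <- pop$geno[ids, , drop = FALSE]
  if (eps > 0) {
    set.seed(seed)
    err <- matrix(stats::runif(length(g)) < eps, nrow(g))
    g[err] <- vapply(g[err], function(v) sample(setdiff(0:2, v), 1L), 0L)
  }
  info <- data.frame(individual_id = ids,
                     sex = pop$ped$sex[match(ids, pop$ped$id)],
                     stringsAsFactors = FALSE)
  structure(list(info = info, geno = g, members = NULL, panel = pop$panel),
            class = "individual_set")
}

# undirected parent-offspring link sets, for precision/recall scoring
undirected_links <- function(a_id, b_id) {
  keep <- !is.na(b_id)
  unique(paste(pmin(a_id[keep], b_id[keep]), pmax(a_id[keep], b_id[keep])))
}

true_po_links <- function(ped_df, within = NULL) {
  if (!is.null(within)) {
    ped_df <- ped_df[ped_df$id %in% within, , drop = FALSE]
    ped_df$dam_id[!(ped_df$dam_id %in% within)] <- NA
    ped_df$sire_id[!(ped_df$sire_id %in% within)] <- NA
  }
  unique(c(undirected_links(ped_df$id, ped_df$dam_id),
           undirected_links(ped_df$id, ped_df$sire_id)))
}

assigned_po_links <- function(ped_result) {
  a <- ped_result$assignments
  unique(c(undirected_links(a$offspring_id, a$dam_id),
           undirected_links(a$offspring_id, a$sire_id)))
}

# sample_set built from explicit autosomal dose rows (plus clean haploid
# calls for a given sex), so matching rules can be exercised exactly
sample_set_from_doses <- function(doses, sex = "F", x = NULL, y = NULL) {
  panel <- marker_panel()
  n <- nrow(doses)
  auto <- matrix("NN", n, 85, dimnames = list(NULL, panel$auto_loci))
  ok <- !is.na(doses)
  auto[ok] <- c("AA", "AB", "BB")[doses[ok] + 1L]
  sex <- rep_len(sex, n)
  hap <- cbind(
    matrix("1", n, 4, dimnames = list(NULL, panel$mt_loci)),
    matrix(ifelse(rep(sex == "M", 4), "1", "-"), n, 4,
           dimnames = list(NULL, panel$y_loci)),
    matrix("1", n, 3, dimnames = list(NULL, panel$x_loci)))
  calls <- cbind(auto, hap)
  meta <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    individual_id = NA_character_,
    date = "2014-09-01",
    x = x %||% rep(0, n), y = y %||% rep(0, n),
    stringsAsFactors = FALSE)
  rownames(calls) <- meta$sample_id
  structure(list(meta = meta, calls = calls, panel = panel),
            class = "sample_set")
}

# independent union-find, the oracle for single-linkage partitions
uf_partition <- function(n, edges) {
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- findp(edges[k, 1]); b <- findp(edges[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), findp, 0L)
}

# brute-force grid search oracle for the saturation fit: coarse grid,
# then local refinement down to `step`
grid_fit_oracle <- function(xs, ys, step = 1e-3) {
  sse <- function(a, b) sum((ys - a * xs / (b + xs))^2)
  a_rng <- c(max(ys), 3 * max(ys))
  b_rng <- c(step, 2 * max(xs))
  best <- c(a = NA, b = NA)
  for (pass in 1:10) {
    a_grid <- seq(a_rng[1], a_rng[2], length.out = 41)
    b_grid <- seq(b_rng[1], b_rng[2], length.out = 41)
    best_sse <- Inf  # fresh search on each (shrinking) window
    for (a in a_grid) for (b in b_grid) {
      s <- sse(a, b)
      if (s < best_sse) { best_sse <- s; best <- c(a = a, b = b) }
    }
    da <- diff(a_rng) / 40; db <- diff(b_rng) / 40
    # window of +/- 3 cells so a coarse off-by-one cannot trap the search
    a_rng <- c(best["a"] - 3 * da, best["a"] + 3 * da)
    b_rng <- c(max(best["b"] - 3 * db, step / 10), best["b"] + 3 * db)
    if (da < step / 4 && db < step / 4) break
  }
  best
}
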