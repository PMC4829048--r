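#' Simulation configuration
#'
#' Parameters for the individual-based demographic simulator. Defaults
#' describe a solitary, long-lived, polygynandrous large carnivore with
#' female philopatry and sex-specific adult mortality (7.2%/yr females,
#' 11.6%/yr males), sampled noninvasively via feces with allelic dropout
#' and a per-call typing-error rate of 0.01.
#'
#' @param n_founders founding population size (both sexes required).
#' @param n_years number of simulated years.
#' @param litter_size_mean expected cubs per litter (Poisson, truncated at 4).
#' @param breeding_prob annual probability that a breeding-age female litters.
#' @param breeding_age age (years) at first possible breeding.
#' @param adult_mortality_f,adult_mortality_m annual adult mortality by sex.
#' @param cub_mortality annual mortality applied below `breeding_age`.
#' @param philopatry_sd_f,dispersal_sd_m standard deviation (map units) of
#'   daughter settlement around the dam / son natal dispersal. Female
#'   philopatry requires `philopatry_sd_f < dispersal_sd_m`.
#' @param mating_sd spatial scale of mate choice: sires are drawn with
#'   probability proportional to `exp(-d^2 / (2 * mating_sd^2))`.
#' @param samples_per_individual_mean Poisson mean of fecal samples per
#'   living individual (before zero inflation).
#' @param sampling_zero_prob extra probability that an individual is never
#'   sampled (zero inflation controls sampling coverage).
#' @param sample_scatter_sd standard deviation of sample locations around
#'   an individual's center.
#' @param dropout_prob per-assay probability of amplification failure.
#' @param typing_error per-call probability of an erroneous call.
#' @param area_w,area_h study-area width/height in abstract planar units.
#' @param seed master RNG seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_founders = 120L,
                       n_years = 12L,
                       litter_size_mean = 2.4,
                       breeding_prob = 0.35,
                       breeding_age = 5L,
                       adult_mortality_f = 0.072,
                       adult_mortality_m = 0.116,
                       cub_mortality = 0.22,
                       philopatry_sd_f = 5,
                       dispersal_sd_m = 25,
                       mating_sd = 20,
                       samples_per_individual_mean = 2.5,
                       sampling_zero_prob = 0.25,
                       sample_scatter_sd = 3,
                       dropout_prob = 0.05,
                       typing_error = 0.01,
                       area_w = 100,
                       area_h = 100,
                       seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders), n_years = as.integer(n_years),
    litter_size_mean = litter_size_mean, breeding_prob = breeding_prob,
    breeding_age = as.integer(breeding_age),
    adult_mortality_f = adult_mortality_f,
    adult_mortality_m = adult_mortality_m,
    cub_mortality = cub_mortality,
    philopatry_sd_f = philopatry_sd_f, dispersal_sd_m = dispersal_sd_m,
    mating_sd = mating_sd,
    samples_per_individual_mean = samples_per_individual_mean,
    sampling_zero_prob = sampling_zero_prob,
    sample_scatter_sd = sample_scatter_sd,
    dropout_prob = dropout_prob, typing_error = typing_error,
    area_w = area_w, area_h = area_h, seed = as.integer(seed)
  )
  probs <- c("breeding_prob", "adult_mortality_f", "adult_mortality_m",
             "cub_mortality", "sampling_zero_prob", "dropout_prob",
             "typing_error")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$philopatry_sd_f < 0 || cfg$dispersal_sd_m < 0) {
    stop("spatial standard deviations must be non-negative")
  }
  if (cfg$philopatry_sd_f >= cfg$dispersal_sd_m) {
    stop("female philopatry requires philopatry_sd_f < dispersal_sd_m")
  }
  if (cfg$n_founders < 2L) stop("n_founders must be at least 2")
  structure(cfg, class = "sim_config")
}

new_population <- function(ped, geno, mt_hap, panel, year) {
  structure(list(ped = ped, geno = geno, mt_hap = mt_hap,
                 panel = panel, year = year),
            class = "true_population")
}

#' @export
print.true_population <- function(x, ...) {
  alive <- sum(is.na(x$ped$death_year))
  cat("true_population: year", x$year, "-", nrow(x$ped),
      "individuals ever,", alive, "alive\n")
  invisible(x)
}

#' Number of living individuals
#' @param pop a `true_population`
#' @return integer count
#' @export
n_alive <- function(pop) sum(is.na(pop$ped$death_year))

alive_ids <- function(pop) pop$ped$id[is.na(pop$ped$death_year)]

#' Initialize a founder population
#'
#' Founders receive Hardy-Weinberg genotypes at the panel's autosomal
#' frequencies, ages from the stationary age distribution implied by the
#' adult mortality rates, uniform centers on the study area, and (for the
#' matrilineal markers) founder-specific mitochondrial haplotypes.
#'
#' @param config a [sim_config()]
#' @param panel a [marker_panel()]
#' @return a `true_population`: pedigree table (`ped`), autosomal genotype
#'   matrix coded 0/1/2 alternate-allele doses (`geno`), mt haplotype ids
#'   (`mt_hap`), panel and current year.
#' @export
init_population <- function(config, panel = marker_panel()) {
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_founders
  sex <- rep(c("F", "M"), length.out = n)[sample.int(n)]
  if (!all(c("F", "M") %in% sex)) stop("founders must include both sexes")
  mort <- ifelse(sex == "F", config$adult_mortality_f, config$adult_mortality_m)
  # age = breeding_age + geometric(adult mortality), capped at 30
  age <- pmin(config$breeding_age + stats::rgeom(n, prob = pmax(mort, 0.02)), 30L)
  ids <- sprintf("I%05d", seq_len(n))
  ped <- data.frame(
    id = ids, sex = sex,
    birth_year = -age,          # year 0 is the founding instant
    death_year = NA_integer_,
    dam_id = NA_character_, sire_id = NA_character_,
    x = stats::runif(n, 0, config$area_w),
    y = stats::runif(n, 0, config$area_h),
    stringsAsFactors = FALSE
  )
  p <- panel$auto_freq
  geno <- sapply(p, function(pb) stats::rbinom(n, 2L, pb))
  if (n == 1L) geno <- matrix(geno, nrow = 1L)
  dimnames(geno) <- list(ids, panel$auto_loci)
  mt_hap <- stats::setNames(seq_len(n), ids)
  new_population(ped, geno, mt_hap, panel, year = 0L)
}

#' Mendelian offspring genotype
#'
#' One allele per autosomal locus is drawn uniformly from each parent's
#' pair. With dose coding (0/1/2 alternate alleles) each parent transmits
#' an alternate allele with probability dose/2, independently across loci.
#'
#' @param dam_g,sire_g integer vectors of parental doses (0/1/2), no NAs.
#' @param panel a [marker_panel()] (supplies the locus count).
#' @return integer vector of offspring doses.
#' @export
mendelian_offspring_genotype <- function(dam_g, sire_g, panel = NULL) {
  if (anyNA(dam_g) || anyNA(sire_g)) {
    stop("parental genotypes must be complete")
  }
  L <- length(dam_g)
  if (length(sire_g) != L) stop("parental genotypes differ in length")
  stats::rbinom(L, 1L, dam_g / 2) + stats::rbinom(L, 1L, sire_g / 2)
}

#' Advance the population by one year
#'
#' Breeding-age females litter with probability `breeding_prob`; litter
#' sizes are Poisson (mean `litter_size_mean`) truncated at 4; the sire of
#' each litter is a breeding-age male drawn with weight
#' `exp(-d^2/(2*mating_sd^2))` of his distance to the female, so males can
#' sire litters with several females. Offspring genotypes are Mendelian,
#' mitochondrial haplotypes matrilineal; daughters settle near the dam,
#' sons disperse. A single annual Bernoulli mortality per individual
#' follows breeding: cub mortality below breeding age, sex-specific adult
#' mortality from breeding age on.
#'
#' @param pop a `true_population`
#' @param config a [sim_config()]
#' @return the advanced `true_population` (attribute `extinct` flags an
#'   empty population)
#' @export
advance_year <- function(pop, config) {
  if (nrow(pop$ped) == 0L) stop("population is empty")
  year <- pop$year + 1L
  ped <- pop$ped
  alive <- is.na(ped$death_year)
  age <- year - ped$birth_year

  fem <- which(alive & ped$sex == "F" & age >= config$breeding_age)
  males <- which(alive & ped$sex == "M" & age >= config$breeding_age)

  kids <- list()
  if (length(fem) > 0L && length(males) > 0L) {
    litters <- stats::rbinom(length(fem), 1L, config$breeding_prob) == 1L
    for (fi in fem[litters]) {
      size <- min(stats::rpois(1L, config$litter_size_mean), 4L)
      if (size == 0L) next
      d2 <- (ped$x[males] - ped$x[fi])^2 + (ped$y[males] - ped$y[fi])^2
      w <- exp(-d2 / (2 * config$mating_sd^2))
      if (all(w == 0)) w <- rep(1, length(males))
      si <- males[sample.int(length(males), 1L, prob = w)]
      for (k in seq_len(size)) {
        sx <- if (stats::runif(1) < 0.5) "F" else "M"
        sd_off <- if (sx == "F") config$philopatry_sd_f else config$dispersal_sd_m
        kids[[length(kids) + 1L]] <- list(
          sex = sx,
          dam = ped$id[fi], sire = ped$id[si],
          dam_row = fi, sire_row = si,
          x = min(max(ped$x[fi] + stats::rnorm(1, 0, sd_off), 0), config$area_w),
          y = min(max(ped$y[fi] + stats::rnorm(1, 0, sd_off), 0), config$area_h)
        )
      }
    }
  }

  geno <- pop$geno
  mt_hap <- pop$mt_hap
  if (length(kids) > 0L) {
    n0 <- nrow(ped)
    new_ids <- sprintf("I%05d", n0 + seq_along(kids))
    kid_ped <- data.frame(
      id = new_ids,
      sex = vapply(kids, `[[`, "", "sex"),
      birth_year = year, death_year = NA_integer_,
      dam_id = vapply(kids, `[[`, "", "dam"),
      sire_id = vapply(kids, `[[`, "", "sire"),
      x = vapply(kids, `[[`, 0, "x"),
      y = vapply(kids, `[[`, 0, "y"),
      stringsAsFactors = FALSE
    )
    kid_geno <- t(vapply(kids, function(k) {
      mendelian_offspring_genotype(geno[k$dam_row, ], geno[k$sire_row, ])
    }, integer(ncol(geno))))
    rownames(kid_geno) <- new_ids
    ped <- rbind(ped, kid_ped)
    geno <- rbind(geno, kid_geno)
    mt_hap <- c(mt_hap,
                stats::setNames(mt_hap[vapply(kids, `[[`, "", "dam")], new_ids))
  }

  # annual mortality after breeding (newborns included)
  alive <- which(is.na(ped$death_year))
  age <- year - ped$birth_year[alive]
  p_die <- ifelse(age < config$breeding_age, config$cub_mortality,
                  ifelse(ped$sex[alive] == "F",
                         config$adult_mortality_f, config$adult_mortality_m))
  dies <- stats::runif(length(alive)) < p_die
  ped$death_year[alive[dies]] <- year

  out <- new_population(ped, geno, mt_hap, pop$panel, year)
  attr(out, "extinct") <- !any(is.na(ped$death_year))
  out
}

#' Simulate a population over several years
#'
#' Convenience driver: [init_population()] followed by `n_years` calls to
#' [advance_year()], all seeded from the master seed in `config`.
#'
#' @param config a [sim_config()]
#' @param panel a [marker_panel()]
#' @return the final `true_population`
#' @export
simulate_population <- function(config, panel = marker_panel()) {
  pop <- init_population(config, panel)
  set.seed(derive_seed(config$seed, 2L))
  for (yr in seq_len(config$n_years)) {
    pop <- advance_year(pop, config)
    if (isTRUE(attr(pop, "extinct"))) {
      warning("population went extinct in year ", pop$year)
      break
    }
  }
  pop
}

# true (error-free) call matrix for a set of individuals: 96 assay columns
true_calls <- function(pop, ids) {
  panel <- pop$panel
  g <- pop$geno[ids, , drop = FALSE]
  auto <- matrix(c("AA", "AB", "BB")[g + 1L], nrow = length(ids),
                 dimnames = list(ids, panel$auto_loci))
  sex <- pop$ped$sex[match(ids, pop$ped$id)]
  hap <- function(loci, present) {
    matrix(ifelse(rep(present, length(loci)), "1", "-"),
           nrow = length(ids), ncol = length(loci),
           dimnames = list(ids, loci))
  }
  cbind(auto,
        hap(panel$mt_loci, rep(TRUE, length(ids))),
        hap(panel$y_loci, sex == "M"),
        hap(panel$x_loci, rep(TRUE, length(ids))))
}

#' Collect noninvasive fecal samples from a population
#'
#' Each living individual contributes a zero-inflated Poisson number of
#' samples. Sample calls derive from the true genotype with independent
#' per-assay dropout (probability `dropout_prob`, call becomes missing)
#' and per-call typing error (probability `typing_error`; an erroneous
#' autosomal call is replaced by one of the two other calls uniformly, an
#' erroneous haploid presence call is flipped). Sample locations scatter
#' around the individual's center; dates fall in an autumn collection
#' season of the final simulated year.
#'
#' @param pop a `true_population`
#' @param config a [sim_config()]
#' @param seed optional override of the sampling stream seed
#' @return a `sample_set`: list with `meta` (sample_id, individual_id,
#'   date, x, y) and `calls` (character matrix, one row per sample, one
#'   column per assay; missing is "NN" autosomal, "-" haploid)
#' @export
collect_samples <- function(pop, config, seed = NULL) {
  if (nrow(pop$ped) == 0L) stop("population is empty")
  set.seed(seed %||% derive_seed(config$seed, 3L))
  ids <- alive_ids(pop)
  n_samp <- stats::rpois(length(ids), config$samples_per_individual_mean)
  n_samp[stats::runif(length(ids)) < config$sampling_zero_prob] <- 0L
  src <- rep(ids, n_samp)
  m <- length(src)
  panel <- pop$panel

  if (m == 0L) {
    return(structure(list(
      meta = data.frame(sample_id = character(), individual_id = character(),
                        date = character(), x = numeric(), y = numeric(),
                        stringsAsFactors = FALSE),
      calls = matrix(character(), 0L, length(panel_assays(panel)),
                     dimnames = list(NULL, panel_assays(panel))),
      panel = panel), class = "sample_set"))
  }

  rows <- match(src, pop$ped$id)
  meta <- data.frame(
    sample_id = sprintf("S%05d", seq_len(m)),
    individual_id = src,
    date = format(as.Date(sprintf("%04d-08-01", 2000L + pop$year)) +
                    sample.int(120L, m, replace = TRUE) - 1L),
    x = pop$ped$x[rows] + stats::rnorm(m, 0, config$sample_scatter_sd),
    y = pop$ped$y[rows] + stats::rnorm(m, 0, config$sample_scatter_sd),
    stringsAsFactors = FALSE
  )

  calls <- true_calls(pop, ids)[match(src, ids), , drop = FALSE]
  rownames(calls) <- meta$sample_id
  n_auto <- length(panel$auto_loci)
  auto <- calls[, seq_len(n_auto), drop = FALSE]
  hapl <- calls[, -seq_len(n_auto), drop = FALSE]

  # typing error first (a mis-typed call can subsequently drop out)
  err <- matrix(stats::runif(length(auto)) < config$typing_error, nrow = m)
  if (any(err)) {
    idx <- which(err)
    cur <- auto[idx]
    auto[idx] <- vapply(cur, function(cl) {
      sample(setdiff(c("AA", "AB", "BB"), cl), 1L)
    }, "")
  }
  herr <- matrix(stats::runif(length(hapl)) < config$typing_error, nrow = m)
  hapl[herr] <- ifelse(hapl[herr] == "1", "-", "1")

  # allelic dropout: assays present in the sample fail to amplify
  drop_a <- matrix(stats::runif(length(auto)) < config$dropout_prob, nrow = m)
  auto[drop_a] <- "NN"
  drop_h <- matrix(stats::runif(length(hapl)) < config$dropout_prob, nrow = m)
  hapl[drop_h & hapl == "1"] <- "-"

  calls <- cbind(auto, hapl)
  structure(list(meta = meta, calls = calls, panel = panel),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("sample_set:", nrow(x$meta), "samples from",
      length(unique(x$meta$individual_id)), "individuals\n")
  invisible(x)
}

#' Write a sample set to CSV
#'
#' Columns: sample_id, individual_id (latent truth, optional), ISO-8601
#' date, x, y, then one column per assay; missing autosomal calls are
#' "NN", missing haploid calls "-".
#'
#' @param samples a `sample_set`
#' @param path output file
#' @param truth_column keep the latent individual id column?
#' @export
write_samples_csv <- function(samples, path, truth_column = TRUE) {
  df <- cbind(samples$meta, as.data.frame(samples$calls,
                                          stringsAsFactors = FALSE))
  if (!truth_column) df$individual_id <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample set from CSV
#' @param path CSV written by [write_samples_csv()] (or equivalent)
#' @param panel the panel describing the assay columns
#' @return a `sample_set`
#' @export
read_samples_csv <- function(path, panel = marker_panel()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character"))
  assays <- panel_assays(panel)
  missing_assays <- setdiff(assays, names(df))
  if (length(missing_assays) > 0L) {
    stop("sample CSV lacks assay columns: ",
         paste(utils::head(missing_assays, 5L), collapse = ", "))
  }
  meta_cols <- intersect(c("sample_id", "individual_id", "date", "x", "y"),
                         names(df))
  meta <- df[meta_cols]
  if (is.null(meta$individual_id)) meta$individual_id <- NA_character_
  calls <- as.matrix(df[assays])
  rownames(calls) <- meta$sample_id
  structure(list(meta = meta, calls = calls, panel = panel),
            class = "sample_set")
}

#' Write the true pedigree to CSV
#' @param pop a `true_population`
#' @param path output file
#' @export
write_pedigree_csv <- function(pop, path) {
  utils::write.csv(pop$ped, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
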