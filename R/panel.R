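#' SNP marker panel
#'
#' Describes a genotyping panel of the kind used for noninvasive bear
#' monitoring: 85 autosomal biallelic SNPs for identity and kinship, plus
#' 4 mitochondrial assays (species confirmation), 4 Y-chromosome and
#' 3 X-chromosome assays (sex assignment) — 96 assays in total.
#'
#' @param auto_freq numeric vector of length 85 with the population
#'   frequency of the alternate ("B") allele at each autosomal locus;
#'   all values must lie strictly inside (0, 1). Names are used as locus
#'   ids (defaults `auto_01`..`auto_85`).
#' @param n_mt,n_y,n_x counts of mitochondrial, Y and X assays.
#' @return an object of class `marker_panel` with fields `auto_freq`,
#'   `auto_loci`, `mt_loci`, `y_loci`, `x_loci`.
#' @examples
#' pan <- marker_panel()
#' length(pan$auto_loci)  # 85
#' @export
marker_panel <- function(auto_freq = default_allele_freqs(),
                         n_mt = 4L, n_y = 4L, n_x = 3L) {
  if (length(auto_freq) != 85L) {
    stop("panel requires exactly 85 autosomal loci, got ", length(auto_freq))
  }
  if (any(auto_freq <= 0 | auto_freq >= 1)) {
    stop("allele frequencies must lie strictly inside (0, 1)")
  }
  if (is.null(names(auto_freq))) {
    names(auto_freq) <- sprintf("auto_%02d", seq_along(auto_freq))
  }
  structure(
    list(
      auto_freq = auto_freq,
      auto_loci = names(auto_freq),
      mt_loci   = sprintf("mt_%d", seq_len(n_mt)),
      y_loci    = sprintf("y_%d", seq_len(n_y)),
      x_loci    = sprintf("x_%d", seq_len(n_x))
    ),
    class = "marker_panel"
  )
}

#' Default autosomal allele frequencies
#'
#' A fixed, evenly spaced spectrum of alternate-allele frequencies on
#' (0.15, 0.85), the informative range typical of SNPs ascertained for
#' individual identification. Deterministic so that the default panel is
#' identical across sessions.
#'
#' @return named numeric vector of length 85
#' @export
default_allele_freqs <- function() {
  f <- seq(0.15, 0.85, length.out = 85)
  names(f) <- sprintf("auto_%02d", seq_along(f))
  f
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel: 85 autosomal +", length(x$mt_loci), "mtDNA +",
      length(x$y_loci), "Y +", length(x$x_loci), "X assays\n")
  invisible(x)
}

panel_assays <- function(panel) {
  c(panel$auto_loci, panel$mt_loci, panel$y_loci, panel$x_loci)
}
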