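# Synthetic phased haplotype panels around a focal derived allele.
#
# A copying/mosaic model rather than a full coalescent: every haplotype is a
# mosaic of a small founder pool (switching founders at a background
# recombination rate, with per-site mutational noise). Under a partial sweep
# (`sweep_strength` > 0) each derived-allele carrier is additionally
# overwritten with one designated "sweep founder" over an exponentially
# distributed window around the focal site whose mean length scales with
# `sweep_strength` — giving direct control of shared-haplotype length. At
# `sweep_strength = 0` derived labels are assigned to exchangeable neutral
# haplotypes, so derived and ancestral homozygosity profiles are equal in
# expectation by construction.

#' Phased haplotype matrix container
#'
#' @param haps Binary matrix, haplotypes x sites (0 ancestral, 1 derived).
#' @param positions Strictly increasing physical positions (bp, 1-based).
#' @param focal_index 1-based column index of the focal site.
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(haps, positions, focal_index) {
  haps <- as.matrix(haps)
  if (!all(haps %in% c(0L, 1L))) {
    stop("haplotype alleles must be 0/1 with no missing data", call. = FALSE)
  }
  if (length(positions) != ncol(haps)) {
    stop("`positions` must have one entry per site", call. = FALSE)
  }
  if (any(diff(positions) <= 0)) {
    stop("`positions` must be strictly increasing", call. = FALSE)
  }
  if (focal_index < 1 || focal_index > ncol(haps)) {
    stop("`focal_index` out of bounds", call. = FALSE)
  }
  structure(list(haps = haps, positions = as.numeric(positions),
                 focal_index = as.integer(focal_index),
                 focal_allele = haps[, focal_index]),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<haplotype_matrix> %d haplotypes x %d sites, focal site %d (pos %s, derived freq %.3f)\n",
    nrow(x$haps), ncol(x$haps), x$focal_index,
    format(x$positions[x$focal_index], big.mark = ","),
    mean(x$focal_allele)))
  invisible(x)
}

#' Generate a haplotype panel around a focal allele
#'
#' @param n_haps Number of haplotypes.
#' @param n_sites Number of polymorphic sites (including the focal site).
#' @param focal_index 1-based index of the focal site.
#' @param derived_freq Frequency of the derived focal allele, in (0, 1).
#' @param sweep_strength Non-negative sweep intensity; 0 gives the
#'   exchangeable neutral model, larger values lengthen the haplotype shared
#'   by derived carriers around the focal site.
#' @param seed Integer seed.
#' @param region_length Physical span of the panel in bp.
#' @param n_founders Founder pool size for the copying model.
#' @param recomb_rate Per-bp founder-switch rate.
#' @param mutation_rate Per-site allele-flip probability (noise).
#' @param sweep_scale Mean one-sided swept-window length per unit of
#'   `sweep_strength`, in bp.
#' @return A [haplotype_matrix()].
#' @export
generate_haplotypes <- function(n_haps, n_sites, focal_index = NULL,
                                derived_freq = 0.25, sweep_strength = 0,
                                seed = 1L, region_length = 4e5,
                                n_founders = 8L, recomb_rate = 1e-5,
                                mutation_rate = 0.01,
                                sweep_scale = 5e4) {
  if (is.null(focal_index)) focal_index <- ceiling(n_sites / 2)
  if (focal_index < 1 || focal_index > n_sites) {
    stop("`focal_index` out of bounds", call. = FALSE)
  }
  if (derived_freq <= 0 || derived_freq >= 1) {
    stop("`derived_freq` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (sweep_strength < 0) stop("`sweep_strength` must be >= 0", call. = FALSE)
  with_seed(seed, {
    positions <- sort(sample.int(region_length, n_sites))
    founders <- matrix(rbinom(n_founders * n_sites, 1L, 0.5),
                       n_founders, n_sites)
    gaps <- c(0, diff(positions))
    p_switch <- 1 - exp(-recomb_rate * gaps)
    haps <- matrix(0L, n_haps, n_sites)
    for (h in seq_len(n_haps)) {
      f <- sample.int(n_founders, 1L)
      row <- integer(n_sites)
      for (s in seq_len(n_sites)) {
        if (s > 1L && runif(1) < p_switch[s]) f <- sample.int(n_founders, 1L)
        row[s] <- founders[f, s]
      }
      haps[h, ] <- row
    }
    # mutational noise
    flip <- matrix(runif(n_haps * n_sites) < mutation_rate, n_haps, n_sites)
    haps[flip] <- 1L - haps[flip]

    n_derived <- max(1L, min(n_haps - 1L, round(derived_freq * n_haps)))
    derived <- sample.int(n_haps, n_derived)
    if (sweep_strength > 0) {
      sweep_founder <- founders[1L, ]
      fpos <- positions[focal_index]
      for (h in derived) {
        lwin <- rexp(1, rate = 1 / (sweep_strength * sweep_scale))
        rwin <- rexp(1, rate = 1 / (sweep_strength * sweep_scale))
        keep <- positions >= fpos - lwin & positions <= fpos + rwin
        haps[h, keep] <- sweep_founder[keep]
      }
    }
    haps[, focal_index] <- 0L
    haps[derived, focal_index] <- 1L
    haplotype_matrix(haps, positions, focal_index)
  })
}
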