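# Selection-scan statistics around a focal indel: population
# differentiation (Hudson FST, rank-normal Z scores), haplotype-based
# statistics (EHH, integrated EHH, a log2 iEHH-ratio IHS), and empirical
# placement against a matched control set of short indels.

#' Hudson FST per variant between two populations
#'
#' The Hudson estimator
#' \deqn{F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#'                     {p_1(1-p_2) + p_2(1-p_1)}}
#' computed per variant from sample allele frequencies and sizes
#' (chromosomes), clipped to \[0, 1\]. Variants monomorphic for the same
#' allele in both populations are returned as `NA`.
#'
#' @param freq_table Data frame with columns `variant`, `pop`, `freq`
#'   (alternate-allele frequency in \[0, 1\]) and `n` (chromosomes sampled).
#' @param pop_a,pop_b Population labels present in `freq_table`.
#' @return Data frame with `variant`, `fst`, and the two frequencies.
#' @export
fst_pairwise <- function(freq_table, pop_a, pop_b) {
  stopifnot(all(c("variant", "pop", "freq", "n") %in% names(freq_table)))
  for (p in c(pop_a, pop_b)) {
    if (!p %in% freq_table$pop) {
      stop(sprintf("population '%s' not present in the frequency table", p),
           call. = FALSE)
    }
  }
  a <- freq_table[freq_table$pop == pop_a, ]
  b <- freq_table[freq_table$pop == pop_b, ]
  m <- merge(a, b, by = "variant", suffixes = c("_a", "_b"))
  if (any(m$freq_a < 0 | m$freq_a > 1 | m$freq_b < 0 | m$freq_b > 1) ||
      any(m$n_a < 1 | m$n_b < 1)) {
    stop("frequencies must lie in [0, 1] and sample sizes be >= 1",
         call. = FALSE)
  }
  p1 <- m$freq_a; p2 <- m$freq_b; n1 <- m$n_a; n2 <- m$n_b
  num <- (p1 - p2)^2 - p1 * (1 - p1) / pmax(n1 - 1, 1) -
    p2 * (1 - p2) / pmax(n2 - 1, 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(den > 0, pmin(pmax(num / den, 0), 1), NA_real_)
  data.frame(variant = m$variant, fst = fst, freq_a = p1, freq_b = p2,
             stringsAsFactors = FALSE)
}

#' Inverse-normal rank Z scores
#'
#' Values are ranked (average ranks for ties) and mapped through
#' `qnorm((rank - 0.5) / N)`, giving approximately standard-normal scores
#' that are invariant to any strictly monotone transform of the input.
#'
#' @param values Numeric vector with at least 2 finite values; `NA`s are
#'   passed through as `NA`.
#' @return Numeric vector of Z scores.
#' @export
rank_normal_z <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2L) stop("need at least 2 finite values", call. = FALSE)
  out <- rep(NA_real_, length(values))
  v <- values[ok]
  if (length(unique(v)) == 1L) {
    out[ok] <- 0
    return(out)
  }
  r <- rank(v, ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / length(v))
  out
}

# ---- EHH --------------------------------------------------------------

#' Extended haplotype homozygosity around the focal site
#'
#' For the carriers of one focal-allele class, EHH at a flanking site x is
#' the probability that two distinct carriers drawn at random are identical
#' over every site from the focal site out to x:
#' \deqn{EHH(x) = \sum_h n_h (n_h - 1) / (n_c (n_c - 1))}
#' where the sum runs over distinct extended haplotypes with multiplicities
#' `n_h` among the `n_c` carriers. Computed separately leftward and
#' rightward of the focal site.
#'
#' @param haps A [haplotype_matrix()].
#' @param allele_class `"derived"` (focal allele 1) or `"ancestral"` (0).
#' @return An object of class `ehh_profile`: a data frame with columns
#'   `side` (`"left"`/`"right"`), `pos`, `distance` (bp from the focal
#'   site, 0 at the focal site itself where EHH = 1) and `ehh`; attributes
#'   `allele_class` and `n_carriers`.
#' @export
ehh <- function(haps, allele_class = c("derived", "ancestral")) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  allele_class <- match.arg(allele_class)
  want <- if (allele_class == "derived") 1L else 0L
  carriers <- which(haps$focal_allele == want)
  nc <- length(carriers)
  if (nc < 2L) {
    stop(sprintf("EHH undefined: fewer than 2 %s carriers", allele_class),
         call. = FALSE)
  }
  h <- haps$haps[carriers, , drop = FALSE]
  fi <- haps$focal_index
  fpos <- haps$positions[fi]
  one_side <- function(idx, side) {
    if (length(idx) == 0L) {
      return(data.frame(side = character(0L), pos = numeric(0L),
                        distance = numeric(0L), ehh = numeric(0L)))
    }
    grp <- rep(1L, nc) # all carriers share the focal allele at distance 0
    vals <- numeric(length(idx))
    for (i in seq_along(idx)) {
      s <- idx[i]
      # refine the partition by the allele at the next site outward
      grp <- as.integer(factor(paste(grp, h[, s])))
      tab <- tabulate(grp)
      vals[i] <- sum(tab * (tab - 1)) / (nc * (nc - 1))
    }
    data.frame(side = side, pos = haps$positions[idx],
               distance = abs(haps$positions[idx] - fpos), ehh = vals,
               stringsAsFactors = FALSE)
  }
  left <- one_side(rev(seq_len(fi - 1L)), "left")
  right <- one_side(seq_len(ncol(h))[-seq_len(fi)], "right")
  focal <- data.frame(side = "focal", pos = fpos, distance = 0, ehh = 1,
                      stringsAsFactors = FALSE)
  out <- rbind(focal, left, right)
  structure(out, allele_class = allele_class, n_carriers = nc,
            class = c("ehh_profile", "data.frame"))
}

#' Integrated EHH
#'
#' Trapezoidal integration of the EHH decay curve over physical distance,
#' each direction truncated exactly where the (linearly interpolated) curve
#' first drops below `threshold`; the two directional integrals are summed.
#' If EHH never drops below the threshold before the last site, integration
#' stops at the last site and the result is flagged unbounded.
#'
#' @param profile An [ehh()] result.
#' @param threshold Truncation level (default 0.05).
#' @return A numeric scalar (bp) with attribute `unbounded` (logical: did
#'   either flank end above the threshold?).
#' @export
iehh <- function(profile, threshold = 0.05) {
  stopifnot(inherits(profile, "ehh_profile"))
  unbounded <- FALSE
  side_integral <- function(side) {
    p <- profile[profile$side == side, ]
    if (nrow(p) == 0L) return(0)
    d <- c(0, p$distance)
    e <- c(1, p$ehh)
    total <- 0
    for (i in seq_len(length(d) - 1L)) {
      e0 <- e[i]; e1 <- e[i + 1L]
      if (e0 < threshold) break
      if (e1 >= threshold) {
        total <- total + (d[i + 1L] - d[i]) * (e0 + e1) / 2
      } else {
        # linear crossing point of the threshold inside this segment
        frac <- (e0 - threshold) / (e0 - e1)
        total <- total + frac * (d[i + 1L] - d[i]) * (e0 + threshold) / 2
        return(total)
      }
    }
    if (e[length(e)] >= threshold) unbounded <<- TRUE
    total
  }
  out <- side_integral("left") + side_integral("right")
  attr(out, "unbounded") <- unbounded
  out
}

#' Integrated haplotype statistic (log2 iEHH ratio)
#'
#' `IHS = log2(iEHH_derived / iEHH_ancestral)` — the plain log ratio, not
#' the standardized frequency-binned iHS of the wider selection-scan
#' literature.
#'
#' @param iehh_derived,iehh_ancestral Positive iEHH values.
#' @return Numeric scalar.
#' @export
ihs <- function(iehh_derived, iehh_ancestral) {
  if (any(c(iehh_derived, iehh_ancestral) <= 0)) {
    stop("iEHH inputs must be > 0", call. = FALSE)
  }
  log2(as.numeric(iehh_derived) / as.numeric(iehh_ancestral))
}

#' EHH/iEHH/IHS scan at a focal site
#'
#' Convenience wrapper computing both allele-class profiles, their iEHH
#' integrals and the IHS at the focal site of a haplotype panel.
#'
#' @param haps A [haplotype_matrix()].
#' @param threshold iEHH truncation threshold.
#' @return List with `derived`, `ancestral` (profiles), `iehh_derived`,
#'   `iehh_ancestral`, `ihs`.
#' @export
ehh_scan <- function(haps, threshold = 0.05) {
  d <- ehh(haps, "derived")
  a <- ehh(haps, "ancestral")
  id <- iehh(d, threshold)
  ia <- iehh(a, threshold)
  list(derived = d, ancestral = a,
       iehh_derived = as.numeric(id), iehh_ancestral = as.numeric(ia),
       ihs = ihs(as.numeric(id), as.numeric(ia)))
}

# ---- control set and empirical placement ------------------------------

#' Select a frequency-matched short-indel control set
#'
#' Keeps autosomal indels of bounded length segregating within a frequency
#' band around a target (default 25% +/- 5%), excluding the focal variant —
#' the null cohort against which the focal variant's statistics are placed.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `freq`; indel status and length are derived from `ref`/`alt`.
#' @param target_freq,tolerance Frequency band `[target - tol, target + tol]`.
#' @param max_len Maximum indel length in bp (default 2).
#' @param autosomes Chromosomes considered autosomal.
#' @param exclude_pos Optional `chrom:pos` pairs (data frame) to drop, e.g.
#'   the focal variant itself.
#' @return The filtered subset of `variants` with an added `indel_len`
#'   column; zero rows (with a warning) if nothing passes.
#' @export
select_control_set <- function(variants, target_freq = 0.25,
                               tolerance = 0.05, max_len = 2,
                               autosomes = c("2L", "2R", "3L", "3R"),
                               exclude_pos = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "freq") %in% names(variants)))
  len <- abs(nchar(variants$alt) - nchar(variants$ref))
  keep <- len >= 1 & len <= max_len &
    variants$chrom %in% autosomes &
    variants$freq >= target_freq - tolerance &
    variants$freq <= target_freq + tolerance
  if (!is.null(exclude_pos)) {
    keep <- keep & !(paste(variants$chrom, variants$pos) %in%
                       paste(exclude_pos$chrom, exclude_pos$pos))
  }
  out <- variants[keep, , drop = FALSE]
  out$indel_len <- len[keep]
  if (nrow(out) == 0L) warning("control set is empty")
  rownames(out) <- NULL
  out
}

#' Empirical percentile and two-sided p against a control distribution
#'
#' @param stat_value Observed statistic at the focal variant.
#' @param control_values Statistic values over the control set.
#' @return List with `percentile` (100 x proportion of controls <= stat)
#'   and `p_value` (2 x the smaller tail proportion, capped at 1 and
#'   floored at `1/(N + 1)`).
#' @export
empirical_percentile <- function(stat_value, control_values) {
  control_values <- control_values[is.finite(control_values)]
  n <- length(control_values)
  if (n == 0L) stop("no finite control values", call. = FALSE)
  lower <- mean(control_values <= stat_value)
  upper <- mean(control_values >= stat_value)
  p <- min(1, 2 * min(lower, upper))
  p <- max(p, 1 / (n + 1))
  list(percentile = 100 * lower, p_value = p, n_controls = n)
}
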