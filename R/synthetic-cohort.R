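# Synthetic inbred-line cohort with a planted causal indel.
#
# Emulates a panel of near-fully homozygous wild-derived lines crossed to a
# deficiency stock: lines are homozygous at almost all calls, with a small
# residual of heterozygous and missing calls so the hemizygosity remapping
# rules are exercised. The phenotype is an ON-percentage in [0, 100]
# generated on the logit scale from the causal allele plus Gaussian noise.

#' Generate an inbred-line cohort with a planted causal variant
#'
#' @param n_lines Number of lines (203 matches the full wild-derived panel
#'   scale; tests use fewer).
#' @param n_variants Number of variants on one chromosome arm.
#' @param causal_index 1-based index of the causal variant; must fall inside
#'   `deficiency`.
#' @param effect_size Effect of carrying the causal alternate allele, in
#'   logit units of the ON proportion (negative lowers %ON).
#' @param deficiency A [deficiency_interval()]; defaults to a ~200 kb
#'   interval on chromosome arm 3R.
#' @param seed Integer seed.
#' @param het_rate,missing_rate Residual heterozygous / missing call rates
#'   (defaults 2% and 1%: inbred but imperfect).
#' @param baseline Intercept on the logit scale (default `qlogis(0.65)`).
#' @param noise_sd Line-level Gaussian noise SD on the logit scale.
#' @param n_subpops Number of equally sized subpopulations; with more than
#'   one, per-subpopulation allele frequencies are drawn from a
#'   Balding-Nichols model so the relationship-matrix PCs have structure to
#'   find.
#' @param subpop_fst Balding-Nichols differentiation parameter.
#' @return A list with `genotypes` (a [genotype_matrix()]), `phenotypes`
#'   (data frame `line_id`, `pct_on`), `deficiency`, and `truth` (causal
#'   index, effect size, carrier status, subpopulation labels).
#' @export
generate_cross_cohort <- function(n_lines, n_variants, causal_index,
                                  effect_size,
                                  deficiency = deficiency_interval(
                                    "3R", 16.2e6, 16.4e6),
                                  seed = 1L,
                                  het_rate = 0.02, missing_rate = 0.01,
                                  baseline = stats::qlogis(0.65),
                                  noise_sd = 0.4,
                                  n_subpops = 1L, subpop_fst = 0.1) {
  if (causal_index < 1 || causal_index > n_variants) {
    stop("`causal_index` must be within 1..n_variants", call. = FALSE)
  }
  with_seed(seed, {
    # positions: causal inside the deficiency, the rest spread around it so
    # the sorted position rank of the causal variant equals causal_index
    span <- deficiency$end - deficiency$start
    causal_pos <- round(runif(1, deficiency$start + 1, deficiency$end - 1))
    left <- sort(round(runif(causal_index - 1,
                             deficiency$start - 2 * span, causal_pos - 1)))
    right <- sort(round(runif(n_variants - causal_index,
                              causal_pos + 1, deficiency$end + 2 * span)))
    pos <- c(left, causal_pos, right)
    pos <- pos + cumsum(c(0, diff(pos) == 0)) # break rare ties
    causal_pos <- pos[causal_index]
    is_indel <- runif(n_variants) < 0.3
    is_indel[causal_index] <- TRUE # the planted causal variant is an indel
    ref <- sample(c("A", "C", "G", "T"), n_variants, replace = TRUE)
    alt <- ifelse(is_indel, paste0(ref, "C"),
                  vapply(ref, function(b) {
                    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
                  }, character(1L)))
    variants <- data.frame(chrom = deficiency$chrom, pos = pos,
                           ref = ref, alt = alt, is_indel = is_indel,
                           stringsAsFactors = FALSE)

    # ancestral allele frequencies; optional Balding-Nichols subpopulations
    p_anc <- runif(n_variants, 0.1, 0.9)
    subpop <- rep_len(seq_len(n_subpops), n_lines)
    pmat <- matrix(p_anc, n_subpops, n_variants, byrow = TRUE)
    if (n_subpops > 1L && subpop_fst > 0) {
      a <- p_anc * (1 - subpop_fst) / subpop_fst
      b <- (1 - p_anc) * (1 - subpop_fst) / subpop_fst
      for (s in seq_len(n_subpops)) {
        pmat[s, ] <- stats::rbeta(n_variants, a, b)
      }
    }
    # inbred lines: homozygous alt with the line's subpopulation frequency
    calls <- matrix(0L, n_lines, n_variants)
    for (s in seq_len(n_subpops)) {
      rows <- which(subpop == s)
      calls[rows, ] <- 2L * matrix(
        runif(length(rows) * n_variants) <
          matrix(pmat[s, ], length(rows), n_variants, byrow = TRUE),
        length(rows), n_variants)
    }
    carrier <- calls[, causal_index] == 2L
    # residual heterozygosity / missingness (never on the causal column, so
    # the planted truth stays exactly known)
    mask <- matrix(runif(n_lines * n_variants), n_lines, n_variants)
    mask[, causal_index] <- 1
    calls[mask < het_rate] <- 1L
    calls[mask >= het_rate & mask < het_rate + missing_rate] <- NA

    lines <- sprintf("line_%03d", seq_len(n_lines))
    gm <- genotype_matrix(variants, lines, calls)

    logit <- baseline + effect_size * as.numeric(carrier) +
      rnorm(n_lines, 0, noise_sd)
    pct_on <- 100 * stats::plogis(logit)
    list(genotypes = gm,
         phenotypes = data.frame(line_id = lines, pct_on = pct_on,
                                 stringsAsFactors = FALSE),
         deficiency = deficiency,
         truth = list(causal_index = causal_index, causal_pos = causal_pos,
                      effect_size = effect_size, carrier = carrier,
                      subpop = subpop))
  })
}
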