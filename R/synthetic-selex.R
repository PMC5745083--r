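# Synthetic SELEX-seq style read sets.
#
# Cycle 0 is uniform random sequence; each later selection cycle resamples
# reads with probability proportional to a Boltzmann weight of the best PWM
# log-odds score on either strand. This is a deliberately simple generative
# stand-in for iterated protein binding + amplification: enrichment of
# high-affinity k-mers grows monotonically with cycle in expectation, with
# `temperature` tuning the selection stringency.

#' Generate SELEX-seq style read sets across selection cycles
#'
#' @param pwm A [pwm()] describing the binding preference under selection.
#' @param n_reads Reads per cycle.
#' @param read_length Read length (must be at least the PWM width).
#' @param n_cycles Number of selection cycles (>= 1); cycle 0 is also
#'   returned.
#' @param temperature Boltzmann temperature in bits; lower = stricter
#'   selection. Default 2.
#' @param seed Integer seed.
#' @param embed_site Optional site sequence planted verbatim into a fraction
#'   `embed_freq` of cycle-0 reads (for containment-count calibration).
#' @param embed_freq Fraction of cycle-0 reads receiving `embed_site`.
#' @return A list of character vectors of reads, one per cycle, named
#'   `"cycle0"` ... `"cycleN"`.
#' @export
generate_selex_reads <- function(pwm, n_reads, read_length, n_cycles,
                                 temperature = 2, seed = 1L,
                                 embed_site = NULL, embed_freq = 0) {
  stopifnot(inherits(pwm, "pwm"))
  w <- ncol(pwm$mat)
  if (read_length < w) {
    stop("`read_length` must be at least the PWM width", call. = FALSE)
  }
  if (n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  if (temperature <= 0) stop("`temperature` must be > 0", call. = FALSE)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    mat <- matrix(sample(bases, n_reads * read_length, replace = TRUE),
                  n_reads, read_length)
    reads <- apply(mat, 1L, paste, collapse = "")
    if (!is.null(embed_site) && embed_freq > 0) {
      stopifnot(nchar(embed_site) <= read_length)
      pick <- runif(n_reads) < embed_freq
      at <- sample.int(read_length - nchar(embed_site) + 1L, sum(pick),
                       replace = TRUE)
      substr(reads[pick], at, at + nchar(embed_site) - 1L) <- embed_site
    }
    out <- vector("list", n_cycles + 1L)
    out[[1L]] <- reads
    for (cyc in seq_len(n_cycles)) {
      sc <- pwm_score_reads(pwm, reads)
      wgt <- exp((sc - max(sc)) / temperature)
      reads <- reads[sample.int(n_reads, n_reads, replace = TRUE,
                                prob = wgt)]
      out[[cyc + 1L]] <- reads
    }
    names(out) <- paste0("cycle", 0:n_cycles)
    out
  })
}
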