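# Preference-index statistics for two-choice green/blue phototaxis trials.

#' Preference index of a trial
#'
#' `PI = (N_G - N_B) / (N_G + N_B)`: +1 is pure green preference, -1 pure
#' blue. Vectorised over trials.
#'
#' @param n_green,n_blue Non-negative fly counts with positive totals.
#' @return Numeric vector of PIs in \[-1, 1\].
#' @export
preference_index <- function(n_green, n_blue) {
  if (any(n_green < 0 | n_blue < 0)) {
    stop("fly counts must be non-negative", call. = FALSE)
  }
  tot <- n_green + n_blue
  if (any(tot == 0)) {
    stop("unscorable trial: no flies chose either side", call. = FALSE)
  }
  (n_green - n_blue) / tot
}

#' Per-line mean preference index
#'
#' The per-line statistic is the arithmetic mean of per-trial PIs (not the
#' PI of pooled counts), with SEM = SD / sqrt(n_trials) across trials.
#' Warns below the conventional floor of 5 trials per genotype.
#'
#' @param trials Data frame with columns `n_green`, `n_blue` (one row per
#'   trial for a single line).
#' @return List with `mean_pi`, `sem`, `n_trials`.
#' @export
line_mean_pi <- function(trials) {
  stopifnot(all(c("n_green", "n_blue") %in% names(trials)))
  if (nrow(trials) == 0L) stop("no scorable trials", call. = FALSE)
  pis <- preference_index(trials$n_green, trials$n_blue)
  n <- length(pis)
  if (n < 5L) warning("fewer than 5 trials for this line")
  list(mean_pi = mean(pis),
       sem = if (n > 1L) sd(pis) / sqrt(n) else NA_real_,
       n_trials = n)
}

#' Compare mean preference indices between two groups of lines
#'
#' Welch's unequal-variance two-sample t-test on per-line mean PIs.
#'
#' @param pi_group_a,pi_group_b Numeric vectors of per-line mean PIs
#'   (at least 2 lines each).
#' @return List with `mean_a`, `mean_b`, `difference` (a - b), `p_value`,
#'   `t`, `df`.
#' @export
group_compare <- function(pi_group_a, pi_group_b) {
  if (length(pi_group_a) < 2L || length(pi_group_b) < 2L) {
    stop("need at least 2 lines per group", call. = FALSE)
  }
  tt <- t.test(pi_group_a, pi_group_b, var.equal = FALSE)
  list(mean_a = mean(pi_group_a), mean_b = mean(pi_group_b),
       difference = mean(pi_group_a) - mean(pi_group_b),
       p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter))
}
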