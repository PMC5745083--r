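# Synthetic two-choice phototaxis trials.

#' Generate T-maze trial counts
#'
#' Each trial releases `n_flies` flies into a green/blue choice; the number
#' choosing the green arm is Binomial(`n_flies`, `green_prob`) and the rest
#' choose blue. The default of 100 flies per trial matches the standard
#' protocol scale.
#'
#' @param n_trials Number of trials.
#' @param n_flies Flies per trial (> 0).
#' @param green_prob Per-fly probability of choosing green, in \[0, 1\].
#' @param seed Integer seed.
#' @param line_id,genotype Optional labels copied into every row.
#' @return Data frame with columns `line_id`, `genotype`, `trial`,
#'   `n_green`, `n_blue`.
#' @export
generate_tmaze_trials <- function(n_trials, n_flies = 100L, green_prob = 0.5,
                                  seed = 1L, line_id = "line_1",
                                  genotype = "no_sin") {
  stopifnot_scalar_prob(green_prob, "green_prob")
  if (n_flies <= 0) stop("`n_flies` must be > 0", call. = FALSE)
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  with_seed(seed, {
    ng <- rbinom(n_trials, n_flies, green_prob)
    data.frame(line_id = line_id, genotype = genotype,
               trial = seq_len(n_trials),
               n_green = ng, n_blue = n_flies - ng,
               stringsAsFactors = FALSE)
  })
}
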