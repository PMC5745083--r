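# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so every generator is a pure function of its arguments.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a master seed, staying < 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483647
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over the alphabet A, C, G, T, N.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("CGCCCACACC")  # "GGTGTGGGCG"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE))
}

# Fast reverse complement for many equal-length strings (used in hot paths).
revcomp_fast <- function(x) {
  if (length(x) == 0L) return(character(0L))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
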