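# Position weight matrices: construction from oriented k-mers and log-odds
# scoring. A PWM summarises per-position base preferences and assumes
# positional independence — exactly the assumption the positional-dependence
# analysis (see positional_dependence()) interrogates.

DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' @param mat 4 x width numeric matrix of base frequencies, rows named
#'   A, C, G, T; every column must sum to 1 (within 1e-9).
#' @return An object of class `pwm` with the frequency matrix and the
#'   per-column information content (2 - Shannon entropy, bits).
#' @export
pwm <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)", call. = FALSE)
  rownames(mat) <- DNA_BASES
  if (any(mat < 0)) stop("PWM frequencies must be >= 0", call. = FALSE)
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9)) {
    stop("every PWM column must sum to 1", call. = FALSE)
  }
  ic <- apply(mat, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  structure(list(mat = mat, info = ic), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, total information %.2f bits\n",
              ncol(x$mat), sum(x$info)))
  print(round(x$mat, 3))
  invisible(x)
}

#' Build a PWM from consensus-oriented k-mers
#'
#' Column frequencies are count-weighted base proportions with an optional
#' pseudocount added per base per column.
#'
#' @param kmers Character vector of equal-length, consensus-oriented k-mers.
#' @param counts Positive weights, one per k-mer (default all 1).
#' @param pseudocount Added to every base count in every column (default 0).
#' @return A [pwm()].
#' @export
build_pwm <- function(kmers, counts = rep(1, length(kmers)),
                      pseudocount = 0) {
  if (length(kmers) == 0L) stop("no k-mers supplied", call. = FALSE)
  w <- unique(nchar(kmers))
  if (length(w) != 1L) stop("k-mers must all have the same length",
                            call. = FALSE)
  stopifnot(length(counts) == length(kmers), all(counts > 0),
            pseudocount >= 0)
  chars <- matrix(unlist(strsplit(kmers, "", fixed = TRUE)),
                  nrow = length(kmers), byrow = TRUE)
  mat <- vapply(seq_len(w), function(j) {
    cnt <- vapply(DNA_BASES, function(b) {
      sum(counts[chars[, j] == b])
    }, numeric(1L)) + pseudocount
    cnt / sum(cnt)
  }, numeric(4L))
  pwm(mat)
}

#' Consensus sequence of a PWM
#'
#' @param x A [pwm()].
#' @return Character scalar: the per-column argmax base (ties: first of
#'   A, C, G, T).
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$mat, 2L, which.max)], collapse = "")
}

# log2-odds score matrix against a uniform background, with pseudocounted
# frequencies so zero-frequency cells stay finite.
pwm_logodds <- function(x, pseudocount = 1e-3) {
  f <- sweep(x$mat + pseudocount, 2L, colSums(x$mat + pseudocount), "/")
  log2(f / 0.25)
}

#' Best PWM log-odds score within a sequence (both strands)
#'
#' Scans every window of both the sequence and its reverse complement and
#' returns the maximal log2-odds score against a uniform background.
#'
#' @param x A [pwm()].
#' @param sequence A single DNA string at least as long as the PWM width.
#' @param pseudocount Frequency pseudocount used to keep log-odds finite.
#' @return A list with `score` (bits), `position` (1-based window start on
#'   the forward strand) and `strand` (`"+"` or `"-"`).
#' @export
pwm_score <- function(x, sequence, pseudocount = 1e-3) {
  stopifnot(inherits(x, "pwm"), is.character(sequence),
            length(sequence) == 1L)
  w <- ncol(x$mat)
  n <- nchar(sequence)
  if (n < w) stop("sequence is shorter than the PWM width", call. = FALSE)
  lo <- pwm_logodds(x, pseudocount)
  score_strand <- function(seq) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    idx <- match(ch, DNA_BASES)
    vapply(seq_len(n - w + 1L), function(s) {
      b <- idx[s:(s + w - 1L)]
      if (anyNA(b)) return(-Inf)
      sum(lo[cbind(b, seq_len(w))])
    }, numeric(1L))
  }
  fwd <- score_strand(sequence)
  rev <- score_strand(revcomp(sequence))
  if (max(fwd) >= max(rev)) {
    list(score = max(fwd), position = which.max(fwd), strand = "+")
  } else {
    # window position reported on the forward strand
    p <- which.max(rev)
    list(score = max(rev), position = n - w + 2L - p, strand = "-")
  }
}

# Vectorised best-score-per-read (max over windows and strands) for
# equal-length reads; used by the SELEX read generator.
pwm_score_reads <- function(x, reads, pseudocount = 1e-3) {
  w <- ncol(x$mat)
  lo <- pwm_logodds(x, pseudocount)
  n <- unique(nchar(reads))
  stopifnot(length(n) == 1L, n >= w)
  enc <- function(strings) {
    m <- matrix(match(unlist(strsplit(strings, "", fixed = TRUE)),
                      DNA_BASES), nrow = length(strings), byrow = TRUE)
    m
  }
  best_for <- function(m) {
    best <- rep(-Inf, nrow(m))
    for (s in seq_len(n - w + 1L)) {
      sc <- rep(0, nrow(m))
      for (j in seq_len(w)) sc <- sc + lo[cbind(m[, s + j - 1L], j)]
      best <- pmax(best, sc)
    }
    best
  }
  pmax(best_for(enc(reads)), best_for(enc(revcomp_fast(reads))))
}
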