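# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own optimized code paths.

# string reverse complement, character by character
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# all k-mers over ACGT
oracle_all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

# canonical form by explicit string comparison
oracle_canonical <- function(kmers) {
  rc <- oracle_revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# naive window-by-window canonical k-mer count of a read set
oracle_kmer_counts <- function(reads, k) {
  out <- character(0L)
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (s in seq_len(n - k + 1L)) {
      w <- substr(r, s, s + k - 1L)
      if (grepl("[^ACGT]", w)) next
      out <- c(out, oracle_canonical(w))
    }
  }
  table(out)
}

# EHH by explicit substring enumeration and ordered-pair counting
oracle_ehh_at <- function(h, focal, x) {
  # h: carriers x sites 0/1 matrix; homozygosity of the substring spanning
  # focal..x (either direction), counting ordered pairs of identical rows
  rng <- if (x >= focal) focal:x else x:focal
  key <- apply(h[, rng, drop = FALSE], 1L, paste, collapse = "")
  tab <- table(key)
  nc <- nrow(h)
  sum(tab * (tab - 1)) / (nc * (nc - 1))
}

# naive best log2-odds PWM scan over both strands
oracle_pwm_best <- function(mat, seq, pseudocount = 1e-3) {
  f <- sweep(mat + pseudocount, 2L, colSums(mat + pseudocount), "/")
  lo <- log2(f / 0.25)
  score_one <- function(s) {
    w <- ncol(lo)
    n <- nchar(s)
    best <- -Inf
    for (i in seq_len(n - w + 1L)) {
      ch <- strsplit(substr(s, i, i + w - 1L), "", fixed = TRUE)[[1L]]
      idx <- match(ch, c("A", "C", "G", "T"))
      best <- max(best, sum(lo[cbind(idx, seq_len(w))]))
    }
    best
  }
  max(score_one(seq), score_one(oracle_revcomp(seq)))
}

# hand OLS t statistic for simple regression y ~ x
oracle_simple_t <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  b / se
}
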