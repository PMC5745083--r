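# Canonical k-mer counting and binding-site statistics for SELEX-seq style
# read sets.
#
# Two distinct orientation conventions coexist and are tagged on every
# k-mer table:
#   * "lexmin"    — counting convention: each window is keyed by the
#                   lexicographic minimum of the k-mer and its reverse
#                   complement, so both strands collapse onto one key;
#   * "consensus" — reporting convention: k-mers are reverse complemented
#                   as needed to minimise Hamming distance to a consensus.
# Conflating the two corrupts counts, so they are kept explicit.

# ---- encoding helpers -------------------------------------------------

# decode base-4 integer codes (A=0 C=1 G=2 T=3) to k-mer strings
decode_kmer <- function(codes, k) {
  if (length(codes) == 0L) return(character(0L))
  m <- matrix("", length(codes), k)
  rem <- codes
  for (j in k:1) {
    m[, j] <- DNA_BASES[(rem %% 4) + 1L]
    rem <- rem %/% 4
  }
  do.call(paste0, split(m, col(m)))
}

encode_kmer <- function(kmers) {
  k <- unique(nchar(kmers))
  stopifnot(length(k) == 1L)
  chars <- matrix(match(unlist(strsplit(kmers, "", fixed = TRUE)),
                        DNA_BASES) - 1L,
                  nrow = length(kmers), byrow = TRUE)
  as.numeric(chars %*% 4^((k - 1):0))
}

# canonical (lexicographic-minimum) form of k-mer strings
canonical_kmer <- function(kmers) {
  rc <- revcomp_fast(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Size of the canonical k-mer universe
#'
#' For even k, the number of distinct canonical k-mers is
#' `(4^k + 4^(k/2)) / 2`: reverse-complement palindromes (of which there are
#' `4^(k/2)`) are their own canonical form, all other k-mers pair up.
#'
#' @param k Even k-mer length.
#' @return Number of distinct canonical k-mers.
#' @examples
#' canonical_universe_size(10) # 524800
#' @export
canonical_universe_size <- function(k) {
  if (any(k %% 2 != 0)) {
    stop("only even k supported (odd k has no reverse-complement palindromes; ",
         "the universe convention here is defined for even k)", call. = FALSE)
  }
  (4^k + 4^(k / 2)) / 2
}

# ---- k-mer tables -----------------------------------------------------

#' Count canonical k-mers in a read set
#'
#' Every length-k window of every read is counted once under
#' lexicographic-minimum canonicalization (the smaller of the k-mer and its
#' reverse complement). Windows containing non-ACGT characters are skipped.
#'
#' @param reads Character vector of reads over A, C, G, T, N.
#' @param k K-mer length (1..15).
#' @param cycle Optional label recording which selection cycle the reads
#'   came from.
#' @return An object of class `kmer_table`: a data frame with columns
#'   `kmer` and `count`, sorted by decreasing count, with attributes `k`,
#'   `cycle`, `orientation = "lexmin"` and `n_windows` (total windows
#'   counted).
#' @export
canonical_kmer_counts <- function(reads, k, cycle = NA) {
  stopifnot(is.character(reads), k >= 1)
  if (all(nchar(reads) < k)) {
    warning("k exceeds every read length; returning an empty table")
    codes <- numeric(0L)
  } else {
    codes <- .cpp_canonical_codes(reads, as.integer(k))
  }
  tab <- sort(table(codes), decreasing = TRUE)
  df <- data.frame(kmer = decode_kmer(as.numeric(names(tab)), k),
                   count = as.integer(tab), stringsAsFactors = FALSE)
  structure(df, k = as.integer(k), cycle = cycle, orientation = "lexmin",
            n_windows = length(codes),
            class = c("kmer_table", "data.frame"))
}

#' Merge canonical k-mer tables by adding counts
#'
#' @param ... `kmer_table` objects (or a single list of them) produced with
#'   the same k. Counting is associative, so the merge is invariant to
#'   order.
#' @return A merged `kmer_table` with `cycle = "merged"`.
#' @export
merge_kmer_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1L]], "kmer_table")) {
    tabs <- tabs[[1L]]
  }
  stopifnot(length(tabs) >= 1L,
            all(vapply(tabs, inherits, logical(1L), "kmer_table")))
  k <- unique(vapply(tabs, attr, integer(1L), "k"))
  stopifnot(length(k) == 1L)
  all_counts <- do.call(rbind, lapply(tabs, function(t) t[c("kmer", "count")]))
  agg <- stats::aggregate(count ~ kmer, data = all_counts, FUN = sum)
  agg <- agg[order(-agg$count, agg$kmer), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, k = k, cycle = "merged", orientation = "lexmin",
            n_windows = sum(vapply(tabs, attr, numeric(1L), "n_windows")),
            class = c("kmer_table", "data.frame"))
}

# canonical count of one or more query k-mers (0 when absent)
kmer_count_of <- function(table, kmers) {
  stopifnot(inherits(table, "kmer_table"))
  key <- canonical_kmer(toupper(kmers))
  out <- table$count[match(key, table$kmer)]
  out[is.na(out)] <- 0L
  out
}

# ---- orientation ------------------------------------------------------

#' Orient k-mers toward a consensus
#'
#' Returns each k-mer or its reverse complement, whichever has the smaller
#' Hamming distance to `consensus`; ties keep the forward orientation.
#'
#' @param kmer Character vector of k-mers.
#' @param consensus Consensus sequence of the same length.
#' @return Character vector of oriented k-mers.
#' @export
consensus_orient <- function(kmer, consensus) {
  stopifnot(is.character(kmer), is.character(consensus),
            length(consensus) == 1L)
  if (any(nchar(kmer) != nchar(consensus))) {
    stop("k-mer and consensus lengths differ", call. = FALSE)
  }
  hamming <- function(a, b) {
    mapply(function(x, y) {
      sum(strsplit(x, "", fixed = TRUE)[[1L]] !=
            strsplit(y, "", fixed = TRUE)[[1L]])
    }, a, b, USE.NAMES = FALSE)
  }
  rc <- revcomp_fast(kmer)
  ifelse(hamming(kmer, consensus) <= hamming(rc, consensus), kmer, rc)
}

# ---- read-level site counts ------------------------------------------

#' The focal regulatory binding sites
#'
#' The four 10-/12-mer sequences at the heart of the affinity analysis: the
#' endogenous core site without the single-base insertion, the same core
#' with it, the PWM-optimal core, and the extended endogenous context.
#'
#' @return A list with elements `without_sin`, `with_sin`, `optimal`,
#'   `extended`.
#' @export
binding_site_set <- function() {
  list(without_sin = "CGCCCACACA",
       with_sin = "CGCCCACACC",
       optimal = "CGCCCACGCA",
       extended = "ACGCCCACACAC")
}

#' Count reads containing each binding site
#'
#' Substring containment is tested on both strands of every read; the four
#' counts partition the read set.
#'
#' @param reads Character vector of reads.
#' @param sites A list with `with_sin` and `without_sin` site sequences
#'   (default [binding_site_set()]).
#' @return A list of class `site_read_counts` with `n_with_only`,
#'   `n_without_only`, `n_both`, `n_neither` and `n_total`.
#' @export
count_site_reads <- function(reads, sites = binding_site_set()) {
  if (length(reads) == 0L) stop("empty read set", call. = FALSE)
  has_with <- .cpp_contains_site(reads, sites$with_sin,
                                 revcomp(sites$with_sin))
  has_without <- .cpp_contains_site(reads, sites$without_sin,
                                    revcomp(sites$without_sin))
  structure(list(n_with_only = sum(has_with & !has_without),
                 n_without_only = sum(!has_with & has_without),
                 n_both = sum(has_with & has_without),
                 n_neither = sum(!has_with & !has_without),
                 n_total = length(reads)),
            class = "site_read_counts")
}

#' McNemar's test on paired site containment counts
#'
#' The chi-square statistic (no continuity correction) on the discordant
#' counts, with an exact binomial p-value alongside when the discordant
#' total is small. Reads containing both sites are excluded from the test.
#'
#' @param counts A [count_site_reads()] result, or any list with
#'   `n_with_only` and `n_without_only`.
#' @param exact_below Discordant-total threshold under which the exact
#'   binomial p is also reported (default 25).
#' @return A list with `statistic`, `p_value` (chi-square, 1 df),
#'   `exact_p` (`NA` unless the discordant total is below `exact_below`),
#'   and the discordant counts.
#' @export
mcnemar_test <- function(counts, exact_below = 25) {
  a <- counts$n_with_only
  b <- counts$n_without_only
  if (a + b == 0) {
    stop("no discordant reads: the McNemar statistic is undefined",
         call. = FALSE)
  }
  stat <- (a - b)^2 / (a + b)
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  exact <- NA_real_
  if (a + b < exact_below) {
    exact <- binom.test(a, a + b, p = 0.5)$p.value
  }
  list(statistic = stat, p_value = p, exact_p = exact,
       n_with_only = a, n_without_only = b)
}

# ---- rank statistics --------------------------------------------------

#' How many k-mers outrank a site
#'
#' Counts canonical k-mers whose frequency strictly exceeds that of `site`,
#' and expresses the count as a percentage of a denominator universe.
#'
#' @param table A `kmer_table`.
#' @param site Site sequence of length k (canonicalized internally).
#' @param denominator `"universe"` (default: all `(4^k + 4^(k/2))/2`
#'   canonical k-mers, even k only) or `"observed"` (distinct k-mers in the
#'   table).
#' @return A list with `count`, `pct` and the `denominator` size used.
#' @export
rank_kmers_above <- function(table, site,
                             denominator = c("universe", "observed")) {
  stopifnot(inherits(table, "kmer_table"))
  denominator <- match.arg(denominator)
  k <- attr(table, "k")
  if (nchar(site) != k) stop("site length must equal k", call. = FALSE)
  site_count <- kmer_count_of(table, site)
  count <- sum(table$count > site_count)
  denom <- if (denominator == "universe") {
    canonical_universe_size(k)
  } else {
    nrow(table)
  }
  list(count = count, pct = 100 * count / denom, denominator = denom,
       site_count = site_count)
}

# ---- positional dependence -------------------------------------------

#' Counts of core-site variants at selected positions
#'
#' Instantiates a wildcard template at the queried positions with every base
#' combination and looks up each resulting k-mer's canonical count — the
#' grid that exposes interactions between motif positions which a PWM (by
#' its independence assumption) cannot represent.
#'
#' @param table A `kmer_table`.
#' @param core_template Template of length k with `.` or `N` at the queried
#'   positions.
#' @param positions 1-based positions within the template to vary.
#' @param alphabet Bases to substitute (default A, C, G, T).
#' @return A data frame with one column per queried position, the
#'   instantiated `kmer`, and its `count`.
#' @export
positional_dependence <- function(table, core_template, positions,
                                  alphabet = DNA_BASES) {
  stopifnot(inherits(table, "kmer_table"))
  k <- attr(table, "k")
  if (nchar(core_template) != k) {
    stop("template length must equal the table's k", call. = FALSE)
  }
  if (any(positions < 1 | positions > k)) {
    stop("queried position out of range", call. = FALSE)
  }
  tmpl <- strsplit(toupper(core_template), "", fixed = TRUE)[[1L]]
  if (!all(tmpl[positions] %in% c(".", "N"))) {
    stop("template must carry wildcards ('.' or 'N') at the queried positions",
         call. = FALSE)
  }
  combos <- expand.grid(rep(list(alphabet), length(positions)),
                        stringsAsFactors = FALSE)
  names(combos) <- paste0("pos", positions)
  combos$kmer <- apply(combos, 1L, function(bases) {
    s <- tmpl
    s[positions] <- bases
    paste(s, collapse = "")
  })
  combos$count <- kmer_count_of(table, combos$kmer)
  combos
}

# ---- sequence arithmetic ---------------------------------------------

#' Insert a base into a sequence
#'
#' @param sequence DNA string.
#' @param pos_1based Insertion point: the base is inserted *before* this
#'   1-based position, so `length(sequence) + 1` appends.
#' @param base Single base to insert.
#' @return The lengthened sequence.
#' @examples
#' apply_insertion("CGCCCACACA", 10, "C") # "CGCCCACACCA"
#' @export
apply_insertion <- function(sequence, pos_1based, base) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(base) == 1L)
  n <- nchar(sequence)
  if (pos_1based < 1 || pos_1based > n + 1) {
    stop("insertion position out of range", call. = FALSE)
  }
  paste0(substr(sequence, 1L, pos_1based - 1L), base,
         substr(sequence, pos_1based, n))
}
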