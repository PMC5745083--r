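# Canonical counting against brute-force string oracles, site statistics,
# orientation, PWMs, and the insertion operation.

test_that("canonical counting matches the naive string oracle", {
  expect_equal(canonical_kmer_counts("AAAA", 4)$kmer, "AAAA")
  expect_equal(canonical_kmer_counts("ACGT", 4)$kmer, "ACGT") # palindrome
  set.seed(5)
  reads <- vapply(1:40, function(i) {
    paste(sample(c("A", "C", "G", "T", "N"), 25, replace = TRUE,
                 prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  }, character(1L))
  for (k in c(3L, 7L)) {
    tab <- canonical_kmer_counts(reads, k)
    oracle <- oracle_kmer_counts(reads, k)
    expect_equal(attr(tab, "n_windows"), sum(oracle))
    expect_setequal(tab$kmer, names(oracle))
    expect_equal(tab$count[match(names(oracle), tab$kmer)],
                 as.integer(oracle))
  }
})

test_that("canonicalization is an involution (exhaustive at k = 6)", {
  for (k in c(2L, 4L, 6L)) {
    all_k <- oracle_all_kmers(k)
    tab <- canonical_kmer_counts(all_k, k)
    # every canonical key equals the canonical form of its reverse complement
    expect_identical(tab$kmer, oracle_canonical(tab$kmer))
    # counting all 4^k strings covers the whole canonical universe
    expect_equal(nrow(tab), canonical_universe_size(k))
    expect_equal(sum(tab$count), 4^k)
  }
  expect_equal(canonical_universe_size(c(2, 4, 6)), c(10, 136, 2080))
  expect_error(canonical_universe_size(5), "even")
})

test_that("tables merge by addition, invariant to order", {
  set.seed(9)
  sets <- lapply(1:3, function(i) {
    vapply(1:30, function(j) {
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    }, character(1L))
  })
  tabs <- lapply(sets, canonical_kmer_counts, k = 5L)
  m1 <- merge_kmer_tables(tabs)
  m2 <- merge_kmer_tables(tabs[c(3, 1, 2)])
  expect_identical(m1$kmer, m2$kmer)
  expect_identical(m1$count, m2$count)
  pooled <- canonical_kmer_counts(unlist(sets), 5L)
  expect_equal(sum(m1$count), sum(pooled$count))
  expect_equal(m1$count[match(pooled$kmer, m1$kmer)], pooled$count)
  site <- m1$kmer[5L]
  expect_equal(rank_kmers_above(m1, site, denominator = "observed")$count,
               rank_kmers_above(m2, site, denominator = "observed")$count)
})

test_that("consensus orientation minimizes Hamming distance", {
  cons <- "CGCCCACGCA"
  expect_equal(consensus_orient(cons, cons), cons)
  expect_equal(consensus_orient(oracle_revcomp(cons), cons), cons)
  expect_error(consensus_orient("ACGT", cons), "length")
  set.seed(13)
  kmers <- vapply(1:200, function(i) {
    paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = "")
  }, character(1L))
  oriented <- consensus_orient(kmers, cons)
  hd <- function(a, b) {
    mapply(function(x, y) sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]]),
           a, b, USE.NAMES = FALSE)
  }
  expect_true(all(hd(oriented, cons) <= hd(kmers, cons)))
  expect_true(all(hd(oriented, cons) <= hd(oracle_revcomp(kmers), cons)))
  # ties keep the forward orientation (ACGT is its own reverse complement)
  expect_equal(consensus_orient("ACGT", "AAAA"), "ACGT")
  expect_equal(consensus_orient("AATT", "AGTT"), "AATT") # d = 1 both ways
})

test_that("read-level site counts scan both strands and partition reads", {
  sites <- binding_site_set()
  reads <- c(paste0("TTT", sites$with_sin, "GGG"),
             paste0("AAA", sites$without_sin, "CCC"),
             paste0("AA", oracle_revcomp(sites$with_sin), "CC"),
             "ACGTACGTACGTACGTACGT")
  sc <- count_site_reads(reads, sites)
  expect_equal(sc$n_with_only, 2L) # forward and reverse-complement hits
  expect_equal(sc$n_without_only, 1L)
  expect_equal(sc$n_neither, 1L)
  expect_equal(sc$n_with_only + sc$n_without_only + sc$n_both + sc$n_neither,
               sc$n_total)
  expect_error(count_site_reads(character(0L)), "empty")
})

test_that("McNemar matches hand arithmetic and the exact binomial oracle", {
  expect_error(mcnemar_test(list(n_with_only = 0, n_without_only = 0)),
               "undefined")
  res <- mcnemar_test(list(n_with_only = 10, n_without_only = 2))
  expect_equal(res$statistic, 16 / 3)
  expect_equal(res$exact_p, binom.test(10, 12, 0.5)$p.value)
  expect_equal(mcnemar_test(list(n_with_only = 5, n_without_only = 5))$p_value,
               1)
  # monotone in the count imbalance at fixed total
  stats <- vapply(0:6, function(d) {
    mcnemar_test(list(n_with_only = 10 + d, n_without_only = 10 - d))$statistic
  }, numeric(1L))
  expect_true(all(diff(stats) > 0))
  # asymptotic and exact p agree for discordant totals >= 25, within the
  # O(1/sqrt(n)) error expected of the normal approximation
  for (ab in list(c(20, 10), c(25, 14), c(40, 22), c(60, 40))) {
    m <- mcnemar_test(list(n_with_only = ab[1L], n_without_only = ab[2L]),
                      exact_below = Inf)
    expect_lt(abs(m$p_value - m$exact_p), 0.25 / sqrt(sum(ab)))
  }
})

test_that("rank counts and universe percentages match printed conventions", {
  tab <- canonical_kmer_counts(c("AAAAAAAAAAAA", "AAAAAAAAAAAC"), 10)
  top <- tab$kmer[which.max(tab$count)]
  expect_equal(rank_kmers_above(tab, top)$count, 0L)
  rk <- rank_kmers_above(tab, "GGGGGGGGGG", denominator = "observed")
  expect_equal(rk$denominator, nrow(tab))
  expect_error(rank_kmers_above(tab, "AAAA"), "length")
})

test_that("positional dependence grids address the canonical table", {
  sites <- binding_site_set()
  reads <- c(rep(sites$without_sin, 5), rep(sites$optimal, 9),
             rep("CGCCCACGCC", 2))
  tab <- canonical_kmer_counts(reads, 10)
  grid <- positional_dependence(tab, "CGCCCAC.C.", c(8, 10))
  expect_equal(nrow(grid), 16L)
  expect_equal(grid$count[grid$pos8 == "A" & grid$pos10 == "A"], 5L)
  expect_equal(grid$count[grid$pos8 == "G" & grid$pos10 == "A"], 9L)
  expect_equal(grid$count[grid$pos8 == "G" & grid$pos10 == "C"], 2L)
  expect_equal(grid$kmer[grid$pos8 == "G" & grid$pos10 == "A"],
               sites$optimal)
  expect_error(positional_dependence(tab, "CGCCCAC.C.", c(8, 11)),
               "range")
  expect_error(positional_dependence(tab, "CGCCCACGCA", c(8, 10)),
               "wildcards")
  # an empty table yields a zero grid
  empty <- canonical_kmer_counts("TTTTTTTTTTT", 10)
  g0 <- positional_dependence(empty, "CGCCCAC.C.", c(8, 10))
  expect_true(all(g0$count == 0L))
})

test_that("PWMs build, score, and recover generating frequencies", {
  one <- build_pwm("ACGT")
  expect_equal(as.numeric(one$mat[cbind(1:4, 1:4)]), rep(1, 4)) # one-hot
  expect_equal(pwm_consensus(one), "ACGT")
  uni <- pwm(matrix(0.25, 4, 6))
  expect_equal(uni$info, rep(0, 6))
  expect_equal(pwm_score(uni, "ACGTACGTAC")$score, 0)
  # near-one-hot consensus scores about 2 bits per column
  sharp <- build_pwm("CGCCCACGCA", pseudocount = 1e-4)
  sc <- pwm_score(sharp, "CGCCCACGCA")
  expect_gt(sc$score, 2 * 10 - 0.1)
  expect_error(pwm_score(sharp, "ACGT"), "shorter")
  # brute-force scan oracle on random sequences
  set.seed(23)
  mix <- build_pwm(c("CGCCCACGCA", "CGCCCACACA", "CGCCCACACC"),
                   counts = c(5, 3, 2), pseudocount = 0.5)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
               collapse = "")
    expect_equal(pwm_score(mix, s)$score, oracle_pwm_best(mix$mat, s),
                 tolerance = 1e-10)
  }
  # parameter recovery from draws of a known PWM
  truth <- build_pwm(c("CGCCCACGCA", "CGCCCACACA"), counts = c(7, 3))
  set.seed(29)
  draws <- vapply(1:1000, function(i) {
    paste(vapply(1:10, function(j) {
      sample(c("A", "C", "G", "T"), 1L, prob = truth$mat[, j])
    }, character(1L)), collapse = "")
  }, character(1L))
  fit <- build_pwm(draws)
  expect_lt(max(abs(fit$mat - truth$mat)), 0.05)
  expect_error(build_pwm(character(0L)), "no k-mers")
})

test_that("single-base insertion produces the with-sin core", {
  sites <- binding_site_set()
  lengthened <- apply_insertion(sites$without_sin, 10, "C")
  expect_equal(nchar(lengthened), nchar(sites$without_sin) + 1L)
  expect_equal(substr(lengthened, 1, 10), sites$with_sin)
  expect_equal(apply_insertion("ACGT", 1, "G"), "GACGT")
  expect_equal(apply_insertion("ACGT", 5, "G"), "ACGTG")
  expect_error(apply_insertion("ACGT", 6, "G"), "range")
})
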