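# Hemizygosity cross simulation and association scan.
#
# Wild-derived inbred lines are crossed to a deficiency stock; progeny are
# hemizygous for the wild allele inside the deleted interval and
# heterozygous (line / balancer) outside it. The cross is simulated at the
# genotype level by three remapping rules, then a per-variant ordinary
# least squares scan with relationship-matrix principal components as
# covariates, family-wise corrected by max(T) permutation and compared to a
# Bonferroni line.

#' Simulate a deficiency cross at the genotype level
#'
#' Remaps every call of an inbred-line genotype matrix to the progeny
#' genotype implied by crossing to a deficiency stock:
#' homozygous reference stays homozygous reference; homozygous alternate
#' stays homozygous alternate inside the deficiency interval (hemizygous
#' exposure) and becomes heterozygous outside it; every other call
#' (heterozygous or missing) becomes missing and is excluded downstream.
#'
#' @param genotypes A [genotype_matrix()].
#' @param deficiency A [deficiency_interval()].
#' @return A remapped [genotype_matrix()] (variant metadata unchanged).
#' @export
simulate_cross <- function(genotypes, deficiency) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(deficiency, "deficiency_interval"))
  inside <- in_interval(genotypes$variants, deficiency)
  calls <- genotypes$calls
  out <- matrix(NA_integer_, nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  out[calls == 0L] <- 0L
  hom_alt <- !is.na(calls) & calls == 2L
  out[hom_alt & matrix(inside, nrow(calls), ncol(calls), byrow = TRUE)] <- 2L
  out[hom_alt & matrix(!inside, nrow(calls), ncol(calls), byrow = TRUE)] <- 1L
  genotype_matrix(genotypes$variants, genotypes$lines, out)
}

#' Principal components of the genetic relationship matrix
#'
#' Dosages (0/1/2; missing mean-imputed per variant) are standardized per
#' variant — centered by `2p` and scaled by `sqrt(2p(1-p))` with `p` the
#' sample allele frequency — and the top eigenvectors of the resulting
#' relationship matrix `Z Z' / m` are returned as covariates. Monomorphic
#' variants are skipped.
#'
#' @param genotypes A [genotype_matrix()] (typically the post-cross matrix).
#' @param n_pcs Number of components (requires more lines than PCs).
#' @return Numeric matrix, lines x `n_pcs`.
#' @export
compute_relationship_pcs <- function(genotypes, n_pcs = 20L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- length(genotypes$lines)
  if (n < n_pcs + 1L) {
    stop("need at least n_pcs + 1 lines", call. = FALSE)
  }
  d <- genotype_dosage(genotypes) * 1.0
  # mean-impute missing calls per variant
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2L]]
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1 & apply(d, 2L, function(x) length(unique(x)) > 1L)
  if (!any(poly)) stop("no polymorphic variants", call. = FALSE)
  z <- sweep(d[, poly, drop = FALSE], 2L, 2 * p[poly], "-")
  z <- sweep(z, 2L, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  grm <- tcrossprod(z) / sum(poly)
  ev <- eigen(grm, symmetric = TRUE)
  pcs <- ev$vectors[, seq_len(n_pcs), drop = FALSE]
  rownames(pcs) <- genotypes$lines
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  pcs
}

# Per-variant precomputation shared by the scan and the permutation test:
# for each tested variant, the informative-line subset, the covariate QR,
# and the covariate-residualized dosage.
scan_prepare <- function(genotypes, phenotype, covariates, mac_floor) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            all(c("line_id", "pct_on") %in% names(phenotype)))
  lines <- intersect(genotypes$lines, phenotype$line_id)
  if (length(lines) < 3L) stop("too few phenotyped lines", call. = FALSE)
  y <- phenotype$pct_on[match(lines, phenotype$line_id)]
  d <- genotype_dosage(genotypes)[match(lines, genotypes$lines), ,
                                  drop = FALSE] * 1.0
  if (is.null(covariates)) {
    cv <- matrix(numeric(0L), length(lines), 0L)
  } else {
    cv <- as.matrix(covariates)[match(lines, rownames(covariates)), ,
                                drop = FALSE]
  }
  k <- ncol(cv) + 1L # + intercept
  m <- ncol(d)
  per_variant <- vector("list", m)
  for (v in seq_len(m)) {
    s <- which(!is.na(d[, v]))
    x <- d[s, v]
    mac <- min(sum(x), sum(2 - x)) # minor-allele count over informative lines
    if (length(s) < k + 2L || mac < mac_floor || sd(x) == 0) {
      per_variant[[v]] <- list(tested = FALSE)
      next
    }
    C <- cbind(intercept = 1, cv[s, , drop = FALSE])
    qrc <- qr(C)
    if (qrc$rank < ncol(C)) {
      per_variant[[v]] <- list(tested = FALSE)
      next
    }
    Q <- qr.Q(qrc)
    xt <- x - Q %*% crossprod(Q, x)
    denom <- sum(xt^2)
    if (denom < 1e-12) {
      # dosage fully explained by covariates: untestable, not a crash
      per_variant[[v]] <- list(tested = FALSE)
      next
    }
    per_variant[[v]] <- list(tested = TRUE, s = s, Q = Q, xt = drop(xt),
                             denom = denom, df = length(s) - ncol(C) - 1L)
  }
  list(lines = lines, y = y, per_variant = per_variant, k = k)
}

# t statistics for (possibly many) phenotype columns at one prepared variant
variant_t <- function(pv, Y) {
  Ys <- Y[pv$s, , drop = FALSE]
  Yt <- Ys - pv$Q %*% crossprod(pv$Q, Ys)
  beta <- drop(crossprod(pv$xt, Yt)) / pv$denom
  rss <- colSums(Yt^2) - beta^2 * pv$denom
  rss <- pmax(rss, 0)
  se <- sqrt(rss / pv$df / pv$denom)
  t <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  list(beta = beta, t = t)
}

#' Per-variant linear association scan
#'
#' Ordinary least squares of the phenotype on additive dosage plus
#' covariates and an intercept, per variant, with missing-call lines
#' dropped for that variant. Variants below the minor-allele-count floor,
#' with singular designs, or with dosage collinear with the covariates are
#' flagged untested.
#'
#' @param genotypes A (post-cross) [genotype_matrix()].
#' @param phenotype Data frame with `line_id` and `pct_on`.
#' @param covariates Optional lines x k matrix with rownames matching line
#'   identifiers (e.g. [compute_relationship_pcs()] output).
#' @param mac_floor Minimum minor-allele count for a variant to be tested
#'   (default 5).
#' @return Data frame, one row per variant: `chrom`, `pos`, `tested`,
#'   `beta`, `t`, `p`, `n_used`.
#' @export
association_scan <- function(genotypes, phenotype, covariates = NULL,
                             mac_floor = 5L) {
  prep <- scan_prepare(genotypes, phenotype, covariates, mac_floor)
  Y <- matrix(prep$y, ncol = 1L)
  m <- nrow(genotypes$variants)
  res <- data.frame(chrom = genotypes$variants$chrom,
                    pos = genotypes$variants$pos,
                    tested = FALSE, beta = NA_real_, t = NA_real_,
                    p = NA_real_, n_used = NA_integer_,
                    stringsAsFactors = FALSE)
  for (v in seq_len(m)) {
    pv <- prep$per_variant[[v]]
    if (!pv$tested) next
    vt <- variant_t(pv, Y)
    res$tested[v] <- TRUE
    res$beta[v] <- vt$beta
    res$t[v] <- vt$t
    res$p[v] <- 2 * pt(abs(vt$t), df = pv$df, lower.tail = FALSE)
    res$n_used[v] <- length(pv$s)
  }
  res
}

#' max(T) permutation p-values
#'
#' The raw phenotype vector is permuted across lines `n_perm` times; for
#' each permutation the covariates are refit and the maximum |t| over all
#' tested variants recorded. The empirical p for variant v is
#' `(1 + #\{permutations with max|t| >= |t_v|\}) / (n_perm + 1)`, which
#' controls the family-wise error rate by construction and is monotone
#' non-increasing in |t_v|.
#'
#' @inheritParams association_scan
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @return The [association_scan()] data frame with an added `emp_p`
#'   column (`NA` for untested variants) and attribute `max_t_null` (the
#'   permutation distribution of max |t|).
#' @export
maxT_permutation <- function(genotypes, phenotype, covariates = NULL,
                             n_perm = 1000L, seed = 1L, mac_floor = 5L) {
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  scan <- association_scan(genotypes, phenotype, covariates, mac_floor)
  prep <- scan_prepare(genotypes, phenotype, covariates, mac_floor)
  n <- length(prep$y)
  Yperm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) prep$y[sample.int(n)], numeric(n))
  })
  max_t <- rep(0, n_perm)
  for (v in seq_along(prep$per_variant)) {
    pv <- prep$per_variant[[v]]
    if (!pv$tested) next
    vt <- variant_t(pv, Yperm)
    max_t <- pmax(max_t, abs(vt$t))
  }
  obs <- abs(scan$t)
  scan$emp_p <- NA_real_
  tested <- which(scan$tested)
  scan$emp_p[tested] <- vapply(obs[tested], function(tv) {
    (1 + sum(max_t >= tv)) / (n_perm + 1)
  }, numeric(1L))
  attr(scan, "max_t_null") <- max_t
  scan
}

#' Bonferroni threshold and significance flags
#'
#' @param p_values Asymptotic p-values (`NA` for untested variants).
#' @param alpha Family-wise level (default 0.05).
#' @return List with `threshold` (`alpha` divided by the number of tested,
#'   i.e. non-`NA`, variants) and logical `significant` flags.
#' @export
bonferroni_threshold <- function(p_values, alpha = 0.05) {
  m <- sum(!is.na(p_values))
  if (m < 1L) stop("no tested variants", call. = FALSE)
  thr <- alpha / m
  list(threshold = thr, m_tested = m,
       significant = !is.na(p_values) & p_values < thr)
}
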