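# Genotype containers shared by the synthetic cohort generator, the cross
# simulation, and the association scan.

GT_LEVELS <- c("HOM_REF", "HET", "HOM_ALT")

#' Line-by-variant genotype matrix
#'
#' Genotype calls for a panel of (near-)inbred lines. Calls are stored as an
#' integer matrix with codes 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing.
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; an `is_indel` column is derived from REF/ALT lengths if absent.
#' @param lines Character vector of line identifiers.
#' @param calls Integer matrix, `length(lines)` rows by `nrow(variants)`
#'   columns, with codes 0/1/2/`NA`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, lines, calls) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  calls <- as.matrix(calls)
  if (nrow(calls) != length(lines) || ncol(calls) != nrow(variants)) {
    stop("`calls` must be lines x variants", call. = FALSE)
  }
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(variants$is_indel)) {
    variants$is_indel <- nchar(variants$ref) != nchar(variants$alt)
  }
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  calls <- calls[, o, drop = FALSE]
  rownames(calls) <- lines
  structure(list(variants = variants, lines = as.character(lines),
                 calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d variants (%d indels)\n",
              length(x$lines), nrow(x$variants), sum(x$variants$is_indel)))
  invisible(x)
}

#' Deficiency interval
#'
#' A chromosomal deletion interval; crossing a line to a deficiency stock
#' leaves progeny hemizygous for the wild-derived allele inside it.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return An object of class `deficiency_interval`.
#' @export
deficiency_interval <- function(chrom, start, end) {
  if (start > end) stop("`start` must be <= `end`", call. = FALSE)
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end)),
            class = "deficiency_interval")
}

# Additive dosage matrix (lines x variants) from genotype codes; NA kept.
genotype_dosage <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$calls
}

in_interval <- function(variants, interval) {
  variants$chrom == interval$chrom &
    variants$pos >= interval$start & variants$pos <= interval$end
}
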