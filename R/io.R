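# Readers and writers for the minimal formats the pipeline consumes:
# GT-only VCF v4.2, paired single-channel PNG images, FASTA/FASTQ reads,
# and TSV tables. Genome coordinates are 1-based inclusive; raster pixel
# coordinates are 0-based.

# ---- VCF --------------------------------------------------------------

#' Write a minimal VCF v4.2
#'
#' Emits CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO, FORMAT=GT and one
#' genotype column per line/haplotype — the subset every downstream reader
#' consumes.
#'
#' @param x A [genotype_matrix()] (unphased `0/0`-style GT) or a
#'   [haplotype_matrix()] (phased `0|0`-style GT pairing consecutive
#'   haplotypes; an odd final haplotype is dropped with a warning).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (inherits(x, "genotype_matrix")) {
    gt_chr <- matrix("./.", nrow(x$calls), ncol(x$calls))
    gt_chr[which(x$calls == 0L)] <- "0/0"
    gt_chr[which(x$calls == 1L)] <- "0/1"
    gt_chr[which(x$calls == 2L)] <- "1/1"
    samples <- x$lines
    v <- x$variants
    gt_cols <- t(gt_chr)
  } else if (inherits(x, "haplotype_matrix")) {
    n <- nrow(x$haps)
    if (n %% 2L == 1L) {
      warning("odd haplotype count: dropping the last haplotype")
      n <- n - 1L
    }
    a <- x$haps[seq(1L, n, by = 2L), , drop = FALSE]
    b <- x$haps[seq(2L, n, by = 2L), , drop = FALSE]
    gt_cols <- matrix(paste0(t(a), "|", t(b)), ncol = n / 2L)
    samples <- sprintf("hap_pair_%03d", seq_len(n / 2L))
    v <- data.frame(chrom = "3R", pos = x$positions,
                    ref = "A", alt = "AC", stringsAsFactors = FALSE)
    header <- c(header,
                sprintf("##focal_index=%d", x$focal_index))
  } else {
    stop("`x` must be a genotype_matrix or haplotype_matrix", call. = FALSE)
  }
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt_cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               body), path)
  invisible(path)
}

#' Read a minimal GT-only VCF
#'
#' @param path VCF path (plain text).
#' @param mode `"genotype"` parses diploid calls (`/` or `|` separated) to
#'   HOM_REF/HET/HOM_ALT/MISSING codes; `"haplotype"` requires phased
#'   (`|`) calls and splits each sample into two haplotypes.
#' @param focal_index For haplotype mode: focal site index (taken from a
#'   `##focal_index` header line when present, else defaults to the middle
#'   site).
#' @return A [genotype_matrix()] or [haplotype_matrix()].
#' @export
read_vcf_minimal <- function(path, mode = c("genotype", "haplotype"),
                             focal_index = NULL) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1L) {
    stop("malformed VCF: missing #CHROM header line", call. = FALSE)
  }
  if (is.null(focal_index)) {
    fi_line <- grep("^##focal_index=", lines, value = TRUE)
    if (length(fi_line)) {
      focal_index <- as.integer(sub("^##focal_index=", "", fi_line[1L]))
    }
  }
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 10L) stop("VCF has no sample columns", call. = FALSE)
  samples <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  recs <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(recs)
  bad <- which(nf != length(hdr))
  if (length(bad)) {
    stop(sprintf("malformed VCF record at line %d", hdr_i + bad[1L]),
         call. = FALSE)
  }
  m <- length(recs)
  variants <- data.frame(
    chrom = vapply(recs, `[[`, character(1L), 1L),
    pos = as.numeric(vapply(recs, `[[`, character(1L), 2L)),
    ref = vapply(recs, `[[`, character(1L), 4L),
    alt = vapply(recs, `[[`, character(1L), 5L),
    stringsAsFactors = FALSE)
  gt_of <- function(field) sub(":.*$", "", field)
  gt <- vapply(recs, function(r) gt_of(r[-(1:9)]),
               character(length(samples)))
  gt <- matrix(gt, nrow = length(samples)) # samples x variants
  if (mode == "genotype") {
    parse_gt <- function(g) {
      al <- strsplit(g, "[/|]")
      bad <- which(lengths(al) != 2L & g != "." & !grepl("^\\.$", g))
      if (length(bad)) {
        stop(sprintf("mixed ploidy or malformed GT in record %d", bad[1L]),
             call. = FALSE)
      }
      vapply(al, function(a) {
        if (length(a) != 2L || any(a == ".")) return(NA_integer_)
        sum(as.integer(a != "0"))
      }, integer(1L))
    }
    calls <- matrix(parse_gt(as.vector(gt)), nrow = length(samples))
    genotype_matrix(variants, samples, calls)
  } else {
    if (any(!grepl("|", gt, fixed = TRUE))) {
      stop("haplotype mode requires phased '|' genotypes", call. = FALSE)
    }
    al <- strsplit(as.vector(gt), "|", fixed = TRUE)
    if (any(lengths(al) != 2L)) {
      stop("mixed ploidy in phased genotypes", call. = FALSE)
    }
    a <- matrix(as.integer(vapply(al, `[[`, character(1L), 1L)),
                nrow = length(samples))
    b <- matrix(as.integer(vapply(al, `[[`, character(1L), 2L)),
                nrow = length(samples))
    haps <- matrix(0L, 2L * length(samples), m)
    haps[seq(1L, 2L * length(samples), by = 2L), ] <- a
    haps[seq(2L, 2L * length(samples), by = 2L), ] <- b
    if (is.null(focal_index)) focal_index <- ceiling(m / 2)
    haplotype_matrix(haps, variants$pos, focal_index)
  }
}

# ---- images -----------------------------------------------------------

#' Write a retina image as paired single-channel PNGs
#'
#' Intensities are scaled by `scale` onto \[0, 1\] (values above `scale`
#' clip) and quantized to the PNG bit depth the png package writes (8 bits
#' in this build); the scale factor is recorded in a JSON sidecar so
#' reading restores the original units up to quantization.
#'
#' @param image A [retina_image()].
#' @param rh3_path,rh4_path Output paths for the two channels.
#' @param scale Intensity mapped to full white (default: the image max).
#' @return Invisible list of the two paths and the sidecar path.
#' @export
write_image_pair <- function(image, rh3_path, rh4_path, scale = NULL) {
  stopifnot(inherits(image, "retina_image"))
  if (is.null(scale)) scale <- max(image$rh3, image$rh4, 1e-12)
  png::writePNG(pmin(image$rh3 / scale, 1), rh3_path, dpi = NULL)
  png::writePNG(pmin(image$rh4 / scale, 1), rh4_path, dpi = NULL)
  sidecar <- paste0(rh3_path, ".meta.json")
  jsonlite::write_json(list(scale = scale), sidecar, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(rh3 = rh3_path, rh4 = rh4_path, meta = sidecar))
}

#' Read a retina image from paired single-channel files
#'
#' Channels are mapped to Rh3/Rh4 by explicit argument, never by guessing;
#' 8- and 16-bit PNGs are both accepted (readPNG maps either onto
#' \[0, 1\]) and promoted to a common numeric range via the recorded
#' scale (or \[0, 1\] without a sidecar).
#'
#' @param rh3_path,rh4_path Paths of the OFF (Rh3) and ON (Rh4) channel
#'   PNGs, which must have identical shapes.
#' @return A [retina_image()].
#' @export
read_image_pair <- function(rh3_path, rh4_path) {
  rh3 <- png::readPNG(rh3_path)
  rh4 <- png::readPNG(rh4_path)
  if (length(dim(rh3)) == 3L) rh3 <- rh3[, , 1L]
  if (length(dim(rh4)) == 3L) rh4 <- rh4[, , 1L]
  if (!identical(dim(rh3), dim(rh4))) {
    stop("channel shapes differ", call. = FALSE)
  }
  scale <- 1
  sidecar <- paste0(rh3_path, ".meta.json")
  if (file.exists(sidecar)) {
    scale <- jsonlite::read_json(sidecar)$scale
  }
  retina_image(rh3 * scale, rh4 * scale)
}

# ---- reads ------------------------------------------------------------

#' Write reads to FASTA
#'
#' @param reads Character vector of sequences.
#' @param path Output path (a `.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read_%d", seq_along(reads))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path Input path (plain or gzip; format inferred from the
#'   extension, `.fq`/`.fastq` meaning FASTQ).
#' @return Character vector of sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

# ---- tables -----------------------------------------------------------

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a data frame
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
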