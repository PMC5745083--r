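# Configuration handling and the umbrella pipeline runner.

PIPELINE_BLOCKS <- c("synthetic", "segmentation", "gwas", "kmer",
                     "popgen", "behavior")
PIPELINE_GLOBALS <- c("seed", "out_dir", "log_level", "stages")

#' Build (and validate) a pipeline configuration
#'
#' @param config A named list, or a path to a YAML/JSON file holding one.
#'   Recognised top-level keys: `seed`, `out_dir`, `log_level`, `stages`
#'   (subset of `r paste(PIPELINE_BLOCKS, collapse = ", ")`), plus one
#'   optional parameter block per stage. Unknown keys are rejected.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), c(PIPELINE_BLOCKS, PIPELINE_GLOBALS))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(seed = 1L, out_dir = "mosaicR7-out", log_level = "info",
                  stages = PIPELINE_BLOCKS)
  cfg <- utils::modifyList(defaults, config)
  bad <- setdiff(cfg$stages, PIPELINE_BLOCKS)
  if (length(bad)) {
    stop("unknown stages: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

log_msg <- function(cfg, stage, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates synthetic inputs for the requested stages, runs each analysis,
#' writes its outputs under `out_dir`, and records every artifact (with an
#' MD5 hash), the seed and the resolved configuration in a JSON manifest.
#' Deterministic stages reproduce identical manifests for identical
#' configs.
#'
#' @param config A [pipeline_config()], list, or config file path.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json` beside `config.json`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(if (inherits(config, "pipeline_config")) {
    unclass(config)
  } else config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0L)
  emit <- function(path) artifacts <<- c(artifacts, path)
  seed <- cfg$seed

  if ("segmentation" %in% cfg$stages) {
    log_msg(cfg, "segmentation", "generating and counting a synthetic retina")
    sc <- do.call(sim_config, utils::modifyList(
      list(seed = child_seed(seed, 1)), cfg$segmentation %||% list()))
    gen <- generate_retina_image(sc)
    paths <- write_image_pair(gen$image,
                              file.path(cfg$out_dir, "retina_rh3.png"),
                              file.path(cfg$out_dir, "retina_rh4.png"))
    mc <- count_mosaic(gen$image)
    write_tsv(mc$regions, file.path(cfg$out_dir, "retina_regions.tsv"))
    write_tsv(data.frame(n_rh3 = mc$n_rh3, n_rh4 = mc$n_rh4,
                         n_ambiguous = mc$n_ambiguous, pct_on = mc$pct_on,
                         pct_on_true = 100 * gen$truth$on_fraction_true,
                         scorable = mc$scorable),
              file.path(cfg$out_dir, "retina_summary.tsv"))
    for (p in c(paths$rh3, paths$rh4, paths$meta,
                file.path(cfg$out_dir, c("retina_regions.tsv",
                                         "retina_summary.tsv")))) emit(p)
  }

  if ("gwas" %in% cfg$stages) {
    log_msg(cfg, "gwas", "simulating cohort, cross and association scan")
    gp <- utils::modifyList(
      list(n_lines = 80L, n_variants = 120L, causal_index = 60L,
           effect_size = -1.5, seed = child_seed(seed, 2)),
      cfg$gwas %||% list())
    n_pcs <- gp$n_pcs %||% 5L
    n_perm <- gp$n_perm %||% 200L
    gp$n_pcs <- NULL; gp$n_perm <- NULL
    cohort <- do.call(generate_cross_cohort, gp)
    write_vcf(cohort$genotypes, file.path(cfg$out_dir, "cohort.vcf"))
    write_tsv(cohort$phenotypes, file.path(cfg$out_dir, "phenotypes.tsv"))
    crossed <- simulate_cross(cohort$genotypes, cohort$deficiency)
    pcs <- compute_relationship_pcs(crossed, n_pcs)
    scan <- maxT_permutation(crossed, cohort$phenotypes, pcs,
                             n_perm = n_perm, seed = child_seed(seed, 3))
    bf <- bonferroni_threshold(scan$p)
    scan$significant <- bf$significant
    write_tsv(scan, file.path(cfg$out_dir, "association.tsv"))
    for (p in file.path(cfg$out_dir, c("cohort.vcf", "phenotypes.tsv",
                                       "association.tsv"))) emit(p)
  }

  if ("kmer" %in% cfg$stages) {
    log_msg(cfg, "kmer", "simulating selection cycles and counting 10-mers")
    kp <- utils::modifyList(
      list(n_reads = 4000L, read_length = 30L, n_cycles = 4L,
           seed = child_seed(seed, 4)),
      cfg$kmer %||% list())
    sites <- binding_site_set()
    kp$pwm <- kp$pwm %||% build_pwm(sites$optimal, pseudocount = 0.4)
    cycles <- do.call(generate_selex_reads, kp)
    last <- cycles[[length(cycles)]]
    write_fasta(last, file.path(cfg$out_dir, "selex_cycle4.fasta"))
    tab <- canonical_kmer_counts(last, 10L,
                                 cycle = length(cycles) - 1L)
    write_tsv(head(tab, 5000L), file.path(cfg$out_dir, "kmer_counts.tsv"))
    counts <- count_site_reads(last, sites)
    site_json <- file.path(cfg$out_dir, "site_counts.json")
    jsonlite::write_json(unclass(counts), site_json, auto_unbox = TRUE)
    for (p in c(file.path(cfg$out_dir, c("selex_cycle4.fasta",
                                         "kmer_counts.tsv")), site_json)) {
      emit(p)
    }
  }

  if ("popgen" %in% cfg$stages) {
    log_msg(cfg, "popgen", "simulating haplotypes and scanning EHH")
    pp <- utils::modifyList(
      list(n_haps = 60L, n_sites = 80L, derived_freq = 0.25,
           sweep_strength = 2, seed = child_seed(seed, 5)),
      cfg$popgen %||% list())
    haps <- do.call(generate_haplotypes, pp)
    write_vcf(haps, file.path(cfg$out_dir, "haplotypes.vcf"))
    scan <- ehh_scan(haps)
    prof <- rbind(scan$derived, scan$ancestral)
    prof$allele <- rep(c("derived", "ancestral"),
                       c(nrow(scan$derived), nrow(scan$ancestral)))
    write_tsv(prof, file.path(cfg$out_dir, "ehh_profile.tsv"))
    write_tsv(data.frame(iehh_derived = scan$iehh_derived,
                         iehh_ancestral = scan$iehh_ancestral,
                         ihs = scan$ihs),
              file.path(cfg$out_dir, "ihs.tsv"))
    for (p in file.path(cfg$out_dir, c("haplotypes.vcf", "ehh_profile.tsv",
                                       "ihs.tsv"))) emit(p)
  }

  if ("behavior" %in% cfg$stages) {
    log_msg(cfg, "behavior", "simulating T-maze trials")
    bp <- utils::modifyList(
      list(n_trials = 5L, n_flies = 100L, green_prob = 0.5,
           seed = child_seed(seed, 6)),
      cfg$behavior %||% list())
    trials <- do.call(generate_tmaze_trials, bp)
    trials$pi <- preference_index(trials$n_green, trials$n_blue)
    write_tsv(trials, file.path(cfg$out_dir, "tmaze_trials.tsv"))
    lm <- line_mean_pi(trials)
    write_tsv(data.frame(line_id = trials$line_id[1L],
                         mean_pi = lm$mean_pi, sem = lm$sem,
                         n_trials = lm$n_trials),
              file.path(cfg$out_dir, "tmaze_summary.tsv"))
    for (p in file.path(cfg$out_dir, c("tmaze_trials.tsv",
                                       "tmaze_summary.tsv"))) emit(p)
  }

  manifest <- list(
    seed = seed,
    stages = cfg$stages,
    artifacts = lapply(artifacts, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(unclass(cfg), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
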