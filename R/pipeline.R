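# End-to-end workflow: trait derivation -> precorrection -> QC -> GRM ->
# null REML + MLMA per trait -> one AWM per key trait -> gene tables and
# summaries -> genomic correlations -> heritability contrasts.

#' Pipeline configuration
#'
#' Either point `genotypes`/`phenotypes`/`annotation` at input files
#' (PLINK prefix, TSV, BED/GFF3), or supply `simulate` (a [sim_config()])
#' to generate a synthetic population in `out_dir`.
#'
#' @param out_dir Output directory.
#' @param genotypes PLINK prefix (`.bed`/`.bim`/`.fam`), or `NULL`.
#' @param phenotypes Phenotype TSV path, or `NULL`.
#' @param annotation BED/GFF3 path, or `NULL`.
#' @param qc_table Optional TSV with `variant_id` and QC columns
#'   (`call_rate`, `maf`, `hwe_p`, `imputation_r2`); when `NULL`, QC
#'   metrics are computed from the genotypes.
#' @param simulate Optional `sim_config` for synthetic mode.
#' @param key_traits Traits anchoring AWM runs.
#' @param traits Traits to scan.
#' @param qc_thresholds Passed to [qc_filter_variants()].
#' @param p_threshold,r_threshold,min_other_traits AWM parameters
#'   (defaults 0.001, 0.25, 2).
#' @param seed Global seed (random SNP panels of the heritability
#'   contrast).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       genotypes = NULL, phenotypes = NULL, annotation = NULL,
                       qc_table = NULL, simulate = NULL,
                       key_traits = c("RFI", "RG", "FE"),
                       traits = c("RFI", "RG", "FE", "FI", "FW", "ADG"),
                       qc_thresholds = list(call_rate = 0.90, maf = 0.01,
                                            hwe_p = 1e-4, r2 = 0.30),
                       p_threshold = 0.001, r_threshold = 0.25,
                       min_other_traits = 2L,
                       seed = 1L) {
  if (missing(out_dir) || !is.character(out_dir))
    stop_config("out_dir is required")
  if (is.null(simulate)) {
    for (p in c(genotypes = genotypes)) {
      if (is.null(p)) stop_config("either simulate or genotypes must be given")
      if (!file.exists(paste0(p, ".bed")))
        stop_config("genotype fileset not found at prefix: ", p)
    }
    for (p in c(phenotypes, annotation, qc_table))
      if (!is.null(p) && !file.exists(p)) stop_config("input not found: ", p)
    if (is.null(phenotypes)) stop_config("phenotypes are required")
    if (is.null(annotation)) stop_config("annotation is required")
  } else if (!inherits(simulate, "sim_config")) {
    stop_config("simulate must be a sim_config")
  }
  if (!all(key_traits %in% traits))
    stop_config("key_traits must be a subset of traits")
  # reuse awm_config validation for the shared thresholds
  awm_config(key_traits[1], p_threshold, r_threshold, min_other_traits)
  structure(list(
    out_dir = out_dir, genotypes = genotypes, phenotypes = phenotypes,
    annotation = annotation, qc_table = qc_table, simulate = simulate,
    key_traits = key_traits, traits = traits,
    qc_thresholds = qc_thresholds, p_threshold = p_threshold,
    r_threshold = r_threshold, min_other_traits = as.integer(min_other_traits),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields mirror the [run_config()] arguments; a `simulate` block
#' is forwarded to [sim_config()] (its `genetic_corr` may be a nested
#' list of rows with trait names).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    s <- y$simulate
    if (!is.null(s$genetic_corr)) {
      gc <- do.call(rbind, lapply(s$genetic_corr, unlist))
      colnames(gc) <- rownames(gc) <- names(s$genetic_corr)
      s$genetic_corr <- gc
    }
    if (!is.null(s$heritabilities)) s$heritabilities <- unlist(s$heritabilities)
    y$simulate <- do.call(sim_config, s)
  }
  do.call(run_config, y)
}

#' Run the whole analysis pipeline
#'
#' Executes every stage in order, writing each stage's outputs before the
#' next starts: derived and precorrected phenotype TSVs, a QC report,
#' per-trait GWAS summary TSVs, per-key-trait AWM and gene tables, a
#' summary JSON (gene counts per category, per-trait counts, gene overlap
#' between key traits), genomic-correlation and heritability-contrast
#' TSVs, and a JSON run manifest with per-file MD5 checksums.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop_config("cfg must be a run_config")
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(path) written <<- c(written, path)

  # --- inputs ---------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    pop <- simulate_population(cfg$simulate)
    paths <- write_population(pop, file.path(out, "sim"))
    for (p in paths) note(p)
    g <- pop$genotypes
    raw <- pop$traits
    ann <- pop$annotation
    qc_tab <- NULL
  } else {
    g <- read_plink(cfg$genotypes)
    raw <- read_phenotypes(cfg$phenotypes)
    ann <- read_annotation(cfg$annotation)
    qc_tab <- if (!is.null(cfg$qc_table))
      read.delim(cfg$qc_table, stringsAsFactors = FALSE) else NULL
  }
  common <- intersect(rownames(g$dosage), raw$animal_id)
  if (length(common) < 3) stop_data("genotypes and phenotypes share too few animals")
  g$dosage <- g$dosage[match(common, rownames(g$dosage)), , drop = FALSE]
  raw <- raw[match(common, raw$animal_id), , drop = FALSE]

  # --- traits ---------------------------------------------------------
  derived <- derive_traits(raw)
  note(write_tsv(derived, file.path(out, "phenotypes_derived.tsv")))
  corrected <- precorrect_phenotypes(derived, traits = cfg$traits)
  corr_out <- corrected
  names(corr_out) <- c("animal_id", paste0(cfg$traits, "_corrected"))
  note(write_tsv(corr_out, file.path(out, "phenotypes_corrected.tsv")))

  # --- QC -------------------------------------------------------------
  qc <- qc_tab %||% variant_qc(g)
  qcres <- qc_filter_variants(qc, cfg$qc_thresholds)
  note(write_tsv(data.frame(filter = names(qcres$counts),
                            n = as.integer(qcres$counts)),
                 file.path(out, "qc_report.tsv")))
  if (length(qcres$keep) == 0) stop_data("QC removed every variant")
  g <- subset_variants(g, qcres$keep)

  # --- GWAS -----------------------------------------------------------
  grm <- compute_grm(g)
  scan <- run_gwas(g, corrected, grm, traits = cfg$traits)
  for (p in write_gwas_results(scan$results, out)) note(p)
  vc_tab <- data.frame(
    trait = names(scan$varcomps),
    sigma_u2 = vapply(scan$varcomps, `[[`, numeric(1), "sigma_u2"),
    sigma_e2 = vapply(scan$varcomps, `[[`, numeric(1), "sigma_e2"),
    h2 = vapply(scan$varcomps, `[[`, numeric(1), "h2"),
    se_h2 = vapply(scan$varcomps, `[[`, numeric(1), "se_h2"))
  note(write_tsv(vc_tab, file.path(out, "variance_components.tsv")))

  # --- AWM per key trait ----------------------------------------------
  selections <- list()
  summaries <- list()
  cors <- list()
  contrasts <- list()
  for (key in cfg$key_traits) {
    acfg <- awm_config(key, cfg$p_threshold, cfg$r_threshold, cfg$min_other_traits)
    awm <- build_awm(scan$results, acfg)
    if (nrow(awm$z) == 0) {
      warning("empty AWM for key trait ", key, "; skipped")
      next
    }
    awm_tab <- cbind(awm$variants, origin = awm$origin,
                     setNames(as.data.frame(awm$z), paste0("z_", awm$traits)),
                     setNames(as.data.frame(awm$assoc), paste0("assoc_", awm$traits)))
    note(write_tsv(awm_tab, file.path(out, sprintf("awm_%s.tsv", key))))
    sel <- select_snp_per_gene(awm, ann)
    selections[[key]] <- sel
    note(write_tsv(as.data.frame(sel), file.path(out, sprintf("genes_%s.tsv", key))))
    summaries[[key]] <- summarize_network(sel)
    if (nrow(awm$z) >= 3 && length(awm$traits) >= 2)
      cors[[key]] <- genomic_correlation(awm)
    if (length(awm$variants$variant_id) >= 10 &&
        length(awm$variants$variant_id) * 2 <= ncol(g$dosage))
      contrasts[[key]] <- heritability_contrast(
        corrected[[key]], g, awm$variants$variant_id, seed = cfg$seed)
  }

  if (length(cors)) {
    # long format: retained trait sets can differ between AWM runs
    blocks <- do.call(rbind, lapply(names(cors), function(key) {
      r <- cors[[key]]$r
      pairs <- which(upper.tri(r, diag = TRUE), arr.ind = TRUE)
      data.frame(key_trait = key,
                 trait1 = rownames(r)[pairs[, 1]],
                 trait2 = colnames(r)[pairs[, 2]],
                 r = r[pairs], n_variants = cors[[key]]$n_variants,
                 row.names = NULL)
    }))
    note(write_tsv(blocks, file.path(out, "genomic_correlations.tsv")))
  }
  if (length(contrasts)) {
    ctab <- do.call(rbind, lapply(names(contrasts), function(key) {
      x <- contrasts[[key]]
      data.frame(trait = key, h2_selected = x$h2_selected,
                 se_selected = x$se_selected, h2_random = x$h2_random,
                 se_random = x$se_random, n_snps = x$n_snps, seed = x$seed)
    }))
    note(write_tsv(ctab, file.path(out, "h2_contrast.tsv")))
  }

  summary_json <- list(
    n_individuals = length(common),
    n_variants_post_qc = ncol(g$dosage),
    qc_counts = as.list(qcres$counts),
    awm = lapply(summaries, function(s)
      list(key_trait = s$key_trait, n_genes = s$n_genes,
           key_only = s$key_only, key_and_other = s$key_and_other,
           other_only = s$other_only, per_trait = as.list(s$per_trait)))
  )
  if (length(selections) >= 2) {
    ov <- gene_overlap(selections)
    summary_json$overlap <- list(shared_all = ov$shared_all,
                                 pairwise = ov$pairwise)
  }
  sj <- file.path(out, "summary.json")
  jsonlite::write_json(summary_json, sj, auto_unbox = TRUE, digits = NA)
  note(sj)

  manifest <- list(
    tool = "awmfe",
    version = as.character(packageVersion("awmfe")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = cfg[c("key_traits", "traits", "p_threshold", "r_threshold",
                   "min_other_traits", "seed")],
    checksums = as.list(tools::md5sum(written))
  )
  mj <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mj, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
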