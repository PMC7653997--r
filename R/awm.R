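# Association weight matrix (AWM) construction and gene selection.
#
# The AWM is a variant x trait matrix of z-score standardized additive
# effects anchored on a key phenotype. Construction is three-staged:
# (1) variants with P <= p_threshold for the key trait seed the rows;
# (2) the other traits are retained when their z-scores over the stage-1
#     rows correlate (|r| >= r_threshold) with the key trait's z-scores;
# (3) variants outside stage 1 are recruited when associated
#     (P <= p_threshold) with at least min_other_traits of the retained
#     non-key traits.
# One marker per gene is then chosen: the variant associated with the
# largest number of traits, ties broken by the lowest cumulated P-value
# over its associated traits, then by genomic position.

#' AWM configuration
#'
#' @param key_trait Trait label anchoring the matrix.
#' @param p_threshold Per-trait association threshold (default 0.001,
#'   inclusive).
#' @param r_threshold Absolute z-score correlation needed to retain a
#'   trait (default 0.25, inclusive).
#' @param min_other_traits Minimum number of retained non-key traits a
#'   secondary variant must be associated with (default 2).
#' @return An `awm_config` list.
#' @export
awm_config <- function(key_trait, p_threshold = 0.001, r_threshold = 0.25,
                       min_other_traits = 2L) {
  if (!is.character(key_trait) || length(key_trait) != 1)
    stop_config("key_trait must be a single trait label")
  if (!(p_threshold > 0 && p_threshold <= 1))
    stop_config("p_threshold must lie in (0, 1]")
  if (!(r_threshold > 0 && r_threshold <= 1))
    stop_config("r_threshold must lie in (0, 1]")
  if (!is_count(min_other_traits))
    stop_config("min_other_traits must be a positive integer")
  structure(list(key_trait = key_trait, p_threshold = p_threshold,
                 r_threshold = r_threshold,
                 min_other_traits = as.integer(min_other_traits)),
            class = "awm_config")
}

empty_awm <- function(traits, cfg) {
  z <- matrix(numeric(0), 0, length(traits), dimnames = list(NULL, traits))
  structure(list(z = z, p = z, assoc = z > 0,
                 origin = character(0),
                 variants = data.frame(variant_id = character(0),
                                       chrom = character(0), pos = integer(0)),
                 traits = traits, key_trait = cfg$key_trait,
                 trait_cor = setNames(numeric(0), character(0)), cfg = cfg),
            class = "awm_matrix")
}

#' Build an association weight matrix
#'
#' @param results Named list of `gwas_result` data.frames (one per
#'   trait, same variant universe in the same order), including the key
#'   trait.
#' @param cfg An `awm_config`.
#' @return An `awm_matrix`: `z`, `p`, `assoc` (variant x retained-trait
#'   matrices), `origin` (`"key"`/`"secondary"` per row), `variants`
#'   (id/chrom/pos), `traits` (retained, key first), `trait_cor`
#'   (z-score correlation of every non-key trait with the key over the
#'   stage-1 rows). If no variant passes stage 1 an empty matrix is
#'   returned with a warning.
#' @export
build_awm <- function(results, cfg) {
  if (!inherits(cfg, "awm_config")) stop_config("cfg must be an awm_config")
  if (!cfg$key_trait %in% names(results))
    stop_config("key trait '", cfg$key_trait, "' missing from results")
  ids <- results[[1]]$variant_id
  for (r in results) if (!identical(r$variant_id, ids))
    stop_data("all gwas_result tables must cover the same variants in the same order")
  traits <- names(results)
  Z <- matrix(unlist(lapply(results, `[[`, "z")), ncol = length(traits),
              dimnames = list(NULL, traits))
  P <- matrix(unlist(lapply(results, `[[`, "p")), ncol = length(traits),
              dimnames = list(NULL, traits))
  key <- cfg$key_trait

  stage1 <- P[, key] <= cfg$p_threshold
  if (!any(stage1)) {
    warning("no variant reaches the key-trait threshold; empty AWM returned")
    return(empty_awm(key, cfg))
  }
  others <- setdiff(traits, key)
  trait_cor <- vapply(others, function(tr) {
    zk <- Z[stage1, key]; zt <- Z[stage1, tr]
    if (sum(stage1) < 2 || sd(zk) == 0 || sd(zt) == 0) return(NA_real_)
    cor(zk, zt)
  }, numeric(1))
  retained_others <- others[!is.na(trait_cor) & abs(trait_cor) >= cfg$r_threshold]
  retained <- c(key, retained_others)

  if (length(retained_others) > 0) {
    n_other_assoc <- rowSums(P[, retained_others, drop = FALSE] <= cfg$p_threshold)
    stage3 <- !stage1 & n_other_assoc >= cfg$min_other_traits
  } else {
    stage3 <- rep(FALSE, length(ids))
  }
  rows <- which(stage1 | stage3)
  map <- results[[key]][rows, c("variant_id", "chrom", "pos")]
  rownames(map) <- NULL
  structure(list(
    z = Z[rows, retained, drop = FALSE],
    p = P[rows, retained, drop = FALSE],
    assoc = P[rows, retained, drop = FALSE] <= cfg$p_threshold,
    origin = ifelse(stage1[rows], "key", "secondary"),
    variants = map,
    traits = retained,
    key_trait = key,
    trait_cor = trait_cor,
    cfg = cfg
  ), class = "awm_matrix")
}

#' @export
print.awm_matrix <- function(x, ...) {
  cat(sprintf("<awm_matrix> key = %s: %d variants (%d key, %d secondary) x %d traits [%s]\n",
              x$key_trait, nrow(x$z), sum(x$origin == "key"),
              sum(x$origin == "secondary"), length(x$traits),
              paste(x$traits, collapse = ", ")))
  invisible(x)
}

#' Assign variants to genes
#'
#' A variant maps to a gene when its position lies within the gene body
#' (1-based closed interval, same chromosome; strand ignored). Variants
#' inside no gene are unassigned (`NA`). When genes overlap, the gene
#' whose midpoint is closest to the variant wins; remaining ties go to
#' the gene starting first.
#'
#' @param variants Data.frame with `variant_id`, `chrom`, `pos`.
#' @param ann A `gene_annotation` data.frame (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @return Character vector of gene ids (or `NA`), named by variant id.
#' @export
assign_genes <- function(variants, ann) {
  if (!all(c("variant_id", "chrom", "pos") %in% names(variants)))
    stop_data("variants needs variant_id, chrom, pos columns")
  if (!all(c("gene_id", "chrom", "start", "end") %in% names(ann)))
    stop_data("annotation needs gene_id, chrom, start, end columns")
  if (nrow(variants) == 0)
    return(setNames(character(0), character(0)))
  vchr <- unique(variants$chrom)
  achr <- unique(ann$chrom)
  if (length(intersect(vchr, achr)) == 0)
    stop_data("no chromosome label shared between variants [",
              paste(head(vchr, 5), collapse = ", "), "] and annotation [",
              paste(head(achr, 5), collapse = ", "), "]")
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  ggr <- GenomicRanges::GRanges(ann$chrom,
                                IRanges::IRanges(ann$start, ann$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vgr, ggr))
  out <- setNames(rep(NA_character_, nrow(variants)), variants$variant_id)
  if (length(hits) > 0) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    mid <- (ann$start[sh] + ann$end[sh]) / 2
    dist <- abs(variants$pos[qh] - mid)
    ord <- order(qh, dist, ann$start[sh], ann$gene_id[sh])
    first <- !duplicated(qh[ord])
    out[qh[ord][first]] <- ann$gene_id[sh[ord][first]]
  }
  out
}

#' Select one marker per gene from an AWM
#'
#' Within each gene, the AWM variant associated with the largest number
#' of retained traits is chosen; ties are broken by the lowest cumulated
#' P-value (arithmetic sum of P over the variant's associated traits),
#' then by genomic position. Variants falling in no gene are dropped
#' from the table and reported through the `"unassigned"` attribute.
#'
#' @param awm A non-empty `awm_matrix`.
#' @param gene_map Either a `gene_annotation` data.frame (genes are then
#'   assigned internally) or a character vector of gene ids named by (or
#'   aligned with) the AWM variants.
#' @return A `gene_selection` data.frame: `gene_id`, `variant_id`,
#'   `chrom`, `pos`, `n_traits_associated`, `traits` (comma-separated),
#'   `cum_p`; attributes `assoc` (gene x trait logical matrix for the
#'   chosen variants), `key_trait`, `unassigned` (variant ids outside
#'   genes).
#' @export
select_snp_per_gene <- function(awm, gene_map) {
  if (!inherits(awm, "awm_matrix")) stop_config("awm must be an awm_matrix")
  if (nrow(awm$z) == 0) stop_data("the AWM is empty")
  if (is.data.frame(gene_map)) gene_map <- assign_genes(awm$variants, gene_map)
  if (!is.null(names(gene_map)))
    gene_map <- gene_map[awm$variants$variant_id]
  if (length(gene_map) != nrow(awm$z))
    stop_data("gene_map does not align with the AWM variants")
  n_assoc <- rowSums(awm$assoc)
  cum_p <- rowSums(awm$p * awm$assoc)
  assigned <- which(!is.na(gene_map))
  sel_rows <- integer(0)
  genes <- character(0)
  for (gene in unique(gene_map[assigned])) {
    cand <- assigned[gene_map[assigned] == gene]
    ord <- order(-n_assoc[cand], cum_p[cand],
                 chrom_rank(awm$variants$chrom[cand]), awm$variants$pos[cand])
    sel_rows <- c(sel_rows, cand[ord[1]])
    genes <- c(genes, gene)
  }
  ord <- order(chrom_rank(awm$variants$chrom[sel_rows]), awm$variants$pos[sel_rows])
  sel_rows <- sel_rows[ord]
  genes <- genes[ord]
  assoc <- awm$assoc[sel_rows, , drop = FALSE]
  rownames(assoc) <- genes
  out <- data.frame(
    gene_id = genes,
    variant_id = awm$variants$variant_id[sel_rows],
    chrom = awm$variants$chrom[sel_rows],
    pos = awm$variants$pos[sel_rows],
    n_traits_associated = unname(n_assoc[sel_rows]),
    traits = vapply(sel_rows, function(i)
      paste(awm$traits[awm$assoc[i, ]], collapse = ","), character(1)),
    cum_p = unname(cum_p[sel_rows]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "assoc") <- assoc
  attr(out, "key_trait") <- awm$key_trait
  attr(out, "unassigned") <- awm$variants$variant_id[is.na(gene_map)]
  class(out) <- c("gene_selection", "data.frame")
  out
}

#' Summarize an AWM gene selection
#'
#' Counts genes by association pattern of their chosen marker: genes
#' associated with the key phenotype only, with the key plus at least
#' one other trait, and with other traits but not the key. The three
#' categories partition the gene total exactly. Per-trait gene counts
#' are also reported.
#'
#' @param sel A `gene_selection`.
#' @param key Key trait label (defaults to the one recorded in `sel`).
#' @return A `network_summary` list: `key_trait`, `n_genes`, `key_only`,
#'   `key_and_other`, `other_only`, `per_trait`.
#' @export
summarize_network <- function(sel, key = attr(sel, "key_trait")) {
  assoc <- attr(sel, "assoc")
  if (nrow(sel) == 0 || is.null(assoc)) {
    return(structure(list(key_trait = key, n_genes = 0L, key_only = 0L,
                          key_and_other = 0L, other_only = 0L,
                          per_trait = integer(0)),
                     class = "network_summary"))
  }
  if (!key %in% colnames(assoc)) stop_data("key trait absent from the selection")
  keyc <- assoc[, key]
  n_other <- rowSums(assoc[, setdiff(colnames(assoc), key), drop = FALSE])
  structure(list(
    key_trait = key,
    n_genes = nrow(assoc),
    key_only = sum(keyc & n_other == 0),
    key_and_other = sum(keyc & n_other > 0),
    other_only = sum(!keyc),
    per_trait = colSums(assoc)
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> key = %s: %d genes (%d key-only + %d key-and-other + %d other)\n",
              x$key_trait, x$n_genes, x$key_only, x$key_and_other, x$other_only))
  if (length(x$per_trait))
    cat("  per trait:", paste(sprintf("%s=%d", names(x$per_trait), x$per_trait),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Gene overlap between AWM runs
#'
#' @param selections Named list of `gene_selection` objects (one per key
#'   trait).
#' @return A list with `shared_all` (gene ids selected in every run) and
#'   `pairwise` (matrix of shared-gene counts).
#' @export
gene_overlap <- function(selections) {
  if (length(selections) < 2) stop_config("need at least two selections")
  ids <- lapply(selections, function(s) s$gene_id)
  k <- length(ids)
  pw <- matrix(0L, k, k, dimnames = list(names(ids), names(ids)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(ids[[i]], ids[[j]]))
  list(shared_all = Reduce(intersect, ids), pairwise = pw)
}
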