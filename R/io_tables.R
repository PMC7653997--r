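# TSV phenotype tables and BED/GFF3 gene annotations.

#' Read a phenotype table
#'
#' Tab-separated with a header; missing values encoded as `NA` are
#' rejected in required fields.
#'
#' @param path TSV path.
#' @param required Columns that must be present and complete.
#' @return A data.frame.
#' @export
read_phenotypes <- function(path,
                            required = c("animal_id", "year", "dam_age_class",
                                         "twinning", "final_age", "test_days",
                                         "initial_weight", "final_weight", "FI")) {
  if (!file.exists(path)) stop_data("missing file: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop_data("phenotype table lacks required columns: ",
              paste(miss, collapse = ", "))
  bad <- required[vapply(d[required], anyNA, logical(1))]
  if (length(bad))
    stop_data("NA values in required phenotype columns: ",
              paste(bad, collapse = ", "))
  d$animal_id <- as.character(d$animal_id)
  d
}

#' Write a tab-separated table
#'
#' @param d A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(d, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
write_phenotypes <- function(d, path) write_tsv(d, path)

#' Read a gene annotation (BED or GFF3)
#'
#' BED input (0-based half-open) and GFF3 input (1-based closed) are both
#' normalized to 1-based closed intervals; for GFF3, only `gene` features
#' are kept when a type column is present. Gene ids come from the BED
#' name column or the GFF3 `ID`/`Name`/`gene_id` attribute.
#'
#' @param path File ending in `.bed`, `.gff`, `.gff3` (optionally `.gz`).
#' @return A `gene_annotation` data.frame: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_data("missing file: ", path)
  base <- sub("\\.gz$", "", path)
  fmt <- if (grepl("\\.bed$", base, ignore.case = TRUE)) "BED"
         else if (grepl("\\.gff3?$", base, ignore.case = TRUE)) "GFF3"
         else stop_data("unrecognized annotation extension: ", basename(path))
  gr <- rtracklayer::import(path, format = fmt)
  mc <- S4Vectors::mcols(gr)
  if (fmt == "GFF3" && "type" %in% names(mc) && any(mc$type == "gene"))
    gr <- gr[mc$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  gene_id <- NULL
  for (col in c("ID", "Name", "gene_id", "name"))
    if (is.null(gene_id) && col %in% names(mc)) gene_id <- as.character(mc[[col]])
  if (is.null(gene_id)) gene_id <- sprintf("gene%05d", seq_along(gr))
  ann <- data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann$gene_id)) stop_data("duplicated gene ids in annotation")
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write a gene annotation as GFF3 or BED
#'
#' @param ann A `gene_annotation` data.frame (1-based closed intervals).
#' @param path Output path.
#' @param format `"gff3"` or `"bed"` (BED is written 0-based half-open).
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(ann, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  gr <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$start, ann$end),
    strand = ifelse(ann$strand %in% c("+", "-"), ann$strand, "*")
  )
  if (format == "gff3") {
    S4Vectors::mcols(gr)$ID <- ann$gene_id
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$source <- "awmfe"
    rtracklayer::export(gr, path, format = "GFF3")
  } else {
    S4Vectors::mcols(gr)$name <- ann$gene_id
    rtracklayer::export(gr, path, format = "BED")
  }
  invisible(path)
}

#' Write per-trait GWAS summary statistics
#'
#' One TSV per trait: `variant_id`, `chrom`, `pos`, `maf`, `beta`, `se`,
#' `z`, `p`.
#'
#' @param results Named list of `gwas_result` data.frames.
#' @param dir Output directory.
#' @return Invisibly, the written paths (named by trait).
#' @export
write_gwas_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(results), function(tr) {
    p <- file.path(dir, sprintf("gwas_%s.tsv", tr))
    write_tsv(results[[tr]][, c("variant_id", "chrom", "pos", "maf",
                                "beta", "se", "z", "p")], p)
    p
  }, character(1))
  invisible(paths)
}

#' Read one per-trait GWAS summary TSV
#'
#' @param path TSV written by [write_gwas_results()].
#' @return A `gwas_result` data.frame.
#' @export
read_gwas_result <- function(path) {
  if (!file.exists(path)) stop_data("missing file: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  need <- c("variant_id", "chrom", "pos", "beta", "se", "z", "p")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_data("summary table lacks columns: ", paste(miss, collapse = ", "))
  class(d) <- c("gwas_result", "data.frame")
  d
}
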