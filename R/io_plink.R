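# PLINK 1 binary genotype I/O (BED/BIM/FAM triplet, variant-major BED).
# Two bits per genotype: 00 = two copies of allele 1, 10 = heterozygote,
# 11 = zero copies, 01 = missing. Dosages count allele 1 (the BIM A1
# column), so 00 -> 2, 10 -> 1, 11 -> 0.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: dosage of the 4 genotypes packed in one byte.
bed_byte_lookup <- function() {
  dec <- c(2L, NA_integer_, 1L, 0L)  # two-bit codes 00, 01, 10, 11
  b <- 0:255
  cbind(dec[b %% 4 + 1], dec[(b %/% 4) %% 4 + 1],
        dec[(b %/% 16) %% 4 + 1], dec[(b %/% 64) %% 4 + 1])
}

#' Read a PLINK BED/BIM/FAM triplet
#'
#' Decodes a variant-major PLINK 1 binary fileset into dosages of the A1
#' allele. Missing genotypes are returned as `NA` (they are mean-imputed
#' later, at GRM/scan time, with a logged count). BIM positions are
#' 1-based.
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A `geno_matrix`.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop_data("missing file: ", p)
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "variant_id", "cm", "pos", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || !identical(raw[1:2], .bed_magic[1:2]))
    stop_data("not a PLINK BED file (magic bytes ",
              paste(sprintf("0x%02x", as.integer(raw[seq_len(min(2, length(raw)))])),
                    collapse = " "), " at offset 0)")
  if (raw[3] != .bed_magic[3])
    stop_data("BED file is not in variant-major mode (mode byte at offset 2)")
  bpv <- ceiling(n / 4)
  expected <- 3 + bpv * m
  if (length(raw) != expected)
    stop_data(sprintf(
      "BED payload is %d bytes but BIM/FAM imply %d (%d variants x %d bytes + 3); first mismatch at byte offset %d",
      length(raw), expected, m, bpv, min(length(raw), expected)))
  lut <- bed_byte_lookup()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  dosage <- matrix(NA_integer_, n, m)
  for (slot in 1:4) {
    if (slot > n) next
    rows <- seq(slot, n, by = 4)
    dosage[rows, ] <- lut[body[seq_along(rows), , drop = FALSE] + 1L, slot]
  }
  rownames(dosage) <- as.character(fam[[2]])
  new_geno_matrix(dosage, bim[, c("variant_id", "chrom", "pos", "a1", "a2")])
}

#' Write a PLINK BED/BIM/FAM triplet
#'
#' Inverse of [read_plink()]: dosages are encoded as counts of A1,
#' `NA` as the missing code. The BED is variant-major.
#'
#' @param g A `geno_matrix`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three written paths.
#' @export
write_plink <- function(g, prefix) {
  X <- g$dosage
  n <- nrow(X)
  m <- ncol(X)
  map <- g$map
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  bim <- data.frame(map$chrom, map$variant_id, 0, map$pos,
                    map$a1 %||% "A", map$a2 %||% "B")
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ids <- rownames(X)
  fam <- data.frame(ids, ids, 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # dosage -> two-bit code: 2 -> 0, 1 -> 2, 0 -> 3, NA -> 1
  code <- matrix(3L, n, m)
  code[!is.na(X) & X == 2] <- 0L
  code[!is.na(X) & X == 1] <- 2L
  code[is.na(X)] <- 1L
  pad <- (4 - n %% 4) %% 4
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  i1 <- seq(1, nrow(code), by = 4)
  bytes <- code[i1, , drop = FALSE] + 4L * code[i1 + 1, , drop = FALSE] +
    16L * code[i1 + 2, , drop = FALSE] + 64L * code[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
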