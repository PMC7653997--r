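# Variant QC and the genomic relationship matrix.

#' Per-variant QC metrics from genotypes
#'
#' Computes call rate, folded minor allele frequency and a 1-df
#' chi-square Hardy-Weinberg test P-value per variant. Fractional
#' (imputed) dosages are rounded to the nearest genotype class for the
#' HWE count table only.
#'
#' @param g A `geno_matrix`.
#' @return A data.frame: `variant_id`, `call_rate`, `maf`, `hwe_p`.
#' @export
variant_qc <- function(g) {
  X <- g$dosage
  n <- nrow(X)
  call_rate <- 1 - colSums(is.na(X)) / n
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  Xr <- round(X)
  n0 <- colSums(Xr == 0, na.rm = TRUE)
  n1 <- colSums(Xr == 1, na.rm = TRUE)
  n2 <- colSums(Xr == 2, na.rm = TRUE)
  nn <- n0 + n1 + n2
  pa <- (2 * n2 + n1) / (2 * nn)
  e0 <- nn * (1 - pa)^2; e1 <- nn * 2 * pa * (1 - pa); e2 <- nn * pa^2
  chi <- (n0 - e0)^2 / pmax(e0, 1e-12) +
         (n1 - e1)^2 / pmax(e1, 1e-12) +
         (n2 - e2)^2 / pmax(e2, 1e-12)
  hwe_p <- pchisq(chi, df = 1, lower.tail = FALSE)
  hwe_p[pa == 0 | pa == 1] <- 1
  data.frame(variant_id = g$map$variant_id, call_rate = call_rate,
             maf = maf, hwe_p = hwe_p, stringsAsFactors = FALSE)
}

#' Filter variants on QC thresholds
#'
#' Retains variants with call rate at or above the threshold, MAF
#' strictly above the threshold, HWE P-value at or above the threshold
#' (strong deviations removed), and -- when an `imputation_r2` column is
#' present -- imputation R2 strictly above the threshold. The strict ">"
#' on MAF and R2 follows the usual "higher than" convention for imputed
#' sequence data (R2 > 0.30, MAF > 0.01).
#'
#' @param qc A data.frame with `variant_id` and any of `call_rate`,
#'   `maf`, `hwe_p`, `imputation_r2`.
#' @param thresholds Named list; defaults `call_rate = 0.90`,
#'   `maf = 0.01`, `hwe_p = 1e-4`, `r2 = 0.30`.
#' @return A `qc_result`: list with `keep` (retained variant ids) and
#'   `counts` (variants entering, failing each filter, and retained).
#'   Filters whose column is absent are skipped.
#' @export
qc_filter_variants <- function(qc,
                               thresholds = list(call_rate = 0.90, maf = 0.01,
                                                 hwe_p = 1e-4, r2 = 0.30)) {
  if (!"variant_id" %in% names(qc)) stop_data("qc table needs a variant_id column")
  thr <- utils::modifyList(list(call_rate = 0.90, maf = 0.01,
                                hwe_p = 1e-4, r2 = 0.30), thresholds)
  for (v in unlist(thr)) if (!is.na(v) && (v < 0 || v > 1))
    stop_config("QC thresholds must lie in [0, 1]")
  n <- nrow(qc)
  ok <- rep(TRUE, n)
  counts <- c(n_input = n)
  apply_filter <- function(pass, label) {
    counts[label] <<- sum(ok & !pass)
    ok <<- ok & pass
  }
  if ("call_rate" %in% names(qc))
    apply_filter(qc$call_rate >= thr$call_rate, "fail_call_rate")
  if ("maf" %in% names(qc))
    apply_filter(qc$maf > thr$maf, "fail_maf")
  if ("hwe_p" %in% names(qc))
    apply_filter(qc$hwe_p >= thr$hwe_p, "fail_hwe")
  if ("imputation_r2" %in% names(qc))
    apply_filter(is.na(qc$imputation_r2) | qc$imputation_r2 > thr$r2, "fail_r2")
  counts["n_retained"] <- sum(ok)
  if (!any(ok)) message("QC retained no variants")
  structure(list(keep = qc$variant_id[ok], counts = counts,
                 thresholds = thr), class = "qc_result")
}

#' Subset a genotype matrix by variant ids
#'
#' @param g A `geno_matrix`.
#' @param ids Variant ids to keep (order taken from the map).
#' @return A `geno_matrix` restricted to `ids`.
#' @export
subset_variants <- function(g, ids) {
  keep <- g$map$variant_id %in% ids
  if (!any(keep)) stop_data("none of the requested variant ids are present")
  new_geno_matrix(g$dosage[, keep, drop = FALSE], g$map[keep, , drop = FALSE])
}

# Mean-impute missing dosages column-wise; used by GRM and MLMA.
impute_dosage <- function(X) {
  nmiss <- sum(is.na(X))
  if (nmiss > 0) {
    message(sprintf("mean-imputing %d missing genotype calls", nmiss))
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  X
}

#' Genomic relationship matrix (frequency-centered)
#'
#' VanRaden's first method: \eqn{G = Z Z' / (2 \sum_k p_k (1 - p_k))}
#' where Z is the dosage matrix centered by twice the allele frequency.
#' Under random mating the mean diagonal is close to 1. Monomorphic
#' variants are excluded; missing calls are mean-imputed with a message.
#'
#' @param g A `geno_matrix`.
#' @return A `grm`: list with `K` (n x n matrix), `n_snps_used`, `ids`.
#' @export
compute_grm <- function(g) {
  X <- impute_dosage(g$dosage)
  if (nrow(X) < 2) stop_data("need at least two individuals")
  p <- colMeans(X) / 2
  colvar <- colMeans(X^2) - colMeans(X)^2
  poly <- p > 0 & p < 1 & colvar > 1e-12
  if (!any(poly)) stop_data("all variants are monomorphic; GRM undefined")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  K <- (K + t(K)) / 2
  structure(list(K = K, n_snps_used = sum(poly), ids = rownames(X)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d individuals, %d SNPs, mean diagonal %.3f\n",
              nrow(x$K), x$n_snps_used, mean(diag(x$K))))
  invisible(x)
}

#' Eigendecomposition of a GRM
#'
#' Computed once per GRM and shared between the REML fit and the
#' per-variant scan (the rotated model is diagonal, so every variant test
#' is O(n)). Tiny negative eigenvalues are floored at zero.
#'
#' @param grm A `grm`.
#' @return A list with `values` and `vectors`.
#' @export
grm_eigen <- function(grm) {
  e <- eigen(grm$K, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e
}

#' Bonferroni significance threshold on the -log10 scale
#'
#' @param alpha Family-wise error rate, in (0, 1].
#' @param m Number of tests (>= 1).
#' @return `-log10(alpha / m)`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha <= 1))
    stop_config("alpha must lie in (0, 1]")
  if (!is_count(m)) stop_config("m must be a positive integer")
  -log10(alpha / m)
}

#' Top associated variants
#'
#' Ranks a scan result by ascending P-value, breaking ties by genomic
#' coordinates, and returns the first `k` variants. When an annotation is
#' supplied, each variant is paired with the gene it falls in (strictly
#' within gene bodies; `NA` otherwise).
#'
#' @param res A `gwas_result` data.frame (from [run_mlma()]).
#' @param k Number of variants to return.
#' @param annotation Optional `gene_annotation`.
#' @return The top-`k` rows of `res`, with a `gene_id` column when
#'   `annotation` is given.
#' @export
top_k_variants <- function(res, k, annotation = NULL) {
  if (!is_count(k)) stop_config("k must be a positive integer")
  ord <- order(res$p, chrom_rank(res$chrom), res$pos)
  out <- res[head(ord, k), , drop = FALSE]
  if (!is.null(annotation))
    out$gene_id <- assign_genes(out, annotation)
  rownames(out) <- NULL
  out
}
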