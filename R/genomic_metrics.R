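# Post-AWM quantitative genetics: z-score genomic correlations between
# traits and GREML SNP-heritability of selected versus random panels.

#' Genomic correlations from AWM z-scores
#'
#' Pearson correlation between every pair of retained traits' z-score
#' columns over all AWM rows -- a summary-statistic proxy for the
#' genetic correlation restricted to the co-associated variant set.
#'
#' @param awm An `awm_matrix` with at least 3 rows and 2 retained traits.
#' @return A `genomic_cor`: list with `r` (symmetric correlation matrix,
#'   unit diagonal), `traits`, `n_variants`.
#' @export
genomic_correlation <- function(awm) {
  if (!inherits(awm, "awm_matrix")) stop_config("awm must be an awm_matrix")
  if (nrow(awm$z) < 3)
    stop_data("genomic correlations need at least 3 AWM variants")
  if (length(awm$traits) < 2)
    stop_data("genomic correlations need at least 2 retained traits")
  r <- cor(awm$z)
  structure(list(r = r, traits = awm$traits, n_variants = nrow(awm$z),
                 key_trait = awm$key_trait),
            class = "genomic_cor")
}

#' @export
print.genomic_cor <- function(x, ...) {
  cat(sprintf("<genomic_cor> key = %s, %d variants\n", x$key_trait, x$n_variants))
  print(round(x$r, 2))
  invisible(x)
}

#' SNP-based heritability from a marker subset (GREML)
#'
#' Builds a genomic relationship matrix from the given variant subset
#' only and estimates the fraction of phenotypic variance it captures by
#' restricted maximum likelihood ([fit_null_reml()]).
#'
#' @param y Corrected trait vector.
#' @param g A `geno_matrix`.
#' @param snp_subset Character vector of variant ids (>= 10, polymorphic).
#' @return A `varcomp` (see [fit_null_reml()]) with the panel size
#'   attached as attribute `"n_snps"`.
#' @export
greml_h2 <- function(y, g, snp_subset) {
  if (length(snp_subset) == 0) stop_data("snp_subset is empty")
  if (length(snp_subset) < 10)
    stop_data("snp_subset must contain at least 10 variants")
  gs <- subset_variants(g, snp_subset)
  grm <- compute_grm(gs)
  vc <- fit_null_reml(y, grm)
  attr(vc, "n_snps") <- grm$n_snps_used
  vc
}

#' Heritability contrast: selected versus random SNP panels
#'
#' Estimates the SNP-based heritability captured by a selected panel
#' (e.g. the AWM variants) and by an equal-size panel drawn uniformly
#' without replacement from the remaining variants, mirroring the
#' selected-versus-random comparison used to judge how much signal a
#' co-association analysis concentrates.
#'
#' @param y Corrected trait vector.
#' @param g A `geno_matrix`.
#' @param selected Character vector of selected variant ids.
#' @param seed Integer seed for the random draw.
#' @return An `h2_contrast`: list with `trait_n`, `h2_selected`,
#'   `se_selected`, `h2_random`, `se_random`, `n_snps`, `seed`,
#'   `random_panel`.
#' @export
heritability_contrast <- function(y, g, selected, seed = 1L) {
  if (length(selected) == 0) stop_data("selected panel is empty")
  selected <- unique(selected)
  all_ids <- g$map$variant_id
  missing <- setdiff(selected, all_ids)
  if (length(missing))
    stop_data("selected ids absent from the genotypes: ",
              paste(head(missing, 5), collapse = ", "))
  remaining <- setdiff(all_ids, selected)
  if (length(remaining) < length(selected))
    stop_data("not enough remaining variants to draw an equal-size random panel")
  set.seed(seed)
  random_panel <- sample(remaining, length(selected))
  vc_sel <- greml_h2(y, g, selected)
  vc_ran <- greml_h2(y, g, random_panel)
  structure(list(
    n = length(y),
    h2_selected = vc_sel$h2, se_selected = vc_sel$se_h2,
    h2_random = vc_ran$h2, se_random = vc_ran$se_h2,
    n_snps = length(selected), seed = as.integer(seed),
    random_panel = random_panel
  ), class = "h2_contrast")
}

#' @export
print.h2_contrast <- function(x, ...) {
  cat(sprintf("<h2_contrast> %d SNPs/panel: h2 selected = %.3f (SE %.3f), random = %.3f (SE %.3f)\n",
              x$n_snps, x$h2_selected, x$se_selected, x$h2_random, x$se_random))
  invisible(x)
}
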