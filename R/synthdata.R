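# Synthetic population generator: genotypes with block LD, multi-trait
# phenotypes with target heritabilities and genetic correlations, and a
# synthetic gene annotation. Defaults emulate the design of a French
# Charolais feed-efficiency experiment: ~789 genotyped growing bulls,
# moderate heritabilities (0.35) and the pedigree-level genetic
# correlations among daily feed intake (FI), average daily gain (ADG)
# and final weight (FW).

.base_traits <- c("FI", "ADG", "FW")
.trait_means <- c(FI = 10.63, ADG = 1.44, FW = 695)
.trait_sds   <- c(FI = 1.23,  ADG = 0.19, FW = 87)

#' Default genetic correlation matrix for the base traits
#'
#' Pedigree-scale genetic correlations among daily feed intake (FI),
#' average daily gain (ADG) and final weight (FW) typical of growing
#' beef bulls: r(FI,ADG) = 0.44, r(FI,FW) = 0.76, r(ADG,FW) = 0.80.
#'
#' @return A symmetric 3 x 3 correlation matrix with unit diagonal,
#'   dimnames `FI`, `ADG`, `FW`.
#' @export
default_genetic_corr <- function() {
  R <- diag(3)
  dimnames(R) <- list(.base_traits, .base_traits)
  R["FI", "ADG"] <- R["ADG", "FI"] <- 0.44
  R["FI", "FW"]  <- R["FW", "FI"]  <- 0.76
  R["ADG", "FW"] <- R["FW", "ADG"] <- 0.80
  R
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic population. Defaults emulate
#' the genotyped subset of a growing-bull feed-efficiency design: 789
#' individuals, tens of thousands of SNPs, heritabilities of 0.35 for the
#' base traits, 22 contemporary-group year classes, four dam-age classes,
#' a small twinning rate and a 175-day test period.
#'
#' @param n_individuals Number of individuals.
#' @param n_variants Number of variants.
#' @param maf_range Length-2 numeric, lower/upper bound of simulated minor
#'   allele frequencies, in (0, 0.5].
#' @param n_causal Number of causal variants (all pleiotropic across the
#'   base traits).
#' @param heritabilities Named vector of h2 in \[0, 1\] for `FI`, `ADG`, `FW`.
#' @param genetic_corr Symmetric positive semi-definite correlation matrix
#'   across the base traits (unit diagonal).
#' @param n_years Number of contemporary-group year classes.
#' @param dam_age_classes Number of dam-age classes (4 gives the
#'   conventional 3/4/5/6+ coding).
#' @param twinning_rate Probability that an animal is born twin.
#' @param test_days Length of the feeding test, days.
#' @param ld_block_size Variants per LD block (1 = independent variants).
#' @param ld_rho Latent AR(1) correlation between adjacent variants within
#'   an LD block.
#' @param n_chrom Number of chromosomes the variants are spread over.
#' @param n_genes Number of genes in the synthetic annotation.
#' @param gene_coverage Fraction of variants that fall inside genes.
#' @param seed Integer seed; the whole population is deterministic given
#'   the config.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 789L,
                       n_variants = 20000L,
                       maf_range = c(0.05, 0.5),
                       n_causal = 300L,
                       heritabilities = c(FI = 0.35, ADG = 0.35, FW = 0.35),
                       genetic_corr = default_genetic_corr(),
                       n_years = 22L,
                       dam_age_classes = 4L,
                       twinning_rate = 0.03,
                       test_days = 175L,
                       ld_block_size = 1L,
                       ld_rho = 0.8,
                       n_chrom = 10L,
                       n_genes = 1000L,
                       gene_coverage = 0.4,
                       seed = 1L) {
  if (!is_count(n_individuals) || n_individuals < 2)
    stop_config("n_individuals must be an integer >= 2")
  if (!is_count(n_variants)) stop_config("n_variants must be a positive integer")
  check_maf_range(maf_range)
  if (!is_count(n_causal) || n_causal > n_variants)
    stop_config("n_causal must be a positive integer <= n_variants")
  if (n_causal < 3)
    stop_config("n_causal must be >= 3 to support a 3-trait genetic covariance")
  if (!all(.base_traits %in% names(heritabilities)))
    stop_config("heritabilities must be named and cover FI, ADG, FW")
  h2 <- heritabilities[.base_traits]
  if (any(h2 < 0 | h2 > 1)) stop_config("heritabilities must lie in [0, 1]")
  if (!is.matrix(genetic_corr) ||
      !all(.base_traits %in% rownames(genetic_corr)) ||
      !all(.base_traits %in% colnames(genetic_corr)))
    stop_config("genetic_corr must be a matrix with FI, ADG, FW dimnames")
  R <- genetic_corr[.base_traits, .base_traits]
  if (max(abs(R - t(R))) > 1e-10) stop_config("genetic_corr must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) stop_config("genetic_corr must have a unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop_config("genetic_corr must be positive semi-definite")
  if (!is_count(n_years) || !is_count(dam_age_classes))
    stop_config("n_years and dam_age_classes must be positive integers")
  if (twinning_rate < 0 || twinning_rate > 1)
    stop_config("twinning_rate must be a probability")
  if (!is_count(test_days)) stop_config("test_days must be a positive integer")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range),
    n_causal = as.integer(n_causal),
    heritabilities = h2,
    genetic_corr = R,
    n_years = as.integer(n_years),
    dam_age_classes = as.integer(dam_age_classes),
    twinning_rate = twinning_rate,
    test_days = as.integer(test_days),
    ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho,
    n_chrom = as.integer(n_chrom),
    n_genes = as.integer(n_genes),
    gene_coverage = gene_coverage,
    seed = as.integer(seed)
  ), class = "sim_config")
}

check_maf_range <- function(maf_range) {
  if (length(maf_range) != 2 || !is.numeric(maf_range) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_config("maf_range must satisfy 0 < low <= high <= 0.5")
  invisible(maf_range)
}

new_geno_matrix <- function(dosage, map) {
  stopifnot(ncol(dosage) == nrow(map))
  rownames(dosage) <- rownames(dosage) %||% sprintf("ind%05d", seq_len(nrow(dosage)))
  colnames(dosage) <- map$variant_id
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d variants, %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Empirical minor allele frequencies
#'
#' @param g A `geno_matrix`.
#' @return Numeric vector of per-variant folded allele frequencies
#'   `min(p, 1 - p)` where `p` is the mean dosage / 2.
#' @export
geno_maf <- function(g) {
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Simulate genotype dosages with block linkage disequilibrium
#'
#' Draws two haplotypes per individual through a Gaussian copula: each
#' variant's latent value follows an AR(1) process within its LD block
#' (independent across blocks), and the allele is the latent value
#' thresholded at the normal quantile of the variant's allele frequency.
#' Marginal frequencies are therefore exact while adjacent variants in a
#' block are positively correlated.
#'
#' @param n Number of individuals (>= 2).
#' @param m Number of variants (>= 1).
#' @param maf_range Length-2 vector in (0, 0.5]; per-variant allele
#'   frequencies are drawn uniformly within it.
#' @param ld_block_size Variants per LD block; 1 gives independent variants.
#' @param ld_rho AR(1) correlation of the latent process within a block.
#' @param n_chrom Number of chromosomes (contiguous variant chunks).
#' @param seed Integer seed; output is deterministic given the arguments.
#'
#' @return A `geno_matrix`: integer dosages in \{0, 1, 2\} (individuals x
#'   variants) plus a variant map (`variant_id`, `chrom`, `pos`, `a1`, `a2`).
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               ld_block_size = 1L, ld_rho = 0.8,
                               n_chrom = 1L, seed = 1L) {
  if (!is_count(n) || n < 2) stop_config("n must be an integer >= 2")
  if (!is_count(m)) stop_config("m must be a positive integer")
  check_maf_range(maf_range)
  if (!is_count(ld_block_size)) stop_config("ld_block_size must be a positive integer")
  if (!is_count(n_chrom) || n_chrom > m) stop_config("n_chrom must be in [1, m]")
  set.seed(seed)
  maf <- runif(m, maf_range[1], maf_range[2])
  chrom_sizes <- diff(floor(seq(0, m, length.out = n_chrom + 1)))
  chrom <- rep(seq_len(n_chrom), chrom_sizes)
  pos <- unlist(lapply(split(seq_len(m), factor(chrom, levels = seq_len(n_chrom))),
                       function(i) seq_along(i) * 1000L), use.names = FALSE)
  # block index restarts at each chromosome
  block <- unlist(lapply(split(seq_len(m), factor(chrom, levels = seq_len(n_chrom))),
                         function(i) ceiling(seq_along(i) / ld_block_size)),
                  use.names = FALSE)
  block_id <- cumsum(c(TRUE, diff(block) != 0 | diff(chrom) != 0))
  thr <- qnorm(maf)
  draw_hap <- function() {
    Z <- matrix(rnorm(n * m), n, m)
    if (ld_block_size > 1L && ld_rho > 0) {
      same <- c(FALSE, block_id[-1] == block_id[-m])
      sq <- sqrt(1 - ld_rho^2)
      for (j in which(same)) Z[, j] <- ld_rho * Z[, j - 1L] + sq * Z[, j]
    }
    # column-major recycling of thr matches matrix layout
    (Z < rep(thr, each = n)) * 1L
  }
  dosage <- draw_hap() + draw_hap()
  storage.mode(dosage) <- "integer"
  map <- data.frame(
    variant_id = sprintf("var%06d", seq_len(m)),
    chrom = as.character(chrom),
    pos = pos,
    a1 = "A", a2 = "B",
    stringsAsFactors = FALSE
  )
  new_geno_matrix(dosage, map)
}

#' Simulate phenotypes for the base traits
#'
#' Generates FI, ADG and FW records as the sum of a trait mean, fixed
#' effects (contemporary-group year, dam-age class, twinning, a final-age
#' covariate), a genomic breeding value built from causal-variant dosages,
#' and residual noise. Causal effects are drawn from a multivariate normal
#' across traits and then rotated/scaled so that the realized breeding
#' values match `cfg$genetic_corr` and `cfg$heritabilities` exactly
#' (heritability measured against the nominal phenotypic variances).
#' Initial weight and test length are emitted so that ADG and metabolic
#' mid-test weight are derivable downstream.
#'
#' @param g A `geno_matrix` (the causal variants are drawn from it).
#' @param cfg A `sim_config`; `cfg$seed` makes the output deterministic.
#'
#' @return A `data.frame` (one row per individual) with columns
#'   `animal_id`, `year`, `dam_age_class`, `twinning`, `final_age`,
#'   `test_days`, `initial_weight`, `final_weight`, `FI`, `ADG`, `FW`,
#'   and attributes `true_bv` (n x 3 breeding-value matrix),
#'   `genetic_score` (unit-variance genetic values, defined even at
#'   h2 = 0) and `causal_ids`.
#' @export
simulate_traits <- function(g, cfg) {
  if (!inherits(g, "geno_matrix")) stop_config("g must be a geno_matrix")
  if (!inherits(cfg, "sim_config")) stop_config("cfg must be a sim_config")
  X <- g$dosage
  n <- nrow(X)
  m <- ncol(X)
  if (cfg$n_causal > m) stop_config("n_causal exceeds the number of variants in g")
  h2 <- cfg$heritabilities
  R <- cfg$genetic_corr
  set.seed(cfg$seed)

  causal <- sort(sample.int(m, cfg$n_causal))
  pc <- colMeans(X[, causal, drop = FALSE]) / 2
  Zc <- sweep(X[, causal, drop = FALSE], 2, 2 * pc)
  B <- matrix(rnorm(cfg$n_causal * 3), cfg$n_causal, 3)
  Graw <- scale(Zc %*% B, center = TRUE, scale = FALSE)
  S <- crossprod(Graw) / (n - 1)
  W <- tryCatch(
    solve(chol(S)) %*% chol(R + diag(1e-10, 3)),
    error = function(e) stop_numeric(
      "failed to match the target genetic covariance (", conditionMessage(e), ")")
  )
  Gstd <- Graw %*% W                       # realized covariance == R
  colnames(Gstd) <- .base_traits
  bv <- Gstd %*% diag(sqrt(h2) * .trait_sds[.base_traits], 3)
  colnames(bv) <- .base_traits

  year <- factor(sprintf("Y%02d", sample.int(cfg$n_years, n, replace = TRUE)),
                 levels = sprintf("Y%02d", seq_len(cfg$n_years)))
  dam_levels <- if (cfg$dam_age_classes == 4L) c("3", "4", "5", "6+")
                else as.character(seq_len(cfg$dam_age_classes))
  dam <- factor(sample(dam_levels, n, replace = TRUE), levels = dam_levels)
  twin <- runif(n) < cfg$twinning_rate
  final_age <- round(rnorm(n, 450, 10))

  pheno <- matrix(0, n, 3, dimnames = list(NULL, .base_traits))
  for (t in .base_traits) {
    sdp <- .trait_sds[[t]]
    year_eff <- setNames(rnorm(nlevels(year), 0, 0.5 * sdp), levels(year))
    dam_eff <- setNames(rnorm(length(dam_levels), 0, 0.25 * sdp), dam_levels)
    twin_off <- -0.25 * sdp
    age_slope <- 0.025 * sdp
    e <- rnorm(n, 0, sqrt(1 - h2[[t]]) * sdp)
    pheno[, t] <- .trait_means[[t]] + year_eff[as.character(year)] +
      dam_eff[as.character(dam)] + twin * twin_off +
      age_slope * (final_age - 450) + bv[, t] + e
  }

  final_weight <- pheno[, "FW"]
  initial_weight <- final_weight - pheno[, "ADG"] * cfg$test_days
  # keep weights physical in extreme tails; ADG stays consistent with weights
  initial_weight <- pmax(initial_weight, 0.05 * final_weight)
  adg <- (final_weight - initial_weight) / cfg$test_days

  out <- data.frame(
    animal_id = rownames(X),
    year = as.character(year),
    dam_age_class = as.character(dam),
    twinning = twin,
    final_age = as.numeric(final_age),
    test_days = as.numeric(cfg$test_days),
    initial_weight = initial_weight,
    final_weight = final_weight,
    FI = pheno[, "FI"],
    ADG = adg,
    FW = final_weight,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "true_bv") <- bv
  attr(out, "genetic_score") <- Gstd
  attr(out, "causal_ids") <- g$map$variant_id[causal]
  out
}

#' Simulate a gene annotation over the variant map
#'
#' Lays non-overlapping gene intervals along each chromosome so that
#' approximately `coverage_fraction` of the variants fall inside a gene.
#' Genes are allocated to chromosomes proportionally to their variant
#' counts; within a chromosome each gene covers a run of consecutive
#' variants at a seeded random offset inside its segment.
#'
#' @param g A `geno_matrix`.
#' @param n_genes Number of genes (must not exceed the variant count).
#' @param coverage_fraction Target fraction of variants inside genes,
#'   in (0, 1].
#' @param seed Integer seed.
#'
#' @return A `gene_annotation` data.frame: `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (1-based closed intervals).
#' @export
simulate_annotation <- function(g, n_genes, coverage_fraction, seed = 1L) {
  if (!inherits(g, "geno_matrix")) stop_config("g must be a geno_matrix")
  if (!(is.numeric(coverage_fraction) && coverage_fraction > 0 && coverage_fraction <= 1))
    stop_config("coverage_fraction must lie in (0, 1]")
  map <- g$map
  m <- nrow(map)
  if (!is_count(n_genes) || n_genes > m)
    stop_config("n_genes must be a positive integer <= number of variants")
  set.seed(seed)
  chroms <- unique(map$chrom)
  mc <- as.numeric(table(factor(map$chrom, levels = chroms)))
  quota <- n_genes * mc / m
  gcount <- floor(quota)
  rem <- n_genes - sum(gcount)
  if (rem > 0) {
    o <- order(quota - gcount, decreasing = TRUE)
    gcount[o[seq_len(rem)]] <- gcount[o[seq_len(rem)]] + 1
  }
  rows <- vector("list", n_genes)
  gid <- 0L
  for (ci in seq_along(chroms)) {
    idx <- which(map$chrom == chroms[ci])
    L <- length(idx)
    k <- min(gcount[ci], L)
    if (k == 0L) next
    bounds <- floor(seq(0, L, length.out = k + 1))
    for (s in seq_len(k)) {
      seg <- idx[(bounds[s] + 1L):bounds[s + 1L]]
      ncov <- round(coverage_fraction * length(seg))
      gid <- gid + 1L
      if (ncov < 1L) {
        # empty gene: a 1-bp interval between variant positions
        p0 <- map$pos[seg[1L]] + 1L
        rows[[gid]] <- data.frame(gene_id = NA, chrom = chroms[ci],
                                  start = p0, end = p0,
                                  strand = sample(c("+", "-"), 1L),
                                  stringsAsFactors = FALSE)
      } else {
        off <- sample.int(length(seg) - ncov + 1L, 1L) - 1L
        cov <- seg[(off + 1L):(off + ncov)]
        rows[[gid]] <- data.frame(gene_id = NA, chrom = chroms[ci],
                                  start = map$pos[cov[1L]],
                                  end = map$pos[cov[ncov]],
                                  strand = sample(c("+", "-"), 1L),
                                  stringsAsFactors = FALSE)
      }
    }
  }
  ann <- do.call(rbind, rows[seq_len(gid)])
  ann$gene_id <- sprintf("gene%05d", seq_len(nrow(ann)))
  ann <- ann[, c("gene_id", "chrom", "start", "end", "strand")]
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Simulate a complete population
#'
#' Runs [simulate_genotypes()], [simulate_traits()] and
#' [simulate_annotation()] under one configuration.
#'
#' @param cfg A `sim_config`.
#' @return A `sim_population` list: `genotypes`, `traits`, `annotation`,
#'   `true_bv`, `genetic_score`, `causal_ids`, `config`.
#' @export
simulate_population <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_config("cfg must be a sim_config")
  g <- simulate_genotypes(cfg$n_individuals, cfg$n_variants, cfg$maf_range,
                          ld_block_size = cfg$ld_block_size, ld_rho = cfg$ld_rho,
                          n_chrom = cfg$n_chrom, seed = cfg$seed)
  traits <- simulate_traits(g, cfg)
  ann <- simulate_annotation(g, cfg$n_genes, cfg$gene_coverage,
                             seed = cfg$seed + 1000L)
  structure(list(
    genotypes = g,
    traits = traits,
    annotation = ann,
    true_bv = attr(traits, "true_bv"),
    genetic_score = attr(traits, "genetic_score"),
    causal_ids = attr(traits, "causal_ids"),
    config = cfg
  ), class = "sim_population")
}

#' Write a simulated population to disk
#'
#' Emits the PLINK BED/BIM/FAM triplet, a phenotype TSV, the annotation as
#' GFF3, and a JSON sidecar of true simulation parameters (causal ids,
#' heritabilities, genetic correlations) for downstream assertions.
#'
#' @param pop A `sim_population`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_population <- function(pop, dir) {
  if (!inherits(pop, "sim_population")) stop_config("pop must be a sim_population")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- file.path(dir, "genotypes")
  write_plink(pop$genotypes, prefix)
  phen_path <- file.path(dir, "phenotypes.tsv")
  write_phenotypes(pop$traits, phen_path)
  ann_path <- file.path(dir, "annotation.gff3")
  write_annotation(pop$annotation, ann_path, format = "gff3")
  sidecar <- file.path(dir, "sim_params.json")
  jsonlite::write_json(list(
    n_individuals = pop$config$n_individuals,
    n_variants = pop$config$n_variants,
    n_causal = pop$config$n_causal,
    heritabilities = as.list(pop$config$heritabilities),
    genetic_corr = pop$config$genetic_corr,
    seed = pop$config$seed,
    causal_ids = pop$causal_ids
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
              fam = paste0(prefix, ".fam"), phenotypes = phen_path,
              annotation = ann_path, params = sidecar))
}
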