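# Fixture builders shared across test files. Heavier fixtures are cached
# for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A moderate population reused by several test files.
shared_pop <- function() {
  cached("shared_pop", simulate_population(
    sim_config(n_individuals = 300, n_variants = 800, n_causal = 100,
               maf_range = c(0.1, 0.5), n_genes = 80, gene_coverage = 0.5,
               n_chrom = 5, seed = 2024)
  ))
}

shared_scan <- function() {
  cached("shared_scan", {
    pop <- shared_pop()
    d <- derive_traits(pop$traits)
    corrected <- precorrect_phenotypes(d)
    grm <- compute_grm(pop$genotypes)
    c(run_gwas(pop$genotypes, corrected, grm),
      list(corrected = corrected, grm = grm, derived = d))
  })
}

# Hand-rollable multi-trait summary-statistic fixtures for AWM tests:
# z from a wide normal, p as 10^-U so a usable fraction clears 0.001.
make_toy_results <- function(n_var, traits, seed, p_exponent_max = 5) {
  set.seed(seed)
  chrom <- sample(1:3, n_var, replace = TRUE)
  pos <- integer(n_var)
  for (cc in unique(chrom)) pos[chrom == cc] <- seq_len(sum(chrom == cc)) * 100L
  setNames(lapply(traits, function(tr) {
    z <- rnorm(n_var, sd = 2)
    p <- 10^-runif(n_var, 0, p_exponent_max)
    data.frame(variant_id = sprintf("v%03d", seq_len(n_var)),
               chrom = as.character(chrom), pos = pos,
               z = z, p = p, stringsAsFactors = FALSE)
  }), traits)
}

# Random gene map over toy variants (some variants intergenic).
make_toy_gene_map <- function(results, n_genes, seed) {
  set.seed(seed)
  ids <- results[[1]]$variant_id
  genes <- c(sprintf("g%02d", seq_len(n_genes)), NA)
  setNames(sample(genes, length(ids), replace = TRUE), ids)
}

# A varcomp with chosen components, for scans with fixed variances.
fixed_varcomp <- function(sigma_u2, sigma_e2) {
  structure(list(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 h2 = sigma_u2 / (sigma_u2 + sigma_e2), se_h2 = NA_real_,
                 loglik = NA_real_, converged = TRUE, n = NA_integer_),
            class = "varcomp")
}
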