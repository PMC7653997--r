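# Hand-set 6-variant x 3-trait enumeration: variants 1-2 pass the key
# stage, trait B duplicates the key z-scores over those rows (r = 1),
# trait C is orthogonal, and variant 5 is associated with B only.
toy_three_trait <- function() {
  mk <- function(z, p) data.frame(
    variant_id = sprintf("v%d", 1:6), chrom = "1", pos = (1:6) * 100L,
    z = z, p = p, stringsAsFactors = FALSE)
  key_z <- c(3, -2.5, 0.1, 0.2, 0.3, -0.1)
  key_p <- c(1e-4, 5e-4, 0.4, 0.5, 0.6, 0.7)
  b_z <- c(3, -2.5, 0.2, 0.1, 2.2, 0.4)          # r = 1 with key on rows 1-2
  b_p <- c(0.2, 0.3, 0.6, 0.7, 5e-4, 0.8)
  c_z <- c(1, 1, 0.5, 0.2, 0.1, 0.3)             # r = 0 with key on rows 1-2
  c_p <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  list(key = mk(key_z, key_p), B = mk(b_z, b_p), C = mk(c_z, c_p))
}

test_that("the three-stage AWM construction follows the rules on a toy table", {
  res <- toy_three_trait()
  awm <- build_awm(res, awm_config("key"))
  expect_equal(awm$variants$variant_id, c("v1", "v2"))
  expect_equal(awm$traits, c("key", "B"))      # C dropped at |r| < 0.25
  expect_equal(unname(awm$origin), c("key", "key"))
  # v5 is associated with B only: below min_other_traits = 2
  expect_false("v5" %in% awm$variants$variant_id)
  # with min_other_traits = 1, v5 is recruited as a secondary variant
  awm1 <- build_awm(res, awm_config("key", min_other_traits = 1))
  expect_true("v5" %in% awm1$variants$variant_id)
  expect_equal(awm1$origin[awm1$variants$variant_id == "v5"], "secondary")
})

test_that("boundary P equal to the threshold is included and empty scans warn", {
  res <- toy_three_trait()
  res$key$p[3] <- 0.001  # exactly at the threshold -> included
  awm <- build_awm(res, awm_config("key"))
  expect_true("v3" %in% awm$variants$variant_id)
  for (tr in names(res)) res[[tr]]$p <- rep(0.5, 6)
  expect_warning(awm0 <- build_awm(res, awm_config("key")), "empty")
  expect_equal(nrow(awm0$z), 0)
  expect_equal(awm0$traits, "key")
})

test_that("relaxing thresholds never shrinks the selection (monotonicity)", {
  for (seed in 1:5) {
    res <- make_toy_results(40, c("K", "A", "B", "C"), seed, p_exponent_max = 4)
    key_rows <- function(p_thr, r_thr) {
      awm <- suppressWarnings(build_awm(res, awm_config("K", p_thr, r_thr)))
      awm$variants$variant_id[awm$origin == "key"]
    }
    expect_true(all(key_rows(0.001, 0.25) %in% key_rows(0.01, 0.25)))
    traits_at <- function(r_thr) {
      suppressWarnings(build_awm(res, awm_config("K", 0.01, r_thr))$traits)
    }
    expect_true(all(traits_at(0.5) %in% traits_at(0.1)))
  }
})

test_that("gene assignment is strictly within gene bodies with midpoint ties", {
  variants <- data.frame(variant_id = c("v1", "v2", "v3"),
                         chrom = "1", pos = c(150L, 250L, 150L))
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                    start = c(100L, 140L), end = c(200L, 400L),
                    strand = "+")
  got <- assign_genes(variants[1, ], ann[1, ])
  expect_equal(unname(got), "gA")
  # pos 250 is outside [100, 200]: unassigned under the within-gene policy
  expect_true(is.na(assign_genes(variants[2, ], ann[1, ])[[1]]))
  # overlapping genes: midpoints 150 vs 270, the nearer one wins
  expect_equal(unname(assign_genes(variants[3, ], ann)[[1]]), "gA")
  bad <- ann
  bad$chrom <- "chr1"
  expect_error(assign_genes(variants, bad), "chr1",
               class = "awmfe_data_error")
})

test_that("one marker per gene: trait count, then cumulated P, then position", {
  res <- make_toy_results(6, c("K", "A", "B"), seed = 1)
  # v1: 3 associated traits; v2: 2; both in gene g1 -> v1 chosen
  res$K$p[1:2] <- c(1e-4, 1e-4); res$A$p[1:2] <- c(1e-4, 0.5)
  res$B$p[1:2] <- c(1e-4, 1e-4)
  # v3 and v4 in g2, both associated with K+A; cum_p 0.0005 vs 0.0012
  res$K$p[3:4] <- c(4e-4, 6e-4); res$A$p[3:4] <- c(1e-4, 6e-4)
  res$B$p[3:4] <- c(0.5, 0.5)
  # v5 alone in g3
  res$K$p[5] <- 1e-4
  res$K$p[6] <- 0.9
  for (tr in c("K", "A", "B")) res[[tr]]$z <- c(2, 2, 2, 2, 2, 2) + rnorm(6, 0, 0.1)
  awm <- build_awm(res, awm_config("K", r_threshold = 0.001, min_other_traits = 1))
  gene_map <- setNames(c("g1", "g1", "g2", "g2", "g3", NA),
                       sprintf("v%03d", 1:6))
  sel <- select_snp_per_gene(awm, gene_map)
  expect_equal(sel$variant_id[sel$gene_id == "g1"], "v001")
  expect_equal(sel$variant_id[sel$gene_id == "g2"], "v003")
  expect_equal(sel$variant_id[sel$gene_id == "g3"], "v005")
  expect_equal(sel$n_traits_associated[sel$gene_id == "g1"], 3)
  expect_equal(sel$cum_p[sel$gene_id == "g2"], 5e-4, tolerance = 1e-12)
})

test_that("build_awm and gene selection agree with the brute-force oracle", {
  cases <- expand.grid(seed = 1:8, p_thr = c(0.001, 0.01),
                       min_other = c(1L, 2L))
  for (i in seq_len(nrow(cases))) {
    seed <- cases$seed[i]
    p_thr <- cases$p_thr[i]
    min_other <- cases$min_other[i]
    traits <- c("K", "T1", "T2", "T3", "T4", "T5")
    res <- make_toy_results(20, traits, seed)
    gene_map <- make_toy_gene_map(res, n_genes = 6, seed = seed + 100)
    ref <- awm_oracle(res, "K", p_thr, 0.25, min_other, gene_map)
    awm <- suppressWarnings(
      build_awm(res, awm_config("K", p_thr, 0.25, min_other)))
    expect_equal(awm$variants$variant_id,
                 res$K$variant_id[ref$rows])
    expect_setequal(awm$traits, ref$traits)
    if (length(ref$rows) > 0 && !is.null(ref$selection) &&
        nrow(ref$selection) > 0) {
      sel <- select_snp_per_gene(awm, gene_map)
      got <- sel[order(sel$gene_id), c("gene_id", "variant_id",
                                       "n_traits_associated", "cum_p")]
      rownames(got) <- NULL
      expect_equal(got$gene_id, ref$selection$gene_id)
      expect_equal(got$variant_id, ref$selection$variant_id)
      expect_equal(got$n_traits_associated, ref$selection$n_traits_associated)
      expect_equal(got$cum_p, ref$selection$cum_p, tolerance = 1e-12)
    }
  }
})

test_that("network summaries partition the gene total exactly", {
  # toy selection with hand-set flags
  assoc <- rbind(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE),
                 c(FALSE, TRUE, TRUE), c(TRUE, FALSE, TRUE))
  colnames(assoc) <- c("K", "A", "B")
  rownames(assoc) <- sprintf("g%d", 1:4)
  sel <- data.frame(gene_id = rownames(assoc),
                    variant_id = sprintf("v%d", 1:4),
                    chrom = "1", pos = 1:4,
                    n_traits_associated = rowSums(assoc),
                    traits = "", cum_p = 0.1)
  attr(sel, "assoc") <- assoc
  attr(sel, "key_trait") <- "K"
  class(sel) <- c("gene_selection", "data.frame")
  s <- summarize_network(sel)
  expect_equal(s$key_only, 1L)
  expect_equal(s$key_and_other, 2L)
  expect_equal(s$other_only, 1L)
  expect_equal(s$key_only + s$key_and_other + s$other_only, s$n_genes)
  expect_equal(unname(s$per_trait), c(3, 2, 2))
  # property over random fixtures
  for (seed in 1:6) {
    res <- make_toy_results(30, c("K", "A", "B", "C"), seed, p_exponent_max = 4)
    awm <- suppressWarnings(build_awm(res, awm_config("K", 0.01, 0.1, 1)))
    if (nrow(awm$z) == 0) next
    gm <- make_toy_gene_map(res, 8, seed)
    if (all(is.na(gm[awm$variants$variant_id]))) next
    s <- summarize_network(select_snp_per_gene(awm, gm))
    expect_equal(s$key_only + s$key_and_other + s$other_only, s$n_genes)
    expect_gte(min(rowSums(attr(select_snp_per_gene(awm, gm), "assoc"))), 1)
  }
})

test_that("AWMs keyed on correlated traits share more genes", {
  # pleiotropic architecture with a handful of sizeable effects: the key
  # trait's matrix is anchored on its strongest signals, so keys with
  # highly correlated effects select overlapping gene sets
  R <- default_genetic_corr()
  R["FI", "ADG"] <- R["ADG", "FI"] <- 0.9
  R["FI", "FW"] <- R["FW", "FI"] <- 0.1
  R["ADG", "FW"] <- R["FW", "ADG"] <- 0.1
  wins <- 0
  losses <- 0
  for (seed in 1:10) {
    cfg <- sim_config(n_individuals = 400, n_variants = 600, n_causal = 12,
                      maf_range = c(0.1, 0.5), genetic_corr = R,
                      heritabilities = c(FI = 0.6, ADG = 0.6, FW = 0.6),
                      n_genes = 150, gene_coverage = 0.6, seed = 7000 + seed)
    pop <- simulate_population(cfg)
    corrected <- precorrect_phenotypes(pop$traits, traits = c("FI", "ADG", "FW"))
    grm <- compute_grm(pop$genotypes)
    scan <- run_gwas(pop$genotypes, corrected, grm)
    sels <- lapply(c("FI", "ADG", "FW"), function(key) {
      awm <- suppressWarnings(build_awm(scan$results, awm_config(key)))
      if (nrow(awm$z) == 0) return(character(0))
      tryCatch(select_snp_per_gene(awm, pop$annotation)$gene_id,
               error = function(e) character(0))
    })
    shared_corr <- length(intersect(sels[[1]], sels[[2]]))   # FI-ADG, rg 0.9
    shared_weak <- length(intersect(sels[[1]], sels[[3]]))   # FI-FW, rg 0.1
    if (shared_corr > shared_weak) wins <- wins + 1
    else if (shared_weak > shared_corr) losses <- losses + 1
  }
  expect_gt(wins, losses)
})
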