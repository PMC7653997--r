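test_that("simulated dosages are valid and deterministic given the seed", {
  g1 <- simulate_genotypes(4, 3, maf_range = c(0.5, 0.5), seed = 7)
  g2 <- simulate_genotypes(4, 3, maf_range = c(0.5, 0.5), seed = 7)
  expect_true(all(g1$dosage %in% 0:2))
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$map, g2$map)
  g3 <- simulate_genotypes(4, 3, maf_range = c(0.5, 0.5), seed = 8)
  expect_false(identical(g1$dosage, g3$dosage))
})

test_that("empirical MAF matches the binomial sampling target", {
  g <- simulate_genotypes(2000, 200, maf_range = c(0.3, 0.3), seed = 3)
  # binomial SE of a per-variant frequency is sqrt(.3*.7/4000) ~ 0.007
  expect_lt(abs(mean(geno_maf(g)) - 0.3), 0.02)
  expect_true(all(geno_maf(g) > 0.3 - 5 * sqrt(0.3 * 0.7 / 4000)))
})

test_that("LD blocks induce positive adjacent-variant dosage correlation", {
  g <- simulate_genotypes(1500, 60, maf_range = c(0.2, 0.4),
                          ld_block_size = 10, ld_rho = 0.8, seed = 5)
  X <- g$dosage
  adj <- vapply(seq_len(59), function(j) cor(X[, j], X[, j + 1]), numeric(1))
  within_block <- (seq_len(59) %% 10) != 0
  expect_true(all(adj[within_block] > 0.2))
  g0 <- simulate_genotypes(1500, 60, maf_range = c(0.2, 0.4),
                           ld_block_size = 1, seed = 5)
  adj0 <- vapply(seq_len(59), function(j) cor(g0$dosage[, j], g0$dosage[, j + 1]),
                 numeric(1))
  expect_lt(max(abs(adj0)), 0.15)
})

test_that("invalid maf_range is a configuration error", {
  expect_error(simulate_genotypes(4, 3, maf_range = c(0, 0.5)),
               class = "awmfe_config_error")
  expect_error(simulate_genotypes(4, 3, maf_range = c(0.1, 0.6)),
               class = "awmfe_config_error")
  expect_error(sim_config(maf_range = c(0.4, 0.1)),
               class = "awmfe_config_error")
})

test_that("sim_config validates the genetic correlation matrix", {
  R <- default_genetic_corr()
  R["FI", "ADG"] <- 0.9  # asymmetric
  expect_error(sim_config(genetic_corr = R), class = "awmfe_config_error")
  R <- default_genetic_corr()
  R["FI", "ADG"] <- R["ADG", "FI"] <- 0.99
  R["FI", "FW"] <- R["FW", "FI"] <- -0.99  # non-PSD given ADG-FW 0.8
  expect_error(sim_config(genetic_corr = R), class = "awmfe_config_error")
  expect_error(sim_config(n_causal = 10000, n_variants = 500),
               class = "awmfe_config_error")
})

test_that("realized breeding values match the target correlation and h2 = 0 kills the signal", {
  g <- simulate_genotypes(2000, 400, maf_range = c(0.1, 0.5), seed = 11)
  R <- default_genetic_corr()
  R["ADG", "FW"] <- R["FW", "ADG"] <- 0.8
  cfg <- sim_config(n_individuals = 2000, n_variants = 400, n_causal = 80,
                    heritabilities = c(FI = 0, ADG = 0.35, FW = 0.35),
                    genetic_corr = R, seed = 11)
  tr <- simulate_traits(g, cfg)
  bv <- attr(tr, "true_bv")
  expect_lt(abs(cor(bv[, "ADG"], bv[, "FW"]) - 0.8), 0.05)
  # h2(FI) = 0: FI carries no signal from its genetic score
  gs <- attr(tr, "genetic_score")
  slope <- coef(lm(tr$FI ~ gs[, "FI"]))[2]
  expect_lt(abs(slope), 3 * summary(lm(tr$FI ~ gs[, "FI"]))$coefficients[2, 2])
  expect_equal(unname(colMeans(is.na(tr))), rep(0, ncol(tr)))
})

test_that("simulated populations are bit-identical under one config", {
  cfg <- sim_config(n_individuals = 60, n_variants = 120, n_causal = 20,
                    n_genes = 12, seed = 99)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$genotypes$dosage, p2$genotypes$dosage)
  expect_identical(p1$traits, p2$traits)
  expect_identical(p1$annotation, p2$annotation)
})

test_that("synthetic annotation hits the requested variant coverage", {
  g <- simulate_genotypes(20, 100, maf_range = c(0.2, 0.5), n_chrom = 2, seed = 5)
  ann <- simulate_annotation(g, n_genes = 10, coverage_fraction = 0.5, seed = 5)
  expect_equal(nrow(ann), 10)
  genes <- assign_genes(g$map, ann)
  expect_lt(abs(mean(!is.na(genes)) - 0.5), 0.1)
  # full coverage with one gene per chromosome assigns every variant
  ann1 <- simulate_annotation(g, n_genes = 2, coverage_fraction = 1, seed = 5)
  expect_true(all(!is.na(assign_genes(g$map, ann1))))
  expect_error(simulate_annotation(g, 10, 0), class = "awmfe_config_error")
  expect_error(simulate_annotation(g, 200, 0.5), class = "awmfe_config_error")
})
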