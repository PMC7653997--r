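test_that("ADG and metabolic mid-test weight follow the endpoint formulas", {
  # 256^0.75 = 64 and 625^0.75 = 125 exactly
  am <- compute_adg_mmw(c(200, 529, 1), c(312, 721, 1), c(112, 96, 30))
  expect_equal(am$MMW, c(64, 125, 1))
  expect_equal(am$ADG, c(1, 2, 0))
  expect_error(compute_adg_mmw(-1, 100, 10), class = "awmfe_data_error")
  expect_error(compute_adg_mmw(100, 100, 0), class = "awmfe_data_error")
})

test_that("the feed-efficiency ratio is gain over intake", {
  expect_equal(compute_fe(1.5, 10), 0.15)
  expect_equal(compute_fe(0, 5), 0)
  expect_error(compute_fe(1, 0), class = "awmfe_data_error")
})

test_that("residual-trait regression recovers known partial coefficients", {
  set.seed(13)
  n <- 200
  d <- data.frame(
    animal_id = sprintf("a%03d", 1:n),
    year = "Y01",
    MMW = runif(n, 60, 120),
    ADG = runif(n, 1, 2),
    final_age = runif(n, 400, 500)
  )
  d$FI <- 0.10 * d$MMW + 2.0 * d$ADG + 0.001 * d$final_age + rnorm(n, 0, 0.01)
  fit <- fit_residual_trait(d, "RFI")
  # independent check: dense normal equations
  X <- cbind(1, d$MMW, d$ADG, d$final_age)
  ref <- solve(crossprod(X), crossprod(X, d$FI))
  expect_lt(abs(fit$beta1 - 0.10), 0.01)
  expect_lt(abs(fit$beta2 - 2.0), 0.1)
  expect_equal(fit$beta1, ref[2, 1], tolerance = 1e-10)
  expect_equal(fit$beta2, ref[3, 1], tolerance = 1e-10)
  expect_equal(fit$beta3, ref[4, 1], tolerance = 1e-10)
})

test_that("RFI and RG have the defining orthogonality properties", {
  pop <- shared_pop()
  d <- derive_traits(pop$traits)
  expect_lt(abs(mean(d$RFI)), 1e-10)
  expect_lt(abs(mean(d$RG)), 1e-10)
  expect_lt(abs(cor(d$RFI, d$MMW)), 1e-8)
  expect_lt(abs(cor(d$RFI, d$ADG)), 1e-8)
  expect_lt(abs(cor(d$RG, d$MMW)), 1e-8)
  expect_lt(abs(cor(d$RG, d$FI)), 1e-8)
  expect_equal(d$FE, d$ADG / d$FI)
})

test_that("residuals are invariant to row permutation", {
  pop <- shared_pop()
  d <- derive_traits(pop$traits)
  set.seed(1)
  dp <- derive_traits(pop$traits[sample(nrow(pop$traits)), ])
  m <- match(d$animal_id, dp$animal_id)
  expect_equal(d$RFI, dp$RFI[m], tolerance = 1e-10)
  expect_equal(d$RG, dp$RG[m], tolerance = 1e-10)
})

test_that("exactly linear intake gives identically zero RFI", {
  set.seed(4)
  n <- 50
  d <- data.frame(
    animal_id = sprintf("a%02d", 1:n),
    year = rep(c("Y01", "Y02"), length.out = n),
    MMW = runif(n, 60, 120),
    ADG = runif(n, 1, 2),
    final_age = runif(n, 400, 500)
  )
  d$FI <- 3 + 0.08 * d$MMW + 1.5 * d$ADG + 0.002 * d$final_age
  fit <- fit_residual_trait(d, "RFI")
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("rank-deficient residual models fail naming the collinear terms", {
  set.seed(2)
  n <- 40
  d <- data.frame(
    animal_id = sprintf("a%02d", 1:n), year = "Y01",
    MMW = runif(n, 60, 120), final_age = runif(n, 400, 500)
  )
  d$ADG <- d$MMW / 50  # exactly collinear with MMW
  d$FI <- rnorm(n, 10)
  expect_error(fit_residual_trait(d, "RFI"), "ADG",
               class = "awmfe_numeric_error")
})

test_that("precorrection removes exactly the fixed-effect structure", {
  set.seed(21)
  n <- 120
  base <- data.frame(
    animal_id = sprintf("a%03d", 1:n),
    year = "Y01", dam_age_class = "3", twinning = FALSE,
    final_age = 450
  )
  y <- rnorm(n, 10)
  # intercept-only model: corrected = centered raw values
  d0 <- cbind(base, FI = y)
  c0 <- precorrect_phenotypes(d0, traits = "FI")
  expect_equal(c0$FI, y - mean(y), tolerance = 1e-10)
  # two balanced year groups with +1/-1 offsets: identical to the
  # no-offset data after centering (closed-form group-mean removal)
  d1 <- base
  d1$year <- rep(c("Y01", "Y02"), each = n / 2)
  d1$final_age <- runif(n, 400, 500)
  d1$FI <- y + rep(c(1, -1), each = n / 2)
  d2 <- d1
  d2$FI <- y
  c1 <- precorrect_phenotypes(d1, traits = "FI")
  c2 <- precorrect_phenotypes(d2, traits = "FI")
  expect_equal(c1$FI, c2$FI, tolerance = 1e-8)
  # orthogonality to the age covariate
  expect_lt(abs(cor(c1$FI, d1$final_age)), 1e-8)
})

test_that("precorrected traits have mean zero for every trait", {
  pop <- shared_pop()
  d <- derive_traits(pop$traits)
  corrected <- precorrect_phenotypes(d)
  for (tr in c("RFI", "RG", "FE", "FI", "FW", "ADG")) {
    expect_lt(abs(mean(corrected[[tr]])), 1e-10)
    expect_lt(abs(cor(corrected[[tr]], d$final_age)), 1e-8)
  }
})
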