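# Trait derivation for feed-efficiency analysis of growing bulls.
# RFI is the residual of regressing daily feed intake on metabolic
# mid-test weight, average daily gain and final age within contemporary
# groups; RG is the residual of regressing gain on intake instead; FE is
# the gain/intake ratio. By construction RFI is phenotypically
# uncorrelated with its component traits, which is the point of the
# criterion.

#' Average daily gain and metabolic mid-test weight
#'
#' ADG is the total weight gain divided by the test length. The mid-test
#' weight is the arithmetic mean of initial and final weights, and the
#' metabolic mid-test weight (MMW) is that midpoint raised to the power
#' 0.75, the classical proxy for maintenance requirements.
#'
#' @param initial_weight,final_weight Weights in kg (> 0), vectorized.
#' @param test_days Test length in days (> 0).
#' @return A data.frame with columns `ADG` (kg/day) and `MMW` (kg^0.75).
#' @export
compute_adg_mmw <- function(initial_weight, final_weight, test_days) {
  if (any(!is.finite(initial_weight)) || any(initial_weight <= 0) ||
      any(!is.finite(final_weight)) || any(final_weight <= 0))
    stop_data("weights must be finite and positive")
  if (any(!is.finite(test_days)) || any(test_days <= 0))
    stop_data("test_days must be finite and positive")
  mid <- (initial_weight + final_weight) / 2
  data.frame(ADG = (final_weight - initial_weight) / test_days,
             MMW = mid^0.75)
}

#' Feed-efficiency ratio
#'
#' @param ADG Average daily gain, kg/day.
#' @param FI Daily feed intake, kg dry matter/day (> 0).
#' @return `ADG / FI`, the weight gain per kg of feed consumed.
#' @export
compute_fe <- function(ADG, FI) {
  if (any(!is.finite(FI)) || any(FI <= 0)) stop_data("FI must be positive")
  ADG / FI
}

# Drop model terms that are constant in the data (single-level factors,
# constant covariates); they are unestimable next to the intercept.
informative_terms <- function(d, factors = character(), covariates = character()) {
  keep <- character()
  for (f in factors) if (length(unique(d[[f]])) > 1)
    keep <- c(keep, sprintf("factor(%s)", f))
  for (v in covariates) if (length(unique(d[[v]])) > 1) keep <- c(keep, v)
  keep
}

#' Fit a residual efficiency trait (RFI or RG)
#'
#' Ordinary least squares of the stated model with contemporary-group
#' year as a categorical fixed effect:
#' \deqn{FI = year + \beta_1 MMW + \beta_2 ADG + \beta_3 age + RFI}
#' for `kind = "RFI"`, and
#' \deqn{ADG = year + \beta_1 MMW + \beta_2 FI + \beta_3 age + RG}
#' for `kind = "RG"`. The residuals are the trait: they have mean zero and
#' are orthogonal to every regressor within the fitted sample.
#'
#' @param d A data.frame with columns `animal_id`, `year`, `final_age`,
#'   `MMW`, `FI`, `ADG`.
#' @param kind `"RFI"` or `"RG"`.
#' @return A `residual_fit`: list with `kind`, `beta1` (MMW), `beta2`
#'   (ADG for RFI / FI for RG), `beta3` (final age), `year_effects`,
#'   `residuals` (named by animal id) and the underlying `lm` fit.
#' @export
fit_residual_trait <- function(d, kind = c("RFI", "RG")) {
  kind <- match.arg(kind)
  response <- if (kind == "RFI") "FI" else "ADG"
  partner <- if (kind == "RFI") "ADG" else "FI"
  need <- c("animal_id", "year", "final_age", "MMW", "FI", "ADG")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_data("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(d[need])) stop_data("NA values in required phenotype columns")
  terms <- informative_terms(d, factors = "year",
                             covariates = c("MMW", partner, "final_age"))
  fit <- lm(reformulate(c("1", terms), response), data = d)
  cf <- coef(fit)
  if (anyNA(cf))
    stop_numeric("rank-deficient design for ", kind, "; collinear terms: ",
                 paste(names(cf)[is.na(cf)], collapse = ", "))
  res <- setNames(resid(fit), d$animal_id)
  structure(list(
    kind = kind,
    beta1 = unname(cf["MMW"]),
    beta2 = unname(cf[partner]),
    beta3 = unname(cf["final_age"]),
    year_effects = cf[grep("^factor\\(year\\)", names(cf))],
    residuals = res,
    fit = fit
  ), class = "residual_fit")
}

#' Derive all six analysis traits from raw records
#'
#' Adds `ADG` (from the endpoint weights), `MMW`, `FE = ADG/FI`, and the
#' residual traits `RFI` and `RG` to a raw phenotype table. `FW` is the
#' final weight.
#'
#' @param d Raw records: `animal_id`, `year`, `dam_age_class`, `twinning`,
#'   `final_age`, `test_days`, `initial_weight`, `final_weight`, `FI`.
#' @return The input data.frame with columns `ADG`, `MMW`, `FW`, `FE`,
#'   `RFI`, `RG` added; the two `residual_fit` objects are attached as
#'   attribute `"fits"`.
#' @export
derive_traits <- function(d) {
  need <- c("animal_id", "year", "final_age", "test_days",
            "initial_weight", "final_weight", "FI")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_data("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(d[need])) stop_data("NA values in required phenotype columns")
  am <- compute_adg_mmw(d$initial_weight, d$final_weight, d$test_days)
  d$ADG <- am$ADG
  d$MMW <- am$MMW
  d$FW <- d$final_weight
  d$FE <- compute_fe(d$ADG, d$FI)
  rfi <- fit_residual_trait(d, "RFI")
  rg <- fit_residual_trait(d, "RG")
  d$RFI <- unname(rfi$residuals[match(d$animal_id, names(rfi$residuals))])
  d$RG <- unname(rg$residuals[match(d$animal_id, names(rg$residuals))])
  attr(d, "fits") <- list(RFI = rfi, RG = rg)
  d
}

#' Precorrect traits for the association-analysis fixed effects
#'
#' Replaces each trait by its OLS residual on contemporary-group year,
#' dam-age class and twinning (categorical) plus final age (covariate).
#' Corrected traits have mean zero and are orthogonal to every fixed
#' effect; this is the correction applied before the mixed-model scan, so
#' the association model itself only carries a grand mean.
#'
#' @param d A data.frame holding the traits and the covariate columns
#'   `year`, `dam_age_class`, `twinning`, `final_age`.
#' @param traits Character vector of trait columns to correct.
#' @return A data.frame `animal_id` + one corrected column per trait
#'   (same names).
#' @export
precorrect_phenotypes <- function(d, traits = c("RFI", "RG", "FE", "FI", "FW", "ADG")) {
  need <- c("animal_id", "year", "dam_age_class", "twinning", "final_age", traits)
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_data("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(d[need])) stop_data("NA values in trait or covariate columns")
  terms <- informative_terms(d, factors = c("year", "dam_age_class", "twinning"),
                             covariates = "final_age")
  Y <- as.matrix(d[traits])
  if (length(terms) == 0) {
    corrected <- scale(Y, center = TRUE, scale = FALSE)
  } else {
    fit <- lm(reformulate(c("1", terms), "Y"), data = cbind(d, Y = I(Y)))
    corrected <- resid(fit)
  }
  out <- data.frame(animal_id = d$animal_id, corrected,
                    stringsAsFactors = FALSE)
  names(out) <- c("animal_id", traits)
  rownames(out) <- NULL
  out
}
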