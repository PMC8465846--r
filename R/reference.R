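# Published summary values from the multi-location hybrid wheat trial this
# package models, shipped as plain CSV. They are summary statistics only
# (the plot-level data were never deposited in machine-readable form) and
# are used for consistency checks, e.g. verifying the logistic quantile
# identities that tie the senescence statistics together.

#' Published combined-environment trait summary
#'
#' Mean, range and broad-sense heritability per trait, as reported for the
#' reference trial (92 hybrids + 35 parents over three locations).
#'
#' @return data.frame: trait, unit, mean, min, max, h2.
#' @export
reference_trait_means <- function() {
  utils::read.csv(system.file("extdata", "reference_trait_means.csv",
                              package = "wheatphen"),
                  stringsAsFactors = FALSE)
}

#' Published trial-site metadata
#'
#' Coordinates, plot sizes, sowing/harvest dates and climate summaries of
#' the three reference trial sites.
#'
#' @return data.frame with parsed `sowing_date` / `harvest_date`.
#' @export
reference_trial_meta <- function() {
  m <- utils::read.csv(system.file("extdata", "reference_trial_meta.csv",
                                   package = "wheatphen"),
                       stringsAsFactors = FALSE)
  m$sowing_date <- parse_trial_date(m$sowing_date)
  m$harvest_date <- parse_trial_date(m$harvest_date)
  m
}

#' Reconstruct mean logistic senescence parameters from two quantiles
#'
#' Given the mean mid-senescence time (TFN50) and end-of-rapid-phase time
#' (TFN10), the logistic quantile formulas pin down the senescence slope
#' and intercept: `a3 = log(9) / (TFN10 - TFN50)`, `b3 = -a3 * TFN50`.
#' Because every TFN statistic is an affine function of `TFN50` and the
#' quantile spacing, this inversion commutes with averaging over genotypes,
#' so the model implied by mean quantiles reproduces the mean of any other
#' quantile.
#'
#' @param tfn50,tfn10 thermal times, degree days.
#' @return list with `a3`, `b3` usable with [tfn()].
#' @export
senescence_from_quantiles <- function(tfn50, tfn10) {
  stopifnot(tfn10 > tfn50)
  a3 <- log(9) / (tfn10 - tfn50)
  list(a3 = a3, b3 = -a3 * tfn50)
}
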