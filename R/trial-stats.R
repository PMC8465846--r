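# ---------------------------------------------------------------------------
# Adjusted means (BLUEs) and broad-sense heritability for augmented designs.
#
# Single location:  y_ij  = mu + alpha_i + beta_j + e_ij          (blocks fixed)
# Combined:         y_ijk = mu + alpha_i + beta_j(k) + L_k + e_ijk (additive;
#                   the genotype x location interaction is saturated for
#                   unreplicated entries and is treated as random when
#                   estimating variance components)
# Heritability:     h2 = sG2 / (sG2 + sr2/n)                (one location)
#                   h2 = sG2 / (sG2 + sGxL2/l + sr2/(n*l))  (l locations)
# with n the average number of replicates per genotype per location.
# ---------------------------------------------------------------------------

# assemble one trait's analysis frame: value, genotype, location, block
trait_frame <- function(traits, plots, trait, scope, location = NULL) {
  tr <- traits[traits$trait == trait & !is.na(traits$value),
               c("plot_id", "value")]
  df <- merge(tr, plots, by = "plot_id")
  if (scope == "single_location") {
    if (is.null(location)) stop("single_location scope needs a location")
    df <- df[df$location == location, , drop = FALSE]
  } else if (length(unique(df$location)) < 2) {
    stop("combined scope requires observations in at least 2 locations")
  }
  df$genotype_id <- factor(df$genotype_id)
  df$location <- factor(df$location)
  df$blockf <- droplevels(interaction(df$location, df$block, sep = ":"))
  df
}

#' Adjusted genotype means (BLUEs) from a fixed-effects model
#'
#' Per-location scope fits `value ~ genotype + block`; the combined scope
#' fits the additive model `value ~ genotype + location-block`, with
#' location absorbed in the per-location block factor. Genotype adjusted
#' means are estimated marginal means over blocks (and locations), under
#' sum-to-zero contrasts. Genotypes missing from some locations are
#' averaged over their observed cells.
#'
#' @param traits long plot-level trait table (`plot_id`, `trait`, `value`).
#' @param plots plot table (`plot_id`, `location`, `block`, `genotype_id`).
#' @param scope `"single_location"` or `"combined"`.
#' @param location location name, required for single-location scope.
#' @param which_traits traits to fit (default: all present).
#' @return long data.frame: `genotype_id`, `trait`, `value`, `level`
#'   (`location_blue` or `combined_blue`), `location` (NA for combined).
#' @export
fit_blues <- function(traits, plots,
                      scope = c("single_location", "combined"),
                      location = NULL, which_traits = NULL) {
  scope <- match.arg(scope)
  if (is.null(which_traits)) which_traits <- unique(traits$trait)
  out <- list()
  for (tr in which_traits) {
    df <- trait_frame(traits, plots, tr, scope, location)
    if (nrow(df) == 0) next
    ng <- nlevels(droplevels(df$genotype_id))
    nb <- nlevels(droplevels(df$blockf))
    df$genotype_id <- droplevels(df$genotype_id)
    df$blockf <- droplevels(df$blockf)
    if (ng == 1) {
      em <- data.frame(genotype_id = levels(df$genotype_id),
                       emmean = mean(df$value))
    } else if (nb == 1) {
      fit <- stats::lm(value ~ genotype_id, data = df,
                       contrasts = list(genotype_id = "contr.sum"))
      em <- as.data.frame(emmeans::emmeans(fit, "genotype_id"))
    } else {
      fit <- stats::lm(value ~ genotype_id + blockf, data = df,
                       contrasts = list(genotype_id = "contr.sum",
                                        blockf = "contr.sum"))
      em <- as.data.frame(emmeans::emmeans(fit, "genotype_id"))
    }
    if (anyNA(em$emmean)) {
      stop(sprintf(
        "trait %s: genotype effect not estimable (aliased with blocks) for: %s",
        tr, paste(em$genotype_id[is.na(em$emmean)], collapse = ", ")))
    }
    out[[tr]] <- data.frame(
      genotype_id = as.character(em$genotype_id),
      trait = tr,
      value = em$emmean,
      level = if (scope == "combined") "combined_blue" else "location_blue",
      location = if (scope == "combined") NA_character_ else location)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Variance components by REML (genotype random, design effects fixed)
#'
#' Single location: `value ~ block + (1 | genotype)`. Combined:
#' `value ~ location-block + (1 | genotype) + (1 | genotype:location)`.
#' Negative estimates cannot occur under REML (the boundary is zero); a
#' component estimated at the boundary is flagged. `method = "mom"` gives a
#' method-of-moments (expected-mean-squares) estimate for single-location
#' data, mainly useful as an independent cross-check.
#'
#' @param traits,plots,scope,location as in [fit_blues()].
#' @param trait single trait to analyze.
#' @param method `"reml"` (default) or `"mom"` (single location only).
#' @return list with `sigma2_g`, `sigma2_gxl` (NA for single location),
#'   `sigma2_res`, `n_bar` (replicates per genotype per location), `l`
#'   (number of locations), `boundary` flag.
#' @export
estimate_variance_components <- function(traits, plots, trait,
                                         scope = c("single_location",
                                                   "combined"),
                                         location = NULL,
                                         method = c("reml", "mom")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  df <- trait_frame(traits, plots, trait, scope, location)
  if (nrow(df) == 0) stop("no observations for trait ", trait)
  l <- length(unique(df$location))
  cells <- nrow(unique(df[, c("genotype_id", "location")]))
  n_bar <- nrow(df) / cells
  zero <- function() list(sigma2_g = 0, sigma2_gxl = if (scope == "combined")
    0 else NA_real_, sigma2_res = 0, n_bar = n_bar, l = l, boundary = TRUE)
  if (stats::sd(df$value) < 1e-12) return(zero())
  if (method == "mom") {
    if (scope != "single_location") {
      stop("method-of-moments estimator implemented for single_location only")
    }
    av <- stats::anova(stats::lm(value ~ blockf + genotype_id, data = df))
    ms_g <- av["genotype_id", "Mean Sq"]
    ms_e <- av["Residuals", "Mean Sq"]
    s2r <- ms_e
    s2g <- max((ms_g - ms_e) / n_bar, 0)
    return(list(sigma2_g = s2g, sigma2_gxl = NA_real_, sigma2_res = s2r,
                n_bar = n_bar, l = l,
                boundary = (ms_g - ms_e) / n_bar < 0))
  }
  # degenerate limit: a saturated fixed-effects fit leaves (near) zero
  # residual -- the REML likelihood is flat there, so report the boundary
  # with expected-mean-squares estimates instead of running the optimizer
  ffix <- if (nlevels(df$blockf) > 1) value ~ blockf + genotype_id else
    value ~ genotype_id
  av0 <- suppressWarnings(stats::anova(stats::lm(ffix, data = df)))
  mse0 <- av0["Residuals", "Mean Sq"]
  if (is.na(mse0) || mse0 < 1e-10 * max(stats::var(df$value), 1)) {
    ms_g <- av0["genotype_id", "Mean Sq"]
    mse0 <- max(mse0, 0, na.rm = TRUE)
    return(list(sigma2_g = max((ms_g - mse0) / n_bar, 0),
                sigma2_gxl = if (scope == "combined") 0 else NA_real_,
                sigma2_res = mse0,
                n_bar = n_bar, l = l, boundary = TRUE))
  }
  form <- if (scope == "combined") {
    value ~ blockf + (1 | genotype_id) + (1 | genotype_id:location)
  } else if (nlevels(df$blockf) > 1) {
    value ~ blockf + (1 | genotype_id)
  } else {
    value ~ (1 | genotype_id)
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = df,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else NA_real_
  }
  s2g <- getv("genotype_id")
  s2gxl <- if (scope == "combined") getv("genotype_id:location") else NA_real_
  s2r <- getv("Residual")
  list(sigma2_g = s2g, sigma2_gxl = s2gxl, sigma2_res = s2r,
       n_bar = n_bar, l = l,
       boundary = isTRUE(s2g < 1e-10) ||
         isTRUE(!is.na(s2gxl) && s2gxl < 1e-10))
}

#' Broad-sense heritability from variance components
#'
#' One location: `h2 = sG2 / (sG2 + sr2 / n)`. Several locations:
#' `h2 = sG2 / (sG2 + sGxL2 / l + sr2 / (n * l))`, with `n` the average
#' number of replicates per genotype per location and `l` the number of
#' locations. The single-location formula is the `l = 1` special case of
#' the combined one with the interaction term absent.
#'
#' @param components list as returned by [estimate_variance_components()].
#' @param scope `"single_location"` or `"combined"`.
#' @return list with `h2` and the components used.
#' @export
heritability <- function(components, scope = c("single_location",
                                               "combined")) {
  scope <- match.arg(scope)
  s2g <- components$sigma2_g
  s2r <- components$sigma2_res
  n <- components$n_bar
  l <- components$l
  stopifnot(n >= 1, s2g >= 0, s2r >= 0)
  denom <- if (scope == "combined") {
    s2gxl <- components$sigma2_gxl
    stopifnot(l >= 2, s2gxl >= 0)
    s2g + s2gxl / l + s2r / (n * l)
  } else {
    s2g + s2r / n
  }
  if (denom == 0) stop("zero phenotypic variance; heritability undefined")
  list(trait = components$trait, scope = scope, h2 = s2g / denom,
       components = components)
}

#' Heritability table for many traits and scopes
#'
#' Convenience wrapper running [estimate_variance_components()] and
#' [heritability()] per trait for each location and for the combined
#' environments.
#'
#' @param traits,plots as in [fit_blues()].
#' @param which_traits traits to analyze (default: all present).
#' @return data.frame: trait, scope, location, h2, sigma2_g, sigma2_gxl,
#'   sigma2_res, n_bar, l, boundary.
#' @export
heritability_table <- function(traits, plots, which_traits = NULL) {
  if (is.null(which_traits)) which_traits <- unique(traits$trait)
  locs <- unique(plots$location)
  rows <- list()
  for (tr in which_traits) {
    for (loc in locs) {
      res <- tryCatch({
        vc <- estimate_variance_components(traits, plots, tr,
                                           scope = "single_location",
                                           location = loc)
        h <- heritability(vc, "single_location")
        data.frame(trait = tr, scope = "single_location", location = loc,
                   h2 = h$h2, sigma2_g = vc$sigma2_g,
                   sigma2_gxl = NA_real_, sigma2_res = vc$sigma2_res,
                   n_bar = vc$n_bar, l = vc$l, boundary = vc$boundary)
      }, error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1]] <- res
    }
    if (length(locs) >= 2) {
      res <- tryCatch({
        vc <- estimate_variance_components(traits, plots, tr,
                                           scope = "combined")
        h <- heritability(vc, "combined")
        data.frame(trait = tr, scope = "combined", location = NA_character_,
                   h2 = h$h2, sigma2_g = vc$sigma2_g,
                   sigma2_gxl = vc$sigma2_gxl, sigma2_res = vc$sigma2_res,
                   n_bar = vc$n_bar, l = vc$l, boundary = vc$boundary)
      }, error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
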