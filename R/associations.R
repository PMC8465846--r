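# ---------------------------------------------------------------------------
# Trait associations on genotype adjusted means: pairwise Pearson
# correlations, grain protein deviation, and hybrid-vs-line ANCOVAs.
# ---------------------------------------------------------------------------

# genotype-level wide table from long BLUEs
blues_wide <- function(blues, which_traits = NULL) {
  if (is.null(which_traits)) which_traits <- unique(blues$trait)
  sub <- blues[blues$trait %in% which_traits,
               c("genotype_id", "trait", "value")]
  wide <- stats::reshape(sub, idvar = "genotype_id", timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide
}

#' Pairwise Pearson correlation matrix on genotype means
#'
#' Pairwise-complete observations; two-sided p-values from `cor.test`.
#' Traits appear in the order given (conventionally measured -> estimated
#' -> modelled). Constant traits yield `r = NA` for their pairs.
#'
#' @param blues genotype-level trait table (`genotype_id`, `trait`, `value`).
#' @param trait_order character vector of traits to include, in order.
#' @return long data.frame: trait_x, trait_y, r, p, n, stars (significance
#'   at 0.05 / 0.01 / 0.001). Symmetric pairs are listed once (upper
#'   triangle), the diagonal carries r = 1.
#' @export
correlation_matrix <- function(blues, trait_order = NULL) {
  if (is.null(trait_order)) {
    trait_order <- intersect(trait_names(), unique(blues$trait))
  }
  wide <- blues_wide(blues, trait_order)
  present <- intersect(trait_order, names(wide))
  rows <- list()
  for (i in seq_along(present)) {
    for (j in i:length(present)) {
      x <- wide[[present[i]]]
      y <- wide[[present[j]]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (i == j) {
        rows[[length(rows) + 1]] <- data.frame(
          trait_x = present[i], trait_y = present[j], r = 1, p = NA_real_,
          n = n, stars = "")
        next
      }
      if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          trait_x = present[i], trait_y = present[j], r = NA_real_,
          p = NA_real_, n = n, stars = "")
        next
      }
      ct <- stats::cor.test(x[ok], y[ok])
      stars <- if (ct$p.value < 0.001) "***" else if (ct$p.value < 0.01)
        "**" else if (ct$p.value < 0.05) "*" else ""
      rows[[length(rows) + 1]] <- data.frame(
        trait_x = present[i], trait_y = present[j],
        r = unname(ct$estimate), p = ct$p.value, n = n, stars = stars)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# hybrid/line grouping for contrasts; checks excluded by default
grouping <- function(panel, include_checks = FALSE) {
  role <- panel$role
  grp <- ifelse(role == "hybrid", "hybrid",
                ifelse(role %in% c("female_parent", "male_parent"), "line",
                       NA_character_))
  if (include_checks) grp[is.na(grp)] <- "line"
  data.frame(genotype_id = panel$id, group = grp)
}

#' Grain protein deviation and the hybrid-vs-line protein offset
#'
#' GPD is the residual of grain protein content regressed on grain yield
#' over the whole panel (hybrids and lines jointly). The group effect is
#' the hybrid-minus-line offset from the joint model
#' `GPC ~ YLD + group`, with its p-value.
#'
#' @param blues genotype-level trait table with `GPC` and `YLD`.
#' @param panel genotype panel (for the hybrid/line grouping).
#' @param include_checks include check varieties in the line group.
#' @return list with `gpd` (data.frame genotype_id, gpd), `offset`
#'   (hybrid minus line, GPC percentage points at equal yield), `offset_p`,
#'   and the fitted regression slope/intercept.
#' @export
grain_protein_deviation <- function(blues, panel, include_checks = FALSE) {
  wide <- blues_wide(blues, c("GPC", "YLD"))
  wide <- merge(wide, grouping(panel, include_checks), by = "genotype_id")
  wide <- wide[!is.na(wide$GPC) & !is.na(wide$YLD) & !is.na(wide$group), ]
  if (stats::sd(wide$YLD) == 0) stop("degenerate yield variance")
  base <- stats::lm(GPC ~ YLD, data = wide)
  gpd <- data.frame(genotype_id = wide$genotype_id,
                    gpd = stats::resid(base))
  wide$group <- factor(wide$group, levels = c("line", "hybrid"))
  grp <- stats::lm(GPC ~ YLD + group, data = wide)
  co <- summary(grp)$coefficients
  list(gpd = gpd,
       offset = unname(co["grouphybrid", "Estimate"]),
       offset_se = unname(co["grouphybrid", "Std. Error"]),
       offset_p = unname(co["grouphybrid", "Pr(>|t|)"]),
       df = stats::df.residual(grp),
       slope = unname(stats::coef(base)["YLD"]),
       intercept = unname(stats::coef(base)["(Intercept)"]))
}

#' Hybrid-vs-line ANCOVA for a response given a covariate
#'
#' Fits `response ~ covariate + group` for the group offset (hybrid minus
#' line at equal covariate) and `response ~ covariate * group` for the
#' slope-difference test. Used for TKW given GPSM, TFN90 given HD, and YLD
#' given HD.
#'
#' @param blues genotype-level trait table.
#' @param panel genotype panel.
#' @param response,covariate trait names.
#' @param include_checks include check varieties in the line group.
#' @return list: `response`, `covariate`, `group_offset`, `offset_p`,
#'   `slope_difference_p`, per-group `slopes` and `intercepts`, `n` per
#'   group.
#' @export
group_ancova <- function(blues, panel, response, covariate,
                         include_checks = FALSE) {
  wide <- blues_wide(blues, c(response, covariate))
  wide <- merge(wide, grouping(panel, include_checks), by = "genotype_id")
  names(wide)[names(wide) == response] <- "resp"
  names(wide)[names(wide) == covariate] <- "cov"
  wide <- wide[stats::complete.cases(wide[, c("resp", "cov", "group")]), ]
  tab <- table(wide$group)
  if (length(tab) < 2) stop("both hybrid and line groups must be present")
  if (any(tab < 3)) stop("need at least 3 genotypes per group")
  wide$group <- factor(wide$group, levels = c("line", "hybrid"))
  add <- stats::lm(resp ~ cov + group, data = wide)
  int <- stats::lm(resp ~ cov * group, data = wide)
  co_add <- summary(add)$coefficients
  co_int <- summary(int)$coefficients
  ci <- stats::coef(int)
  list(response = response, covariate = covariate,
       group_offset = unname(co_add["grouphybrid", "Estimate"]),
       offset_p = unname(co_add["grouphybrid", "Pr(>|t|)"]),
       slope_difference_p = unname(co_int["cov:grouphybrid", "Pr(>|t|)"]),
       slopes = c(line = unname(ci["cov"]),
                  hybrid = unname(ci["cov"] + ci["cov:grouphybrid"])),
       intercepts = c(line = unname(ci["(Intercept)"]),
                      hybrid = unname(ci["(Intercept)"] +
                                        ci["grouphybrid"])),
       n = c(line = unname(tab["line"]), hybrid = unname(tab["hybrid"])))
}
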