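#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Trial data model: genotype panel, plot layout, trait tables, weather.
# All containers are plain data.frames so that every table round-trips
# losslessly through CSV.
# ---------------------------------------------------------------------------

GENOTYPE_ROLES <- c("female_parent", "male_parent", "hybrid",
                    "check_replicated", "check_unreplicated")

#' Names of the trait columns handled by the pipeline
#'
#' Measured agronomic traits, derived yield components and the NDVI-modelled
#' stay-green statistics, in the conventional measured -> estimated ->
#' modelled order used for correlation displays.
#'
#' @return Character vector of trait codes.
#' @export
trait_names <- function() {
  c("YLD", "GPC", "SW", "HD", "HT", "SEEDA", "SEEDL", "SEEDW", "TKW",
    "GPY", "GPSM",
    "NMAX", "GPA", "FPA", "SPA", "DPA", "TA",
    "TFN90", "TFN50", "TFN10", "TFN1")
}

#' Parse trial dates
#'
#' Accepts the two dialects used in trial metadata: `DD/MM/YYYY` and ISO
#' `YYYY-MM-DD`. Anything else (including ambiguous forms such as
#' `MM/DD/YYYY` with day <= 12 written with dashes) is rejected rather than
#' guessed.
#'
#' @param x character vector of date strings.
#' @return `Date` vector.
#' @export
parse_trial_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  dmy <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  ok <- iso | dmy | is.na(x)
  if (!all(ok)) {
    stop("unparseable date string(s): ",
         paste(unique(x[!ok]), collapse = ", "),
         " (expected DD/MM/YYYY or YYYY-MM-DD)")
  }
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out[dmy] <- as.Date(x[dmy], format = "%d/%m/%Y")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("invalid calendar date(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Construct a genotype panel table
#'
#' @param id genotype identifiers.
#' @param role one of `female_parent`, `male_parent`, `hybrid`,
#'   `check_replicated`, `check_unreplicated`.
#' @param female_id,male_id parent ids, required iff `role == "hybrid"`.
#' @return data.frame with columns `id`, `role`, `female_id`, `male_id`.
#' @export
genotype_panel <- function(id, role, female_id = NA_character_,
                           male_id = NA_character_) {
  panel <- data.frame(id = as.character(id),
                      role = as.character(role),
                      female_id = as.character(female_id),
                      male_id = as.character(male_id),
                      stringsAsFactors = FALSE)
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  stopifnot(all(c("id", "role", "female_id", "male_id") %in% names(panel)))
  if (anyDuplicated(panel$id)) {
    stop("duplicate genotype id(s): ",
         paste(unique(panel$id[duplicated(panel$id)]), collapse = ", "))
  }
  bad_role <- setdiff(unique(panel$role), GENOTYPE_ROLES)
  if (length(bad_role)) stop("unknown genotype role(s): ",
                             paste(bad_role, collapse = ", "))
  hyb <- panel$role == "hybrid"
  if (any(hyb & (is.na(panel$female_id) | is.na(panel$male_id)))) {
    stop("hybrid entries must name both female_id and male_id")
  }
  if (any(!hyb & (!is.na(panel$female_id) | !is.na(panel$male_id)))) {
    stop("only hybrids may carry parent ids")
  }
  parents <- unique(c(panel$female_id[hyb], panel$male_id[hyb]))
  missing <- setdiff(parents, panel$id)
  if (length(missing)) {
    stop("hybrid parent(s) absent from panel: ",
         paste(missing, collapse = ", "))
  }
  invisible(panel)
}

#' Read a complete trial bundle from a directory of CSV files
#'
#' Expects `genotypes.csv`, `plots.csv`, `traits_long.csv`, `ndvi_long.csv`,
#' `weather.csv` and `trial_meta.csv` (UTF-8, comma separated, header row;
#' missing values as empty fields). All cross references are validated:
#' every plot must name a known genotype, every trait/NDVI row a known plot,
#' and `(plot_id, trait)` must be unique.
#'
#' @param dir directory containing the bundle.
#' @return A list with elements `panel`, `meta`, `plots`, `traits`, `ndvi`,
#'   `weather`.
#' @export
read_trial <- function(dir) {
  need <- c("genotypes.csv", "plots.csv", "traits_long.csv",
            "ndvi_long.csv", "weather.csv", "trial_meta.csv")
  paths <- file.path(dir, need)
  absent <- need[!file.exists(paths)]
  if (length(absent)) stop("missing input file(s): ",
                           paste(absent, collapse = ", "))
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE,
                                    na.strings = "")
  panel <- rd("genotypes.csv")
  validate_panel(panel)

  plots <- rd("plots.csv")
  stopifnot(all(c("plot_id", "location", "block", "genotype_id") %in%
                  names(plots)))
  plots$block <- as.integer(plots$block)
  if (anyDuplicated(plots$plot_id)) {
    stop("duplicate plot_id(s): ",
         paste(unique(plots$plot_id[duplicated(plots$plot_id)]),
               collapse = ", "))
  }
  unknown <- setdiff(plots$genotype_id, panel$id)
  if (length(unknown)) {
    stop("plots reference unknown genotype id(s): ",
         paste(unknown, collapse = ", "))
  }

  meta <- rd("trial_meta.csv")
  stopifnot(all(c("location", "latitude", "longitude", "plot_size",
                  "sowing_date", "harvest_date", "sowing_density_factor")
                %in% names(meta)))
  meta$sowing_date <- parse_trial_date(meta$sowing_date)
  meta$harvest_date <- parse_trial_date(meta$harvest_date)
  if (any(meta$harvest_date <= meta$sowing_date)) {
    stop("harvest_date must be after sowing_date")
  }
  if (any(meta$sowing_density_factor <= 0 | meta$sowing_density_factor > 1)) {
    stop("sowing_density_factor must lie in (0, 1]")
  }

  traits <- rd("traits_long.csv")
  stopifnot(all(c("plot_id", "trait", "value") %in% names(traits)))
  traits$value <- as.numeric(traits$value)
  key <- paste(traits$plot_id, traits$trait)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (plot, trait) rows: ",
         paste(utils::head(key[dup], 10), collapse = "; "))
  }
  unknown <- setdiff(traits$plot_id, plots$plot_id)
  if (length(unknown)) {
    stop("trait rows reference unknown plot(s): ",
         paste(utils::head(unknown, 10), collapse = ", "))
  }

  ndvi <- rd("ndvi_long.csv")
  stopifnot(all(c("plot_id", "date", "ndvi") %in% names(ndvi)))
  ndvi$date <- parse_trial_date(ndvi$date)
  ndvi$ndvi <- as.numeric(ndvi$ndvi)
  unknown <- setdiff(ndvi$plot_id, plots$plot_id)
  if (length(unknown)) {
    stop("NDVI rows reference unknown plot(s): ",
         paste(utils::head(unknown, 10), collapse = ", "))
  }

  weather <- rd("weather.csv")
  stopifnot(all(c("location", "date", "tmin", "tmax", "rainfall") %in%
                  names(weather)))
  weather$date <- parse_trial_date(weather$date)
  if (any(weather$tmax < weather$tmin)) stop("weather rows with tmax < tmin")

  list(panel = panel, meta = meta, plots = plots, traits = traits,
       ndvi = ndvi, weather = weather)
}

#' Write a trial bundle to CSV
#'
#' Inverse of [read_trial()]; field-for-field lossless round trip. Dates are
#' written ISO.
#'
#' @param bundle list as returned by [read_trial()] or [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    for (col in names(df)) if (inherits(df[[col]], "Date"))
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, na = "")
  }
  wr(bundle$panel, "genotypes.csv")
  wr(bundle$plots, "plots.csv")
  wr(bundle$traits, "traits_long.csv")
  wr(bundle$ndvi, "ndvi_long.csv")
  wr(bundle$weather, "weather.csv")
  wr(bundle$meta, "trial_meta.csv")
  invisible(dir)
}

#' Summarize an augmented-design layout
#'
#' Report-only bookkeeping: entries per block, replication per genotype, and
#' hybrid counts per male and per female parent. Never fails on odd layouts;
#' the caller inspects the report.
#'
#' @param panel genotype panel data.frame.
#' @param plots plot table data.frame.
#' @return list with `entries_per_block`, `replication`, `hybrids_per_male`,
#'   `hybrids_per_female`, `n_plots`.
#' @export
validate_design <- function(panel, plots) {
  if (nrow(plots) == 0) {
    return(list(entries_per_block = data.frame(location = character(),
                                               block = integer(),
                                               n = integer()),
                replication = data.frame(genotype_id = character(),
                                         location = character(),
                                         n = integer()),
                hybrids_per_male = integer(), hybrids_per_female = integer(),
                n_plots = 0L))
  }
  epb <- stats::aggregate(list(n = plots$plot_id),
                          by = list(location = plots$location,
                                    block = plots$block), FUN = length)
  rep_tab <- stats::aggregate(list(n = plots$plot_id),
                              by = list(genotype_id = plots$genotype_id,
                                        location = plots$location),
                              FUN = length)
  hyb <- panel[panel$role == "hybrid", , drop = FALSE]
  list(entries_per_block = epb,
       replication = rep_tab,
       hybrids_per_male = if (nrow(hyb)) table(hyb$male_id) else integer(),
       hybrids_per_female = if (nrow(hyb)) table(hyb$female_id) else integer(),
       n_plots = nrow(plots))
}

#' Growing-cycle duration in whole days
#'
#' @param meta trial metadata data.frame (or one row of it) with
#'   `sowing_date` and `harvest_date`.
#' @return integer vector of harvest minus sowing, in days.
#' @export
cycle_duration <- function(meta) {
  d <- as.integer(meta$harvest_date - meta$sowing_date)
  if (any(d < 0)) stop("harvest_date precedes sowing_date")
  d
}

#' Climate summary over a growing cycle
#'
#' Daily mean temperature is `(tmin + tmax) / 2`. Frost days count `tmin <
#' 0` and hot days `tmax > 25` (the conventional thresholds for winter wheat
#' trials in temperate Europe); both thresholds are arguments.
#'
#' @param weather one location's daily weather data.frame.
#' @param meta the matching trial metadata row.
#' @param frost_below,hot_above thresholds in degrees C.
#' @return list with `mean_temp`, `sum_temp`, `n_frost_days`, `n_hot_days`,
#'   `cumulative_rainfall`.
#' @export
weather_summary <- function(weather, meta, frost_below = 0, hot_above = 25) {
  span <- seq(meta$sowing_date, meta$harvest_date, by = "day")
  w <- weather[weather$date >= meta$sowing_date &
                 weather$date <= meta$harvest_date, , drop = FALSE]
  missing <- setdiff(as.character(span), as.character(w$date))
  if (length(missing)) {
    stop("weather coverage gap, missing date(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  }
  tmean <- (w$tmin + w$tmax) / 2
  list(mean_temp = mean(tmean),
       sum_temp = sum(tmean),
       n_frost_days = sum(w$tmin < frost_below),
       n_hot_days = sum(w$tmax > hot_above),
       cumulative_rainfall = sum(w$rainfall))
}

#' Grain protein yield from yield and protein content
#'
#' `GPY = YLD * GPC / 100` (t/ha of protein).
#'
#' @param yld grain yield, t/ha.
#' @param gpc grain protein content, percent.
#' @return grain protein yield, t/ha.
#' @export
derive_gpy <- function(yld, gpc) {
  if (any(yld < 0, na.rm = TRUE)) stop("negative yield")
  if (any(gpc < 0 | gpc > 100, na.rm = TRUE)) stop("GPC outside [0, 100]")
  yld * gpc / 100
}

#' Grains per square meter from yield and thousand-kernel weight
#'
#' `GPSM = YLD * 1e5 / TKW`: yield in t/ha is 100 g/m2, so grain count per
#' m2 is `100 / (TKW/1000)`.
#'
#' @param yld grain yield, t/ha.
#' @param tkw thousand-kernel weight, g.
#' @return grains per square meter.
#' @export
derive_gpsm <- function(yld, tkw) {
  if (any(yld < 0, na.rm = TRUE)) stop("negative yield")
  if (any(tkw <= 0, na.rm = TRUE)) stop("TKW must be positive")
  yld * 1e5 / tkw
}

#' Fill in derivable yield components in a plot-level trait table
#'
#' Adds GPY (from YLD, GPC) and GPSM (from YLD, TKW) rows for plots where
#' they are absent but derivable. Supplied values always win; when a
#' supplied value disagrees with its derivation by more than `warn_rel`
#' relative, a warning lists the plots.
#'
#' @param traits long trait table (`plot_id`, `trait`, `value`).
#' @param warn_rel relative-gap threshold for the consistency warning.
#' @return augmented trait table.
#' @export
derive_components <- function(traits, warn_rel = 0.02) {
  sub <- traits[traits$trait %in% c("YLD", "GPC", "TKW", "GPY", "GPSM"),
                c("plot_id", "trait", "value")]
  wide <- stats::reshape(sub, idvar = "plot_id", timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  for (t in c("YLD", "GPC", "TKW", "GPY", "GPSM"))
    if (!t %in% names(wide)) wide[[t]] <- NA_real_
  out <- traits
  add <- function(trait, value) {
    keep <- !is.na(value)
    if (!any(keep)) return(invisible(NULL))
    out <<- rbind(out, data.frame(plot_id = wide$plot_id[keep],
                                  trait = trait, value = value[keep]))
  }
  gpy_d <- ifelse(!is.na(wide$YLD) & !is.na(wide$GPC),
                  derive_gpy(pmax(wide$YLD, 0), wide$GPC), NA_real_)
  gpsm_d <- ifelse(!is.na(wide$YLD) & !is.na(wide$TKW) & wide$TKW > 0,
                   wide$YLD * 1e5 / wide$TKW, NA_real_)
  chk <- function(sup, der, name) {
    both <- !is.na(sup) & !is.na(der) & abs(der) > 0
    gap <- abs(sup[both] - der[both]) / abs(der[both])
    if (any(gap > warn_rel)) {
      warning(sprintf("%s supplied vs derived disagree >%g%% for plot(s): %s",
                      name, 100 * warn_rel,
                      paste(utils::head(wide$plot_id[both][gap > warn_rel], 5),
                            collapse = ", ")))
    }
  }
  chk(wide$GPY, gpy_d, "GPY")
  chk(wide$GPSM, gpsm_d, "GPSM")
  add("GPY", ifelse(is.na(wide$GPY), gpy_d, NA_real_))
  add("GPSM", ifelse(is.na(wide$GPSM), gpsm_d, NA_real_))
  rownames(out) <- NULL
  out
}
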