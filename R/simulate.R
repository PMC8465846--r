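# ---------------------------------------------------------------------------
# Synthetic field-trial generator. Emulates an incomplete factorial crossing
# scheme (19 CMS females x 16 restorer males, 92 selected F1s) grown with
# 35 parent lines and 5 checks in an augmented design (160 entries, 8
# blocks, 4 replicated checks + 1 unreplicated) at 3 locations, with
# plot-level traits carrying additive + dominance genetic architecture and
# per-plot three-phase NDVI time series. True values are emitted alongside
# the data and are never read by the analysis pipeline.
# ---------------------------------------------------------------------------

#' Simulation configuration with study-shaped defaults
#'
#' Trait architecture defaults place the parent means, genetic / GxL /
#' residual standard deviations, and the target mid-parent heterosis
#' percentages at the values typical of a multi-location winter wheat
#' hybrid trial in northern France. Dominance is parameterized directly as
#' the target mid-parent heterosis percent per trait; the GPC-YLD trade-off
#' is induced by a shared latent factor per genotype, and senescence timing
#' is genetically coupled to heading date with a -0.78 loading.
#'
#' @param ... overrides for any top-level field (e.g. `n_hybrids = 20`,
#'   `ndvi_noise_sd = 0`, `traits = <data.frame>`).
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_females = 19, n_males = 16, n_hybrids = 92,
    n_locations = 3, n_blocks = 8,
    replicated_checks = 4, unreplicated_checks = 1,
    locations = data.frame(
      location = c("Nord", "Centre", "Est"),
      latitude = c(48.4, 49.7, 49.3),
      longitude = c(1.7, 2.7, 4.2),
      plot_size = c(12.4, 10.6, 12.0),
      sowing_date = as.Date(c("2019-10-25", "2019-10-29", "2019-10-12")),
      harvest_date = as.Date(c("2020-07-11", "2020-07-29", "2020-07-19"))),
    # trait: parent mean, additive SD, target mid-parent heterosis % and its
    # between-hybrid SD, GxL SD, residual SD, shared-latent loading
    traits = data.frame(
      trait = c("YLD", "GPC", "SW", "HD", "HT", "TKW"),
      mean = c(8.5, 11.9, 81.7, 132.6, 93.4, 41.1),
      add_sd = c(0.66, 0.63, 1.05, 1.97, 2.66, 1.70),
      het_mp = c(5.0, -0.7, 0.8, -2.3, 6.7, 7.7),
      het_sd = c(5.5, 2.6, 0.7, 0.9, 3.4, 3.9),
      gxl_sd = c(0.61, 0.45, 0.78, 0.98, 0.50, 1.41),
      res_sd = c(0.62, 0.55, 0.69, 0.81, 1.76, 0.91),
      loading = c(0.87, -0.87, 0, 0, 0, 0)),
    block_sd = 0.3,        # multiplied by each trait's residual SD
    loc_sd_factor = 1.0,   # location effect SD = factor * trait GxL SD
    hybrid_density = 0.85, # sowing density of hybrids relative to lines
    gpsm_extra_penalty = 0,  # extra % applied to hybrid grain number
    # senescence architecture (degree days, centered on heading)
    phenology = list(
      tfn50_mean = 688.5, tfn50_gsd = 25, tfn50_hd_loading = -0.9,
      width_mean = 121.3, width_gsd = 8,
      het_tfn50 = 4.3, het_tfn50_sd = 3.0, het_width = -2.7,
      tfn_gxl_sd = 4.1, tfn_res_sd = 4.1,
      ndvi_final_mean = 0.14, ndvi_final_sd = 0.01,
      amplitude_mean = 0.72, amplitude_sd = 0.03,
      a2_mean = -2e-4, a2_sd = 4e-5,
      tt_nmax_mean = -30, tt_nmax_sd = 20,
      flower_end_offset = 60,   # breakpoint sits this far before TFN90
      ndvi_emergence = 0.05),
    ndvi_noise_sd = 0.02,
    timepoints = c(13, 14),
    # weather generator: sinusoidal annual cycle + daily noise
    weather = list(mean = 11.8, amplitude = 7.8, peak_doy = 199,
                   daily_sd = 2.5, halfrange = 4, halfrange_sd = 2,
                   wet_prob = 0.45, rain_mean = 3.5),
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$n_hybrids > cfg$n_females * cfg$n_males) {
    stop("n_hybrids exceeds the number of possible crosses")
  }
  if (cfg$n_hybrids < max(3 * cfg$n_males, 2 * cfg$n_females)) {
    stop("n_hybrids too small to give every male 3 and every female 2 crosses")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate the genotype panel and its true genetic values
#'
#' Samples an incomplete factorial so that every male sires at least 3 and
#' every female at least 2 hybrids. Parent genetic values are drawn from
#' the configured additive architecture (with the shared latent factor
#' inducing trait correlations); a hybrid's true value is its mid-parent
#' times `1 + (het_mp + het_sd * z) / 100`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `panel` (genotype table), `truth` (long data.frame
#'   genotype_id, trait, true value — includes the senescence anchors
#'   `TFN50g`, `WIDTHg`).
#' @export
simulate_panel <- function(config, seed = config$seed) {
  set.seed(seed + 101L)
  nf <- config$n_females; nm <- config$n_males
  females <- sprintf("FEM%02d", seq_len(nf))
  males <- sprintf("MA%02d", seq_len(nm))
  checks <- sprintf("CHK%d", seq_len(config$replicated_checks +
                                       config$unreplicated_checks))
  # crossing scheme: 3 per male, then top up females below 2, then fill
  pairs <- expand.grid(f = females, m = males, stringsAsFactors = FALSE)
  chosen <- logical(nrow(pairs))
  for (m in males) {
    idx <- which(pairs$m == m)
    chosen[sample(idx, 3)] <- TRUE
  }
  fcount <- table(factor(pairs$f[chosen], levels = females))
  for (f in females[fcount < 2]) {
    need <- 2 - sum(pairs$f[chosen] == f)
    idx <- which(pairs$f == f & !chosen)
    chosen[sample(idx, need)] <- TRUE
  }
  n_more <- config$n_hybrids - sum(chosen)
  if (n_more < 0) stop("crossing constraints overshoot n_hybrids")
  if (n_more > 0) chosen[sample(which(!chosen), n_more)] <- TRUE
  crosses <- pairs[chosen, , drop = FALSE]
  hyb_ids <- paste0(crosses$f, "x", crosses$m)

  panel <- rbind(
    data.frame(id = females, role = "female_parent",
               female_id = NA_character_, male_id = NA_character_),
    data.frame(id = males, role = "male_parent",
               female_id = NA_character_, male_id = NA_character_),
    data.frame(id = checks,
               role = c(rep("check_replicated", config$replicated_checks),
                        rep("check_unreplicated",
                            config$unreplicated_checks)),
               female_id = NA_character_, male_id = NA_character_),
    data.frame(id = hyb_ids, role = "hybrid",
               female_id = crosses$f, male_id = crosses$m))
  validate_panel(panel)

  ta <- config$traits
  lines <- c(females, males, checks)
  u <- stats::rnorm(length(lines))            # shared latent factor
  gv <- matrix(NA_real_, length(lines), nrow(ta),
               dimnames = list(lines, ta$trait))
  for (k in seq_len(nrow(ta))) {
    lam <- ta$loading[k]
    z <- lam * u + sqrt(max(1 - lam^2, 0)) * stats::rnorm(length(lines))
    gv[, k] <- ta$mean[k] + ta$add_sd[k] * z
  }
  # dominance deviations share the latent structure of the additive values,
  # so the trait trade-offs persist across the hybrid fraction of the panel
  vh <- stats::rnorm(length(hyb_ids))
  hybm <- matrix(NA_real_, length(hyb_ids), nrow(ta),
                 dimnames = list(hyb_ids, ta$trait))
  zmat <- matrix(NA_real_, length(hyb_ids), nrow(ta),
                 dimnames = list(hyb_ids, ta$trait))
  for (k in seq_len(nrow(ta))) {
    lam <- ta$loading[k]
    z <- lam * vh + sqrt(max(1 - lam^2, 0)) * stats::rnorm(length(hyb_ids))
    zmat[, k] <- z
    mp <- (gv[crosses$f, k] + gv[crosses$m, k]) / 2
    het <- ta$het_mp[k] + ta$het_sd[k] * z
    hybm[, k] <- mp * (1 + het / 100)
  }
  gmat <- rbind(gv, hybm)

  ph <- config$phenology
  hd_dev <- (gmat[lines, "HD"] - ta$mean[ta$trait == "HD"]) /
    ta$add_sd[ta$trait == "HD"]
  lam <- ph$tfn50_hd_loading
  tfn50_lines <- ph$tfn50_mean + ph$tfn50_gsd *
    (lam * hd_dev + sqrt(1 - lam^2) * stats::rnorm(length(lines)))
  width_lines <- stats::setNames(
    pmax(ph$width_mean + ph$width_gsd * stats::rnorm(length(lines)), 60),
    lines)
  tfn50 <- c(tfn50_lines, {
    mp <- (tfn50_lines[crosses$f] + tfn50_lines[crosses$m]) / 2
    z <- lam * zmat[, "HD"] +
      sqrt(1 - lam^2) * stats::rnorm(length(hyb_ids))
    mp * (1 + (ph$het_tfn50 + ph$het_tfn50_sd * z) / 100)
  })
  width <- c(width_lines, {
    mpw <- (width_lines[crosses$f] + width_lines[crosses$m]) / 2
    pmax(mpw * (1 + ph$het_width / 100), 60)
  })
  names(tfn50) <- names(width) <- c(lines, hyb_ids)

  truth <- rbind(
    do.call(rbind, lapply(colnames(gmat), function(tr)
      data.frame(genotype_id = rownames(gmat), trait = tr,
                 value = gmat[, tr]))),
    data.frame(genotype_id = names(tfn50), trait = "TFN50g", value = tfn50),
    data.frame(genotype_id = names(width), trait = "WIDTHg", value = width))
  rownames(truth) <- NULL
  list(panel = panel, truth = truth)
}

#' Simulate daily weather for every location
#'
#' Sinusoidal annual mean temperature plus Gaussian daily noise, tuned so a
#' late-October to mid-July cycle accumulates roughly 2700-3000 degree days
#' with a mean near 10.5 C. Coverage runs from sowing to harvest.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data.frame `location`, `date`, `tmin`, `tmax`, `rainfall`.
#' @export
simulate_weather <- function(config, seed = config$seed) {
  set.seed(seed + 303L)
  wp <- config$weather
  out <- list()
  for (i in seq_len(nrow(config$locations))) {
    loc <- config$locations[i, ]
    dates <- seq(loc$sowing_date, loc$harvest_date, by = "day")
    doy <- as.integer(format(dates, "%j"))
    tmean <- wp$mean + wp$amplitude *
      cos(2 * pi * (doy - wp$peak_doy) / 365.25) +
      stats::rnorm(length(dates), 0, wp$daily_sd)
    half <- pmax(wp$halfrange + stats::rnorm(length(dates), 0,
                                             wp$halfrange_sd), 0.5)
    wet <- stats::runif(length(dates)) < wp$wet_prob
    rain <- ifelse(wet, round(stats::rexp(length(dates), 1 / wp$rain_mean),
                              1), 0)
    out[[i]] <- data.frame(location = loc$location, date = dates,
                           tmin = round(tmean - half, 1),
                           tmax = round(tmean + half, 1),
                           rainfall = rain)
  }
  do.call(rbind, out)
}

#' Simulate the field layout and plot-level agronomic traits
#'
#' Per location: every block holds the replicated checks plus an equal
#' share of the unreplicated entries (hybrids, parents, unreplicated
#' check). A plot observation is genotype truth + location effect + GxL
#' draw + block effect + residual. GPY and GPSM are derived from the
#' plot-level YLD, GPC and TKW; hybrids optionally receive an extra grain
#' number penalty (percent) reflecting their reduced sowing density.
#'
#' @param config a [sim_config()].
#' @param panel_sim output of [simulate_panel()].
#' @param seed integer seed.
#' @return list with `plots`, `traits` (long plot-level table including
#'   derived GPY/GPSM), and `effects` (the drawn location/GxL/block
#'   effects, for diagnostics).
#' @export
simulate_trial <- function(config, panel_sim, seed = config$seed) {
  set.seed(seed + 202L)
  panel <- panel_sim$panel
  truth <- panel_sim$truth
  ta <- config$traits
  locs <- config$locations$location
  rep_checks <- panel$id[panel$role == "check_replicated"]
  singles <- panel$id[panel$role != "check_replicated"]
  nb <- config$n_blocks
  if (length(singles) %% nb != 0) {
    # pad by recycling nothing; uneven blocks are allowed, filled round-robin
  }
  plots <- list()
  for (loc in locs) {
    shuffled <- sample(singles)
    block_of <- rep(seq_len(nb), length.out = length(shuffled))
    df <- rbind(
      data.frame(location = loc, block = block_of, genotype_id = shuffled),
      data.frame(location = loc,
                 block = rep(seq_len(nb), each = length(rep_checks)),
                 genotype_id = rep(rep_checks, nb)))
    df <- df[order(df$block), , drop = FALSE]
    df$plot_id <- sprintf("%s_B%d_P%02d", loc, df$block,
                          stats::ave(seq_len(nrow(df)), df$block,
                                     FUN = seq_along))
    plots[[loc]] <- df
  }
  plots <- do.call(rbind, plots)
  rownames(plots) <- NULL
  plots <- plots[, c("plot_id", "location", "block", "genotype_id")]

  gval <- function(tr) {
    v <- truth$value[truth$trait == tr]
    names(v) <- truth$genotype_id[truth$trait == tr]
    v
  }
  genos <- unique(panel$id)
  rows <- list()
  eff <- list()
  for (k in seq_len(nrow(ta))) {
    tr <- ta$trait[k]
    g <- gval(tr)
    loc_eff <- stats::rnorm(length(locs), 0,
                            config$loc_sd_factor * ta$gxl_sd[k])
    names(loc_eff) <- locs
    gxl <- matrix(stats::rnorm(length(genos) * length(locs), 0,
                               ta$gxl_sd[k]),
                  length(genos), length(locs),
                  dimnames = list(genos, locs))
    blk <- matrix(stats::rnorm(config$n_blocks * length(locs), 0,
                               config$block_sd * ta$res_sd[k]),
                  config$n_blocks, length(locs),
                  dimnames = list(NULL, locs))
    res <- stats::rnorm(nrow(plots), 0, ta$res_sd[k])
    val <- g[plots$genotype_id] + loc_eff[plots$location] +
      gxl[cbind(plots$genotype_id, plots$location)] +
      blk[cbind(plots$block, match(plots$location, locs))] + res
    rows[[tr]] <- data.frame(plot_id = plots$plot_id, trait = tr,
                             value = round(val, 4))
    eff[[tr]] <- list(location = loc_eff, gxl = gxl, block = blk)
  }
  traits <- do.call(rbind, rows)
  wide <- stats::reshape(traits, idvar = "plot_id", timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  if (all(c("YLD", "GPC") %in% names(wide))) {
    traits <- rbind(traits,
                    data.frame(plot_id = wide$plot_id, trait = "GPY",
                               value = round(wide$YLD * wide$GPC / 100, 4)))
  }
  if (all(c("YLD", "TKW") %in% names(wide))) {
    is_hyb <- plots$genotype_id[match(wide$plot_id, plots$plot_id)] %in%
      panel$id[panel$role == "hybrid"]
    gpsm <- wide$YLD * 1e5 / wide$TKW
    gpsm[is_hyb] <- gpsm[is_hyb] * (1 + config$gpsm_extra_penalty / 100)
    traits <- rbind(traits,
                    data.frame(plot_id = wide$plot_id, trait = "GPSM",
                               value = round(gpsm, 1)))
  }
  rownames(traits) <- NULL
  list(plots = plots, traits = traits, effects = eff)
}

#' Simulate per-plot NDVI time series from the three-phase model
#'
#' Each plot gets a true phenology: mid-senescence time and senescence
#' width from the genotype anchors plus GxL and plot noise, a flowering
#' line ending at the true phase boundary (set `flower_end_offset` degree
#' days before the senescence onset), and a growing line from emergence to
#' the NDVI maximum. Measurement dates follow per-location campaign
#' schedules shared by every plot of the location (as ground campaigns do):
#' 13-14 visits, sparse monthly passes over winter and roughly weekly to
#' ten-day passes from spring to harvest, with a small per-campaign jitter.
#' The piecewise curve is evaluated at heading-centered thermal time,
#' Gaussian noise is added and values are clipped to [0, 1].
#'
#' @param config a [sim_config()].
#' @param panel_sim output of [simulate_panel()].
#' @param trial output of [simulate_trial()].
#' @param weather output of [simulate_weather()].
#' @param seed integer seed.
#' @return list with `ndvi` (long data.frame plot_id, date, ndvi) and
#'   `truth` (per-plot true a1..b3, anchors and boundaries).
#' @export
simulate_ndvi <- function(config, panel_sim, trial, weather,
                          seed = config$seed) {
  set.seed(seed + 404L)
  ph <- config$phenology
  plots <- trial$plots
  truth <- panel_sim$truth
  hd <- trial$traits[trial$traits$trait == "HD", ]
  tfn50_g <- truth$value[truth$trait == "TFN50g"]
  names(tfn50_g) <- truth$genotype_id[truth$trait == "TFN50g"]
  width_g <- truth$value[truth$trait == "WIDTHg"]
  names(width_g) <- truth$genotype_id[truth$trait == "WIDTHg"]
  locs <- unique(plots$location)
  genos <- unique(plots$genotype_id)
  tfn_gxl <- matrix(stats::rnorm(length(genos) * length(locs), 0,
                                 ph$tfn_gxl_sd),
                    length(genos), length(locs),
                    dimnames = list(genos, locs))
  ndvi_rows <- list(); truth_rows <- list()
  for (loc in locs) {
    meta <- config$locations[config$locations$location == loc, ]
    w <- weather[weather$location == loc, ]
    ax0 <- build_thermal_axis(w, meta$sowing_date, meta$sowing_date)
    year0 <- as.Date(paste0(format(meta$harvest_date, "%Y"), "-01-01"))
    # campaign schedule shared by all plots of the location: sparse winter
    # passes, ten-day passes through May, then roughly weekly visits over
    # grain filling and senescence up to harvest
    npts <- sample(config$timepoints, 1)
    d_w <- meta$sowing_date + 35 +
      round(seq(0, 1, length.out = 3) *
              as.integer(year0 + 105 - (meta$sowing_date + 35)))
    d_may <- year0 + c(120, 130, 140)
    d_jun <- year0 + 152 +
      round(seq(0, 1, length.out = npts - 6L) *
              as.integer(meta$harvest_date - (year0 + 152)))
    camp <- sort(unique(pmin(pmax(c(d_w, d_may, d_jun) +
                                    sample(-2:2, npts, replace = TRUE),
                                  meta$sowing_date + 30),
                             meta$harvest_date)))
    loc_plots <- which(plots$location == loc)
    for (pi in loc_plots) {
      pid <- plots$plot_id[pi]
      gid <- plots$genotype_id[pi]
      hval <- hd$value[match(pid, hd$plot_id)]
      heading_date <- year0 + round(hval) - 1
      if (heading_date < meta$sowing_date ||
          heading_date > meta$harvest_date) next
      href <- tt_at(ax0, heading_date)
      ttc <- ax0$tt - href             # centered axis values per day
      tt_sow <- ttc[1]
      tt_harv <- ttc[length(ttc)]
      tfn50 <- tfn50_g[gid] + tfn_gxl[gid, loc] +
        stats::rnorm(1, 0, ph$tfn_res_sd)
      wdt <- max(width_g[gid] + stats::rnorm(1, 0, ph$tfn_res_sd / 2), 50)
      a3 <- log(9) / wdt
      b3 <- -a3 * tfn50
      fe <- (tfn50 - wdt) - ph$flower_end_offset   # true phase boundary
      final <- ph$ndvi_final_mean + stats::rnorm(1, 0, ph$ndvi_final_sd)
      amp <- ph$amplitude_mean + stats::rnorm(1, 0, ph$amplitude_sd)
      a2 <- ph$a2_mean + stats::rnorm(1, 0, ph$a2_sd)
      b2 <- (final + amp) - a2 * fe    # flowering line anchored at boundary
      tt_nmax <- ph$tt_nmax_mean + stats::rnorm(1, 0, ph$tt_nmax_sd)
      nmax <- a2 * tt_nmax + b2
      if (nmax > 0.98) {            # NDVI saturates below 1
        amp <- amp - (nmax - 0.98)
        b2 <- (final + amp) - a2 * fe
        nmax <- a2 * tt_nmax + b2
      }
      a1 <- (nmax - ph$ndvi_emergence) / (tt_nmax - tt_sow)
      b1 <- nmax - a1 * tt_nmax
      dts <- camp
      tts <- tt_at(ax0, dts) - href
      y <- ifelse(tts <= tt_nmax, a1 * tts + b1,
                  ifelse(tts <= fe, a2 * tts + b2,
                         senescence_curve(tts, a3, b3, final, amp)))
      if (config$ndvi_noise_sd > 0) {
        y <- y + stats::rnorm(length(y), 0, config$ndvi_noise_sd)
      }
      y <- pmin(pmax(y, 0), 1)
      ndvi_rows[[pid]] <- data.frame(plot_id = pid, date = dts,
                                     ndvi = round(y, 4))
      truth_rows[[pid]] <- data.frame(
        plot_id = pid, a1 = a1, b1 = b1, a2 = a2, b2 = b2, a3 = a3, b3 = b3,
        ndvi_final = final, ndvi_amplitude = amp, tt_sowing = tt_sow,
        tt_nmax = tt_nmax, tt_flower_end = fe, tfn50 = tfn50, width = wdt,
        tt_harvest = tt_harv)
    }
  }
  ndvi <- do.call(rbind, ndvi_rows)
  ptruth <- do.call(rbind, truth_rows)
  rownames(ndvi) <- rownames(ptruth) <- NULL
  list(ndvi = ndvi, truth = ptruth)
}

#' Simulate a complete study bundle
#'
#' Runs panel, weather, trial and NDVI generation under one master seed
#' (sub-stages use fixed offsets from it, so any stage is individually
#' reproducible) and assembles the bundle consumed by [read_trial()] /
#' the analysis stages, plus the simulation truth.
#'
#' @param config a [sim_config()].
#' @param seed master seed (defaults to `config$seed`).
#' @return list with the bundle elements `panel`, `meta`, `plots`,
#'   `traits`, `ndvi`, `weather` and a `truth` list (`genotypes`,
#'   `phenology`, `config`).
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed) {
  ps <- simulate_panel(config, seed)
  wx <- simulate_weather(config, seed)
  tr <- simulate_trial(config, ps, seed)
  nd <- simulate_ndvi(config, ps, tr, wx, seed)
  meta <- config$locations
  meta$sowing_density_factor <- config$hybrid_density
  list(panel = ps$panel, meta = meta, plots = tr$plots, traits = tr$traits,
       ndvi = nd$ndvi, weather = wx,
       truth = list(genotypes = ps$truth, phenology = nd$truth,
                    config = config))
}

#' Write a simulated study to disk as the standard CSV bundle
#'
#' The analysis inputs go to `dir`, the simulation truth to `dir/truth`.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  write_trial(sim, dir)
  tdir <- file.path(dir, "truth")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$truth$genotypes,
                   file.path(tdir, "genotype_truth.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$phenology,
                   file.path(tdir, "phenology_truth.csv"), row.names = FALSE)
  invisible(dir)
}
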