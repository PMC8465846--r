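# ---------------------------------------------------------------------------
# Thermal-time phenology: three-phase canopy model
#   growing    f(TT) = a1 * TT + b1
#   flowering  g(TT) = a2 * TT + b2
#   senescence h(TT) = ndvi_final + amplitude / (1 + exp(a3 * TT + b3))
# with TT the cumulative thermal time (base 0 C) centered on heading date.
# ---------------------------------------------------------------------------

# numerically stable log(1 + exp(u))
softplus <- function(u) ifelse(u > 30, u, log1p(exp(u)))

#' Evaluate the logistic senescence curve
#'
#' @param tt thermal time, degree days centered on heading.
#' @param a3,b3 logistic slope (>0 for a decreasing curve) and intercept.
#' @param ndvi_final asymptotic NDVI after senescence.
#' @param amplitude NDVI drop across senescence (>0).
#' @return NDVI values.
#' @export
senescence_curve <- function(tt, a3, b3, ndvi_final, amplitude) {
  ndvi_final + amplitude / (1 + exp(a3 * tt + b3))
}

#' Build a heading-centered thermal-time axis
#'
#' Thermal time accumulates the daily mean temperature `(tmin + tmax)/2`
#' truncated at a base of 0 C, from sowing onward, and is then centered so
#' that the heading date maps to 0 degree days.
#'
#' @param weather one location's daily weather.
#' @param sowing_date,heading_date `Date` scalars; heading must fall within
#'   the weather coverage.
#' @param base_temp base temperature in C.
#' @return list with `date`, `tt` (centered, degree days) and
#'   `heading_reference` (cumulative thermal time from sowing at heading).
#' @export
build_thermal_axis <- function(weather, sowing_date, heading_date,
                               base_temp = 0) {
  w <- weather[weather$date >= sowing_date, , drop = FALSE]
  w <- w[order(w$date), , drop = FALSE]
  if (nrow(w) == 0) stop("weather does not cover the sowing date")
  span <- seq(sowing_date, max(w$date), by = "day")
  if (length(span) != nrow(w) || any(w$date != span)) {
    stop("weather series must be daily and contiguous from sowing")
  }
  if (heading_date < sowing_date || heading_date > max(w$date)) {
    stop("heading date outside weather coverage")
  }
  daily <- pmax((w$tmin + w$tmax) / 2 - base_temp, 0)
  cum <- cumsum(daily)
  href <- cum[match(heading_date, w$date)]
  list(date = w$date, tt = cum - href, heading_reference = href)
}

#' Look up thermal time for calendar dates on an axis
#'
#' @param axis result of [build_thermal_axis()].
#' @param dates `Date` vector within the axis coverage.
#' @return centered thermal time, degree days.
#' @export
tt_at <- function(axis, dates) {
  i <- match(dates, axis$date)
  if (anyNA(i)) stop("date(s) outside thermal axis coverage: ",
                     paste(dates[is.na(i)], collapse = ", "))
  axis$tt[i]
}

safe_r <- function(fitted, observed, tol = 1e-8) {
  if (stats::sd(fitted) < tol || stats::sd(observed) < tol) {
    if (max(abs(fitted - observed)) < 1e-6) 1 else NA_real_
  } else {
    abs(stats::cor(fitted, observed))
  }
}

ols_line <- function(tt, ndvi) {
  if (length(tt) < 2) stop("need at least 2 points for a line fit")
  if (stats::sd(tt) == 0) stop("all thermal times identical; line undefined")
  slope <- stats::cov(tt, ndvi) / stats::var(tt)
  intercept <- mean(ndvi) - slope * mean(tt)
  fitted <- slope * tt + intercept
  list(slope = slope, intercept = intercept,
       r = safe_r(fitted, ndvi),
       sse = sum((ndvi - fitted)^2))
}

#' Fit the linear growing phase
#'
#' Ordinary least squares of NDVI on thermal time over the growing-phase
#' points. `r` is the magnitude of the Pearson correlation between fitted
#' and observed values.
#'
#' @param tt,ndvi growing-phase observations.
#' @return list with `a1`, `b1`, `r`, `sse`.
#' @export
fit_growing <- function(tt, ndvi) {
  f <- ols_line(tt, ndvi)
  list(a1 = f$slope, b1 = f$intercept, r = f$r, sse = f$sse)
}

#' Fit the linear flowering plateau
#'
#' @param tt,ndvi flowering-phase observations.
#' @return list with `a2`, `b2`, `r`, `sse`.
#' @export
fit_flowering <- function(tt, ndvi) {
  f <- ols_line(tt, ndvi)
  list(a2 = f$slope, b2 = f$intercept, r = f$r, sse = f$sse)
}

#' Fit the logistic senescence curve by nonlinear least squares
#'
#' `ndvi_final` and `amplitude` are anchored from the data (lowest post-peak
#' NDVI; drop from the flowering line at the phase boundary) and held fixed;
#' only `a3` and `b3` are free, with `a3 > 0` enforced. Initial values
#' default to `a3 = 4 / span(tt)`, `b3 = -a3 * median(tt)`; on failure up to
#' `n_starts` restarts jitter the start by +/-50%.
#'
#' @param tt,ndvi senescence-phase observations (>= 3 points).
#' @param ndvi_final,amplitude fixed curve anchors; `amplitude > 0`.
#' @param init optional `c(a3, b3)` start.
#' @param n_starts maximum number of jittered restarts.
#' @return list with `a3`, `b3`, `r`, `sse`, `converged`.
#' @export
fit_senescence <- function(tt, ndvi, ndvi_final, amplitude, init = NULL,
                           n_starts = 5) {
  if (length(tt) < 3) stop("need at least 3 senescence points")
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("amplitude must be positive")
  }
  span <- diff(range(tt))
  if (span <= 0) stop("degenerate senescence thermal-time span")
  if (is.null(init)) init <- c(a3 = 4 / span, b3 = -(4 / span) * stats::median(tt))
  dat <- data.frame(tt = tt, ndvi = ndvi)
  starts <- vector("list", n_starts)
  starts[[1]] <- list(a3 = unname(init[1]), b3 = unname(init[2]))
  # deterministic jitter ladder, no RNG involvement
  jit <- c(0.5, 1.5, 0.75, 1.25)
  for (k in seq_len(n_starts - 1)) {
    f <- jit[((k - 1) %% length(jit)) + 1]
    starts[[k + 1]] <- list(a3 = unname(init[1]) * f, b3 = unname(init[2]) * f)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ndvi ~ ndvi_final + amplitude / (1 + exp(a3 * tt + b3)),
        data = dat, start = st,
        lower = c(a3 = 1e-8, b3 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-14) {
      cf <- stats::coef(fit)
      best <- list(a3 = unname(cf["a3"]), b3 = unname(cf["b3"]), sse = sse,
                   fitted = as.numeric(stats::fitted(fit)))
    }
  }
  if (is.null(best)) {
    return(list(a3 = NA_real_, b3 = NA_real_, r = NA_real_, sse = NA_real_,
                converged = FALSE))
  }
  list(a3 = best$a3, b3 = best$b3, r = safe_r(best$fitted, ndvi),
       sse = best$sse, converged = TRUE)
}

#' Split an NDVI series into growing, flowering and senescence phases
#'
#' Growing-phase points run up to and including the NDVI maximum. The
#' flowering/senescence boundary is chosen by exhaustive search over
#' post-peak split indices, minimizing the joint sum of squared errors of
#' the flowering line (left) plus the logistic senescence curve (right),
#' with at least 3 points on each side. The alternative rule
#' `boundary = "logistic_all"` fits the logistic to all post-peak points and
#' cuts the flowering phase at the thermal time where 99% of the amplitude
#' remains.
#'
#' @param tt,ndvi full series, `tt` ascending.
#' @param boundary `"sse_search"` (default) or `"logistic_all"`.
#' @return list with index vectors `growing`, `flowering`, `senescence`,
#'   scalars `tt_nmax`, `tt_flower_end`, `ndvi_final`, and `available`
#'   (FALSE when no senescence fit is possible, with a `reason`).
#' @export
segment_phases <- function(tt, ndvi, boundary = c("sse_search",
                                                  "logistic_all"),
                           peak_tol = 0.02) {
  boundary <- match.arg(boundary)
  stopifnot(length(tt) == length(ndvi), !is.unsorted(tt))
  n <- length(tt)
  # peak = first observation within measurement tolerance of the series
  # maximum, so a noisy late plateau point cannot swallow the flowering phase
  m <- which(ndvi >= max(ndvi) - peak_tol)[1]
  unavailable <- function(reason) {
    list(growing = seq_len(m), flowering = integer(), senescence = integer(),
         tt_nmax = tt[m], tt_flower_end = NA_real_, ndvi_final = NA_real_,
         available = FALSE, reason = reason)
  }
  post <- m:n                       # peak opens the flowering phase
  if (n - m < 3) return(unavailable("fewer than 3 post-peak points"))
  final <- min(ndvi[post])
  if (boundary == "logistic_all") {
    sen <- if (n - m >= 3) (m + 1):n else integer()
    amp0 <- max(ndvi[post]) - final
    f <- fit_senescence(tt[sen], ndvi[sen], final, amp0)
    if (!f$converged) return(unavailable("logistic fit failed"))
    cut <- tfn(list(a3 = f$a3, b3 = f$b3), 0.99)
    flo <- post[tt[post] <= cut]
    sen <- setdiff(post, flo)
    if (length(flo) < 2 || length(sen) < 3) {
      return(unavailable("degenerate split at TFN99"))
    }
    return(list(growing = seq_len(m), flowering = flo, senescence = sen,
                tt_nmax = tt[m], tt_flower_end = max(tt[flo]),
                ndvi_final = final, available = TRUE, reason = NA_character_))
  }
  search <- function(min_flo) {
    cand <- seq(m + min_flo - 1, n - 3)  # senescence side keeps >= 3 points
    best <- NULL
    for (j in cand) {
      if (j < m + 1) next
      flo <- m:j
      sen <- (j + 1):n
      g <- tryCatch(ols_line(tt[flo], ndvi[flo]), error = function(e) NULL)
      if (is.null(g)) next
      amp <- g$slope * tt[j] + g$intercept - final
      if (!is.finite(amp) || amp <= 0) next
      s <- tryCatch(fit_senescence(tt[sen], ndvi[sen], final, amp,
                                   n_starts = 1),
                    error = function(e) NULL)
      if (is.null(s) || !s$converged) next
      total <- g$sse + s$sse
      if (is.null(best) || total < best$total - 1e-14) {
        best <- list(j = j, total = total)
      }
    }
    best
  }
  best <- search(3)
  # fall back to a 2-point flowering side when the peak sits too close to
  # the true boundary for a 3-point plateau to exist
  if (is.null(best)) best <- search(2)
  if (is.null(best)) return(unavailable("no admissible breakpoint"))
  j <- best$j
  list(growing = seq_len(m), flowering = m:j, senescence = (j + 1):n,
       tt_nmax = tt[m], tt_flower_end = tt[j], ndvi_final = final,
       available = TRUE, reason = NA_character_)
}

#' Thermal time at which a given fraction of the NDVI amplitude remains
#'
#' Inverts the logistic senescence curve in closed form:
#' `TT = (log((1 - f) / f) - b3) / a3`. The conventional stay-green
#' statistics are `TFN90` (f = 0.90, onset), `TFN50` (f = 0.50,
#' mid-senescence), `TFN10` (f = 0.10, end of the rapid phase) and `TFN1`
#' (f = 0.01, end of senescence).
#'
#' @param model list with elements `a3 > 0` and `b3`.
#' @param remaining_fraction fraction(s) of the amplitude remaining, in (0, 1).
#' @return thermal time(s), degree days.
#' @export
tfn <- function(model, remaining_fraction) {
  a3 <- model$a3
  b3 <- model$b3
  if (!is.finite(a3) || a3 <= 0) stop("a3 must be positive")
  f <- remaining_fraction
  stopifnot(all(f > 0 & f < 1))
  (log((1 - f) / f) - b3) / a3
}

# definite integral of a line over [t1, t2]
line_area <- function(slope, intercept, t1, t2) {
  slope / 2 * (t2^2 - t1^2) + intercept * (t2 - t1)
}

# closed-form antiderivative of the logistic senescence curve:
#   H(t) = final*t + A*(t - log(1 + exp(a3*t + b3)) / a3)
logistic_area <- function(a3, b3, ndvi_final, amplitude, t1, t2) {
  H <- function(t) ndvi_final * t + amplitude * (t - softplus(a3 * t + b3) / a3)
  H(t2) - H(t1)
}

#' Areas under the three phase curves
#'
#' GPA integrates the growing line from sowing to the NDVI maximum; FPA the
#' flowering line from the maximum to the fitted phase boundary; SPA the
#' logistic from the boundary to TFN1 (closed-form antiderivative). DPA is
#' FPA + SPA by definition. TA is, by default, the trapezoid area under the
#' measured NDVI points from sowing to harvest (`ta_mode = "measured"`);
#' `ta_mode = "modelled"` returns GPA + DPA instead.
#'
#' @param model fitted phenology model as returned by [fit_phenology()].
#' @param ta_mode `"measured"` or `"modelled"`.
#' @return list with `gpa`, `fpa`, `spa`, `dpa`, `ta`.
#' @export
phase_areas <- function(model, ta_mode = c("measured", "modelled")) {
  ta_mode <- match.arg(ta_mode)
  if (!isTRUE(model$available)) {
    return(list(gpa = NA_real_, fpa = NA_real_, spa = NA_real_,
                dpa = NA_real_, ta = NA_real_))
  }
  gpa <- line_area(model$a1, model$b1, model$tt_sowing, model$tt_nmax)
  fpa <- line_area(model$a2, model$b2, model$tt_nmax, model$tt_flower_end)
  tfn1 <- tfn(model, 0.01)
  spa <- logistic_area(model$a3, model$b3, model$ndvi_final,
                       model$ndvi_amplitude, model$tt_flower_end, tfn1)
  dpa <- fpa + spa
  ta <- if (ta_mode == "modelled") {
    gpa + dpa
  } else {
    sum(diff(model$tt) * (utils::head(model$ndvi, -1) +
                            utils::tail(model$ndvi, -1)) / 2)
  }
  list(gpa = gpa, fpa = fpa, spa = spa, dpa = dpa, ta = ta)
}

#' Fit the complete three-phase model to one NDVI series
#'
#' Segments the series, fits the growing and flowering lines and the
#' logistic senescence curve (`ndvi_final` = lowest post-peak NDVI;
#' `amplitude` = flowering line at the boundary minus `ndvi_final`, both
#' held fixed during the nonlinear fit). Series with fewer than
#' `min_points` observations are not fitted.
#'
#' @param tt,ndvi full series on the heading-centered thermal axis.
#' @param tt_sowing thermal time of sowing (negative), for the GPA integral.
#' @param boundary phase-boundary rule, see [segment_phases()].
#' @param min_points minimum observations required to attempt a fit.
#' @return a `phenology_model` list: coefficients `a1, b1, a2, b2, a3, b3`,
#'   anchors `ndvi_final`, `ndvi_amplitude`, boundaries `tt_sowing`,
#'   `tt_nmax`, `tt_flower_end`, fit quality `r_growing`, `r_flowering`,
#'   `r_senescence`, flag `available` (+ `reason`), and the data.
#' @export
fit_phenology <- function(tt, ndvi, tt_sowing = min(tt),
                          boundary = "sse_search", min_points = 8) {
  o <- order(tt)
  tt <- tt[o]; ndvi <- ndvi[o]
  base <- list(tt = tt, ndvi = ndvi, tt_sowing = tt_sowing,
               nmax = max(ndvi),
               a1 = NA_real_, b1 = NA_real_, a2 = NA_real_, b2 = NA_real_,
               a3 = NA_real_, b3 = NA_real_,
               ndvi_final = NA_real_, ndvi_amplitude = NA_real_,
               tt_nmax = NA_real_, tt_flower_end = NA_real_,
               r_growing = NA_real_, r_flowering = NA_real_,
               r_senescence = NA_real_,
               available = FALSE, reason = NA_character_)
  if (length(tt) < min_points) {
    base$reason <- sprintf("only %d observations (< %d)", length(tt),
                           min_points)
    return(structure(base, class = "phenology_model"))
  }
  seg <- segment_phases(tt, ndvi, boundary = boundary)
  base$tt_nmax <- seg$tt_nmax
  if (length(seg$growing) >= 2) {
    gr <- fit_growing(tt[seg$growing], ndvi[seg$growing])
    base$a1 <- gr$a1; base$b1 <- gr$b1; base$r_growing <- gr$r
  }
  if (!seg$available) {
    base$reason <- seg$reason
    return(structure(base, class = "phenology_model"))
  }
  fl <- fit_flowering(tt[seg$flowering], ndvi[seg$flowering])
  base$a2 <- fl$a2; base$b2 <- fl$b2; base$r_flowering <- fl$r
  base$tt_flower_end <- seg$tt_flower_end
  base$ndvi_final <- seg$ndvi_final
  amp <- fl$a2 * seg$tt_flower_end + fl$b2 - seg$ndvi_final
  if (!is.finite(amp) || amp <= 0) {
    base$reason <- "non-positive senescence amplitude"
    return(structure(base, class = "phenology_model"))
  }
  base$ndvi_amplitude <- amp
  se <- fit_senescence(tt[seg$senescence], ndvi[seg$senescence],
                       seg$ndvi_final, amp)
  if (!se$converged) {
    base$reason <- "senescence fit did not converge"
    return(structure(base, class = "phenology_model"))
  }
  # identifiability guard: the fitted mid-senescence time must sit near the
  # observed senescence window and the implied width must be resolvable
  span_post <- max(tt) - seg$tt_nmax
  mid <- -se$b3 / se$a3
  width <- log(9) / se$a3
  sen_rng <- range(tt[seg$senescence])
  if (width > span_post || mid < sen_rng[1] - width ||
      mid > sen_rng[2] + width) {
    base$reason <- "senescence timing unidentifiable from sampled points"
    return(structure(base, class = "phenology_model"))
  }
  base$a3 <- se$a3; base$b3 <- se$b3; base$r_senescence <- se$r
  base$available <- TRUE
  structure(base, class = "phenology_model")
}

#' Stay-green statistics and phase areas for one fitted model
#'
#' @param model a `phenology_model`.
#' @param ta_mode passed to [phase_areas()].
#' @return one-row data.frame with `NMAX`, `TFN90`, `TFN50`, `TFN10`,
#'   `TFN1`, `GPA`, `FPA`, `SPA`, `DPA`, `TA`.
#' @export
phenology_traits <- function(model, ta_mode = "measured") {
  tf <- if (isTRUE(model$available)) {
    tfn(model, c(0.90, 0.50, 0.10, 0.01))
  } else rep(NA_real_, 4)
  ar <- phase_areas(model, ta_mode = ta_mode)
  data.frame(NMAX = model$nmax,
             TFN90 = tf[1], TFN50 = tf[2], TFN10 = tf[3], TFN1 = tf[4],
             GPA = ar$gpa, FPA = ar$fpa, SPA = ar$spa, DPA = ar$dpa,
             TA = ar$ta)
}

#' Fit the three-phase model to every plot of a trial bundle
#'
#' Converts each plot's NDVI dates to heading-centered thermal time (heading
#' date taken from the plot's HD trait, counted in days from 1 January of
#' the harvest year) and fits the model. Plots that cannot be fitted are
#' flagged with a reason, never dropped silently.
#'
#' @param bundle trial bundle as returned by [read_trial()] or
#'   [simulate_study()].
#' @param boundary,ta_mode,min_points see [fit_phenology()], [phase_areas()].
#' @return list with `traits` (one row per plot: plot_id, the ten modelled
#'   traits, the three R values, `available`, `reason`), `models` (fitted
#'   coefficients per plot), and `fit_report` (mean and SD of each R across
#'   fitted plots, number fitted/failed).
#' @export
phenology_pipeline <- function(bundle, boundary = "sse_search",
                               ta_mode = "measured", min_points = 8) {
  plots <- bundle$plots
  hd <- bundle$traits[bundle$traits$trait == "HD", c("plot_id", "value")]
  rows <- list(); mods <- list()
  axis_cache <- list()
  for (loc in unique(plots$location)) {
    meta <- bundle$meta[bundle$meta$location == loc, , drop = FALSE]
    w <- bundle$weather[bundle$weather$location == loc, , drop = FALSE]
    year0 <- as.Date(paste0(format(meta$harvest_date, "%Y"), "-01-01"))
    # cumulative (uncentered) axis once per location
    ax0 <- build_thermal_axis(w, meta$sowing_date, meta$sowing_date)
    loc_plots <- plots$plot_id[plots$location == loc]
    for (pid in loc_plots) {
      obs <- bundle$ndvi[bundle$ndvi$plot_id == pid, , drop = FALSE]
      if (nrow(obs) == 0) next
      hval <- hd$value[match(pid, hd$plot_id)]
      if (is.na(hval)) {
        rows[[pid]] <- data.frame(plot_id = pid, phenology_traits(
          structure(list(nmax = max(obs$ndvi), available = FALSE),
                    class = "phenology_model")),
          r_growing = NA_real_, r_flowering = NA_real_,
          r_senescence = NA_real_, available = FALSE,
          reason = "no heading date")
        next
      }
      heading_date <- year0 + round(hval) - 1
      href <- tt_at(ax0, heading_date)  # ax0 centered at sowing-day TT
      ttv <- tt_at(ax0, obs$date) - href
      tt_sow <- ax0$tt[1] - href
      fit <- fit_phenology(ttv, obs$ndvi, tt_sowing = tt_sow,
                           boundary = boundary, min_points = min_points)
      tr <- phenology_traits(fit, ta_mode = ta_mode)
      rows[[pid]] <- data.frame(plot_id = pid, tr,
                                r_growing = fit$r_growing,
                                r_flowering = fit$r_flowering,
                                r_senescence = fit$r_senescence,
                                available = fit$available,
                                reason = fit$reason)
      mods[[pid]] <- data.frame(plot_id = pid, a1 = fit$a1, b1 = fit$b1,
                                a2 = fit$a2, b2 = fit$b2, a3 = fit$a3,
                                b3 = fit$b3, ndvi_final = fit$ndvi_final,
                                ndvi_amplitude = fit$ndvi_amplitude,
                                tt_sowing = fit$tt_sowing,
                                tt_nmax = fit$tt_nmax,
                                tt_flower_end = fit$tt_flower_end,
                                available = fit$available)
    }
  }
  traits <- do.call(rbind, rows)
  models <- do.call(rbind, mods)
  rownames(traits) <- rownames(models) <- NULL
  ok <- traits$available
  fit_report <- data.frame(
    phase = c("growing", "flowering", "senescence"),
    mean_r = c(mean(traits$r_growing[ok], na.rm = TRUE),
               mean(traits$r_flowering[ok], na.rm = TRUE),
               mean(traits$r_senescence[ok], na.rm = TRUE)),
    sd_r = c(stats::sd(traits$r_growing[ok], na.rm = TRUE),
             stats::sd(traits$r_flowering[ok], na.rm = TRUE),
             stats::sd(traits$r_senescence[ok], na.rm = TRUE)))
  list(traits = traits, models = models, fit_report = fit_report,
       n_fitted = sum(ok), n_failed = sum(!ok))
}
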