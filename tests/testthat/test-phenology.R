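test_that("thermal axis accumulates truncated daily means centered on heading", {
  dates <- seq(as.Date("2019-10-25"), by = "day", length.out = 301)
  w <- data.frame(location = "L", date = dates, tmin = 10, tmax = 10,
                  rainfall = 0)
  ax <- build_thermal_axis(w, dates[1], dates[101])  # heading 100 d later
  expect_equal(tt_at(ax, dates[101]), 0)
  expect_equal(tt_at(ax, dates[1]), -1000)

  # sub-zero daily means contribute nothing
  w2 <- w
  w2$tmin[5] <- w2$tmax[5] <- -5
  ax2 <- build_thermal_axis(w2, dates[1], dates[101])
  expect_equal(tt_at(ax2, dates[1]), -990)   # day 5 dropped from the sum
  expect_equal(tt_at(ax2, dates[4]) - tt_at(ax2, dates[3]), 10)
  expect_equal(tt_at(ax2, dates[5]) - tt_at(ax2, dates[4]), 0)

  expect_error(build_thermal_axis(w, dates[1], dates[301] + 5),
               "outside weather coverage")
})

test_that("thermal axis matches a brute-force cumulative loop", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(100:300, 1)
    dates <- seq(as.Date("2019-10-01"), by = "day", length.out = n)
    tmid <- rnorm(n, 8, 7)
    half <- abs(rnorm(n, 4, 2))
    w <- data.frame(location = "L", date = dates, tmin = tmid - half,
                    tmax = tmid + half, rainfall = 0)
    h <- sample(2:n, 1)
    ax <- build_thermal_axis(w, dates[1], dates[h])
    cum <- 0; loop <- numeric(n)
    for (i in seq_len(n)) {
      daily <- (w$tmin[i] + w$tmax[i]) / 2
      cum <- cum + max(daily, 0)
      loop[i] <- cum
    }
    expect_equal(ax$tt, loop - loop[h])
  }
})

test_that("phase line fits are exact on lines and match the normal equations", {
  tt <- c(-1200, -900, -600, -300, 0)
  y <- 0.001 * tt + 1
  f <- fit_growing(tt, y)
  expect_equal(f$a1, 0.001)
  expect_equal(f$b1, 1)
  expect_equal(f$r, 1)

  two <- fit_flowering(c(0, 100), c(0.9, 0.85))
  expect_equal(two$a2, -5e-4)
  expect_equal(two$r, 1)

  set.seed(11)
  for (rep in 1:20) {
    tt <- rnorm(10, 0, 300)
    y <- rnorm(10, 0.5, 0.2)
    f <- fit_growing(tt, y)
    X <- cbind(1, tt)
    beta <- solve(t(X) %*% X, t(X) %*% y)   # normal-equations oracle
    expect_equal(f$b1, beta[1], tolerance = 1e-10)
    expect_equal(f$a1, beta[2], tolerance = 1e-10)
  }
  expect_error(fit_growing(c(5, 5, 5), c(1, 2, 3)), "identical")
})

test_that("senescence fit recovers noiseless parameters and is optimal", {
  tt <- seq(450, 1000, length.out = 10)
  pts <- logistic_points(tt, a3 = 0.02, b3 = -13.77)
  f <- fit_senescence(pts$tt, pts$ndvi, 0.14, 0.72)
  expect_true(f$converged)
  expect_equal(f$a3, 0.02, tolerance = 1e-6)
  expect_equal(f$b3, -13.77, tolerance = 1e-5)
  expect_equal(f$r, 1)

  expect_error(fit_senescence(pts$tt, pts$ndvi, 0.14, 0), "positive")

  # with noise, the fitted SSE cannot exceed the SSE at the true parameters
  pts <- logistic_points(tt, 0.02, -13.77, noise_sd = 0.02, seed = 5)
  f <- fit_senescence(pts$tt, pts$ndvi, 0.14, 0.72)
  sse_true <- sum((pts$ndvi - senescence_curve(pts$tt, 0.02, -13.77,
                                               0.14, 0.72))^2)
  expect_lte(f$sse, sse_true + 1e-12)
})

test_that("noisy senescence refits stay within 5% on the slope", {
  # 14 observation times across the senescence window, noise sd 0.02
  tt <- seq(430, 1050, length.out = 14)
  set.seed(99)
  rel <- replicate(500, {
    y <- senescence_curve(tt, 0.02, -13.77, 0.14, 0.72) +
      rnorm(14, 0, 0.02)
    f <- fit_senescence(tt, y, 0.14, 0.72, n_starts = 1)
    abs(f$a3 - 0.02) / 0.02
  })
  expect_lt(median(rel), 0.05)
})

test_that("TFN formulas invert the logistic and keep their spacing", {
  m <- list(a3 = 0.02, b3 = -13.77)
  expect_equal(tfn(m, 0.50), 688.5)
  expect_equal(tfn(m, 0.10) - tfn(m, 0.50), log(9) / 0.02)
  expect_equal(tfn(m, 0.50) - tfn(m, 0.90), log(9) / 0.02)
  expect_error(tfn(list(a3 = -0.01, b3 = 1), 0.5), "positive")

  # ordering, symmetry and the quantile-ratio identity over random draws
  set.seed(21)
  for (rep in 1:200) {
    m <- list(a3 = runif(1, 0.005, 0.08), b3 = runif(1, -30, -2))
    v <- tfn(m, c(0.90, 0.50, 0.10, 0.01))
    expect_true(all(diff(v) > 0))
    expect_equal(v[2], (v[1] + v[3]) / 2, tolerance = 1e-9)
    expect_equal((v[4] - v[2]) / (v[3] - v[2]), log(99) / log(9),
                 tolerance = 1e-9)
  }
})

test_that("TFN values agree with bisection inversion of the curve", {
  set.seed(31)
  for (rep in 1:100) {
    a3 <- runif(1, 0.005, 0.08)
    b3 <- runif(1, -40, -1)
    final <- runif(1, 0.05, 0.2)
    amp <- runif(1, 0.4, 0.9)
    m <- list(a3 = a3, b3 = b3)
    for (f in c(0.9, 0.5, 0.1, 0.01)) {
      target <- final + f * amp
      root <- uniroot(function(t)
        senescence_curve(t, a3, b3, final, amp) - target,
        lower = -b3 / a3 - 2e4, upper = -b3 / a3 + 2e4, tol = 1e-9)$root
      expect_equal(tfn(m, f), root, tolerance = 1e-6)
    }
  }
})

test_that("closed-form phase areas match quadrature and their identities", {
  # constant integrand limit: amplitude ~ 0 gives area = final * span
  m0 <- list(available = TRUE, a1 = 0.001, b1 = 1, a2 = 0, b2 = 0.9,
             a3 = 0.02, b3 = -13.77, ndvi_final = 0.2,
             ndvi_amplitude = 1e-12, tt_sowing = -1000, tt_nmax = 0,
             tt_flower_end = 400, tt = c(-1000, 0, 1000),
             ndvi = c(0.1, 0.9, 0.2), nmax = 0.9)
  ar0 <- phase_areas(m0, ta_mode = "modelled")
  tfn1 <- tfn(m0, 0.01)
  expect_equal(ar0$spa, 0.2 * (tfn1 - 400), tolerance = 1e-6)

  set.seed(41)
  for (rep in 1:50) {
    m <- list(available = TRUE,
              a1 = runif(1, 5e-4, 2e-3), b1 = runif(1, 0.8, 1.2),
              a2 = runif(1, -5e-4, 0), b2 = runif(1, 0.8, 1),
              a3 = runif(1, 0.01, 0.05), b3 = runif(1, -30, -5),
              ndvi_final = runif(1, 0.05, 0.2),
              ndvi_amplitude = runif(1, 0.4, 0.9),
              tt_sowing = runif(1, -1500, -1000),
              tt_nmax = runif(1, -100, 50),
              tt_flower_end = NA, tt = NULL, ndvi = NULL, nmax = NA)
    m$tt_flower_end <- tfn(m, 0.99) - runif(1, 0, 100)
    ar <- phase_areas(m, ta_mode = "modelled")
    h <- function(t) senescence_curve(t, m$a3, m$b3, m$ndvi_final,
                                      m$ndvi_amplitude)
    q <- integrate(h, m$tt_flower_end, tfn(m, 0.01),
                   rel.tol = 1e-10)$value
    expect_equal(ar$spa, q, tolerance = 1e-6)
    g <- function(t) m$a2 * t + m$b2
    qf <- integrate(g, m$tt_nmax, m$tt_flower_end, rel.tol = 1e-10)$value
    expect_equal(ar$fpa, qf, tolerance = 1e-6)
    expect_identical(ar$dpa, ar$fpa + ar$spa)
  }
})

test_that("phase segmentation recovers a known breakpoint and degenerates safely", {
  s <- threephase_series()
  seg <- segment_phases(s$tt, s$ndvi)
  expect_true(seg$available)
  # recovered boundary within one observation of the last true flowering point
  true_j <- max(which(s$tt <= s$pars$fe))
  fitted_j <- max(seg$flowering)
  expect_lte(abs(fitted_j - true_j), 1)

  inc <- segment_phases(seq(0, 120, 10), seq(0.1, 0.9, length.out = 13))
  expect_false(inc$available)
  expect_equal(length(inc$growing), 13)
  expect_equal(length(inc$senescence), 0)
})

test_that("full model fit recovers a noiseless three-phase series", {
  s <- threephase_series()
  fit <- fit_phenology(s$tt, s$ndvi, tt_sowing = s$pars$tt_sow)
  expect_true(fit$available)
  expect_equal(fit$a1, s$pars$a1, tolerance = 1e-6)
  expect_equal(fit$a2, s$pars$a2, tolerance = 1e-6)
  # ndvi_final is anchored at the lowest observed post-peak point, so the
  # logistic recovery is limited by the tail coverage of the sampling
  expect_equal(fit$a3, s$pars$a3, tolerance = 0.02)
  expect_equal(-fit$b3 / fit$a3, s$pars$tfn50, tolerance = 0.01)
  tr <- phenology_traits(fit, ta_mode = "modelled")
  expect_equal(tr$TFN50, s$pars$tfn50, tolerance = 5)

  # short series are flagged, never fitted
  short <- fit_phenology(s$tt[1:6], s$ndvi[1:6], tt_sowing = s$pars$tt_sow)
  expect_false(short$available)
  expect_match(short$reason, "observations")
})

test_that("pipeline reports per-plot failures and cohort fit quality", {
  sim <- simulate_study(sim_config(n_hybrids = 20, n_females = 6,
                                   n_males = 5, seed = 3,
                                   ndvi_noise_sd = 0))
  # truncate one plot to 4 points: flagged unavailable, others fitted
  p1 <- sim$ndvi$plot_id[1]
  keep <- sim$ndvi$plot_id != p1 | !duplicated(sim$ndvi$plot_id) |
    ave(seq_len(nrow(sim$ndvi)), sim$ndvi$plot_id,
        FUN = seq_along) <= 4
  sim$ndvi <- sim$ndvi[sim$ndvi$plot_id != p1 |
                         ave(seq_len(nrow(sim$ndvi)), sim$ndvi$plot_id,
                             FUN = seq_along) <= 4, ]
  ph <- phenology_pipeline(sim)
  row1 <- ph$traits[ph$traits$plot_id == p1, ]
  expect_false(row1$available)
  expect_match(row1$reason, "observations")
  expect_gt(ph$n_fitted, 0.9 * nrow(sim$plots))
  # noiseless cohort: R at 1 up to boundary-sample misassignment (a sample
  # falling between the true phase limit and the fitted one joins the
  # neighbouring segment, leaving a kink in an otherwise perfect fit)
  ok <- ph$traits$available
  expect_true(all(ph$traits$r_growing[ok] > 0.99))
  expect_true(all(ph$traits$r_senescence[ok] > 0.99))
  expect_gt(mean(ph$traits$r_growing[ok]), 0.995)
  expect_gt(mean(ph$traits$r_senescence[ok]), 0.999)
})

test_that("averaging linearity ties mean TFN spacings together exactly", {
  set.seed(51)
  a3 <- runif(30, 0.01, 0.05)
  b3 <- -a3 * runif(30, 600, 750)
  t50 <- mapply(function(a, b) tfn(list(a3 = a, b3 = b), 0.5), a3, b3)
  t10 <- mapply(function(a, b) tfn(list(a3 = a, b3 = b), 0.1), a3, b3)
  t1 <- mapply(function(a, b) tfn(list(a3 = a, b3 = b), 0.01), a3, b3)
  expect_equal(mean(t1 - t50), (log(99) / log(9)) * mean(t10 - t50),
               tolerance = 1e-12)
})
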