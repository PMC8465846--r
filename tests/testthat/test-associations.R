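assoc_panel <- function(n_hyb = 20, n_line = 10) {
  ids <- c(sprintf("P%02d", seq_len(n_line)),
           sprintf("H%02d", seq_len(n_hyb)))
  genotype_panel(
    id = ids,
    role = c(rep("female_parent", n_line), rep("hybrid", n_hyb)),
    female_id = c(rep(NA, n_line), rep("P01", n_hyb)),
    male_id = c(rep(NA, n_line), rep("P02", n_hyb)))
}

long_blues <- function(df) {
  do.call(rbind, lapply(setdiff(names(df), "genotype_id"), function(tr)
    data.frame(genotype_id = df$genotype_id, trait = tr,
               value = df[[tr]])))
}

test_that("correlation matrix is exact on linear data and matches formulas", {
  x <- seq(1, 10)
  blues <- long_blues(data.frame(genotype_id = paste0("g", 1:10),
                                 YLD = x, GPC = 2 * x))
  cm <- correlation_matrix(blues, c("YLD", "GPC"))
  expect_equal(cm$r[cm$trait_x == "YLD" & cm$trait_y == "GPC"], 1)
  expect_equal(cm$r[cm$trait_x == "YLD" & cm$trait_y == "YLD"], 1)

  set.seed(43)
  for (rep in 1:20) {
    a <- rnorm(25); b <- rnorm(25)
    blues <- long_blues(data.frame(genotype_id = paste0("g", 1:25),
                                   YLD = a, GPC = b))
    cm <- correlation_matrix(blues, c("YLD", "GPC"))
    cell <- cm[cm$trait_x == "YLD" & cm$trait_y == "GPC", ]
    # hand-rolled Pearson r and its t-distribution p-value
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    tstat <- r * sqrt(23 / (1 - r^2))
    expect_equal(cell$r, r, tolerance = 1e-12)
    expect_equal(cell$p, 2 * pt(-abs(tstat), 23), tolerance = 1e-12)
    expect_equal(cell$n, 25)
  }

  # a constant trait cannot carry a correlation
  blues <- long_blues(data.frame(genotype_id = paste0("g", 1:10),
                                 YLD = x, GPC = rep(1, 10)))
  cm <- correlation_matrix(blues, c("YLD", "GPC"))
  expect_true(is.na(cm$r[cm$trait_x == "YLD" & cm$trait_y == "GPC"]))
})

test_that("independent traits rarely show strong correlation at panel size", {
  set.seed(47)
  strong <- replicate(500, {
    abs(cor(rnorm(127), rnorm(127))) >= 0.3
  })
  expect_lt(mean(strong), 0.05)
})

test_that("correlations are invariant to positive affine rescaling", {
  set.seed(53)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  b1 <- long_blues(data.frame(genotype_id = paste0("g", 1:30), YLD = a,
                              GPC = b))
  b2 <- long_blues(data.frame(genotype_id = paste0("g", 1:30),
                              YLD = 3 * a + 7, GPC = 0.2 * b - 1))
  r1 <- correlation_matrix(b1, c("YLD", "GPC"))
  r2 <- correlation_matrix(b2, c("YLD", "GPC"))
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
})

test_that("grain protein deviation is exact on constructed data", {
  pan <- assoc_panel()
  n <- nrow(pan)
  yld <- seq(6, 10, length.out = n)
  # all points on one line: every residual vanishes
  blues <- long_blues(data.frame(genotype_id = pan$id, YLD = yld,
                                 GPC = 14 - 0.5 * yld))
  g <- suppressWarnings(grain_protein_deviation(blues, pan))
  expect_equal(g$gpd$gpd, rep(0, n), tolerance = 1e-12)

  # hybrids displaced by +0.21 protein points at equal yield
  is_hyb <- pan$role == "hybrid"
  gpc <- 14 - 0.5 * yld + 0.21 * is_hyb
  blues <- long_blues(data.frame(genotype_id = pan$id, YLD = yld,
                                 GPC = gpc))
  g <- suppressWarnings(grain_protein_deviation(blues, pan))
  expect_equal(g$offset, 0.21, tolerance = 1e-12)
  expect_lt(g$offset_p, 1e-10)

  # residuals of the joint regression sum to zero
  set.seed(59)
  blues <- long_blues(data.frame(genotype_id = pan$id, YLD = yld,
                                 GPC = 14 - 0.5 * yld + rnorm(n, 0, 0.3)))
  g <- grain_protein_deviation(blues, pan)
  expect_lt(abs(sum(g$gpd$gpd)), 1e-8 * n)

  expect_error(grain_protein_deviation(
    long_blues(data.frame(genotype_id = pan$id, YLD = rep(8, n),
                          GPC = rnorm(n))), pan), "degenerate")
})

test_that("noisy protein offsets are covered by their confidence intervals", {
  pan <- assoc_panel(n_hyb = 92, n_line = 35)
  n <- nrow(pan)
  is_hyb <- pan$role == "hybrid"
  set.seed(61)
  covered <- replicate(200, {
    yld <- runif(n, 6.5, 10)
    gpc <- 14 - 0.5 * yld + 0.21 * is_hyb + rnorm(n, 0, 0.3)
    blues <- long_blues(data.frame(genotype_id = pan$id, YLD = yld,
                                   GPC = gpc))
    g <- grain_protein_deviation(blues, pan)
    half <- qt(0.975, g$df) * g$offset_se
    g$offset - half <= 0.21 && 0.21 <= g$offset + half
  })
  expect_gte(mean(covered), 0.93)
})

test_that("group ANCOVA is exact on parallel lines and null on identical groups", {
  pan <- assoc_panel(n_hyb = 10, n_line = 10)
  x <- c(seq(1, 10), seq(1, 10))
  set.seed(67)
  noise <- rnorm(10, 0, 0.1)
  # identical groups: duplicated points, so the interaction is exactly zero
  y <- c(2 - 0.5 * seq(1, 10) + noise, 2 - 0.5 * seq(1, 10) + noise)
  blues <- long_blues(data.frame(genotype_id = pan$id, TKW = y, GPSM = x))
  a <- group_ancova(blues, pan, "TKW", "GPSM")
  expect_equal(a$group_offset, 0, tolerance = 1e-12)
  expect_equal(a$slope_difference_p, 1, tolerance = 1e-12)

  # parallel lines two units apart: offset recovered exactly
  y2 <- ifelse(pan$role == "hybrid", 2, 0) + 30 - 0.4 * x +
    rep(noise, 2)
  blues <- long_blues(data.frame(genotype_id = pan$id, TKW = y2, GPSM = x))
  a <- group_ancova(blues, pan, "TKW", "GPSM")
  expect_equal(a$group_offset, 2, tolerance = 1e-10)
  expect_equal(unname(a$slopes["line"]), unname(a$slopes["hybrid"]),
               tolerance = 1e-10)

  solo <- pan[pan$role == "hybrid", ]
  expect_error(group_ancova(blues, solo, "TKW", "GPSM"), "both hybrid")
})

test_that("the slope-difference test has power against distinct slopes", {
  pan <- assoc_panel(n_hyb = 60, n_line = 60)
  is_hyb <- pan$role == "hybrid"
  set.seed(71)
  hits <- replicate(100, {
    x <- runif(120, 0, 5)
    slope <- ifelse(is_hyb, -0.5, -1)
    y <- 10 + slope * x + rnorm(120, 0, 0.1)
    blues <- long_blues(data.frame(genotype_id = pan$id, TKW = y,
                                   GPSM = x))
    group_ancova(blues, pan, "TKW", "GPSM")$slope_difference_p < 0.01
  })
  expect_gte(mean(hits), 0.95)
})
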