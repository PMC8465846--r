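# Shared fixture builders. Everything is generated in code; no stored data.

# points on the logistic senescence curve
logistic_points <- function(tt, a3, b3, final = 0.14, amp = 0.72,
                            noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- senescence_curve(tt, a3, b3, final, amp)
  if (noise_sd > 0) y <- y + rnorm(length(tt), 0, noise_sd)
  data.frame(tt = tt, ndvi = y)
}

# a complete noiseless three-phase series with known parameters
threephase_series <- function(tt_sow = -1400, tt_nmax = -30, fe = 470,
                              tfn50 = 688.5, width = 121.3,
                              final = 0.14, a2 = -2e-4,
                              tt = NULL, noise_sd = 0, seed = NULL) {
  a3 <- log(9) / width
  b3 <- -a3 * tfn50
  amp <- 0.72
  b2 <- (final + amp) - a2 * fe
  nmax <- a2 * tt_nmax + b2
  a1 <- (nmax - 0.05) / (tt_nmax - tt_sow)
  b1 <- nmax - a1 * tt_nmax
  if (is.null(tt)) {
    tt <- c(seq(tt_sow + 150, tt_nmax, length.out = 5),
            seq(tt_nmax + 60, fe, length.out = 4),
            seq(fe + 30, tfn50 + 2.2 * width, length.out = 5))
  }
  if (!is.null(seed)) set.seed(seed)
  y <- ifelse(tt <= tt_nmax, a1 * tt + b1,
              ifelse(tt <= fe, a2 * tt + b2,
                     senescence_curve(tt, a3, b3, final, amp)))
  if (noise_sd > 0) y <- y + rnorm(length(tt), 0, noise_sd)
  list(tt = tt, ndvi = y,
       pars = list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, a3 = a3, b3 = b3,
                   final = final, amp = amp, tt_sow = tt_sow,
                   tt_nmax = tt_nmax, fe = fe, tfn50 = tfn50,
                   width = width))
}

# tiny balanced complete-block trial: g genotypes x b blocks, one location
balanced_trial <- function(g = 4, b = 3, geno_effects = seq_len(g),
                           block_effects = rep(0, b), noise_sd = 0,
                           seed = 1) {
  set.seed(seed)
  ids <- sprintf("G%02d", seq_len(g))
  plots <- expand.grid(genotype_id = ids, block = seq_len(b),
                       stringsAsFactors = FALSE)
  plots$location <- "L1"
  plots$plot_id <- sprintf("L1_B%d_%s", plots$block, plots$genotype_id)
  vals <- geno_effects[match(plots$genotype_id, ids)] +
    block_effects[plots$block] + rnorm(nrow(plots), 0, noise_sd)
  traits <- data.frame(plot_id = plots$plot_id, trait = "Y", value = vals)
  list(plots = plots[, c("plot_id", "location", "block", "genotype_id")],
       traits = traits, geno = setNames(geno_effects, ids))
}

# small augmented design: reps checks in every block, entries once
augmented_trial <- function(n_entries = 12, n_blocks = 3, n_checks = 2,
                            block_effects = c(0, 2, -1), noise_sd = 0,
                            seed = 1) {
  set.seed(seed)
  entries <- sprintf("E%02d", seq_len(n_entries))
  checks <- sprintf("C%d", seq_len(n_checks))
  geno <- setNames(rnorm(n_entries + n_checks, 10, 2),
                   c(entries, checks))
  rows <- list()
  per_block <- split(entries, rep(seq_len(n_blocks),
                                  length.out = n_entries))
  for (b in seq_len(n_blocks)) {
    ids <- c(per_block[[b]], checks)
    rows[[b]] <- data.frame(genotype_id = ids, block = b,
                            location = "L1")
  }
  plots <- do.call(rbind, rows)
  plots$plot_id <- sprintf("L1_B%d_%s", plots$block, plots$genotype_id)
  vals <- geno[plots$genotype_id] + block_effects[plots$block] +
    rnorm(nrow(plots), 0, noise_sd)
  traits <- data.frame(plot_id = plots$plot_id, trait = "Y", value = vals)
  list(plots = plots[, c("plot_id", "location", "block", "genotype_id")],
       traits = traits, geno = geno)
}
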