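# ---------------------------------------------------------------------------
# Mid-parent and best-parent heterosis on genotype adjusted means:
#   Het_i = 100 * (HYB_i - mean(F_i, M_i)) / mean(F_i, M_i)
#   Bet_i = 100 * (HYB_i - max(F_i, M_i))  / max(F_i, M_i)
# Records exist only where the hybrid and BOTH parents have values.
# ---------------------------------------------------------------------------

#' Per-hybrid heterosis records
#'
#' @param blues genotype-level trait table (`genotype_id`, `trait`, `value`),
#'   typically combined-environment BLUEs.
#' @param panel genotype panel with hybrid pedigree (`id`, `role`,
#'   `female_id`, `male_id`).
#' @param which_traits traits to process (default: all present).
#' @return data.frame with one row per complete (hybrid, trait) trio:
#'   hybrid/parent values, `mid_parent`, `best_parent`, `het_mp`, `het_bp`
#'   (percent), and `undefined` flag for zero mid-parent records (excluded
#'   from summaries). The skipped (incomplete) trios are attached as
#'   attribute `"skipped"`.
#' @export
compute_heterosis <- function(blues, panel, which_traits = NULL) {
  if (is.null(which_traits)) which_traits <- unique(blues$trait)
  hyb <- panel[panel$role == "hybrid", , drop = FALSE]
  val <- function(g, tr) {
    v <- blues$value[blues$genotype_id == g & blues$trait == tr]
    if (length(v) == 1) v else NA_real_
  }
  rows <- list(); skipped <- list()
  for (tr in which_traits) {
    for (i in seq_len(nrow(hyb))) {
      hv <- val(hyb$id[i], tr)
      fv <- val(hyb$female_id[i], tr)
      mv <- val(hyb$male_id[i], tr)
      if (is.na(hv) || is.na(fv) || is.na(mv)) {
        skipped[[length(skipped) + 1]] <-
          data.frame(hybrid_id = hyb$id[i], trait = tr,
                     missing = paste(c("hybrid", "female", "male")[
                       c(is.na(hv), is.na(fv), is.na(mv))], collapse = "+"))
        next
      }
      mp <- (fv + mv) / 2
      bp <- max(fv, mv)
      undef <- mp == 0
      rows[[length(rows) + 1]] <- data.frame(
        hybrid_id = hyb$id[i], trait = tr,
        hybrid_value = hv, female_value = fv, male_value = mv,
        mid_parent = mp, best_parent = bp,
        het_mp = if (undef) NA_real_ else 100 * (hv - mp) / mp,
        het_bp = if (bp == 0) NA_real_ else 100 * (hv - bp) / bp,
        undefined = undef)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hybrid_id = character(), trait = character(),
               hybrid_value = numeric(), female_value = numeric(),
               male_value = numeric(), mid_parent = numeric(),
               best_parent = numeric(), het_mp = numeric(),
               het_bp = numeric(), undefined = logical())
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(hybrid_id = character(), trait = character(),
               missing = character())
  out
}

#' Per-trait heterosis summary
#'
#' Mean, range, coefficient of variation (sd/mean) and the share of hybrids
#' with positive heterosis, plus the p-value of a two-sided one-sample
#' Student t-test of the per-hybrid heterosis values against zero. With
#' `test = "two_sample"` the p-value instead comes from a Welch two-sample
#' t-test of hybrid trait values against parent-line trait values.
#'
#' @param records output of [compute_heterosis()].
#' @param trait trait to summarize.
#' @param kind `"mid_parent"` or `"best_parent"`.
#' @param test `"one_sample"` (default) or `"two_sample"`.
#' @param blues,panel required for `test = "two_sample"` only.
#' @return one-row data.frame: trait, kind, n_hybrids, mean_pct, p_value,
#'   min_pct, max_pct, cv, frac_positive.
#' @export
summarize_heterosis <- function(records, trait,
                                kind = c("mid_parent", "best_parent"),
                                test = c("one_sample", "two_sample"),
                                blues = NULL, panel = NULL) {
  kind <- match.arg(kind)
  test <- match.arg(test)
  r <- records[records$trait == trait & !records$undefined, , drop = FALSE]
  het <- if (kind == "mid_parent") r$het_mp else r$het_bp
  het <- het[!is.na(het)]
  n <- length(het)
  p <- NA_real_
  if (n >= 2) {
    if (test == "one_sample") {
      p <- if (stats::sd(het) == 0) {
        if (mean(het) == 0) 1 else 0
      } else {
        stats::t.test(het, mu = 0)$p.value
      }
    } else {
      stopifnot(!is.null(blues), !is.null(panel))
      hv <- blues$value[blues$trait == trait &
                          blues$genotype_id %in%
                          panel$id[panel$role == "hybrid"]]
      pv <- blues$value[blues$trait == trait &
                          blues$genotype_id %in%
                          panel$id[panel$role %in% c("female_parent",
                                                     "male_parent")]]
      p <- stats::t.test(hv, pv)$p.value
    }
  }
  m <- mean(het)
  data.frame(trait = trait, kind = kind, n_hybrids = n,
             mean_pct = m, p_value = p,
             min_pct = if (n) min(het) else NA_real_,
             max_pct = if (n) max(het) else NA_real_,
             cv = if (n >= 2 && m != 0) stats::sd(het) / m else NA_real_,
             frac_positive = if (n) mean(het > 0) else NA_real_)
}

#' Heterosis summaries for all traits and both kinds
#'
#' @param records output of [compute_heterosis()].
#' @inheritParams summarize_heterosis
#' @return data.frame of per-trait summaries, mid-parent then best-parent.
#' @export
summarize_heterosis_all <- function(records, test = "one_sample",
                                    blues = NULL, panel = NULL) {
  traits <- unique(records$trait)
  out <- do.call(rbind, c(
    lapply(traits, function(tr)
      summarize_heterosis(records, tr, "mid_parent", test, blues, panel)),
    lapply(traits, function(tr)
      summarize_heterosis(records, tr, "best_parent", test, blues, panel))))
  rownames(out) <- NULL
  out
}

#' Heterosis summaries restricted to the top-k yielding hybrids
#'
#' Selects the `k` hybrids with the highest yield BLUE (ties broken by
#' hybrid id, so the subset is deterministic) and summarizes their
#' heterosis records.
#'
#' @param blues genotype-level trait table containing the ranking trait.
#' @param records output of [compute_heterosis()].
#' @param k number of hybrids to keep.
#' @param rank_trait trait used for ranking (default `"YLD"`).
#' @inheritParams summarize_heterosis
#' @return data.frame of per-trait summaries over the subset, with the
#'   selected hybrid ids as attribute `"hybrids"`.
#' @export
top_k_subset <- function(blues, records, k, rank_trait = "YLD",
                         test = "one_sample", panel = NULL) {
  hyb_ids <- unique(records$hybrid_id)
  y <- blues[blues$trait == rank_trait & blues$genotype_id %in% hyb_ids, ]
  if (k > nrow(y)) stop("k exceeds the number of ranked hybrids")
  y <- y[order(-y$value, y$genotype_id), ]
  keep <- y$genotype_id[seq_len(k)]
  sub <- records[records$hybrid_id %in% keep, , drop = FALSE]
  attr(sub, "skipped") <- attr(records, "skipped")
  out <- summarize_heterosis_all(sub, test = test, blues = blues,
                                 panel = panel)
  attr(out, "hybrids") <- keep
  out
}
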