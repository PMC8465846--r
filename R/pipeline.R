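# ---------------------------------------------------------------------------
# Orchestration: run the stages end to end on a directory of CSV artifacts.
# Stage outputs are plain CSV so that any stage can be re-run or inspected
# in isolation; each stage checks that its upstream artifacts exist and
# names the producing stage when they do not.
# ---------------------------------------------------------------------------

stage_file <- function(dir, name) file.path(dir, name)

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact %s; run the '%s' stage first",
                 basename(path), producer))
  }
  path
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Run one or all pipeline stages
#'
#' Stages: `simulate` writes a synthetic bundle under `out/input` (plus the
#' simulation truth under `out/input/truth`); `phenology` fits the
#' three-phase NDVI model per plot; `stats` computes per-location and
#' combined BLUEs and the heritability table for all traits (measured,
#' derived and modelled); `heterosis` computes per-hybrid records and
#' per-trait summaries (full panel and top-5-yield subset) on the combined
#' BLUEs; `associations` computes the correlation matrix, grain protein
#' deviation and the hybrid-vs-line ANCOVAs. `all` chains everything.
#'
#' With the same `seed` and configuration, two runs produce byte-identical
#' output files.
#'
#' @param stage one of `all`, `simulate`, `phenology`, `stats`,
#'   `heterosis`, `associations`.
#' @param out output directory (created if needed).
#' @param input directory holding the input bundle; defaults to
#'   `out/input` (where `simulate` writes it).
#' @param seed master seed for the synthetic bundle.
#' @param config simulation configuration, defaults to
#'   `sim_config(seed = seed)`.
#' @param ta_mode,boundary phenology options, see [phase_areas()],
#'   [segment_phases()].
#' @param heterosis_test `"one_sample"` or `"two_sample"`.
#' @param top_k size of the top-yield hybrid subset summary.
#' @return invisibly, the list of files written.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "phenology", "stats",
                                   "heterosis", "associations"),
                         out, input = file.path(out, "input"), seed = 1,
                         config = NULL, ta_mode = "measured",
                         boundary = "sse_search",
                         heterosis_test = "one_sample", top_k = 5) {
  stage <- match.arg(stage)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character()

  if (stage %in% c("all", "simulate")) {
    if (is.null(config)) config <- sim_config(seed = seed)
    sim <- simulate_study(config, seed = seed)
    write_study(sim, input)
    written <- c(written, list.files(input, recursive = TRUE,
                                     full.names = TRUE))
  }

  if (stage %in% c("all", "phenology")) {
    bundle <- read_trial(input)
    ph <- phenology_pipeline(bundle, boundary = boundary, ta_mode = ta_mode)
    write_csv_out(ph$traits, stage_file(out, "phenology_traits.csv"))
    write_csv_out(ph$models, stage_file(out, "phenology_models.csv"))
    write_csv_out(ph$fit_report, stage_file(out, "phenology_fit_report.csv"))
    written <- c(written, stage_file(out, c("phenology_traits.csv",
                                            "phenology_models.csv",
                                            "phenology_fit_report.csv")))
  }

  if (stage %in% c("all", "stats")) {
    bundle <- read_trial(input)
    ph_path <- require_artifact(stage_file(out, "phenology_traits.csv"),
                                "phenology")
    ph <- utils::read.csv(ph_path, na.strings = "")
    full <- rbind(bundle$traits[, c("plot_id", "trait", "value")],
                  long_phenology(ph))
    blues_loc <- do.call(rbind, lapply(unique(bundle$plots$location),
                                       function(loc)
      fit_blues(full, bundle$plots, "single_location", location = loc)))
    blues_comb <- fit_blues(full, bundle$plots, "combined")
    herit <- heritability_table(full, bundle$plots)
    write_csv_out(blues_loc, stage_file(out, "blues_location.csv"))
    write_csv_out(blues_comb, stage_file(out, "blues_combined.csv"))
    write_csv_out(herit, stage_file(out, "heritability.csv"))
    written <- c(written, stage_file(out, c("blues_location.csv",
                                            "blues_combined.csv",
                                            "heritability.csv")))
  }

  if (stage %in% c("all", "heterosis")) {
    bundle <- read_trial(input)
    bpath <- require_artifact(stage_file(out, "blues_combined.csv"), "stats")
    blues <- utils::read.csv(bpath, na.strings = "")
    rec <- compute_heterosis(blues, bundle$panel)
    summ <- summarize_heterosis_all(rec, test = heterosis_test,
                                    blues = blues, panel = bundle$panel)
    write_csv_out(rec, stage_file(out, "heterosis_records.csv"))
    write_csv_out(summ, stage_file(out, "heterosis_summary.csv"))
    nhyb <- length(unique(rec$hybrid_id))
    if (nhyb >= top_k && top_k >= 1) {
      top <- top_k_subset(blues, rec, top_k, test = heterosis_test,
                          panel = bundle$panel)
      write_csv_out(top, stage_file(out, "heterosis_topk.csv"))
      written <- c(written, stage_file(out, "heterosis_topk.csv"))
    }
    written <- c(written, stage_file(out, c("heterosis_records.csv",
                                            "heterosis_summary.csv")))
  }

  if (stage %in% c("all", "associations")) {
    bundle <- read_trial(input)
    bpath <- require_artifact(stage_file(out, "blues_combined.csv"), "stats")
    blues <- utils::read.csv(bpath, na.strings = "")
    corr <- correlation_matrix(blues)
    gpd <- grain_protein_deviation(blues, bundle$panel)
    anc <- do.call(rbind, lapply(list(c("TKW", "GPSM"), c("TFN90", "HD"),
                                      c("YLD", "HD")), function(rc) {
      a <- group_ancova(blues, bundle$panel, rc[1], rc[2])
      data.frame(response = a$response, covariate = a$covariate,
                 group_offset = a$group_offset, offset_p = a$offset_p,
                 slope_difference_p = a$slope_difference_p,
                 slope_line = a$slopes["line"],
                 slope_hybrid = a$slopes["hybrid"],
                 n_line = a$n["line"], n_hybrid = a$n["hybrid"])
    }))
    rownames(anc) <- NULL
    write_csv_out(corr, stage_file(out, "correlations.csv"))
    write_csv_out(gpd$gpd, stage_file(out, "gpd.csv"))
    write_csv_out(data.frame(offset = gpd$offset, offset_p = gpd$offset_p,
                             slope = gpd$slope, intercept = gpd$intercept),
                  stage_file(out, "gpd_group_test.csv"))
    write_csv_out(anc, stage_file(out, "ancova_results.csv"))
    written <- c(written, stage_file(out, c("correlations.csv", "gpd.csv",
                                            "gpd_group_test.csv",
                                            "ancova_results.csv")))
  }

  invisible(written)
}

# per-plot phenology trait table (wide) -> long rows for the trait table
long_phenology <- function(ph) {
  cols <- intersect(c("NMAX", "TFN90", "TFN50", "TFN10", "TFN1",
                      "GPA", "FPA", "SPA", "DPA", "TA"), names(ph))
  out <- do.call(rbind, lapply(cols, function(tr)
    data.frame(plot_id = ph$plot_id, trait = tr, value = ph[[tr]])))
  out[!is.na(out$value), ]
}
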