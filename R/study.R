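# Whole-study convenience driver: simulate a cohort, quantify every ROI,
# average to sample level, substitute detection-limited hormone values, and
# correlate hormones with image metrics.

#' Run a full synthetic-cohort study
#'
#' Generates a cohort with [generate_cohort()], quantifies every ROI bundle
#' with [quantify_bundle()] (failures become NA rows), averages ROI metrics
#' per sample, applies the lower-limit-of-detection substitutions, and
#' computes Spearman correlations between hormone levels and image metrics.
#'
#' @param params A [cohort_sim_params()] object.
#' @param config A [pipeline_config()]; for the default simulated tissue
#'   (2 px strands, 18 px cells) scales of 1--2 px and a 9 px closing radius
#'   are appropriate.
#' @param p_method Passed to [correlate_cohort()].
#' @param metrics Metric columns to correlate; by default all quantified
#'   metrics. Restrict this when some metrics are constant across the cohort
#'   (their correlation is undefined and would be skipped with a warning).
#' @return List with `per_roi` (per-ROI metric table), `samples`
#'   (sample-level table merged with substituted hormone values) and
#'   `correlations` (tidy correlation table).
#' @export
run_cohort_study <- function(params,
                             config = pipeline_config(scales_px = c(1, 2),
                                                      closing_radius_px = 9L),
                             p_method = "auto", metrics = NULL) {
  coh <- generate_cohort(params)
  per_roi <- run_quantify(coh$bundles, config)
  metric_cols <- c("mfi_epithelium", "mfi_intermediate", "height_um",
                   "pct_accessible", "pct_intact",
                   "pct_fragmented_intermediate")
  samples <- average_rois(per_roi[, c("sample_id", "channel", metric_cols)])
  hormones <- substitute_lld(coh$hormones)
  merged <- merge(hormones, samples, by = "sample_id")
  cors <- correlate_cohort(merged, p_method = p_method, metrics = metrics)
  list(per_roi = per_roi, samples = merged, correlations = cors)
}
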