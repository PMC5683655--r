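# Scoring a pipeline run against the planted truth of a synthetic scenario.

#' Evaluate a pipeline result against the planted truth
#'
#' Computes the recovery metrics used to validate the pipeline on synthetic
#' data: the fraction of planted sites recovered by a DRM consensus peak and
#' the fraction of consensus peaks overlapping no planted site; Class I
#' recall and Class II specificity of the occupancy classification against
#' the planted class labels; the fraction of site-matched peaks whose
#' retention category equals the planted one; whether the Group A call set
#' equals the planted Group A genes; and the median relative error of the
#' recovered size factors. Because every planted site carries a true
#' occupancy decrease, a common within-condition scale is confounded with
#' the genotype effect, so size factors are compared after rescaling both
#' vectors to geometric mean 1 within each condition.
#'
#' @param result A `"drm_pipeline"` from [run_drm_pipeline()].
#' @param truth The scenario's `"drm_truth"`.
#' @return One-row tibble of metrics.
#' @export
evaluate_against_truth <- function(result, truth) {
  sites <- truth$sites
  wt <- result$wt_drm
  pr <- overlap_pairs(sites, wt)
  site_recovered <- seq_len(nrow(sites)) %in% pr$i
  peak_real <- seq_len(nrow(wt)) %in% pr$j

  cls <- result$classes |>
    inner_join(tibble(peak_id = sites$site_id, truth_class = sites$class_label),
               by = "peak_id")
  class1_recall <- mean(cls$class_label[cls$truth_class == "I"] == "I")
  class2_specificity <- mean(cls$class_label[cls$truth_class == "II"] == "II")

  # Retention: each WT DRM peak overlapping exactly one planted site is
  # compared to that site's planted retention category.
  match_tab <- tibble(peak = pr$j, site = pr$i) |>
    group_by(.data$peak) |>
    filter(n() == 1) |>
    ungroup()
  ret <- result$retention$category[match_tab$peak]
  ret_truth <- sites$retention_category[match_tab$site]
  retention_match <- if (length(ret)) mean(ret == ret_truth) else NA_real_

  group_a_called <- result$groups$gene_id[result$groups$group == "A"]
  sf_est <- attr(result$differential, "size_factors")
  sf_true <- truth$size_factors[names(sf_est)]
  cond <- ifelse(grepl("^wt", names(sf_est)), "WT", "mutant")
  rel <- sf_est / sf_true
  for (cc in unique(cond)) {
    i <- cond == cc
    rel[i] <- rel[i] / exp(mean(log(rel[i])))
  }
  tibble(
    n_drm_peaks = nrow(wt),
    n_sites = nrow(sites),
    site_recovery = mean(site_recovered),
    spurious_rate = if (nrow(wt)) mean(!peak_real) else NA_real_,
    class1_recall = class1_recall,
    class2_specificity = class2_specificity,
    retention_match = retention_match,
    group_a_exact = setequal(group_a_called, truth$group_a),
    group_a_called = length(group_a_called),
    group_a_truth = length(truth$group_a),
    size_factor_median_rel_err = median(abs(rel - 1))
  )
}
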