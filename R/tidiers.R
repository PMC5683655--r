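# broom-style tidiers for the package's result objects.

#' Tidy a differential-occupancy result
#' @param x A `"drm_diff"` from [test_occupancy()].
#' @param ... Unused.
#' @return A plain tibble of the per-(peak, subunit) results.
#' @export
tidy.drm_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "drm_diff")
  as_tibble(out)
}

#' One-row summary of a differential-occupancy result
#' @param x A `"drm_diff"` from [test_occupancy()].
#' @param ... Unused.
#' @return Tibble with test counts, the pooled dispersion and the FDR level.
#' @export
glance.drm_diff <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_significant_decrease = sum(x$significant_decrease),
    n_significant_increase = sum(x$significant_increase),
    dispersion = attr(x, "dispersion"),
    fdr_alpha = attr(x, "fdr_alpha")
  )
}

#' Tidy a peak classification
#' @param x A `"drm_classes"` from [classify_peaks()].
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.drm_classes <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "drm_classes")
  as_tibble(out)
}

#' One-row summary of a peak classification
#'
#' Reports the Class I / Class II split together with the share of Class I
#' peaks decreased for at least three and for all six tested subunits, and
#' the count of peaks with any significant increase.
#'
#' @param x A `"drm_classes"` from [classify_peaks()].
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.drm_classes <- function(x, ...) {
  n1 <- sum(x$class_label == "I")
  tibble(
    n_peaks = nrow(x),
    n_class1 = n1,
    n_class2 = sum(x$class_label == "II"),
    frac_class1_ge3_subunits = if (n1) mean(x$n_subunits_decreased[x$class_label == "I"] >= 3) else NA_real_,
    frac_class1_all6 = if (n1) mean(x$all_six_decreased[x$class_label == "I"]) else NA_real_,
    n_any_increase = sum(x$any_increased)
  )
}

#' Tidy an enrichment result
#' @param x A `"drm_enrichment"` row.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.drm_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "drm_enrichment")
  as_tibble(out)
}

#' One-row summary of an enrichment result
#' @param x A `"drm_enrichment"` row.
#' @param ... Unused.
#' @return Tibble with the observed/expected ratio and p-value.
#' @export
glance.drm_enrichment <- function(x, ...) {
  tibble(observed = x$k, expected = x$expected,
         fold_enrichment = ifelse(x$expected > 0, x$k / x$expected, NA_real_),
         p_value = x$p_value)
}
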