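# Differential occupancy: fragment counting, median-of-ratios size factors,
# a method-of-moments negative-binomial Wald test, BH-FDR, and the Class I /
# Class II peak classification.

#' Count fragments over consensus peaks
#'
#' A fragment is assigned to a peak when its midpoint
#' (`floor((start + end) / 2)`) lies inside the peak's half-open interval;
#' midpoint assignment makes the count unambiguous across adjacent peaks.
#'
#' @param fragments Tibble of fragment intervals with a `sample` column
#'   (optionally `subunit`).
#' @param peaks Consensus peak tibble with `peak_id`.
#' @return Long tibble `peak_id`, `sample`, `count` (plus `subunit` when the
#'   fragments carry one), complete over all peak x sample combinations.
#' @export
count_fragments <- function(fragments, peaks) {
  check_intervals(fragments, "fragments")
  check_intervals(peaks, "peaks")
  fragments <- as_tibble(fragments)
  fragments$`..mid` <- as.integer(floor((fragments$start + fragments$end) / 2))
  keys <- c("sample", intersect("subunit", names(fragments)))
  grid <- tidyr::expand_grid(peak_id = peaks$peak_id,
                             distinct(fragments[, keys, drop = FALSE]))
  mids <- tibble(chrom = fragments$chrom, start = fragments$`..mid`,
                 end = fragments$`..mid` + 1L)
  pr <- overlap_pairs(peaks, mids)
  hits <- bind_cols(peak_id = peaks$peak_id[pr$i], fragments[pr$j, keys, drop = FALSE])
  counted <- hits |> dplyr::count(dplyr::across(dplyr::all_of(c("peak_id", keys))), name = "count")
  grid |>
    left_join(counted, by = c("peak_id", keys)) |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Median-of-ratios size factors
#'
#' For sample j, `s_j` is the median over rows i (restricted to rows with
#' all-positive counts) of `c_ij / g_i`, where `g_i` is the row's geometric
#' mean across samples. The factors are then rescaled to geometric mean 1,
#' so identical samples get factors of exactly 1; ratios between samples are
#' unaffected by the rescaling.
#'
#' @param counts A samples-in-columns count matrix, or a long count tibble
#'   (`peak_id`, `subunit`, `sample`, `count`) which is pivoted internally.
#' @param pseudocount Added to every count before the ratio computation;
#'   default 0. When no row has all-positive counts the function stops and
#'   instructs the caller to rerun with `pseudocount = 1`.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts, pseudocount = 0) {
  mat <- counts_matrix(counts)$mat + pseudocount
  logmat <- log(mat)
  ok <- is.finite(rowSums(logmat))
  if (!any(ok)) {
    abort(paste0("no row has all-positive counts; rerun with `pseudocount = 1` ",
                 "(documented fallback) or filter rows first"))
  }
  g <- exp(rowMeans(logmat[ok, , drop = FALSE]))
  sf <- apply(mat[ok, , drop = FALSE], 2, function(cc) median(cc / g))
  sf / exp(mean(log(sf)))
}

# Accept either a numeric matrix (columns = samples) or the long tibble and
# return list(mat, rows); rows is a tibble of (peak_id, subunit) per matrix row.
counts_matrix <- function(counts) {
  if (is.matrix(counts)) {
    rows <- tibble(peak_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
                   subunit = NA_character_)
    return(list(mat = counts, rows = rows))
  }
  counts <- as_tibble(counts)
  need <- c("peak_id", "sample", "count")
  if (!all(need %in% names(counts))) {
    abort("long `counts` needs columns peak_id, sample, count (subunit optional)")
  }
  if (!"subunit" %in% names(counts)) counts$subunit <- NA_character_
  wide <- counts |>
    select("peak_id", "subunit", "sample", "count") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count")
  mat <- as.matrix(wide[, -(1:2)])
  if (anyNA(mat)) abort("count table is not complete over peak x sample")
  if (any(mat < 0)) abort("negative counts")
  list(mat = mat, rows = wide[, 1:2])
}

#' Negative-binomial Wald test for occupancy change
#'
#' Tests every (peak, subunit) row of a count table for a difference between
#' mutant and wild-type occupancy. Counts are normalised by size factors,
#' a single method-of-moments dispersion is pooled across all rows of the
#' table (`alpha = max(eps, (V - M) / M^2)` with `V` the average within-group
#' variance and `M` the average group-pooled mean, `eps = 1e-8`), and each
#' row gets a Wald z statistic
#' `log2fc / SE` with `log2fc = log2((mu_mut + 0.5) / (mu_wt + 0.5))` and
#' `SE^2 = (1/ln 2)^2 * [(1/n_wt)(1/(mu_wt+0.5) + alpha) +
#' (1/n_mut)(1/(mu_mut+0.5) + alpha)]`; p is the two-sided standard normal
#' tail. FDR is controlled per subunit family with [bh_fdr()].
#'
#' @param counts Long count tibble (`peak_id`, `subunit`, `sample`,
#'   `count`).
#' @param samples Tibble `sample`, `condition` (`"WT"`/`"mutant"`),
#'   `replicate`.
#' @param config A [drm_config()] (supplies `fdr_alpha`).
#' @param size_factors Optional named per-sample factors; estimated with
#'   [size_factors()] when omitted.
#' @return A tibble of class `"drm_diff"`: `peak_id`, `subunit`, `log2fc`,
#'   `p_value`, `fdr`, `significant_decrease`, `significant_increase`.
#'   Attributes record the dispersion and size factors used.
#' @export
test_occupancy <- function(counts, samples, config = drm_config(),
                           size_factors = NULL) {
  cm <- counts_matrix(counts)
  samples <- as_tibble(samples)
  if (!all(colnames(cm$mat) %in% samples$sample)) {
    abort("every count column needs a row in `samples`")
  }
  cond <- samples$condition[match(colnames(cm$mat), samples$sample)]
  if (!all(c("WT", "mutant") %in% cond)) abort("need samples in both conditions (WT, mutant)")
  n_wt <- sum(cond == "WT"); n_mut <- sum(cond == "mutant")
  if (n_wt < 2 || n_mut < 2) abort("need >= 2 replicates per condition")
  if (is.null(size_factors)) {
    size_factors <- size_factors(cm$mat)
  }
  sf <- size_factors[colnames(cm$mat)]
  if (anyNA(sf)) abort("size factors missing for some samples")
  y <- sweep(cm$mat, 2, sf, "/")
  yw <- y[, cond == "WT", drop = FALSE]
  ym <- y[, cond == "mutant", drop = FALSE]
  mu_wt <- rowMeans(yw); mu_mut <- rowMeans(ym)
  v_wt <- apply(yw, 1, var); v_mut <- apply(ym, 1, var)
  v_pool <- ((n_wt - 1) * v_wt + (n_mut - 1) * v_mut) / (n_wt + n_mut - 2)
  m_pool <- (n_wt * mu_wt + n_mut * mu_mut) / (n_wt + n_mut)
  alpha <- max(1e-8, (mean(v_pool) - mean(m_pool)) / mean(m_pool)^2)
  log2fc <- log2((mu_mut + 0.5) / (mu_wt + 0.5))
  se2 <- (1 / log(2))^2 * ((1 / n_wt) * (1 / (mu_wt + 0.5) + alpha) +
                             (1 / n_mut) * (1 / (mu_mut + 0.5) + alpha))
  z <- log2fc / sqrt(se2)
  p <- pmin(1, 2 * pnorm(-abs(z)))
  res <- bind_cols(cm$rows, tibble(log2fc = log2fc, p_value = p))
  res <- res |>
    group_by(.data$subunit) |>
    mutate(fdr = bh_fdr(.data$p_value)) |>
    ungroup() |>
    mutate(significant_decrease = .data$fdr < config$fdr_alpha & .data$log2fc < 0,
           significant_increase = .data$fdr < config$fdr_alpha & .data$log2fc > 0)
  attr(res, "dispersion") <- alpha
  attr(res, "size_factors") <- sf
  attr(res, "fdr_alpha") <- config$fdr_alpha
  class(res) <- c("drm_diff", class(res))
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as a named step
#' so the multiplicity correction used by the pipeline is explicit.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values in the input order (empty in, empty out).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) abort("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Classify peaks into occupancy Class I and Class II
#'
#' Class I: occupancy significantly decreased in the mutant (BH FDR below
#' `fdr_alpha`, negative log2 fold change) for at least one of the six
#' tested subunits (DPL-1, EFL-1, LIN-9, LIN-37, LIN-52, LIN-54; LIN-35 is
#' not tested in its own null mutant). Class II: no significant decrease for
#' any subunit. The two classes partition the tested peaks.
#'
#' @param results A `"drm_diff"` tibble from [test_occupancy()].
#' @param config A [drm_config()].
#' @return A tibble of class `"drm_classes"`: `peak_id`, `class_label`
#'   (`"I"`/`"II"`), `n_subunits_decreased`, `all_six_decreased`,
#'   `any_increased`.
#' @export
classify_peaks <- function(results, config = drm_config()) {
  results <- as_tibble(results)
  by_peak <- results |>
    filter(.data$subunit %in% TESTED_SUBUNITS) |>
    group_by(.data$peak_id) |>
    summarise(
      n_tested = dplyr::n_distinct(.data$subunit),
      n_subunits_decreased = sum(.data$significant_decrease),
      any_increased = any(.data$significant_increase),
      .groups = "drop"
    )
  short <- by_peak |> filter(.data$n_tested < length(TESTED_SUBUNITS))
  if (nrow(short)) {
    abort(sprintf("peak %s has results for only %d of the %d tested subunits",
                  short$peak_id[1], short$n_tested[1], length(TESTED_SUBUNITS)))
  }
  out <- by_peak |>
    mutate(class_label = ifelse(.data$n_subunits_decreased >= 1, "I", "II"),
           all_six_decreased = .data$n_subunits_decreased == length(TESTED_SUBUNITS)) |>
    select("peak_id", "class_label", "n_subunits_decreased",
           "all_six_decreased", "any_increased")
  class(out) <- c("drm_classes", class(out))
  out
}
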