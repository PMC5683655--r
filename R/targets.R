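# Target-gene expression module: thresholding differential-expression call
# tables, Group A/B classification of DRM target genes, overlap enrichment,
# and the qPCR quantities used for validation.

#' Apply significance thresholds to a differential-expression table
#'
#' A gene is `up` when its q-value is below `de_q_threshold` and its linear
#' fold change exceeds `de_fc_threshold` (i.e. `log2fc > log2(threshold)`);
#' `down` symmetrically; otherwise `unchanged`.
#'
#' @param stats Tibble with `gene_id`, `log2fc`, `q_value` and (optionally)
#'   `experiment` labels.
#' @param config A [drm_config()].
#' @return The input plus a `direction` column (`up`/`down`/`unchanged`).
#' @examples
#' apply_de_thresholds(tibble::tibble(gene_id = "a", log2fc = 0.68, q_value = 0.04))
#' @export
apply_de_thresholds <- function(stats, config = drm_config()) {
  stats <- as_tibble(stats)
  need <- c("gene_id", "log2fc", "q_value")
  miss <- setdiff(need, names(stats))
  if (length(miss)) abort(sprintf("`stats` is missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(stats$q_value <= 0 | stats$q_value > 1)) abort("q-values must lie in (0, 1]")
  lfc_cut <- log2(config$de_fc_threshold)
  stats |>
    mutate(direction = dplyr::case_when(
      .data$q_value < config$de_q_threshold & .data$log2fc > lfc_cut ~ "up",
      .data$q_value < config$de_q_threshold & .data$log2fc < -lfc_cut ~ "down",
      TRUE ~ "unchanged"
    ))
}

#' Partition DRM target genes into Group A and Group B
#'
#' Group A ("high-confidence DRM targets"): genes bound by DRM in their
#' promoter AND called `up` in at least one differential-expression
#' experiment. Group B: the remaining DRM target genes. The two groups
#' partition the target set.
#'
#' @param drm_targets Character vector of DRM target gene ids
#'   ([extract_target_genes()]).
#' @param calls Expression-call tibble ([apply_de_thresholds()]) with an
#'   `experiment` column (a constant label is filled in when absent).
#' @return Tibble `gene_id`, `group` (`"A"`/`"B"`), `supporting_experiments`
#'   (list-column of experiment labels with an `up` call).
#' @export
group_targets <- function(drm_targets, calls) {
  calls <- as_tibble(calls)
  if (!"experiment" %in% names(calls)) calls$experiment <- "experiment_1"
  up <- calls |>
    filter(.data$direction == "up", .data$gene_id %in% drm_targets) |>
    group_by(.data$gene_id) |>
    summarise(supporting_experiments = list(sort(unique(.data$experiment))),
              .groups = "drop")
  tibble(gene_id = sort(unique(drm_targets))) |>
    left_join(up, by = "gene_id") |>
    mutate(
      supporting_experiments = map(.data$supporting_experiments, function(x) x %||% character(0)),
      group = ifelse(lengths(.data$supporting_experiments) > 0, "A", "B")
    ) |>
    select("gene_id", "group", "supporting_experiments")
}

#' Hypergeometric enrichment of DRM targets in a gene set
#'
#' Tests whether a differential-expression gene set overlaps the DRM target
#' genes more than expected by chance, over a stated gene universe:
#' `k = |targets & de_set|`, `K = |targets|`, `n = |de_set|`,
#' `N = |universe|`, upper-tail hypergeometric.
#'
#' @param targets Character vector of DRM target genes (subset of universe).
#' @param de_set Character vector of differentially expressed genes (subset
#'   of universe).
#' @param universe Character vector: all genes considered.
#' @return A `"drm_enrichment"` row (see [hypergeom_upper_tail()]).
#' @export
group_enrichment <- function(targets, de_set, universe) {
  targets <- unique(targets); de_set <- unique(de_set); universe <- unique(universe)
  if (!all(targets %in% universe)) abort("`targets` must be a subset of `universe`")
  if (!all(de_set %in% universe)) abort("`de_set` must be a subset of `universe`")
  hypergeom_upper_tail(k = length(intersect(targets, de_set)),
                       K = length(targets), n = length(de_set),
                       N = length(universe))
}

#' Relative quantity (Rq) from qPCR Ct values with efficiency correction
#'
#' For each sample, `Rq = E_ref^Ct_ref / E_target^Ct_target` relative to the
#' reference gene (act-2 in the wet-lab design). With equal efficiencies
#' this reduces to `E^(Ct_ref - Ct_target)`.
#'
#' @param records Tibble `sample_id`, `gene_id`, `ct`, and optionally
#'   `efficiency` (amplification efficiency in (1, 2]; defaults to 2).
#' @param target_gene Gene to quantify.
#' @param reference_gene Reference (control) gene; every sample must have it.
#' @return List with `per_sample` (tibble `sample_id`, `rq`), `mean_rq` and
#'   `sem_rq`.
#' @examples
#' rec <- tibble::tibble(sample_id = rep(c("s1", "s2"), each = 2),
#'                       gene_id = rep(c("cdk-1", "act-2"), 2),
#'                       ct = c(21, 22, 20.5, 22))
#' qpcr_relative_quantity(rec, "cdk-1", "act-2")
#' @export
qpcr_relative_quantity <- function(records, target_gene, reference_gene = "act-2") {
  records <- as_tibble(records)
  if (!"efficiency" %in% names(records)) records$efficiency <- 2
  records$efficiency[is.na(records$efficiency)] <- 2
  if (any(records$efficiency <= 1 | records$efficiency > 2)) {
    abort("amplification efficiencies must lie in (1, 2]")
  }
  if (any(records$ct <= 0)) abort("Ct values must be positive")
  per_sample <- records |>
    filter(.data$gene_id %in% c(target_gene, reference_gene)) |>
    group_by(.data$sample_id) |>
    summarise(
      rq = {
        it <- which(.data$gene_id == target_gene)
        ir <- which(.data$gene_id == reference_gene)
        if (length(ir) == 0) abort(sprintf("sample %s lacks the reference gene %s",
                                           .data$sample_id[1], reference_gene))
        if (length(it) == 0) abort(sprintf("sample %s lacks the target gene %s",
                                           .data$sample_id[1], target_gene))
        .data$efficiency[ir[1]]^.data$ct[ir[1]] / .data$efficiency[it[1]]^.data$ct[it[1]]
      },
      .groups = "drop"
    )
  n <- nrow(per_sample)
  list(per_sample = per_sample,
       mean_rq = mean(per_sample$rq),
       sem_rq = if (n > 1) sd(per_sample$rq) / sqrt(n) else NA_real_)
}

#' Log2 fold enrichment for ChIP-qPCR
#'
#' Enrichment of the ChIP signal at a target region over a negative control
#' region, from Ct values of ChIP and input material at both regions
#' (amplification efficiency 2 assumed at all amplicons):
#' `log2FE = (Ct_chip_ctrl - Ct_input_ctrl) - (Ct_chip_target - Ct_input_target)`.
#' Antisymmetric under swapping the target and control regions.
#'
#' @param ct_chip_target,ct_input_target Ct of the target amplicon in ChIP
#'   and input.
#' @param ct_chip_ctrl,ct_input_ctrl Ct of the negative-control amplicon in
#'   ChIP and input.
#' @return Numeric log2 fold enrichment.
#' @examples
#' chipqpcr_log2_enrichment(20, 22, 24, 24) # target dCt 2 cycles lower -> +2
#' @export
chipqpcr_log2_enrichment <- function(ct_chip_target, ct_input_target,
                                     ct_chip_ctrl, ct_input_ctrl) {
  (ct_chip_ctrl - ct_input_ctrl) - (ct_chip_target - ct_input_target)
}
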