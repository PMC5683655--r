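# End-to-end orchestration: from per-subunit replicate peak calls and count
# tables to consensus peaks, retention, occupancy classes, annotation,
# motif enrichment and target groups.

#' Run the full DRM occupancy pipeline on a scenario
#'
#' Chains every stage of the analysis: replicate reproducibility filtering
#' per subunit, the E2F-DP / LIN-35 / MuvB consensus vote in the wild type,
#' mutant E2F-DP and MuvB consensus regions and retention classification,
#' size-factor normalised NB Wald tests and Class I/II calls from the count
#' table, promoter annotation and target-gene extraction, conserved CDE/CHR
#' motif presence with hypergeometric enrichment over background promoters
#' and a chi-squared class association, and Group A/B target classification
#' from the expression calls.
#'
#' @param scenario A `"drm_scenario"` ([simulate_drm_scenario()]) or a list
#'   with the same components (`peaks`, `genes`, `counts`, `samples`,
#'   `genome`, `conservation`, `expression`, and optionally `count_regions`).
#' @param config A [drm_config()].
#' @return List of class `"drm_pipeline"` with components `wt_drm`,
#'   `mut_e2fdp`, `mut_muvb`, `retention`, `differential`, `classes`,
#'   `annotation`, `annotation_summary`, `target_genes`, `motif_presence`,
#'   `motif_enrichment`, `class_chi2`, `expression_calls`, `groups`,
#'   `group_enrichment`.
#' @export
run_drm_pipeline <- function(scenario, config = drm_config()) {
  peaks <- scenario$peaks
  rep_filter <- function(condition, subunits) {
    sets <- list()
    for (s in subunits) {
      sub <- filter(peaks, .data$condition == !!condition, .data$subunit == s)
      if (nrow(sub)) sets[[s]] <- reproducible_peaks(sub, config$min_replicates)
    }
    sets
  }
  wt_sets <- rep_filter("WT", DRM_SUBUNITS)
  wt_drm <- consensus_drm(wt_sets, config)

  mut_sets <- rep_filter("mutant", c(E2FDP_SUBUNITS, MUVB_SUBUNITS))
  mut_e2fdp <- if (all(E2FDP_SUBUNITS %in% names(mut_sets))) {
    overlap_vote(mut_sets[E2FDP_SUBUNITS], 2L, id_prefix = "mut_e2fdp")
  } else empty_consensus()
  present_muvb <- intersect(MUVB_SUBUNITS, names(mut_sets))
  mut_muvb <- if (length(present_muvb) >= config$muvb_vote_k) {
    overlap_vote(mut_sets[present_muvb], config$muvb_vote_k, id_prefix = "mut_muvb")
  } else empty_consensus()
  retention <- retention_classify(wt_drm, mut_e2fdp, mut_muvb)

  differential <- test_occupancy(scenario$counts, scenario$samples, config)
  classes <- classify_peaks(differential, config)

  annotation <- annotate_peaks(wt_drm, scenario$genes, config)
  annotation_summary <- summarize_annotation(annotation)
  target_genes <- extract_target_genes(annotation)

  # Motifs: conserved CDE/CHR presence per DRM peak, enrichment against the
  # promoters of non-target genes as background universe.
  bg_windows <- promoter_windows(
    filter(scenario$genes, !.data$gene_id %in% target_genes), config)
  chr_pres <- region_motif_presence(wt_drm, scenario$genome, config$chr_pattern,
                                    config$chr_max_mismatch,
                                    scenario$conservation, config)
  cde_pres <- region_motif_presence(wt_drm, scenario$genome, config$cde_pattern,
                                    config$cde_max_mismatch,
                                    scenario$conservation, config)
  chr_bg <- region_motif_presence(bg_windows, scenario$genome, config$chr_pattern,
                                  config$chr_max_mismatch,
                                  scenario$conservation, config)
  cde_bg <- region_motif_presence(bg_windows, scenario$genome, config$cde_pattern,
                                  config$cde_max_mismatch,
                                  scenario$conservation, config)
  enrich_one <- function(pres, bg) {
    hypergeom_upper_tail(k = sum(pres$has_motif),
                         K = sum(pres$has_motif) + sum(bg$has_motif),
                         n = nrow(pres), N = nrow(pres) + nrow(bg))
  }
  motif_enrichment <- bind_rows(
    mutate(enrich_one(chr_pres, chr_bg), motif = "CHR", .before = 1),
    mutate(enrich_one(cde_pres, cde_bg), motif = "CDE", .before = 1)
  )

  # Chi-squared class association needs a class per DRM peak: peaks inherit
  # the class of the count region (site) they overlap.
  regions <- scenario$count_regions %||%
    (if (!is.null(scenario$truth)) scenario$truth$sites else NULL)
  class_chi2 <- NULL
  peak_classes <- NULL
  if (!is.null(regions)) {
    pr <- overlap_pairs(wt_drm, regions)
    region_id <- regions$site_id %||% regions$peak_id
    map_tab <- tibble(peak_id = wt_drm$peak_id[pr$i], region = region_id[pr$j]) |>
      distinct(.data$peak_id, .keep_all = TRUE) |>
      left_join(tibble(region = classes$peak_id, class_label = classes$class_label),
                by = "region")
    peak_classes <- left_join(tibble(peak_id = wt_drm$peak_id), map_tab, by = "peak_id")
    joined <- peak_classes |>
      left_join(select(chr_pres, "region_id", "has_motif"),
                by = c(peak_id = "region_id")) |>
      filter(!is.na(.data$class_label))
    class_chi2 <- tryCatch(
      class_association_chi2(joined$has_motif, joined$class_label),
      error = function(e) NULL)
  }

  expression_calls <- apply_de_thresholds(scenario$expression, config)
  groups <- group_targets(target_genes, expression_calls)
  up_genes <- unique(expression_calls$gene_id[expression_calls$direction == "up"])
  grp_enr <- group_enrichment(targets = target_genes, de_set = up_genes,
                              universe = unique(scenario$genes$gene_id))

  structure(list(
    wt_drm = wt_drm, mut_e2fdp = mut_e2fdp, mut_muvb = mut_muvb,
    retention = retention, differential = differential, classes = classes,
    annotation = annotation, annotation_summary = annotation_summary,
    target_genes = target_genes, motif_presence = list(chr = chr_pres, cde = cde_pres),
    motif_background = list(chr = chr_bg, cde = cde_bg),
    motif_enrichment = motif_enrichment, peak_classes = peak_classes,
    class_chi2 = class_chi2, expression_calls = expression_calls,
    groups = groups, group_enrichment = grp_enr, config = config
  ), class = "drm_pipeline")
}

#' @export
print.drm_pipeline <- function(x, ...) {
  cat("DRM occupancy pipeline result\n")
  cat(sprintf("  high-confidence DRM peaks : %d\n", nrow(x$wt_drm)))
  rt <- table(x$retention$category)
  cat(sprintf("  retention                 : %s\n",
              paste(sprintf("%s=%d", names(rt), rt), collapse = ", ")))
  n_of <- function(t, k) if (k %in% names(t)) t[[k]] else 0L
  cl <- table(x$classes$class_label)
  cat(sprintf("  occupancy classes         : I=%d, II=%d\n",
              n_of(cl, "I"), n_of(cl, "II")))
  cat(sprintf("  promoter share            : %s%%\n", x$annotation_summary$promoter_percentage))
  cat(sprintf("  DRM target genes          : %d (Group A: %d)\n",
              length(x$target_genes), sum(x$groups$group == "A")))
  invisible(x)
}
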