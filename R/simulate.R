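# Seeded synthetic-data generator. Emulates the statistical structure of the
# real study: co-bound promoter sites detected independently by each subunit
# with boundary jitter and dropout, genotype-dependent occupancy loss
# realised as negative-binomial counts, planted conserved CDE/CHR motifs,
# and expression tables in which a subset of bound genes is upregulated in
# the mutant. A machine-readable truth object makes every pipeline stage
# testable without external data.

#' Default parameters of the synthetic scenario
#'
#' The defaults define the study conditions used throughout the package's
#' tests: a 2 x 1 Mb toy genome, 400 genes (30% in divergent pairs), 150
#' co-bound promoter sites, per-subunit per-replicate detection probability
#' 0.9 with 50 bp boundary jitter, 3 replicates per genotype,
#' negative-binomial counts (baseline mean 200, dispersion 0.05) with a 60%
#' strong (log2fc ~ N(-2, 0.5)) / 40% weak (log2fc ~ N(-0.3, 0.2)) occupancy
#' drop in the mutant, CHR motifs planted in 60% and CDE in 45% of sites
#' with conservation Uniform(0.8, 1) over planted spans against a Beta(1, 3)
#' background, a 40/45/15 retained-both / lost-both / retained-one retention
#' pattern, and 40% of bound genes upregulated (log2fc ~ N(1.2, 0.3)
#' truncated above log2(1.5), q ~ Uniform(0.001, 0.04)) in at least one of
#' three expression experiments.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `"drm_scenario_params"`.
#' @export
drm_scenario_params <- function(...) {
  p <- list(
    n_chroms = 2L, chrom_length = 1000000L,
    n_genes = 400L, divergent_pair_fraction = 0.3,
    gene_length_min = 1000L, gene_length_max = 4000L,
    gap_min = 500L, gap_max = 2500L,
    pair_tss_gap_min = 300L, pair_tss_gap_max = 800L,
    n_sites = 150L,
    detection_prob = 0.9, jitter_sd = 50,
    peak_width_mean = 300, peak_width_sd = 100,
    peak_width_min = 100L, peak_width_max = 800L,
    noise_peaks = 30L, n_replicates = 3L,
    baseline_mean = 200, dispersion = 0.05,
    strong_fraction = 0.6,
    strong_lfc_mean = -2, strong_lfc_sd = 0.5,
    weak_lfc_mean = -0.3, weak_lfc_sd = 0.2,
    retain_both = 0.40, retain_none = 0.45, retain_one = 0.15,
    chr_plant_rate = 0.6, cde_plant_rate = 0.45,
    cons_motif_min = 0.8, cons_motif_max = 1.0,
    cons_bg_shape1 = 1, cons_bg_shape2 = 3, cons_bin = 100L,
    gc_content = 0.36,
    size_factor_min = 0.7, size_factor_max = 1.4,
    group_a_fraction = 0.4,
    group_a_lfc_mean = 1.2, group_a_lfc_sd = 0.3,
    group_a_q_min = 0.001, group_a_q_max = 0.04,
    experiment_labels = c("lin35_EE", "lin35_L1", "lin54_ME"),
    experiment_support_prob = 0.6
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) abort(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")))
  p[names(dots)] <- dots
  probs <- c(p$divergent_pair_fraction, p$detection_prob, p$strong_fraction,
             p$retain_both, p$retain_none, p$retain_one,
             p$chr_plant_rate, p$cde_plant_rate, p$group_a_fraction,
             p$experiment_support_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            abs(p$retain_both + p$retain_none + p$retain_one - 1) < 1e-9)
  structure(p, class = "drm_scenario_params")
}

# Derived per-component RNG substreams: components can be regenerated
# independently of each other from the one scenario seed.
sub_seed <- function(seed, component) {
  as.integer((as.numeric(seed) + 1000003 * component) %% 2147483629 + 1)
}

gen_genes <- function(params, seed) {
  set.seed(sub_seed(seed, 1L))
  p <- params
  n_per_chrom <- ceiling(p$n_genes / p$n_chroms)
  n_pair_genes <- 2L * round(p$n_genes * p$divergent_pair_fraction / 2)
  rows <- list(); pair_of <- character(0)
  gid <- 0L
  for (ci in seq_len(p$n_chroms)) {
    chrom <- sprintf("chr%s", as.character(utils::as.roman(ci)))
    cursor <- 2000L
    placed <- 0L
    while (placed < n_per_chrom && gid < p$n_genes) {
      want_pair <- gid < n_pair_genes && (placed + 2L) <= n_per_chrom
      if (want_pair) {
        len_a <- round(runif(1, p$gene_length_min, p$gene_length_max))
        len_b <- round(runif(1, p$gene_length_min, p$gene_length_max))
        tss_gap <- round(runif(1, p$pair_tss_gap_min, p$pair_tss_gap_max))
        a_start <- cursor; a_end <- a_start + len_a          # '-' gene, TSS at a_end
        b_start <- a_end + tss_gap; b_end <- b_start + len_b # '+' gene, TSS at b_start
        if (b_end + 2000L > p$chrom_length) {
          abort("infeasible packing: too many genes for the chromosome length")
        }
        gid <- gid + 1L
        id_a <- sprintf("gene_%03d", gid)
        rows[[length(rows) + 1L]] <- list(id_a, chrom, "-", a_start, a_end)
        gid <- gid + 1L
        id_b <- sprintf("gene_%03d", gid)
        rows[[length(rows) + 1L]] <- list(id_b, chrom, "+", b_start, b_end)
        pair_of <- c(pair_of, setNames(c(id_b, id_a), c(id_a, id_b)))
        cursor <- b_end + round(runif(1, p$gap_min, p$gap_max))
        placed <- placed + 2L
      } else {
        len <- round(runif(1, p$gene_length_min, p$gene_length_max))
        strand <- sample(c("+", "-"), 1)
        if (cursor + len + 2000L > p$chrom_length) {
          abort("infeasible packing: too many genes for the chromosome length")
        }
        gid <- gid + 1L
        rows[[length(rows) + 1L]] <- list(sprintf("gene_%03d", gid), chrom, strand,
                                          cursor, cursor + len)
        cursor <- cursor + len + round(runif(1, p$gap_min, p$gap_max))
        placed <- placed + 1L
      }
    }
  }
  tab <- purrr::transpose(rows)
  start <- as.integer(unlist(tab[[4]])); end <- as.integer(unlist(tab[[5]]))
  len <- end - start
  e1 <- pmax(50L, as.integer(round(0.3 * len)))
  intron <- pmax(50L, as.integer(round(0.3 * len)))
  exon_starts <- map2(start, e1 + intron, function(s, off) c(s, s + off))
  exon_ends <- pmap(list(start, e1, end), function(s, a, e) c(s + a, e))
  genes <- gene_models(unlist(tab[[1]]), unlist(tab[[2]]), unlist(tab[[3]]),
                       start, end, exon_starts, exon_ends)
  attr(genes, "pair_of") <- pair_of
  genes
}

gen_sites <- function(genes, params, config, seed) {
  set.seed(sub_seed(seed, 2L))
  p <- params
  pair_of <- attr(genes, "pair_of")
  prom <- promoter_windows(genes, config)
  # Promoter slots: one per single gene, one shared per divergent pair.
  paired <- names(pair_of)
  first_of_pair <- paired[paired < pair_of[paired]]
  slots <- c(setdiff(genes$gene_id, paired), first_of_pair)
  if (length(slots) < p$n_sites) abort("not enough promoter slots for the requested sites")
  chosen <- sample(slots, p$n_sites)
  mk <- function(g) {
    w1 <- prom[prom$gene_id == g, ]
    if (g %in% paired) {
      w2 <- prom[prom$gene_id == pair_of[[g]], ]
      lo <- max(w1$start, w2$start); hi <- min(w1$end, w2$end)
      gene_ids <- sort(c(g, pair_of[[g]]))
    } else {
      lo <- w1$start; hi <- w1$end
      gene_ids <- g
    }
    width <- round(rnorm(1, p$peak_width_mean, p$peak_width_sd))
    width <- min(max(width, p$peak_width_min), p$peak_width_max)
    clo <- lo + ceiling(width / 2); chi <- hi - floor(width / 2)
    center <- if (clo < chi) round(runif(1, clo, chi)) else round((lo + hi) / 2)
    tibble(chrom = w1$chrom, start = as.integer(center - floor(width / 2)),
           end = as.integer(center - floor(width / 2) + width),
           center = as.integer(center), gene_ids = list(gene_ids))
  }
  sites <- bind_rows(map(chosen, mk))
  n <- nrow(sites)
  strong <- runif(n) < p$strong_fraction
  lfc <- ifelse(strong, rnorm(n, p$strong_lfc_mean, p$strong_lfc_sd),
                rnorm(n, p$weak_lfc_mean, p$weak_lfc_sd))
  ret <- sample(c("retained_both", "lost_both", "retained_one"), n, replace = TRUE,
                prob = c(p$retain_both, p$retain_none, p$retain_one))
  one_is_e2f <- runif(n) < 0.5
  chr_planted <- runif(n) < p$chr_plant_rate
  cde_planted <- runif(n) < p$cde_plant_rate
  third <- pmax(6L, as.integer(floor((sites$end - sites$start) / 3)))
  chr_pos <- sites$start + as.integer(floor(runif(n) * (third - 6L)))
  cde_pos <- sites$end - third + as.integer(floor(runif(n) * (third - 6L)))
  sites |>
    mutate(
      site_id = sprintf("site_%03d", dplyr::row_number()),
      class_label = ifelse(strong, "I", "II"),
      true_log2fc = lfc,
      retention_category = ret,
      retain_e2fdp = ret == "retained_both" | (ret == "retained_one" & one_is_e2f),
      retain_muvb = ret == "retained_both" | (ret == "retained_one" & !one_is_e2f),
      chr_planted = chr_planted,
      chr_pos = ifelse(chr_planted, chr_pos, NA_integer_),
      cde_planted = cde_planted,
      cde_pos = ifelse(cde_planted, cde_pos, NA_integer_)
    ) |>
    select("site_id", dplyr::everything())
}

gen_peaks <- function(sites, params, seed) {
  set.seed(sub_seed(seed, 3L))
  p <- params
  jit <- function(n) if (p$jitter_sd > 0) round(rnorm(n, 0, p$jitter_sd)) else integer(n)
  chroms <- unique(sites$chrom)
  out <- list()
  for (condition in c("WT", "mutant")) {
    for (subunit in DRM_SUBUNITS) {
      detectable <- if (condition == "WT") {
        rep(TRUE, nrow(sites))
      } else if (subunit %in% E2FDP_SUBUNITS) {
        sites$retain_e2fdp
      } else if (subunit %in% MUVB_SUBUNITS) {
        sites$retain_muvb
      } else {
        rep(FALSE, nrow(sites))   # LIN-35 is absent in its own null mutant
      }
      for (rep_i in seq_len(p$n_replicates)) {
        hit <- detectable & runif(nrow(sites)) < p$detection_prob
        idx <- which(hit)
        if (length(idx)) {
          s <- pmax(0L, sites$start[idx] + jit(length(idx)))
          e <- sites$end[idx] + jit(length(idx))
          e <- pmax(e, s + 50L)
          summit <- pmin(pmax(sites$center[idx] - s, 0L), e - s - 1L)
          site_peaks <- tibble(
            chrom = sites$chrom[idx], start = as.integer(s), end = as.integer(e),
            name = sprintf("%s_%s_r%d_%s", subunit, condition, rep_i, sites$site_id[idx]),
            score = runif(length(idx), 5, 100), strand = "*",
            summit = as.integer(summit),
            subunit = subunit, replicate = sprintf("r%d", rep_i), condition = condition
          )
        } else site_peaks <- NULL
        nw <- round(rnorm(p$noise_peaks, p$peak_width_mean, p$peak_width_sd))
        nw <- pmin(pmax(nw, p$peak_width_min), p$peak_width_max)
        ns <- as.integer(floor(runif(p$noise_peaks, 0, p$chrom_length - nw)))
        noise <- tibble(
          chrom = sample(chroms, p$noise_peaks, replace = TRUE),
          start = ns, end = as.integer(ns + nw),
          name = sprintf("%s_%s_r%d_noise%02d", subunit, condition, rep_i,
                         seq_len(p$noise_peaks)),
          score = runif(p$noise_peaks, 5, 100), strand = "*",
          summit = as.integer(floor(nw / 2)),
          subunit = subunit, replicate = sprintf("r%d", rep_i), condition = condition
        )
        out[[length(out) + 1L]] <- bind_rows(site_peaks, noise)
      }
    }
  }
  bind_rows(out)
}

#' Generate negative-binomial occupancy counts from a planted truth
#'
#' One row per (site, tested subunit), six samples (3 WT + 3 mutant):
#' counts are drawn from a negative binomial with mean
#' `baseline * 2^(log2fc * is_mutant) * size_factor_j` and the scenario
#' dispersion; per-sample size factors are drawn Uniform(0.7, 1.4) and
#' recorded in the returned attributes.
#'
#' @param truth A `"drm_truth"` object (or its `sites` tibble).
#' @param params A [drm_scenario_params()].
#' @param seed Scenario seed (the counts use a derived substream).
#' @return List with `counts` (long tibble: `peak_id`, `subunit`, `sample`,
#'   `condition`, `replicate`, `count`), `samples`, and the true
#'   `size_factors`.
#' @export
generate_counts <- function(truth, params = drm_scenario_params(), seed = 1L) {
  set.seed(sub_seed(seed, 4L))
  p <- params
  sites <- if (is.data.frame(truth)) truth else truth$sites
  samples <- tibble(
    sample = c(sprintf("wt_%d", seq_len(p$n_replicates)),
               sprintf("mut_%d", seq_len(p$n_replicates))),
    condition = rep(c("WT", "mutant"), each = p$n_replicates),
    replicate = rep(sprintf("r%d", seq_len(p$n_replicates)), 2)
  )
  sf <- runif(nrow(samples), p$size_factor_min, p$size_factor_max)
  names(sf) <- samples$sample
  grid <- tidyr::expand_grid(
    tibble(peak_id = sites$site_id, true_log2fc = sites$true_log2fc),
    subunit = TESTED_SUBUNITS
  ) |> tidyr::expand_grid(samples)
  mu <- p$baseline_mean * 2^(grid$true_log2fc * (grid$condition == "mutant")) *
    sf[grid$sample]
  grid$count <- rnbinom(nrow(grid), mu = mu, size = 1 / p$dispersion)
  list(counts = grid[, c("peak_id", "subunit", "sample", "condition", "replicate", "count")],
       samples = samples, size_factors = sf)
}

#' Generate the toy genome and conservation track from a planted truth
#'
#' The genome is random sequence at 36% GC (worm-like); planted CHR/CDE
#' motif instances (exact matches of their IUPAC patterns) are written into
#' the planned positions. The conservation track is Beta(1, 3) background in
#' fixed-width bins with one overriding row per planted motif span drawn
#' Uniform(0.8, 1), so planted spans are conserved above 0.7 by
#' construction.
#'
#' @param truth A `"drm_truth"` object (or its `sites` tibble).
#' @param params A [drm_scenario_params()].
#' @param seed Scenario seed (derived substream).
#' @return List with `genome` (named character), `conservation` (bedGraph
#'   tibble), and `instances` (tibble of planted motif instances).
#' @export
generate_sequences <- function(truth, params = drm_scenario_params(), seed = 1L) {
  set.seed(sub_seed(seed, 5L))
  p <- params
  sites <- if (is.data.frame(truth)) truth else truth$sites
  gc <- p$gc_content
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chroms <- sprintf("chr%s", as.character(utils::as.roman(seq_len(p$n_chroms))))
  chars <- setNames(lapply(chroms, function(ch) {
    sample(names(base_probs), p$chrom_length, replace = TRUE, prob = base_probs)
  }), chroms)
  draw_instance <- function(pattern) {
    paste(map_chr(strsplit(pattern, "")[[1]],
                  function(sym) sample(IUPAC_CLASSES[[sym]], 1)), collapse = "")
  }
  inst <- list()
  for (i in seq_len(nrow(sites))) {
    for (m in c("chr", "cde")) {
      planted <- sites[[paste0(m, "_planted")]][i]
      if (!planted) next
      pos <- sites[[paste0(m, "_pos")]][i]
      pattern <- if (m == "chr") "TTYRAA" else "BSSSSS"
      instance <- draw_instance(pattern)
      chars[[sites$chrom[i]]][(pos + 1):(pos + 6)] <- strsplit(instance, "")[[1]]
      inst[[length(inst) + 1L]] <- tibble(site_id = sites$site_id[i], motif = toupper(m),
                                          chrom = sites$chrom[i], position = pos,
                                          instance = instance)
    }
  }
  genome <- map_chr(chars, paste, collapse = "")
  n_bins <- ceiling(p$chrom_length / p$cons_bin)
  bg <- bind_rows(lapply(chroms, function(ch) {
    tibble(chrom = ch,
           start = as.integer((seq_len(n_bins) - 1L) * p$cons_bin),
           end = as.integer(pmin(seq_len(n_bins) * p$cons_bin, p$chrom_length)),
           score = rbeta(n_bins, p$cons_bg_shape1, p$cons_bg_shape2))
  }))
  instances <- bind_rows(inst)
  motif_rows <- if (nrow(instances)) {
    tibble(chrom = instances$chrom, start = instances$position,
           end = instances$position + 6L,
           score = runif(nrow(instances), p$cons_motif_min, p$cons_motif_max))
  } else NULL
  conservation <- bind_rows(bg, motif_rows)   # motif rows last: last wins
  class(conservation) <- c("drm_conservation", class(conservation))
  list(genome = genome, conservation = conservation, instances = instances)
}

gen_expression <- function(sites, genes, params, seed) {
  set.seed(sub_seed(seed, 6L))
  p <- params
  bound <- sort(unique(unlist(sites$gene_ids)))
  n_a <- round(p$group_a_fraction * length(bound))
  group_a <- sort(sample(bound, n_a))
  labs <- p$experiment_labels
  support <- lapply(group_a, function(g) {
    s <- labs[runif(length(labs)) < p$experiment_support_prob]
    if (!length(s)) s <- sample(labs, 1)
    s
  })
  names(support) <- group_a
  lfc_cut <- log2(1.5) + 0.02
  draw_up_lfc <- function(n) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(n, p$group_a_lfc_mean, p$group_a_lfc_sd)
      out <- c(out, x[x > lfc_cut])
    }
    out[seq_len(n)]
  }
  tabs <- lapply(labs, function(lab) {
    tab <- tibble(gene_id = genes$gene_id, experiment = lab,
                  log2fc = rnorm(nrow(genes), 0, 0.2),
                  q_value = runif(nrow(genes), 0.1, 1))
    up_genes <- group_a[map_lgl(support, function(s) lab %in% s)]
    i <- match(up_genes, tab$gene_id)
    tab$log2fc[i] <- draw_up_lfc(length(i))
    tab$q_value[i] <- runif(length(i), p$group_a_q_min, p$group_a_q_max)
    tab
  })
  list(expression = bind_rows(tabs), bound_genes = bound, group_a = group_a,
       support = support)
}

gen_qpcr <- function(params, seed) {
  set.seed(sub_seed(seed, 7L))
  genes <- c("set-21", "cdk-1", "air-1", "rad-51")
  fold <- c(4, 3, 2, 1.5)
  rt <- list()
  for (cond in c("WT", "lin-35")) {
    for (r in 1:4) {
      sid <- sprintf("%s_r%d", cond, r)
      ct_ref <- runif(1, 15, 16)
      rt[[length(rt) + 1L]] <- tibble(sample_id = sid, condition = cond,
                                      gene_id = "act-2", ct = ct_ref, efficiency = 2)
      for (gi in seq_along(genes)) {
        base <- ct_ref + 6 + gi
        ct <- base - (cond != "WT") * log2(fold[gi]) + rnorm(1, 0, 0.15)
        rt[[length(rt) + 1L]] <- tibble(sample_id = sid, condition = cond,
                                        gene_id = genes[gi], ct = ct, efficiency = 2)
      }
    }
  }
  chip <- tidyr::expand_grid(subunit = c("DPL-1", "LIN-9", "LIN-54"),
                             condition = c("WT", "lin-35"),
                             region = c("mes-2_promoter", "cdk-1_promoter")) |>
    mutate(ct_input_target = runif(n(), 18, 19),
           ct_input_ctrl = runif(n(), 18, 19),
           true_l2fe = runif(n(), 1.5, 4) * ifelse(.data$condition == "WT", 1, 0.6),
           ct_chip_ctrl = runif(n(), 26, 27),
           ct_chip_target = .data$ct_chip_ctrl - .data$ct_input_ctrl +
             .data$ct_input_target - .data$true_l2fe) |>
    select(-"true_l2fe")
  list(rt = bind_rows(rt), chip = chip)
}

#' Generate the complete synthetic scenario
#'
#' Deterministically builds the full toy data set — gene models, per-subunit
#' per-replicate peak calls in both genotypes, occupancy counts, genome,
#' conservation track, expression tables, qPCR tables — together with the
#' planted truth. The same `(params, seed)` always yields identical output;
#' each component uses a derived RNG substream so it can be regenerated
#' independently.
#'
#' @param params A [drm_scenario_params()].
#' @param seed Integer scenario seed.
#' @param config A [drm_config()] (promoter geometry for site placement).
#' @return List of class `"drm_scenario"`: `genes`, `peaks`, `counts`,
#'   `samples`, `genome`, `conservation`, `expression`, `qpcr_rt`,
#'   `qpcr_chip`, and `truth` (class `"drm_truth"`).
#' @export
simulate_drm_scenario <- function(params = drm_scenario_params(), seed = 1L,
                                  config = drm_config()) {
  genes <- gen_genes(params, seed)
  sites <- gen_sites(genes, params, config, seed)
  peaks <- gen_peaks(sites, params, seed)
  cnt <- generate_counts(sites, params, seed)
  seqs <- generate_sequences(sites, params, seed)
  expr <- gen_expression(sites, genes, params, seed)
  qpcr <- gen_qpcr(params, seed)
  truth <- structure(list(
    sites = sites, bound_genes = expr$bound_genes, group_a = expr$group_a,
    support = expr$support, motif_instances = seqs$instances,
    size_factors = cnt$size_factors, params = params, seed = seed
  ), class = "drm_truth")
  structure(list(
    genes = genes, peaks = peaks, counts = cnt$counts, samples = cnt$samples,
    genome = seqs$genome, conservation = seqs$conservation,
    expression = expr$expression, qpcr_rt = qpcr$rt, qpcr_chip = qpcr$chip,
    truth = truth
  ), class = "drm_scenario")
}

#' Write a scenario to disk as plain-text files
#'
#' Peaks become one narrowPeak file per condition/subunit/replicate under
#' `peaks/`; gene models, counts, samples, expression and qPCR tables become
#' TSV; the genome becomes FASTA and the conservation track bedGraph; the
#' truth is serialised as TSV/DCF under `truth/`.
#'
#' @param scenario A `"drm_scenario"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  pk <- scenario$peaks |>
    group_by(.data$condition, .data$subunit, .data$replicate)
  keys <- dplyr::group_keys(pk)
  splits <- dplyr::group_split(pk)
  for (i in seq_len(nrow(keys))) {
    f <- sprintf("%s_%s_%s.narrowPeak", keys$condition[i],
                 gsub("-", "", keys$subunit[i]), keys$replicate[i])
    write_peaks(splits[[i]], file.path(dir, "peaks", f), "narrowPeak")
  }
  write_gene_models(scenario$genes, file.path(dir, "genes.tsv"))
  readr::write_tsv(scenario$counts, file.path(dir, "counts.tsv"), progress = FALSE)
  readr::write_tsv(scenario$samples, file.path(dir, "samples.tsv"), progress = FALSE)
  write_genome(scenario$genome, file.path(dir, "genome.fa"))
  write_conservation(scenario$conservation, file.path(dir, "conservation.bedGraph"))
  readr::write_tsv(scenario$expression, file.path(dir, "expression.tsv"), progress = FALSE)
  readr::write_tsv(scenario$qpcr_rt, file.path(dir, "qpcr_rt.tsv"), progress = FALSE)
  readr::write_tsv(scenario$qpcr_chip, file.path(dir, "qpcr_chip.tsv"), progress = FALSE)
  tr <- scenario$truth
  flat_sites <- tr$sites |>
    mutate(gene_ids = map_chr(.data$gene_ids, paste, collapse = ","))
  readr::write_tsv(flat_sites, file.path(dir, "truth", "sites.tsv"), progress = FALSE)
  writeLines(tr$group_a, file.path(dir, "truth", "group_a.txt"))
  readr::write_tsv(tibble(sample = names(tr$size_factors),
                          size_factor = unname(tr$size_factors)),
                   file.path(dir, "truth", "size_factors.tsv"), progress = FALSE)
  if (nrow(tr$motif_instances)) {
    readr::write_tsv(tr$motif_instances, file.path(dir, "truth", "motif_instances.tsv"),
                     progress = FALSE)
  }
  params_flat <- lapply(unclass(tr$params), paste, collapse = ",")
  write.dcf(as.data.frame(c(params_flat, seed = tr$seed)),
            file.path(dir, "truth", "params.dcf"))
  invisible(dir)
}
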