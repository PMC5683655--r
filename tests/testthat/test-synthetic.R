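# The synthetic-data generator: determinism, truth/file consistency, and
# statistical faithfulness of the planted structure.

test_that("identical (params, seed) produce byte-identical file bundles", {
  p <- small_params()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(simulate_drm_scenario(p, seed = 5), d1)
  write_scenario(simulate_drm_scenario(p, seed = 5), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(h1) == unname(h2)))
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_scenario(simulate_drm_scenario(p, seed = 6), d3)
  h3 <- tools::md5sum(file.path(d3, "counts.tsv"))
  expect_false(unname(h3) == unname(tools::md5sum(file.path(d1, "counts.tsv"))))
})

test_that("emitted files re-read to the truth-implied summaries", {
  p <- small_params()
  sc <- simulate_drm_scenario(p, seed = 8)
  d <- withr::local_tempdir()
  write_scenario(sc, d)

  genes <- read_gene_models(file.path(d, "genes.tsv"))
  expect_equal(genes$gene_id, sc$genes$gene_id)
  expect_equal(genes$tss, sc$genes$tss)

  one <- read_peaks(file.path(d, "peaks", "WT_LIN9_r1.narrowPeak"), "narrowPeak")
  in_mem <- dplyr::filter(sc$peaks, condition == "WT", subunit == "LIN-9",
                          replicate == "r1")
  expect_equal(one$start, in_mem$start)
  expect_equal(one$summit, in_mem$summit)

  cons <- read_conservation(file.path(d, "conservation.bedGraph"))
  expect_equal(nrow(cons), nrow(sc$conservation))

  genome <- read_genome(file.path(d, "genome.fa"))
  expect_identical(genome, sc$genome)

  # truth consistency: site count, motif plant count, Group A size
  tr <- sc$truth
  expect_equal(nrow(tr$sites), p$n_sites)
  expect_equal(nrow(tr$motif_instances),
               sum(tr$sites$chr_planted) + sum(tr$sites$cde_planted))
  expect_equal(length(tr$group_a),
               round(p$group_a_fraction * length(tr$bound_genes)))
  # every site's centre lies inside a promoter window of one of its genes
  prom <- promoter_windows(sc$genes)
  for (i in seq_len(nrow(tr$sites))) {
    w <- prom[prom$gene_id %in% tr$sites$gene_ids[[i]], ]
    expect_true(any(w$start <= tr$sites$center[i] & tr$sites$center[i] < w$end))
  }
})

test_that("peak sets are replicate-identical at detection 1 with zero jitter", {
  sc <- simulate_drm_scenario(small_params(detection_prob = 1, jitter_sd = 0,
                                           noise_peaks = 0L), seed = 3)
  wt <- dplyr::filter(sc$peaks, condition == "WT", subunit == "LIN-54")
  by_rep <- split(wt[, c("chrom", "start", "end")], wt$replicate)
  expect_equal(by_rep$r1, by_rep$r2, ignore_attr = TRUE)
  expect_equal(by_rep$r1, by_rep$r3, ignore_attr = TRUE)
})

test_that("planted motif instances scan positive and pass the conservation filter", {
  sc <- simulate_drm_scenario(small_params(), seed = 4)
  inst <- sc$truth$motif_instances
  expect_gt(nrow(inst), 0)
  for (i in seq_len(nrow(inst))) {
    pattern <- if (inst$motif[i] == "CHR") "TTYRAA" else "BSSSSS"
    seqn <- substring(sc$genome[[inst$chrom[i]]], inst$position[i] + 1,
                      inst$position[i] + 6)
    expect_equal(seqn, inst$instance[i])
    h <- scan_iupac(seqn, pattern, 0, strands = "forward")
    expect_true(any(h$position == 0 & h$mismatches == 0))
    cons <- drmpeaks:::conservation_values(sc$conservation, inst$chrom[i],
                                           inst$position[i], inst$position[i] + 6)
    expect_true(mean(cons) > 0.7)
  }
})

test_that("conserved CHR presence among sites tracks the plant rate", {
  sc <- simulate_drm_scenario(seed = 9)
  sites <- sc$truth$sites
  pres <- region_motif_presence(
    dplyr::rename(sites, peak_id = site_id)[, c("peak_id", "chrom", "start", "end")],
    sc$genome, "TTYRAA", 0L, sc$conservation)
  rate <- mean(pres$has_motif)
  p0 <- drm_scenario_params()$chr_plant_rate
  ci <- 1.96 * sqrt(p0 * (1 - p0) / nrow(sites))
  expect_gte(rate, p0 - ci)
  expect_lte(rate, p0 + ci + 0.05)  # small allowance for background hits
  # all planted sites are positive by construction
  expect_true(all(pres$has_motif[sites$chr_planted]))
  # degenerate CDE has background hits, so presence is at least the realised
  # planted fraction, and every planted site is positive
  pres_cde <- region_motif_presence(
    dplyr::rename(sites, peak_id = site_id)[, c("peak_id", "chrom", "start", "end")],
    sc$genome, "BSSSSS", 1L, sc$conservation)
  expect_true(all(pres_cde$has_motif[sites$cde_planted]))
  expect_gte(mean(pres_cde$has_motif), mean(sites$cde_planted))
})

test_that("generated counts recover the nominal dispersion and size factors", {
  p <- drm_scenario_params()
  # null rows: a truth with log2fc 0 everywhere
  null_truth <- tibble::tibble(site_id = sprintf("s%04d", 1:334),
                               true_log2fc = 0)
  gen <- generate_counts(null_truth, p, seed = 17)
  cm <- drmpeaks:::counts_matrix(gen$counts)
  y <- sweep(cm$mat, 2, gen$size_factors[colnames(cm$mat)], "/")
  disp <- (apply(y, 1, var) - rowMeans(y)) / rowMeans(y)^2
  expect_lt(abs(mean(disp) - p$dispersion) / p$dispersion, 0.25)
  # variance/mean ratio near 1 in the small-dispersion limit
  gen0 <- generate_counts(null_truth, drm_scenario_params(dispersion = 1e-4),
                          seed = 18)
  cm0 <- drmpeaks:::counts_matrix(gen0$counts)
  y0 <- sweep(cm0$mat, 2, gen0$size_factors[colnames(cm0$mat)], "/")
  ratio <- apply(y0, 1, var) / rowMeans(y0)
  expect_lt(abs(mean(ratio) - 1), 0.15)
  # recorded size factors recovered by median-of-ratios (null rows: the
  # factors are fully identifiable here)
  sf_est <- size_factors(cm$mat)
  sf_true <- gen$size_factors[names(sf_est)]
  sf_true <- sf_true / exp(mean(log(sf_true)))
  expect_lt(median(abs(sf_est / sf_true - 1)), 0.05)
})

test_that("group means match the construction under null and planted effects", {
  p <- small_params()
  sc <- simulate_drm_scenario(p, seed = 23)
  cnt <- sc$counts |>
    dplyr::group_by(peak_id, subunit, condition) |>
    dplyr::summarise(m = mean(count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = condition, values_from = m)
  joined <- dplyr::left_join(cnt,
    dplyr::select(sc$truth$sites, peak_id = site_id, true_log2fc, class_label),
    by = "peak_id")
  # strong-drop sites show visibly lower mutant means
  strong <- joined$class_label == "I"
  expect_gt(mean(joined$WT[strong]) / mean(joined$mutant[strong]), 2)
})
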