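# Fragment counting, size factors, the NB Wald test, BH-FDR and the
# Class I / Class II classification.

samples_3v3 <- tibble::tibble(
  sample = c("wt_1", "wt_2", "wt_3", "mut_1", "mut_2", "mut_3"),
  condition = rep(c("WT", "mutant"), each = 3),
  replicate = rep(c("r1", "r2", "r3"), 2)
)

# Long count tibble from a matrix whose columns follow samples_3v3.
long_counts <- function(mat, subunit = "LIN-9") {
  colnames(mat) <- samples_3v3$sample
  tibble::as_tibble(mat) |>
    dplyr::mutate(peak_id = sprintf("pk_%04d", dplyr::row_number()),
                  subunit = subunit) |>
    tidyr::pivot_longer(dplyr::all_of(samples_3v3$sample),
                        names_to = "sample", values_to = "count")
}

test_that("fragment counting assigns by midpoint with half-open bounds", {
  peaks <- tibble::tibble(peak_id = c("a", "b"), chrom = "chrI",
                          start = c(100L, 200L), end = c(200L, 300L))
  frags <- tibble::tibble(
    chrom = "chrI",
    # midpoints: 150 (in a), 199 (in a), 200 (exactly at a's exclusive end -> b),
    # 300 (outside both), 120 (in a)
    start = c(140L, 190L, 190L, 290L, 100L),
    end = c(160L, 208L, 210L, 310L, 140L),
    sample = "s1"
  )
  cm <- count_fragments(frags, peaks)
  expect_equal(cm$count[cm$peak_id == "a"], 3L)
  expect_equal(cm$count[cm$peak_id == "b"], 1L)

  # random fragments match a direct per-fragment containment check
  set.seed(5)
  frags2 <- rand_intervals(400, max_pos = 5000, max_width = 100, chroms = "chrI")
  frags2$sample <- sample(c("s1", "s2"), 400, replace = TRUE)
  peaks2 <- tibble::tibble(peak_id = sprintf("p%d", 1:10), chrom = "chrI",
                           start = seq(0L, 4500L, by = 500L),
                           end = seq(300L, 4800L, by = 500L))
  got <- count_fragments(frags2, peaks2)
  mid <- floor((frags2$start + frags2$end) / 2)
  for (i in seq_len(nrow(peaks2))) {
    for (s in c("s1", "s2")) {
      want <- sum(mid >= peaks2$start[i] & mid < peaks2$end[i] & frags2$sample == s)
      expect_equal(got$count[got$peak_id == peaks2$peak_id[i] & got$sample == s], want)
    }
  }
})

test_that("size factors: identical samples give 1, doubling gives ratio 2, formula matches direct implementation", {
  mat <- matrix(rep(c(10, 20, 30, 40), 6), ncol = 6)
  expect_equal(unname(size_factors(mat)), rep(1, 6), tolerance = 1e-12)

  two <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  sf <- size_factors(two)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  set.seed(9)
  nb <- matrix(rnbinom(500 * 6, mu = 50, size = 10), ncol = 6) + 1L
  got <- size_factors(nb)
  # direct median-of-ratios, rescaled to geometric mean 1
  g <- exp(rowMeans(log(nb)))
  raw <- apply(nb, 2, function(cc) median(cc / g))
  want <- raw / exp(mean(log(raw)))
  expect_equal(unname(got), unname(want), tolerance = 1e-8)

  zero <- matrix(c(0, 5, 3, 0), 2)
  expect_error(size_factors(zero), "pseudocount")
  expect_silent(size_factors(zero, pseudocount = 1))
})

test_that("NB Wald test: constant counts give log2fc 0 and p 1; sign follows group means", {
  mat <- matrix(100, nrow = 3, ncol = 6)
  res <- test_occupancy(long_counts(mat), samples_3v3,
                        size_factors = setNames(rep(1, 6), samples_3v3$sample))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))

  dec <- matrix(rep(c(200, 200, 200, 50, 50, 50), each = 2), nrow = 2, byrow = FALSE)
  res2 <- test_occupancy(long_counts(dec), samples_3v3,
                         size_factors = setNames(rep(1, 6), samples_3v3$sample))
  expect_true(all(res2$log2fc < 0))

  # a condition entirely absent is an error
  expect_error(test_occupancy(long_counts(mat), dplyr::mutate(samples_3v3, condition = "WT")),
               "both conditions")
})

test_that("NB Wald test detects a planted 4-fold decrease with high power", {
  set.seed(101)
  n_sim <- 500
  wt <- matrix(rnbinom(n_sim * 3, mu = 200, size = 20), ncol = 3)
  mut <- matrix(rnbinom(n_sim * 3, mu = 50, size = 20), ncol = 3)
  res <- test_occupancy(long_counts(cbind(wt, mut)), samples_3v3,
                        size_factors = setNames(rep(1, 6), samples_3v3$sample))
  expect_gte(mean(res$p_value < 0.01 & res$log2fc < -1.5), 0.95)
})

test_that("NB Wald test holds its type-I error on null data", {
  set.seed(202)
  mat <- matrix(rnbinom(2000 * 6, mu = 200, size = 20), ncol = 6)
  res <- test_occupancy(long_counts(mat), samples_3v3,
                        size_factors = setNames(rep(1, 6), samples_3v3$sample))
  frac <- mean(res$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("BH q-values match the step-up definition and are order-invariant", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")

  set.seed(31)
  for (rep in 1:30) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bf_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    # invariance under permutation of the input order
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm])[order(perm)], q, tolerance = 1e-12)
  }
})

test_that("classification partitions peaks and responds to effect size monotonically", {
  set.seed(55)
  make_scenario_counts <- function(lfc_strong) {
    n_site <- 60
    strong <- rep(c(TRUE, FALSE), length.out = n_site)
    lfc <- ifelse(strong, lfc_strong, 0)
    rows <- tidyr::expand_grid(site = seq_len(n_site),
                               subunit = drmpeaks:::TESTED_SUBUNITS)
    wt <- matrix(rnbinom(nrow(rows) * 3, mu = 200, size = 20), ncol = 3)
    mut <- matrix(rnbinom(nrow(rows) * 3, mu = 200 * 2^lfc[rows$site], size = 20), ncol = 3)
    cnt <- cbind(wt, mut)
    colnames(cnt) <- samples_3v3$sample
    long <- tibble::as_tibble(cnt) |>
      dplyr::mutate(peak_id = sprintf("s%03d", rows$site), subunit = rows$subunit) |>
      tidyr::pivot_longer(dplyr::all_of(samples_3v3$sample),
                          names_to = "sample", values_to = "count")
    list(long = long, strong = strong)
  }
  recalls <- sapply(c(-0.5, -1.5, -3), function(l) {
    sim <- make_scenario_counts(l)
    res <- test_occupancy(sim$long, samples_3v3,
                          size_factors = setNames(rep(1, 6), samples_3v3$sample))
    cls <- classify_peaks(res)
    expect_equal(sum(cls$class_label == "I") + sum(cls$class_label == "II"), 60L)
    mean(cls$class_label[sim$strong[match(cls$peak_id, sprintf("s%03d", 1:60))]] == "I")
  })
  expect_true(all(diff(recalls) >= 0))
  expect_gte(recalls[3], 0.95)

  # missing subunit rows are an error naming the peak
  sim <- make_scenario_counts(-2)
  res <- test_occupancy(sim$long, samples_3v3,
                        size_factors = setNames(rep(1, 6), samples_3v3$sample))
  expect_error(classify_peaks(res[res$subunit != "LIN-9" | res$peak_id != "s001", ]),
               "s001")
})

test_that("tidy/glance summarise differential results", {
  set.seed(77)
  mat <- matrix(rnbinom(20 * 6, mu = 100, size = 20), ncol = 6)
  res <- test_occupancy(long_counts(mat), samples_3v3)
  td <- tidy(res)
  expect_false(inherits(td, "drm_diff"))
  expect_named(glance(res),
               c("n_tests", "n_significant_decrease", "n_significant_increase",
                 "dispersion", "fdr_alpha"))
  expect_equal(glance(res)$n_tests, 20L)
})
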