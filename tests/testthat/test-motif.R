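# IUPAC scanning, conservation filtering, region presence calls and the
# enrichment statistics.

test_that("IUPAC class membership and mismatch counting on known cases", {
  # TTCGAA matches TTYRAA exactly (Y covers C, R covers G)
  h <- scan_iupac("TTCGAA", "TTYRAA", max_mismatch = 0)
  expect_true(any(h$position == 0 & h$strand == "+" & h$mismatches == 0))
  # TTCGAA is its own reverse complement: palindromic hits pair on both strands
  expect_setequal(h$strand, c("+", "-"))
  expect_equal(unique(h$position), 0L)

  # ACGCGC vs BSSSSS: A not in B, rest in S -> exactly 1 mismatch
  h2 <- scan_iupac("ACGCGC", "BSSSSS", max_mismatch = 1, strands = "forward")
  expect_equal(h2$mismatches[h2$position == 0], 1L)
  h2b <- scan_iupac("ACGCGC", "BSSSSS", max_mismatch = 0, strands = "forward")
  expect_false(any(h2b$position == 0))

  # N in the sequence never matches any pattern symbol
  hN <- scan_iupac("TTNGAA", "TTYRAA", max_mismatch = 0)
  expect_false(any(hN$position == 0 & hN$strand == "+"))
  hN1 <- scan_iupac("TTNGAA", "TTYRAA", max_mismatch = 1, strands = "forward")
  expect_equal(hN1$mismatches[hN1$position == 0], 1L)

  expect_error(scan_iupac("ACGT", "AXGT"), "IUPAC")
})

test_that("scanning agrees with the window-by-window oracle on random sequences", {
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(50:400, 1)
    seqn <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                         prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    pattern <- sample(c("TTYRAA", "BSSSSS", "RYN", "WWSS"), 1)
    mm <- sample(0:2, 1)
    got <- as.data.frame(scan_iupac(seqn, pattern, mm)[, c("position", "strand", "mismatches")])
    want <- bf_scan(seqn, pattern, mm)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("reverse-complement symmetry of the hit list", {
  set.seed(13)
  revcomp <- function(s) {
    paste(rev(c(A = "T", C = "G", G = "C", T = "A",
                N = "N")[strsplit(s, "")[[1]]]), collapse = "")
  }
  for (rep in 1:10) {
    seqn <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    h <- scan_iupac(seqn, "BSSSSS", 1)
    h_rc <- scan_iupac(revcomp(seqn), "BSSSSS", 1)
    # positions mirror: pos -> len - 6 - pos, strands swap
    mirrored <- sort(200 - 6 - h_rc$position)
    expect_equal(sort(h$position), mirrored)
    expect_equal(nrow(h), nrow(h_rc))
  }
})

test_that("presence calls are monotone in the mismatch budget", {
  set.seed(14)
  genome <- c(chrI = paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                           collapse = ""))
  regions <- tibble::tibble(peak_id = sprintf("r%d", 1:20), chrom = "chrI",
                            start = seq(0L, 4750L, by = 250L),
                            end = seq(200L, 4950L, by = 250L))
  prev <- rep(FALSE, 20)
  for (mm in 0:2) {
    pres <- region_motif_presence(regions, genome, "BSSSSS", mm)
    expect_true(all(pres$has_motif >= prev))
    prev <- pres$has_motif
  }
  expect_error(
    region_motif_presence(tibble::tibble(peak_id = "x", chrom = "chrI",
                                         start = 4900L, end = 5100L),
                          genome, "BSSSSS", 0),
    "beyond")
})

test_that("conservation filtering uses the mean over the match span", {
  track <- tibble::tibble(chrom = "chrI",
                          start = 0:5, end = 1:6,
                          score = c(0.6, 0.7, 0.8, 0.6, 0.7, 0.7))
  hits <- tibble::tibble(region_id = "r", chrom = "chrI", position = 0L,
                         strand = "+", mismatches = 0L, match = "TTCGAA")
  # mean 0.6833 does not exceed 0.7
  expect_equal(nrow(filter_conserved(hits, track, 0.7)), 0L)
  high <- dplyr::mutate(track, score = 1)
  kept <- filter_conserved(hits, high, 0.7)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$mean_conservation, 1)
  low <- dplyr::mutate(track, score = 0)
  expect_equal(nrow(filter_conserved(hits, low, 0.7)), 0L)
  # min aggregation is stricter than mean
  mixed <- dplyr::mutate(track, score = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.5))
  expect_equal(nrow(filter_conserved(hits, mixed, 0.7, summary = "mean")), 1L)
  expect_equal(nrow(filter_conserved(hits, mixed, 0.7, summary = "min")), 0L)
})

test_that("hypergeometric upper tail matches exact enumeration", {
  expect_equal(hypergeom_upper_tail(0, 5, 5, 20)$p_value, 1)
  expect_equal(hypergeom_upper_tail(5, 5, 5, 10)$p_value, 1 / 252, tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(6, 5, 5, 10), "inconsistent")

  set.seed(15)
  for (rep in 1:60) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    got <- hypergeom_upper_tail(k, K, n, N)
    expect_equal(got$p_value, min(1, bf_hyper_upper(k, K, n, N)),
                 tolerance = 1e-10)
    expect_equal(got$expected, n * K / N)
  }
  # monotone nonincreasing in k
  ps <- sapply(0:8, function(k) hypergeom_upper_tail(k, 10, 8, 25)$p_value)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("chi-squared class association matches the closed form", {
  balanced <- class_association_chi2(rep(c(TRUE, FALSE), 10),
                                     rep(c("I", "I", "II", "II"), 5))
  expect_equal(balanced$statistic, 0, tolerance = 1e-12)
  expect_equal(balanced$p_value, 1, tolerance = 1e-12)

  perfect <- class_association_chi2(rep(c(TRUE, FALSE), each = 10),
                                    rep(c("I", "II"), each = 10))
  expect_equal(perfect$statistic, 20, tolerance = 1e-12)

  set.seed(16)
  for (rep in 1:40) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
    pres <- rep(c(TRUE, TRUE, FALSE, FALSE), times = as.vector(tab))
    cls <- rep(c("I", "II", "I", "II"), times = as.vector(tab))
    got <- class_association_chi2(pres, cls)
    expect_equal(got$statistic,
                 bf_chi2_2x2(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2]),
                 tolerance = 1e-10)
    expect_equal(got$p_value, pchisq(got$statistic, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(class_association_chi2(rep(TRUE, 4), c("I", "I", "II", "II")),
               "marginal")
})
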