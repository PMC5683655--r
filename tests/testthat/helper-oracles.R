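# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# O(n*m) pairwise overlap: indices of subjects sharing >= 1 bp with query.
bf_overlap_idx <- function(query, subjects) {
  hits <- integer(0)
  for (j in seq_len(nrow(subjects))) {
    if (subjects$chrom[j] == query$chrom &&
        subjects$start[j] < query$end && subjects$end[j] > query$start) {
      hits <- c(hits, j)
    }
  }
  hits
}

# Single-linkage clustering via explicit connected components on the
# pairwise overlap graph (BFS).
bf_cluster <- function(x) {
  n <- nrow(x)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && x$chrom[i] == x$chrom[j] &&
          x$start[i] < x$end[j] && x$start[j] < x$end[i]) {
        adj[[i]] <- c(adj[[i]], j)
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

BF_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

bf_revcomp_pattern <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(pattern, "")[[1]]]), collapse = "")
}

# Window-by-window scan; returns data.frame(position, strand, mismatches).
bf_scan <- function(sequence, pattern, max_mismatch, strands = "both") {
  sq <- strsplit(sequence, "")[[1]]
  pats <- list(`+` = pattern)
  if (strands == "both") pats[["-"]] <- bf_revcomp_pattern(pattern)
  out <- list()
  for (str in names(pats)) {
    pat <- strsplit(pats[[str]], "")[[1]]
    L <- length(pat)
    if (length(sq) < L) next
    for (pos in 0:(length(sq) - L)) {
      mm <- 0L
      for (k in seq_len(L)) {
        if (!(sq[pos + k] %in% BF_IUPAC[[pat[k]]])) mm <- mm + 1L
      }
      if (mm <= max_mismatch) {
        out[[length(out) + 1L]] <- data.frame(position = pos, strand = str,
                                              mismatches = mm)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$position, res$strand), , drop = FALSE]
}

# BH step-up from the defining formula: q_(i) = min_{j >= i} p_(j) * n / j.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(pmin(1, ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- q
  out
}

# Upper-tail hypergeometric by direct enumeration of binomial coefficients.
bf_hyper_upper <- function(k, K, n, N) {
  lo <- max(k, 0)
  hi <- min(K, n)
  if (lo > hi) return(0)
  sum(sapply(lo:hi, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }))
}

# Pearson chi-squared on a 2x2 table from the closed form
# N (ad - bc)^2 / (r1 r2 c1 c2).
bf_chi2_2x2 <- function(a, b, c, d) {
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Random interval table on a couple of chromosomes.
rand_intervals <- function(n, max_pos = 1000L, max_width = 60L,
                           chroms = c("chrI", "chrII")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + width)
}

# Small scaled-down scenario parameters used by unit tests (not the study
# conditions; those live in drm_scenario_params()).
small_params <- function(...) {
  drm_scenario_params(n_chroms = 1L, chrom_length = 300000L, n_genes = 50L,
                      n_sites = 15L, noise_peaks = 5L, ...)
}
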