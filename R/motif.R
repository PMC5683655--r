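# IUPAC motif scanning with a mismatch budget, conservation filtering,
# region-level presence calls, and the two enrichment tests (hypergeometric
# vs background, chi-squared between peak classes).

IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

revcomp_iupac <- function(pattern) {
  chars <- rev(strsplit(pattern, "")[[1]])
  paste(IUPAC_COMPLEMENT[chars], collapse = "")
}

# Mismatch count of every window of `sequence` against `pattern` on the
# given orientation of the pattern. Vectorised: one logical comparison per
# pattern position. An N in the sequence matches no pattern symbol.
window_mismatches <- function(seq_chars, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  bad <- setdiff(pat, names(IUPAC_CLASSES))
  if (length(bad)) abort(sprintf("invalid IUPAC letter(s) in pattern: %s", paste(bad, collapse = ", ")))
  L <- length(pat); n <- length(seq_chars)
  if (n < L) return(integer(0))
  n_win <- n - L + 1L
  mm <- integer(n_win)
  for (k in seq_len(L)) {
    ok <- seq_chars[k:(k + n_win - 1L)] %in% IUPAC_CLASSES[[pat[k]]]
    mm <- mm + !ok
  }
  mm
}

#' Scan a sequence for an IUPAC motif with a mismatch budget
#'
#' Every window of pattern length is compared to the pattern; a window
#' position mismatches when its base is not in the IUPAC class of the
#' pattern symbol (an `N` in the sequence never matches anything). Windows
#' with at most `max_mismatch` mismatches are reported. Reverse-strand hits
#' are matches of the reverse-complemented pattern on the forward sequence,
#' reported in forward coordinates.
#'
#' @param sequence A DNA string over A/C/G/T/N.
#' @param pattern IUPAC pattern string (e.g. `"BSSSSS"`, `"TTYRAA"`).
#' @param max_mismatch Non-negative mismatch budget.
#' @param strands `"both"` (default) or `"forward"`.
#' @return Tibble `position` (0-based forward-strand start), `strand`,
#'   `mismatches`, `match` (the matched forward-strand bases).
#' @examples
#' scan_iupac("TTCGAA", "TTYRAA", max_mismatch = 0)
#' @export
scan_iupac <- function(sequence, pattern, max_mismatch = 0L,
                       strands = c("both", "forward")) {
  strands <- match.arg(strands)
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  L <- nchar(pattern)
  pats <- list(`+` = pattern)
  if (strands == "both") pats$`-` <- revcomp_iupac(pattern)
  out <- imap(pats, function(p, str) {
    mm <- window_mismatches(seq_chars, p)
    pos <- which(mm <= max_mismatch)
    tibble(position = pos - 1L, strand = str, mismatches = mm[pos])
  })
  hits <- bind_rows(out) |> arrange(.data$position, .data$strand)
  hits$match <- if (nrow(hits)) {
    substring(paste(seq_chars, collapse = ""), hits$position + 1L, hits$position + L)
  } else character(0)
  hits
}

#' Keep only conserved motif hits
#'
#' A hit is conserved when the per-base conservation summary over its match
#' span exceeds `threshold`. The summary (mean by default, configurable to
#' min) is stored on the returned hits as `mean_conservation`.
#'
#' @param hits Motif hit tibble with `chrom` and genome-scale `position`
#'   columns and a match length attribute or `match` column.
#' @param track Conservation tibble ([read_conservation()]).
#' @param threshold Conservation threshold (exceed strictly).
#' @param summary `"mean"` or `"min"`.
#' @return The conserved subset of `hits` with `mean_conservation` added.
#' @export
filter_conserved <- function(hits, track, threshold = 0.7,
                             summary = c("mean", "min")) {
  summary <- match.arg(summary)
  agg <- if (summary == "mean") mean else min
  if (nrow(hits) == 0) return(mutate(hits, mean_conservation = numeric(0)))
  L <- nchar(hits$match[1])
  cons <- map_dbl(seq_len(nrow(hits)), function(i) {
    agg(conservation_values(track, hits$chrom[i], hits$position[i], hits$position[i] + L))
  })
  hits$mean_conservation <- cons
  hits[cons > threshold, , drop = FALSE]
}

#' Motif presence per region
#'
#' Scans each region's genomic sequence for the pattern and calls the region
#' positive when at least one hit (conserved hit, when a conservation track
#' is supplied) lies fully inside it. A region is counted once regardless of
#' how many hits it contains.
#'
#' @param regions Interval tibble with `peak_id` (or `name`) identifiers.
#' @param genome Named character vector of chromosome sequences
#'   ([read_genome()]).
#' @param pattern IUPAC pattern.
#' @param max_mismatch Mismatch budget.
#' @param track Optional conservation tibble; when given, only hits whose
#'   conservation summary exceeds `config$conservation_threshold` count.
#' @param config A [drm_config()].
#' @return Tibble `region_id`, `has_motif`, `n_hits`.
#' @export
region_motif_presence <- function(regions, genome, pattern, max_mismatch = 0L,
                                  track = NULL, config = drm_config()) {
  regions <- as_tibble(regions)
  check_intervals(regions, "regions")
  ids <- if ("peak_id" %in% names(regions)) regions$peak_id
         else if ("name" %in% names(regions)) regions$name
         else if ("gene_id" %in% names(regions)) regions$gene_id
         else as.character(seq_len(nrow(regions)))
  res <- map(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]
    if (!ch %in% names(genome)) abort(sprintf("chromosome %s not in genome", ch))
    clen <- nchar(genome[[ch]])
    if (regions$end[i] > clen) {
      abort(sprintf("region %s [%d, %d) extends beyond chromosome %s end (%d)",
                    ids[i], regions$start[i], regions$end[i], ch, clen))
    }
    seq <- substring(genome[[ch]], regions$start[i] + 1L, regions$end[i])
    hits <- scan_iupac(seq, pattern, max_mismatch = max_mismatch)
    if (nrow(hits)) {
      hits$chrom <- ch
      hits$position <- hits$position + regions$start[i]
      if (!is.null(track)) {
        hits <- filter_conserved(hits, track,
                                 threshold = config$conservation_threshold,
                                 summary = config$conservation_summary)
      }
    }
    tibble(region_id = ids[i], has_motif = nrow(hits) > 0, n_hits = nrow(hits))
  })
  bind_rows(res)
}

#' Upper-tail hypergeometric enrichment
#'
#' With a universe of `N` regions of which `K` carry the feature, and a
#' target set of `n` regions of which `k` carry it, computes
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (via `stats::phyper`,
#' which works on log scale internally) together with the expected overlap
#' `n * K / N`.
#'
#' @param k Observed feature-positive targets.
#' @param K Feature-positive regions in the universe.
#' @param n Target set size.
#' @param N Universe size.
#' @return One-row tibble of class `"drm_enrichment"`: `k`, `K`, `n`, `N`,
#'   `expected`, `p_value`.
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 10) # 1 / choose(10, 5)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k < 0 || n > N || k > n || K > N || k > K) {
    abort(sprintf("inconsistent counts: k=%d K=%d n=%d N=%d (need 0<=k<=min(K,n), n<=N, K<=N)",
                  k, K, n, N))
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- tibble(k = as.integer(k), K = as.integer(K), n = as.integer(n),
                N = as.integer(N), expected = n * K / N, p_value = min(1, p))
  class(out) <- c("drm_enrichment", class(out))
  out
}

#' Chi-squared association between motif presence and peak class
#'
#' Pearson chi-squared test (1 df, no continuity correction) on the 2x2
#' table of motif presence against Class I / Class II membership.
#'
#' @param presence Logical vector, motif presence per peak.
#' @param classes Character vector (or `"drm_classes"` tibble) of class
#'   labels per peak, aligned with `presence`.
#' @return One-row tibble: counts of the 2x2 table, `statistic`, `df`,
#'   `p_value`.
#' @export
class_association_chi2 <- function(presence, classes) {
  if (is.data.frame(classes)) classes <- classes$class_label
  tab <- table(factor(presence, levels = c(TRUE, FALSE)),
               factor(classes, levels = c("I", "II")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("a marginal of the 2x2 table is zero; use an exact test instead")
  }
  # chisq.test warns on small expected counts; the asymptotic caveat is
  # documented here rather than re-raised per call
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(with_motif_I = tab[1, 1], with_motif_II = tab[1, 2],
         without_motif_I = tab[2, 1], without_motif_II = tab[2, 2],
         statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}
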