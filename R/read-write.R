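#' Read peak calls from BED-family files
#'
#' Parses BED3, BED6 or ENCODE narrowPeak (BED6+4) into a peak tibble.
#' Coordinates are taken as 0-based half-open, exactly as stored in the
#' file. The narrowPeak 10th column (summit offset from `start`) is kept as
#' `summit`; the conventional missing value `-1` becomes `NA`.
#'
#' @param path Path to a tab-separated peak file.
#' @param dialect One of `"BED3"`, `"BED6"`, `"narrowPeak"`.
#' @param subunit,replicate,condition Optional labels attached to every
#'   parsed peak (subunit name, replicate id, `"WT"` or `"mutant"`).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `summit`, `subunit`, `replicate`, `condition`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chrI\t100\t400", f)
#' read_peaks(f, "BED3")
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "BED6", "BED3"),
                       subunit = NA_character_, replicate = NA_character_,
                       condition = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ncol_need <- c(BED3 = 3L, BED6 = 6L, narrowPeak = 10L)[[dialect]]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  parse_fail <- function(ln, why) {
    abort(sprintf("%s: parse error at line %d: %s", path, ln, why))
  }
  chrom <- character(n); start <- integer(n); end <- integer(n)
  name <- rep(NA_character_, n); score <- rep(NA_real_, n)
  strand <- rep("*", n); summit <- rep(NA_integer_, n)
  for (ln in seq_len(n)) {
    f <- fields[[ln]]
    if (length(f) < ncol_need) parse_fail(ln, sprintf("expected >= %d columns, found %d", ncol_need, length(f)))
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) parse_fail(ln, "non-integer coordinate")
    if (s >= e) parse_fail(ln, sprintf("start >= end (%d >= %d)", s, e))
    if (s < 0) parse_fail(ln, "negative start")
    chrom[ln] <- f[1]; start[ln] <- s; end[ln] <- e
    if (dialect %in% c("BED6", "narrowPeak")) {
      name[ln] <- f[4]
      sc <- suppressWarnings(as.numeric(f[5]))
      score[ln] <- sc
      strand[ln] <- if (f[6] %in% c("+", "-")) f[6] else "*"
    }
    if (dialect == "narrowPeak") {
      sm <- suppressWarnings(as.integer(f[10]))
      if (is.na(sm)) parse_fail(ln, "non-integer summit offset")
      if (sm >= 0) {
        if (sm >= e - s) parse_fail(ln, "summit offset outside peak")
        summit[ln] <- sm
      }
      sv <- suppressWarnings(as.numeric(f[7]))
      if (!is.na(sv)) score[ln] <- sv
    }
  }
  tibble(chrom = chrom, start = start, end = end, name = name,
         score = score, strand = strand, summit = summit,
         subunit = subunit, replicate = replicate, condition = condition)
}

#' Write peaks to BED6 or narrowPeak
#'
#' Inverse of [read_peaks()]: coordinates round-trip exactly.
#'
#' @param peaks A peak tibble (needs `chrom`, `start`, `end`; other columns
#'   optional).
#' @param path Output path.
#' @param dialect `"BED6"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowPeak", "BED6")) {
  dialect <- match.arg(dialect)
  check_intervals(peaks, "peaks")
  n <- nrow(peaks)
  name <- if ("name" %in% names(peaks)) dplyr::coalesce(peaks$name, ".") else rep(".", n)
  score <- if ("score" %in% names(peaks)) dplyr::coalesce(peaks$score, 0) else rep(0, n)
  strand <- if ("strand" %in% names(peaks)) dplyr::coalesce(peaks$strand, "*") else rep("*", n)
  strand[strand == "*"] <- "."
  base <- paste(peaks$chrom, peaks$start, peaks$end, name, score, strand, sep = "\t")
  if (dialect == "narrowPeak") {
    summit <- if ("summit" %in% names(peaks)) peaks$summit else rep(NA_integer_, n)
    summit <- ifelse(is.na(summit), -1L, as.integer(summit))
    base <- paste(base, score, -1, -1, summit, sep = "\t")
  }
  writeLines(base, path)
  invisible(path)
}

#' Read gene models from a tabular file
#'
#' Expects tab-separated columns `gene_id`, `chrom`, `strand`, `txStart`,
#' `txEnd`, `exonStarts`, `exonEnds` (the exon columns are comma-separated
#' lists, 0-based half-open). The strand-aware 5' end becomes `tss` and the
#' 3' end `tts`.
#'
#' @param path Path to the gene-model table (with header).
#' @return A tibble with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`, `tts` and list-columns `exon_starts`, `exon_ends`.
#' @export
read_gene_models <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    strand = readr::col_character(), txStart = readr::col_integer(),
    txEnd = readr::col_integer(), exonStarts = readr::col_character(),
    exonEnds = readr::col_character()
  ), progress = FALSE)
  gene_models(tab$gene_id, tab$chrom, tab$strand, tab$txStart, tab$txEnd,
              strsplit(tab$exonStarts, ","), strsplit(tab$exonEnds, ","))
}

# Construct and validate the gene-model tibble shared by the reader and the
# synthetic generator.
gene_models <- function(gene_id, chrom, strand, start, end,
                        exon_starts, exon_ends) {
  if (!all(strand %in% c("+", "-"))) {
    abort(sprintf("gene strand must be '+' or '-' (offending gene: %s)",
                  gene_id[which(!strand %in% c("+", "-"))[1]]))
  }
  exon_starts <- lapply(exon_starts, function(v) as.integer(v[nzchar(v)]))
  exon_ends <- lapply(exon_ends, function(v) as.integer(v[nzchar(v)]))
  for (i in seq_along(gene_id)) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    if (length(es) != length(ee)) {
      abort(sprintf("gene %s: exonStarts and exonEnds lengths differ (%d vs %d)",
                    gene_id[i], length(es), length(ee)))
    }
    if (length(es)) {
      if (any(ee <= es)) abort(sprintf("gene %s: empty or inverted exon", gene_id[i]))
      if (is.unsorted(es, strictly = TRUE) || any(es[-1] < ee[-length(ee)])) {
        abort(sprintf("gene %s: exons must be sorted and non-overlapping", gene_id[i]))
      }
      if (min(es) < start[i] || max(ee) > end[i]) {
        abort(sprintf("gene %s: exons outside the gene span", gene_id[i]))
      }
    }
  }
  tss <- ifelse(strand == "+", start, end)
  tts <- ifelse(strand == "+", end, start)
  tibble(gene_id = gene_id, chrom = chrom, strand = strand,
         start = as.integer(start), end = as.integer(end),
         tss = as.integer(tss), tts = as.integer(tts),
         exon_starts = exon_starts, exon_ends = exon_ends)
}

#' Write gene models to the tabular format read by [read_gene_models()]
#' @param genes A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  tab <- tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    txStart = genes$start, txEnd = genes$end,
    exonStarts = map_chr(genes$exon_starts, paste, collapse = ","),
    exonEnds = map_chr(genes$exon_ends, paste, collapse = ",")
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a conservation track from bedGraph
#'
#' Rows are `chrom start end value` (0-based half-open). Scores must lie in
#' \[0, 1\] (phastCons scale). Later rows override earlier ones where they
#' overlap ("last wins"); positions not covered by any row score 0.
#'
#' @param path Path to a bedGraph file (no header).
#' @return A tibble `chrom`, `start`, `end`, `score` in file order, with
#'   class `"drm_conservation"` prepended.
#' @export
read_conservation <- function(path) {
  tab <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end", "score"),
                         col_types = "ciid", progress = FALSE)
  bad <- which(tab$score < 0 | tab$score > 1)
  if (length(bad)) {
    abort(sprintf("%s: conservation score outside [0, 1] at line %d (%g)",
                  path, bad[1], tab$score[bad[1]]))
  }
  check_intervals(tab, "conservation track")
  class(tab) <- c("drm_conservation", class(tab))
  tab
}

#' Write a conservation track as bedGraph
#' @param track Conservation tibble (`chrom`, `start`, `end`, `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "score")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

# Per-base conservation over [start, end) on `chrom`, honouring the
# last-row-wins rule; uncovered positions are 0.
conservation_values <- function(track, chrom, start, end) {
  vals <- numeric(end - start)
  rows <- which(track$chrom == chrom & track$start < end & track$end > start)
  for (r in rows) {   # file order => later rows overwrite
    a <- max(track$start[r], start) - start + 1L
    b <- min(track$end[r], end) - start
    vals[a:b] <- track$score[r]
  }
  vals
}

#' Read a genome from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a plain
#' named character vector (one element per chromosome, uppercase).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome to FASTA
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
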