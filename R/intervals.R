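# Interval primitives. All coordinates are 0-based half-open [start, end),
# the BED convention; every 1-based input dialect is converted at the reader
# boundary so no other code ever thinks about off-by-ones.

check_intervals <- function(x, arg = "x") {
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame of intervals", arg))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("`%s` is missing interval column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  bad <- which(!(x$end > x$start) | x$start < 0)
  if (length(bad)) {
    abort(sprintf("invalid interval(s) in `%s` at row(s) %s: need 0 <= start < end",
                  arg, paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(x)
}

#' Find subjects overlapping a query interval
#'
#' Returns the rows of `subjects` that share at least one base with `query`
#' on the same chromosome. Half-open semantics: abutting intervals
#' (`end == start`) do not overlap. Strand is ignored, as appropriate for
#' unstranded ChIP peaks.
#'
#' @param query A one-row data frame (or list) with `chrom`, `start`, `end`.
#' @param subjects A data frame of intervals.
#' @return The overlapping rows of `subjects`, as a tibble.
#' @examples
#' subjects <- tibble::tibble(chrom = "chrI", start = c(0, 9), end = c(10, 20))
#' query_overlaps(list(chrom = "chrI", start = 10, end = 15), subjects)
#' @export
query_overlaps <- function(query, subjects) {
  check_intervals(subjects, "subjects")
  as_tibble(subjects) |>
    filter(.data$chrom == query$chrom,
           .data$start < query$end,
           .data$end > query$start)
}

# All overlapping index pairs (i in x, j in y), same-chrom, >= 1 shared bp.
# Sort-and-sweep per chromosome; returns a tibble of (i, j).
overlap_pairs <- function(x, y) {
  check_intervals(x); check_intervals(y, "y")
  out_i <- integer(0); out_j <- integer(0)
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    xi <- which(x$chrom == ch)
    yj <- which(y$chrom == ch)
    ord_y <- yj[order(y$start[yj])]
    ys <- y$start[ord_y]; ye <- y$end[ord_y]
    for (i in xi) {
      k <- which(ys < x$end[i] & ye > x$start[i])
      if (length(k)) { out_i <- c(out_i, rep(i, length(k))); out_j <- c(out_j, ord_y[k]) }
    }
  }
  tibble(i = out_i, j = out_j)
}

# Single-linkage clustering of intervals by >= 1 bp overlap. Because interval
# overlap chains are contiguous on the genome axis, connected components are
# exactly the runs found by a per-chromosome sort-and-sweep over a running
# maximum end. Returns an integer cluster id per row (input order).
cluster_intervals <- function(x) {
  check_intervals(x)
  cl <- integer(nrow(x))
  nxt <- 0L
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    ord <- idx[order(x$start[idx], x$end[idx])]
    cur_end <- -Inf
    for (i in ord) {
      if (x$start[i] >= cur_end) {   # no overlap with the open run: new cluster
        nxt <- nxt + 1L
        cur_end <- x$end[i]
      } else {
        cur_end <- max(cur_end, x$end[i])
      }
      cl[i] <- nxt
    }
  }
  cl
}
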