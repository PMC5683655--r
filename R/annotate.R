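# Peak-to-gene annotation: strand-aware promoter windows, category
# assignment by peak center with promoter > intron > TTS > intergenic
# precedence, category summaries, and DRM target-gene extraction.

#' Strand-aware promoter windows
#'
#' The promoter of a gene is the window from `promoter_upstream` bp upstream
#' to `promoter_downstream` bp downstream of its TSS (default -1000/+100),
#' oriented by strand and clipped at position 0. Both strands give an 1100 bp
#' window before clipping.
#'
#' @param genes Gene-model tibble ([read_gene_models()]).
#' @param config A [drm_config()].
#' @return Tibble `gene_id`, `chrom`, `strand`, `tss`, `start`, `end`.
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chrI", strand = "+",
#'                     tss = 5000L, tts = 8000L)
#' promoter_windows(g)
#' @export
promoter_windows <- function(genes, config = drm_config()) {
  up <- config$promoter_upstream; down <- config$promoter_downstream
  start <- ifelse(genes$strand == "+", genes$tss - up, genes$tss - down)
  end <- ifelse(genes$strand == "+", genes$tss + down, genes$tss + up)
  tibble(gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
         tss = genes$tss, start = pmax(0L, as.integer(start)), end = as.integer(end))
}

gene_introns <- function(genes) {
  rows <- pmap(list(genes$gene_id, genes$chrom, genes$exon_starts, genes$exon_ends),
               function(gid, ch, es, ee) {
                 if (length(es) < 2) return(NULL)
                 tibble(gene_id = gid, chrom = ch,
                        start = ee[-length(ee)], end = es[-1])
               })
  out <- bind_rows(rows)
  if (nrow(out) == 0) tibble(gene_id = character(), chrom = character(),
                             start = integer(), end = integer()) else out
}

#' Annotate consensus peaks to genomic categories and target genes
#'
#' Each peak is placed by its center with the precedence promoter > intron >
#' TTS > intergenic: a center inside two or more promoter windows is
#' `promoter_bidirectional` (all covering genes are reported); inside
#' exactly one, `promoter_single`; otherwise inside any intron, `intron`;
#' otherwise within `tts_window` bp of any transcription termination site,
#' `tts`; otherwise `intergenic`. Signed TSS distances (positive =
#' downstream of the TSS in the gene's orientation) are reported per
#' promoter gene.
#'
#' @param peaks Consensus peak tibble (needs `peak_id`, `chrom`, `start`,
#'   `end`; `center` used when present).
#' @param genes Gene-model tibble.
#' @param config A [drm_config()].
#' @return Tibble of class `"drm_annotation"`: `peak_id`, `category`,
#'   `gene_ids` (list-column, empty iff intergenic), `distance_to_tss`
#'   (list-column, promoter categories only).
#' @export
annotate_peaks <- function(peaks, genes, config = drm_config()) {
  peaks <- as_tibble(peaks)
  centers <- peak_center(peaks)
  prom <- promoter_windows(genes, config)
  introns <- gene_introns(genes)
  tts_win <- tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = pmax(0L, genes$tts - config$tts_window),
                    end = genes$tts + config$tts_window + 1L)
  cat_v <- character(nrow(peaks))
  gene_l <- vector("list", nrow(peaks))
  dist_l <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]; ce <- centers[i]
    in_prom <- which(prom$chrom == ch & prom$start <= ce & ce < prom$end)
    if (length(in_prom) >= 1) {
      cat_v[i] <- if (length(in_prom) >= 2) "promoter_bidirectional" else "promoter_single"
      gene_l[[i]] <- prom$gene_id[in_prom]
      dist_l[[i]] <- ifelse(prom$strand[in_prom] == "+",
                            ce - prom$tss[in_prom], prom$tss[in_prom] - ce)
      next
    }
    in_intron <- which(introns$chrom == ch & introns$start <= ce & ce < introns$end)
    if (length(in_intron)) {
      cat_v[i] <- "intron"
      gene_l[[i]] <- unique(introns$gene_id[in_intron])
      dist_l[[i]] <- integer(0)
      next
    }
    in_tts <- which(tts_win$chrom == ch & tts_win$start <= ce & ce < tts_win$end)
    if (length(in_tts)) {
      cat_v[i] <- "tts"
      gene_l[[i]] <- unique(tts_win$gene_id[in_tts])
      dist_l[[i]] <- integer(0)
      next
    }
    cat_v[i] <- "intergenic"
    gene_l[[i]] <- character(0)
    dist_l[[i]] <- integer(0)
  }
  out <- tibble(peak_id = peaks$peak_id, category = cat_v,
                gene_ids = gene_l, distance_to_tss = dist_l)
  class(out) <- c("drm_annotation", class(out))
  out
}

ANNOTATION_CATEGORIES <- c("promoter_bidirectional", "promoter_single",
                           "intron", "tts", "intergenic")

#' Summarise an annotation into category counts
#'
#' @param annotations A `"drm_annotation"` tibble, or any tibble with a
#'   `category` column.
#' @return One-row tibble with a count per category, `total`, and
#'   `promoter_percentage` (share of peaks in either promoter category,
#'   rounded to the nearest integer; `NA` for empty input).
#' @examples
#' ann <- tibble::tibble(category = rep(c("promoter_bidirectional",
#'   "promoter_single", "intron", "tts", "intergenic"),
#'   c(423, 688, 148, 48, 111)))
#' summarize_annotation(ann)
#' @export
summarize_annotation <- function(annotations) {
  counts <- table(factor(annotations$category, levels = ANNOTATION_CATEGORIES))
  total <- sum(counts)
  pct <- if (total == 0) NA_real_ else
    round(100 * (counts[["promoter_bidirectional"]] + counts[["promoter_single"]]) / total)
  bind_cols(as_tibble(as.list(counts)), tibble(total = total, promoter_percentage = pct))
}

#' Extract DRM target genes from an annotation
#'
#' DRM target genes are the genes with a DRM peak in their promoter: the
#' union of `gene_ids` over the two promoter categories only (intron, TTS
#' and intergenic peaks contribute nothing).
#'
#' @param annotations A `"drm_annotation"` tibble.
#' @return Sorted character vector of gene ids.
#' @export
extract_target_genes <- function(annotations) {
  keep <- annotations$category %in% c("promoter_bidirectional", "promoter_single")
  sort(unique(unlist(annotations$gene_ids[keep])))
}
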