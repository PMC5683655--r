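#' Pipeline configuration
#'
#' Collects every numeric threshold used by the analysis in one validated
#' list, so that no step carries a hidden constant. Defaults follow the
#' published analysis of DRM chromatin occupancy in *C. elegans* late
#' embryos.
#'
#' @param promoter_upstream Promoter window extent upstream of the TSS, bp.
#' @param promoter_downstream Promoter window extent downstream of the TSS, bp.
#' @param tts_window Half-width of the window around a transcription
#'   termination site used for TTS annotation, bp.
#' @param fdr_alpha FDR threshold for a significant occupancy change.
#' @param muvb_vote_k Minimum number of the four MuvB subunits (LIN-9,
#'   LIN-37, LIN-52, LIN-54) that must overlap to call a MuvB region.
#' @param min_replicates Minimum number of replicates a peak must appear in
#'   to survive reproducibility filtering.
#' @param cde_pattern IUPAC pattern of the CDE (E2F-DP) motif.
#' @param cde_max_mismatch Mismatch budget for the CDE scan.
#' @param chr_pattern IUPAC pattern of the CHR (LIN-54) motif.
#' @param chr_max_mismatch Mismatch budget for the CHR scan.
#' @param conservation_threshold Minimum mean conservation score (phastCons
#'   scale, 0-1) over a motif match for it to count as conserved.
#' @param conservation_summary How to aggregate per-base conservation over a
#'   match span: `"mean"` (default) or `"min"`.
#' @param de_q_threshold q-value threshold for a differential-expression call.
#' @param de_fc_threshold Linear fold-change threshold for a
#'   differential-expression call (applied symmetrically up and down).
#' @param rng_seed Integer seed recorded for provenance.
#'
#' @return A named list with class `"drm_config"`.
#' @examples
#' cfg <- drm_config()
#' cfg$muvb_vote_k
#' @export
drm_config <- function(promoter_upstream = 1000L,
                       promoter_downstream = 100L,
                       tts_window = 1000L,
                       fdr_alpha = 0.05,
                       muvb_vote_k = 3L,
                       min_replicates = 2L,
                       cde_pattern = "BSSSSS",
                       cde_max_mismatch = 1L,
                       chr_pattern = "TTYRAA",
                       chr_max_mismatch = 0L,
                       conservation_threshold = 0.7,
                       conservation_summary = c("mean", "min"),
                       de_q_threshold = 0.05,
                       de_fc_threshold = 1.5,
                       rng_seed = 1L) {
  conservation_summary <- match.arg(conservation_summary)
  cfg <- list(
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    tts_window = as.integer(tts_window),
    fdr_alpha = fdr_alpha,
    muvb_vote_k = as.integer(muvb_vote_k),
    min_replicates = as.integer(min_replicates),
    cde_pattern = cde_pattern,
    cde_max_mismatch = as.integer(cde_max_mismatch),
    chr_pattern = chr_pattern,
    chr_max_mismatch = as.integer(chr_max_mismatch),
    conservation_threshold = conservation_threshold,
    conservation_summary = conservation_summary,
    de_q_threshold = de_q_threshold,
    de_fc_threshold = de_fc_threshold,
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$promoter_upstream >= 0, cfg$promoter_downstream >= 0,
    cfg$tts_window >= 0,
    cfg$fdr_alpha > 0, cfg$fdr_alpha < 1,
    cfg$muvb_vote_k >= 1, cfg$muvb_vote_k <= 4,
    cfg$min_replicates >= 1,
    nchar(cfg$cde_pattern) >= 1, nchar(cfg$chr_pattern) >= 1,
    cfg$cde_max_mismatch >= 0, cfg$chr_max_mismatch >= 0,
    cfg$conservation_threshold >= 0, cfg$conservation_threshold <= 1,
    cfg$de_q_threshold > 0, cfg$de_q_threshold <= 1,
    cfg$de_fc_threshold >= 1
  )
  structure(cfg, class = "drm_config")
}
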