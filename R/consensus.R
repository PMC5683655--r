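# Consensus peak construction: replicate reproducibility filtering, subunit
# overlap voting, the E2F-DP / LIN-35 / MuvB triple intersection that defines
# high-confidence DRM sites, and retention classification in the mutant.

peak_center <- function(x) {
  centers <- as.integer(floor((x$start + x$end) / 2))
  if ("center" %in% names(x)) {
    centers <- ifelse(!is.na(x$center), as.integer(x$center), centers)
  } else if ("summit" %in% names(x)) {
    centers <- ifelse(!is.na(x$summit), x$start + as.integer(x$summit), centers)
  }
  centers
}

#' Reproducibility filter for one subunit's replicate peak sets
#'
#' Single-linkage clusters peaks across replicates by >= 1 bp overlap and
#' keeps clusters supported by at least `min_replicates` distinct
#' replicates, emitting one merged peak per surviving cluster (union span;
#' summit at the median of the member summits). This is the package's
#' reproducibility step standing in for IDR-style replicate filtering.
#'
#' @param peaks Tibble of one subunit's peaks across replicates (columns
#'   `chrom`, `start`, `end`, plus `replicate`; `summit`, `name`, `score`
#'   optional).
#' @param min_replicates Minimum number of distinct replicates per cluster.
#' @return A merged peak tibble (one row per reproducible cluster) carrying
#'   the input's `subunit`/`condition` labels.
#' @export
reproducible_peaks <- function(peaks, min_replicates = 2L) {
  if (min_replicates < 1) abort("`min_replicates` must be >= 1")
  peaks <- as_tibble(peaks)
  if (!"replicate" %in% names(peaks)) abort("`peaks` needs a `replicate` column")
  if (nrow(peaks) == 0) return(peaks[0, c("chrom", "start", "end")])
  n_reps <- dplyr::n_distinct(peaks$replicate)
  if (min_replicates > n_reps) {
    abort(sprintf("`min_replicates` (%d) exceeds the number of replicates present (%d)",
                  min_replicates, n_reps))
  }
  peaks$`..cluster` <- cluster_intervals(peaks)
  peaks$`..center` <- peak_center(peaks)
  kept <- peaks |>
    group_by(.data$`..cluster`) |>
    filter(dplyr::n_distinct(.data$replicate) >= min_replicates) |>
    ungroup()
  if (nrow(kept) == 0) {
    out <- kept[0, c("chrom", "start", "end")]
    out$name <- character(0)
    return(out)
  }
  merged <- kept |>
    group_by(.data$`..cluster`) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      summit = as.integer(round(median(.data$`..center`))) - min(.data$start),
      score = if ("score" %in% names(peaks)) mean(.data$score, na.rm = TRUE) else NA_real_,
      n_replicates = dplyr::n_distinct(.data$replicate),
      subunit = if ("subunit" %in% names(peaks)) .data$subunit[1] else NA_character_,
      condition = if ("condition" %in% names(peaks)) .data$condition[1] else NA_character_,
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start) |>
    select(-"..cluster")
  merged$name <- sprintf("%s_rep%0*d",
                         ifelse(is.na(merged$subunit), "peak", merged$subunit),
                         nchar(nrow(merged)), seq_len(nrow(merged)))
  merged
}

# Normalise one voting set into rows carrying a member map. Raw peaks get a
# one-entry map keyed by their subunit label (falling back to the set name);
# consensus rows keep their existing map.
vote_rows <- function(set, label) {
  set <- as_tibble(set)
  if (nrow(set) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  vote_label = character(), center = integer(), members = list()))
  }
  centers <- peak_center(set)
  if ("members" %in% names(set)) {
    members <- set$members
  } else {
    ids <- if ("name" %in% names(set) && !anyNA(set$name)) set$name else
      sprintf("%s_%d", label, seq_len(nrow(set)))
    keys <- if ("subunit" %in% names(set) && !anyNA(set$subunit)) set$subunit else
      rep(label, nrow(set))
    members <- map2(ids, keys, function(id, k) setNames(list(id), k))
  }
  tibble(chrom = set$chrom, start = set$start, end = set$end,
         vote_label = label, center = as.integer(centers), members = members)
}

merge_member_maps <- function(maps) {
  keys <- unique(unlist(lapply(maps, names)))
  setNames(lapply(keys, function(k) {
    sort(unique(unlist(lapply(maps, function(m) m[[k]]))))
  }), keys)
}

#' Overlap voting across peak sets
#'
#' Single-linkage merges the peaks of several sets (one set per subunit, or
#' per pre-computed region type) and emits one consensus peak for every
#' cluster in which at least `min_subunits` distinct sets are represented.
#' A set contributing several peaks to a cluster still counts once. The
#' consensus interval is the union span of the cluster; its `center` is the
#' median of the member centers (summit when present, midpoint otherwise);
#' `members` maps each original subunit to the contributing peak ids and
#' `n_subunits` counts its non-empty entries.
#'
#' @param sets Named list of peak tibbles (names are the voting labels), or
#'   a single tibble with a `subunit` column to split on.
#' @param min_subunits Minimum number of distinct sets per cluster.
#' @param id_prefix Prefix for the generated `peak_id`s.
#' @return A consensus tibble: `peak_id`, `chrom`, `start`, `end`, `center`,
#'   `n_subunits`, `vote_labels`, `members` (list-column of named lists).
#' @export
overlap_vote <- function(sets, min_subunits, id_prefix = "consensus") {
  if (is.data.frame(sets)) {
    if (!"subunit" %in% names(sets)) abort("a single `sets` tibble needs a `subunit` column")
    sets <- split(as_tibble(sets), sets$subunit)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) abort("`sets` must be named")
  if (min_subunits < 1) abort("`min_subunits` must be >= 1")
  if (min_subunits > length(sets)) {
    abort(sprintf("`min_subunits` (%d) exceeds the number of sets provided (%d)",
                  min_subunits, length(sets)))
  }
  rows <- bind_rows(imap(sets, vote_rows))
  if (nrow(rows) == 0) return(empty_consensus())
  rows$`..cluster` <- cluster_intervals(rows)
  kept <- rows |>
    group_by(.data$`..cluster`) |>
    filter(dplyr::n_distinct(.data$vote_label) >= min_subunits) |>
    ungroup()
  if (nrow(kept) == 0) return(empty_consensus())
  keep <- kept |>
    group_by(.data$`..cluster`) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      center = as.integer(round(median(.data$center))),
      vote_labels = list(sort(unique(.data$vote_label))),
      members = list(merge_member_maps(.data$members)),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start)
  keep$peak_id <- sprintf("%s_%0*d", id_prefix, max(1L, nchar(nrow(keep))), seq_len(nrow(keep)))
  keep$n_subunits <- map_int(keep$members, length)
  keep[, c("peak_id", "chrom", "start", "end", "center",
           "n_subunits", "vote_labels", "members")]
}

empty_consensus <- function() {
  tibble(peak_id = character(), chrom = character(), start = integer(),
         end = integer(), center = integer(), n_subunits = integer(),
         vote_labels = list(), members = list())
}

#' High-confidence DRM consensus peaks
#'
#' Implements the tiered definition of DRM binding sites: E2F-DP regions are
#' the overlap of EFL-1 and DPL-1 peaks; MuvB regions are positions where at
#' least `muvb_vote_k` of the four MuvB subunits (LIN-9, LIN-37, LIN-52,
#' LIN-54) overlap; DRM peaks are the triple intersection of E2F-DP regions,
#' LIN-35 peaks and MuvB regions. The membership map of every DRM peak
#' records all original contributing subunits.
#'
#' @param peaks Tibble of reproducible peaks for all seven subunits (column
#'   `subunit` uses the canonical names), or a named list of per-subunit
#'   tibbles.
#' @param config A [drm_config()].
#' @return The DRM consensus tibble (see [overlap_vote()]), with the
#'   intermediate E2F-DP and MuvB region sets attached as attributes
#'   `e2fdp_regions` and `muvb_regions`.
#' @export
consensus_drm <- function(peaks, config = drm_config()) {
  sets <- if (is.data.frame(peaks)) split(as_tibble(peaks), peaks$subunit) else peaks
  for (s in DRM_SUBUNITS) if (is.null(sets[[s]])) sets[[s]] <- empty_consensus()[, c("chrom", "start", "end")]
  e2f <- overlap_vote(sets[E2FDP_SUBUNITS], 2L, id_prefix = "e2fdp")
  muvb <- overlap_vote(sets[MUVB_SUBUNITS], config$muvb_vote_k, id_prefix = "muvb")
  drm <- overlap_vote(list(`E2F-DP` = e2f, `LIN-35` = sets[["LIN-35"]], MuvB = muvb),
                      3L, id_prefix = "drm")
  attr(drm, "e2fdp_regions") <- e2f
  attr(drm, "muvb_regions") <- muvb
  drm
}

#' Classify retention of E2F-DP and MuvB occupancy in the mutant
#'
#' For each wild-type DRM consensus peak, asks whether it overlaps (>= 1 bp)
#' a mutant E2F-DP consensus region and/or a mutant MuvB consensus region,
#' and assigns one of three categories: `lost_both`, `retained_both`,
#' `retained_one`.
#'
#' @param wt_drm Wild-type DRM consensus tibble ([consensus_drm()]).
#' @param mut_e2fdp Mutant E2F-DP consensus regions (EFL-1/DPL-1 overlap of
#'   the mutant replicate-filtered peaks).
#' @param mut_muvb Mutant MuvB consensus regions (k-of-4 vote).
#' @return Tibble `peak_id`, `e2fdp_retained`, `muvb_retained`, `category`.
#' @export
retention_classify <- function(wt_drm, mut_e2fdp, mut_muvb) {
  hit <- function(subjects) {
    if (is.null(subjects) || nrow(subjects) == 0) return(rep(FALSE, nrow(wt_drm)))
    pr <- overlap_pairs(wt_drm, subjects)
    seq_len(nrow(wt_drm)) %in% pr$i
  }
  a <- hit(mut_e2fdp)
  b <- hit(mut_muvb)
  tibble(
    peak_id = wt_drm$peak_id,
    e2fdp_retained = a,
    muvb_retained = b,
    category = dplyr::case_when(
      a & b ~ "retained_both",
      !a & !b ~ "lost_both",
      TRUE ~ "retained_one"
    )
  )
}
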