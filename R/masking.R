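# Retrotransposon masking: remove the SSTR content carried inside one
# repeat family from the per-segment counts, with a correction that adds
# back the count expected from the masked length at the chromosome-average
# density. Without the correction, masking systematically depresses counts
# in element-rich segments even when the family carries no SSTR enrichment.

#' Mask one retrotransposon family out of the SSTR counts
#'
#' For each segment s and SSTR key k:
#' `adjusted(s, k) = raw(s, k) - inside(s, k) + L_retro(s) * dbar(k)`,
#' where `inside(s, k)` counts occurrences of key k starting inside a family
#' element (and inside s), `L_retro(s)` is the total family-element length
#' overlapping s, and `dbar(k)` is the chromosome-wide mean density of key k
#' over non-excluded segments (total count / total non-excluded length).
#' Negative adjusted counts are floored at 0. With occurrences placed
#' uniformly (no enrichment inside elements), the adjustment is zero in
#' expectation.
#'
#' @param occurrences SSTR occurrences for one chromosome ([scan_sstrs()]).
#' @param family_elements data frame of elements of one family (`start`,
#'   `end`), e.g. one family from [classify_retrotransposons()].
#' @param segments segment data frame incl. `excluded` flags.
#' @param lengths repeat lengths tracked (default 2:12).
#' @return Numeric matrix of adjusted per-segment counts (rows = segments,
#'   columns = [sstr_keys()]).
#' @export
mask_family <- function(occurrences, family_elements, segments,
                        lengths = 2:12) {
  raw <- sstr_count_matrix(occurrences, segments, lengths)
  if (is.null(family_elements) || !nrow(family_elements)) {
    message("family has no elements on this chromosome; counts unchanged")
    return(raw)
  }
  size <- segments$end[1] - segments$start[1]

  # occurrences starting inside a family element
  fam_ir <- to_iranges(family_elements$start, family_elements$end)
  occ_pos <- to_iranges(occurrences$start, occurrences$start + 1L)
  inside_hit <- IRanges::overlapsAny(occ_pos, fam_ir)
  inside <- sstr_count_matrix(occurrences[inside_hit, , drop = FALSE],
                              segments, lengths)

  # family-element length overlapping each segment (elements not merged)
  seg_ir <- to_iranges(segments$start, segments$end)
  ov <- IRanges::findOverlaps(seg_ir, fam_ir)
  inter <- IRanges::pintersect(seg_ir[S4Vectors::queryHits(ov)],
                               fam_ir[S4Vectors::subjectHits(ov)])
  l_retro <- numeric(nrow(segments))
  if (length(ov)) {
    w <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
    l_retro[as.integer(names(w))] <- w
  }

  keep <- !segments$excluded
  total_len <- sum(keep) * size
  dbar <- if (total_len > 0) colSums(raw[keep, , drop = FALSE]) / total_len
          else colSums(raw) * 0
  adjusted <- raw - inside + outer(l_retro, dbar)
  adjusted[adjusted < 0] <- 0
  adjusted
}

#' Before/after correlation report for a masked family
#'
#' Correlates the raw and the masked SSTR tracks against the same feature
#' columns over the same non-excluded segments, for side-by-side rendering.
#'
#' @param tracks_raw list from [segment_tracks()].
#' @param masked_counts adjusted count matrix from [mask_family()].
#' @param feature_keys feature columns to correlate against.
#' @return List with matrices `before` and `after` (identical shape).
#' @export
masked_correlation_report <- function(tracks_raw, masked_counts,
                                      feature_keys = c("gc",
                                                       RETRO_FAMILIES)) {
  if (nrow(masked_counts) != nrow(tracks_raw$segments))
    stop("masked counts and segment table have different numbers of segments")
  size <- tracks_raw$segments$end[1] - tracks_raw$segments$start[1]
  before <- correlate_all(tracks_raw, feature_keys = feature_keys)
  masked_tracks <- tracks_raw
  masked_tracks$values[, colnames(masked_counts)] <- masked_counts / size
  after <- correlate_all(masked_tracks, feature_keys = feature_keys)
  list(before = before, after = after)
}
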