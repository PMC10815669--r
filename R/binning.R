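# Fixed-size segmentation and per-segment tracks.
#
# The segment (default 100 kbp) is the unit of every correlation. Tracks are
# held as a plain numeric matrix: one row per segment, one column per track
# key (176 SSTR keys "unit.length", 11 gene categories, 5 retrotransposon
# families, "gc").

#' Split a chromosome into equal-size segments
#'
#' Only full segments are kept: the trailing remainder shorter than `size`
#' is dropped, so a 99,999 bp chromosome yields no 100 kbp segment at all.
#'
#' @param chrom_length chromosome length in bp.
#' @param size segment size in bp (default 100000).
#' @param chrom_id optional chromosome label.
#' @return Data frame with columns `chrom`, `index` (1-based ordinal),
#'   `start`, `end` (0-based half-open).
#' @export
segment_chromosome <- function(chrom_length, size = 100000L,
                               chrom_id = NA_character_) {
  if (length(size) != 1L || is.na(size) || size < 1)
    stop("segment size must be a positive integer")
  n <- chrom_length %/% size
  starts <- (seq_len(n) - 1L) * size
  data.frame(chrom = rep(chrom_id, n), index = seq_len(n),
             start = starts, end = starts + size,
             stringsAsFactors = FALSE)
}

#' G+C content and sequencing-gap fraction of each segment
#'
#' G+C is computed over unambiguous bases only ((G+C)/(A+C+G+T), 0 when a
#' segment has no ACGT base), so modest N content does not depress it; the
#' gap fraction is the share of N characters in the segment (other ambiguity
#' codes break repeats but do not count as gap).
#'
#' @param seq chromosome sequence (character scalar) or its integer coding.
#' @param segments data frame from [segment_chromosome()].
#' @return Data frame with columns `gc` and `gap_fraction`, one row per
#'   segment.
#' @export
gc_and_gap <- function(seq, segments) {
  if (is.integer(seq)) {
    codes <- seq
    is_n <- seq == 0L   # integer coding folds all ambiguity codes into 0
  } else {
    codes <- encode_seq(seq)
    # only N counts toward the gap fraction, not other ambiguity codes
    is_n <- as.integer(charToRaw(seq)) == utf8ToInt("N")
  }
  n_seg <- nrow(segments)
  gc <- numeric(n_seg); gap <- numeric(n_seg)
  for (i in seq_len(n_seg)) {
    s <- segments$start[i] + 1L; e <- segments$end[i]
    if (e > length(codes)) stop("segment extends beyond sequence end")
    tab <- tabulate(codes[s:e], nbins = 4L)
    acgt <- sum(tab)
    gc[i] <- if (acgt > 0) (tab[2] + tab[3]) / acgt else 0
    gap[i] <- sum(is_n[s:e]) / (e - s + 1L)
  }
  data.frame(gc = gc, gap_fraction = gap)
}

#' Per-segment SSTR count densities
#'
#' Each occurrence is assigned to the segment containing its start position
#' (an occurrence spanning a segment boundary counts once, in the segment
#' where it starts); the density is the count divided by the segment size.
#'
#' @param occurrences data frame from [scan_sstrs()] (one chromosome).
#' @param segments data frame from [segment_chromosome()].
#' @param lengths repeat lengths tracked (default 2:12).
#' @return Numeric matrix, rows = segments, columns = [sstr_keys()] densities.
#' @export
sstr_density_track <- function(occurrences, segments, lengths = 2:12) {
  size <- segments$end[1] - segments$start[1]
  keys <- sstr_keys(lengths)
  counts <- sstr_count_matrix(occurrences, segments, lengths)
  counts / size
}

# raw per-segment counts for each (unit, length) key
sstr_count_matrix <- function(occurrences, segments, lengths = 2:12) {
  keys <- sstr_keys(lengths)
  n_seg <- nrow(segments)
  size <- if (n_seg) segments$end[1] - segments$start[1] else 1L
  m <- matrix(0, nrow = n_seg, ncol = length(keys),
              dimnames = list(NULL, keys))
  if (!nrow(occurrences) || !n_seg) return(m)
  seg_idx <- occurrences$start %/% size + 1L
  key <- paste(occurrences$unit, occurrences$length, sep = ".")
  ok <- seg_idx >= 1L & seg_idx <= n_seg & key %in% keys
  if (!any(ok)) return(m)
  ki <- match(key[ok], keys)
  flat <- (ki - 1L) * n_seg + seg_idx[ok]
  tab <- tabulate(flat, nbins = n_seg * length(keys))
  m[] <- tab
  m
}

#' Per-segment coverage fraction of an interval set
#'
#' Coverage is the fraction of the segment's positions covered by the
#' (merged) intervals; an element only partially overlapping a segment
#' contributes only its overlapping part.
#'
#' @param intervals data frame with `start`, `end` (merged, 0-based
#'   half-open).
#' @param segments data frame from [segment_chromosome()].
#' @return Numeric vector of coverages in \[0, 1\], one per segment.
#' @export
coverage_track <- function(intervals, segments) {
  n_seg <- nrow(segments)
  if (!n_seg) return(numeric(0))
  size <- segments$end[1] - segments$start[1]
  if (!nrow(intervals)) return(numeric(n_seg))
  cov <- IRanges::coverage(to_iranges(intervals$start, intervals$end),
                           width = max(segments$end))
  v <- IRanges::Views(cov, start = segments$start + 1L, end = segments$end)
  as.numeric(IRanges::viewSums(v)) / size
}

#' Per-segment element count density
#'
#' Elements (e.g. retrotransposon copies) are assigned to the segment
#' containing their start position; the value is count / segment size.
#'
#' @param elements data frame with a `start` column (0-based).
#' @param segments data frame from [segment_chromosome()].
#' @return Numeric vector of count densities, one per segment.
#' @export
count_density_track <- function(elements, segments) {
  n_seg <- nrow(segments)
  if (!n_seg) return(numeric(0))
  size <- segments$end[1] - segments$start[1]
  if (!nrow(elements)) return(numeric(n_seg))
  seg_idx <- elements$start %/% size + 1L
  tabulate(seg_idx[seg_idx >= 1L & seg_idx <= n_seg], nbins = n_seg) / size
}

#' Flag segments excluded from correlation
#'
#' A segment is excluded when it overlaps a centromere/exclusion interval by
#' at least 1 bp, or when its sequencing-gap fraction exceeds the threshold
#' (strictly greater than 1% by default, so a segment at exactly the
#' threshold is kept).
#'
#' @param segments data frame from [segment_chromosome()].
#' @param gap_fraction numeric vector from [gc_and_gap()].
#' @param exclusion_intervals data frame with `start`, `end` for this
#'   chromosome (may have zero rows).
#' @param gap_threshold maximum tolerated gap fraction (default 0.01).
#' @return Logical vector, TRUE where the segment is excluded.
#' @export
filter_segments <- function(segments, gap_fraction,
                            exclusion_intervals = NULL,
                            gap_threshold = 0.01) {
  excluded <- gap_fraction > gap_threshold
  if (!is.null(exclusion_intervals) && nrow(exclusion_intervals)) {
    ov <- IRanges::findOverlaps(
      to_iranges(segments$start, segments$end),
      to_iranges(exclusion_intervals$start, exclusion_intervals$end))
    excluded[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  excluded
}

#' Build the full per-segment track table for one chromosome
#'
#' Combines segmentation, G+C/gap, SSTR densities, gene-category coverages,
#' retrotransposon count densities and the exclusion flags into one segment
#' table plus a values matrix.
#'
#' @param seq chromosome sequence (character scalar).
#' @param chrom_id chromosome label.
#' @param occurrences SSTR occurrences for this chromosome ([scan_sstrs()]).
#' @param categories named list of category interval sets
#'   ([derive_gene_categories()]), or NULL.
#' @param retro classified retrotransposons for this chromosome
#'   ([classify_retrotransposons()]), or NULL.
#' @param exclusion_intervals exclusion intervals for this chromosome, or
#'   NULL.
#' @param segment_size segment size in bp (default 100000).
#' @param gap_threshold gap-fraction exclusion threshold (default 0.01).
#' @return List with `segments` (data frame incl. `gc`, `gap_fraction`,
#'   `excluded`) and `values` (numeric matrix of all track columns).
#' @export
segment_tracks <- function(seq, chrom_id, occurrences, categories = NULL,
                           retro = NULL, exclusion_intervals = NULL,
                           segment_size = 100000L, gap_threshold = 0.01) {
  segments <- segment_chromosome(nchar(seq), segment_size, chrom_id)
  if (!nrow(segments))
    return(list(segments = segments,
                values = matrix(0, 0, length(track_keys()),
                                dimnames = list(NULL, track_keys()))))
  gg <- gc_and_gap(seq, segments)
  segments$gc <- gg$gc
  segments$gap_fraction <- gg$gap_fraction
  segments$excluded <- filter_segments(segments, gg$gap_fraction,
                                       exclusion_intervals, gap_threshold)

  sstr <- sstr_density_track(occurrences, segments)
  catm <- matrix(0, nrow(segments), length(GENE_CATEGORIES),
                 dimnames = list(NULL, GENE_CATEGORIES))
  if (!is.null(categories)) {
    for (cat in names(categories))
      catm[, cat] <- coverage_track(categories[[cat]], segments)
  }
  retm <- matrix(0, nrow(segments), length(RETRO_FAMILIES),
                 dimnames = list(NULL, RETRO_FAMILIES))
  if (!is.null(retro) && nrow(retro)) {
    for (fam in RETRO_FAMILIES) {
      el <- retro[retro$family_key == fam, , drop = FALSE]
      retm[, fam] <- count_density_track(el, segments)
    }
  }
  values <- cbind(sstr, catm, retm, gc = segments$gc)
  list(segments = segments, values = values)
}

track_keys <- function() c(sstr_keys(), GENE_CATEGORIES, RETRO_FAMILIES, "gc")

#' Write a segment track table as TSV
#'
#' @param tracks list from [segment_tracks()].
#' @param path output path.
#' @export
write_tracks <- function(tracks, path) {
  df <- cbind(tracks$segments[, c("chrom", "index", "start", "end",
                                  "excluded")],
              as.data.frame(tracks$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
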