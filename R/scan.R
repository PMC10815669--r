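# Maximal-run SSTR scanning.
#
# Internally sequences are mapped to integer codes A=1, C=2, G=3, T=4 and 0
# for every other character (N and all IUPAC ambiguity codes). Runs never
# contain a non-ACGT character and are broken by them.

BASES <- c("A", "C", "G", "T")

# raw-byte lookup table: byte value -> base code (0 for non-ACGT)
.code_table <- local({
  tab <- integer(256)
  tab[utf8ToInt("A") + 1L] <- 1L
  tab[utf8ToInt("C") + 1L] <- 2L
  tab[utf8ToInt("G") + 1L] <- 3L
  tab[utf8ToInt("T") + 1L] <- 4L
  tab
})

#' Encode a DNA string as integer base codes
#' @param seq character scalar (uppercase DNA).
#' @return integer vector, A=1, C=2, G=3, T=4, anything else 0.
#' @keywords internal
encode_seq <- function(seq) {
  if (nchar(seq) == 0L) return(integer(0))
  .code_table[as.integer(charToRaw(seq)) + 1L]
}

decode_seq <- function(codes) {
  if (length(codes) == 0L) return("")
  intToUtf8(c(65L, 67L, 71L, 84L, 78L)[replace(codes, codes == 0L, 5L)])
}

#' Scan for maximal mononucleotide runs
#'
#' Every maximal run of a single base X with length L, 2 <= L <= 12, is
#' reported with the homodinucleotide unit label XX. Runs longer than 12 bp
#' are dropped entirely (they are conventional STRs, not SSTRs); runs are
#' broken by any non-ACGT character.
#'
#' @param seq character scalar, DNA sequence (uppercase).
#' @param chrom_id optional chromosome label attached to the result.
#' @return Data frame with columns `chrom`, `start` (0-based), `length`,
#'   `unit`, sorted by start.
#' @examples
#' scan_mononucleotide("AANAA")  # two (AA, 2) runs
#' @export
scan_mononucleotide <- function(seq, chrom_id = NA_character_) {
  codes <- if (is.integer(seq)) seq else encode_seq(seq)
  occ_df(mono_runs(codes), chrom_id)
}

# core: maximal equal-base runs on integer codes
mono_runs <- function(codes) {
  n <- length(codes)
  if (n == 0L) return(empty_runs())
  r <- rle(codes)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0L & r$lengths >= 2L & r$lengths <= 12L
  list(
    start = starts[keep] - 1L,               # 0-based
    length = r$lengths[keep],
    unit = paste0(BASES[r$values[keep]], BASES[r$values[keep]])
  )
}

#' Scan for maximal dinucleotide (period-2) runs
#'
#' A dinucleotide SSTR is a maximal period-2 interval (s\[j\] == s\[j+2\]
#' throughout, extendable in neither direction) whose first two bases differ,
#' with total length 2--12 bp. Only the maximal run is reported: AGAGAG is a
#' single (AG, 6) occurrence and its contained sub-repeats (AGAG, AG, and
#' the rotated-phase GAGA) are never emitted. Intervals whose first two bases
#' are equal are homopolymers and belong to the mononucleotide scan. Odd
#' lengths are legal (AGAGA is (AG, 5)).
#'
#' @inheritParams scan_mononucleotide
#' @return Data frame as in [scan_mononucleotide()].
#' @examples
#' scan_dinucleotide("AGAGAG")  # one (AG, 6) occurrence
#' scan_dinucleotide("ACGT")    # three maximal length-2 runs
#' @export
scan_dinucleotide <- function(seq, chrom_id = NA_character_) {
  codes <- if (is.integer(seq)) seq else encode_seq(seq)
  occ_df(di_runs(codes), chrom_id)
}

di_runs <- function(codes) {
  n <- length(codes)
  if (n < 2L) return(empty_runs())
  valid <- codes > 0L
  # eq2[j] (1-based j in 1..n-2): positions j, j+1, j+2 valid and s[j]==s[j+2]
  eq2 <- if (n >= 3L) {
    valid[1:(n - 2L)] & valid[2:(n - 1L)] & valid[3:n] &
      codes[1:(n - 2L)] == codes[3:n]
  } else logical(0)

  starts <- integer(0); lens <- integer(0)
  if (length(eq2)) {
    r <- rle(eq2)
    rends <- cumsum(r$lengths)
    rstarts <- rends - r$lengths + 1L
    tr <- r$values
    # a maximal TRUE-run j..j+k-1 in eq2 is a maximal period-2 interval
    # [j, j+k+1] (1-based inclusive), length k + 2
    starts <- rstarts[tr]
    lens <- r$lengths[tr] + 2L
  }
  # maximal length-2 intervals: adjacent valid pairs not covered by eq2 on
  # either side
  pair_ok <- valid[1:(n - 1L)] & valid[2:n]
  left_ext <- c(FALSE, eq2)[1:(n - 1L)]                # eq2[i-1] at pair i
  right_ext <- c(eq2, FALSE)[1:(n - 1L)]               # eq2[i] at pair i
  p <- which(pair_ok & !left_ext & !right_ext)
  starts <- c(starts, p)
  lens <- c(lens, rep(2L, length(p)))

  # unit = first two bases; drop homopolymer intervals and over-long runs
  keep <- lens <= 12L & codes[starts] != codes[starts + 1L]
  starts <- starts[keep]; lens <- lens[keep]
  list(
    start = starts - 1L,
    length = lens,
    unit = paste0(BASES[codes[starts]], BASES[codes[starts + 1L]])
  )
}

empty_runs <- function() list(start = integer(0), length = integer(0),
                              unit = character(0))

occ_df <- function(runs, chrom_id) {
  df <- data.frame(chrom = rep(chrom_id, length(runs$start)),
                   start = runs$start, length = runs$length,
                   unit = runs$unit, stringsAsFactors = FALSE)
  df[order(df$start, df$unit), , drop = FALSE]
}

#' Scan a sequence for all maximal SSTR occurrences
#'
#' Concatenation of the mononucleotide and dinucleotide scans, sorted by
#' (start, unit). The two period classes are scanned independently, so a
#' mononucleotide run and an overlapping dinucleotide run are both kept
#' (e.g. in "AACAC" the (AA, 2) run and the (AC, 4) run share a base).
#'
#' @inheritParams scan_mononucleotide
#' @return Data frame with columns `chrom`, `start` (0-based), `length`,
#'   `unit`, sorted by (start, unit).
#' @examples
#' scan_sstrs("AACAC")
#' scan_sstrs("AGAGA")  # one (AG, 5) occurrence
#' @export
scan_sstrs <- function(seq, chrom_id = NA_character_) {
  codes <- if (is.integer(seq)) seq else encode_seq(seq)
  m <- mono_runs(codes)
  d <- di_runs(codes)
  occ_df(list(start = c(m$start, d$start),
              length = c(m$length, d$length),
              unit = c(m$unit, d$unit)), chrom_id)
}

#' Export SSTR occurrences as BED-like TSV
#'
#' Columns: chrom, start, end, unit, length (0-based half-open coordinates).
#'
#' @param occurrences data frame from [scan_sstrs()].
#' @param path output file path.
#' @export
write_occurrences <- function(occurrences, path) {
  out <- data.frame(chrom = occurrences$chrom,
                    start = occurrences$start,
                    end = occurrences$start + occurrences$length,
                    unit = occurrences$unit,
                    length = occurrences$length)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
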