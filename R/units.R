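#' The 16 SSTR repeat units and their motif groups
#'
#' Super-short tandem repeats (SSTRs) are maximal tandem repeats of total
#' length 2--12 bp built from a 1 bp or 2 bp repeat unit. Every unit is
#' encoded as a two-character label over \{A,C,G,T\}: homodinucleotide labels
#' (AA, CC, GG, TT) stand for mononucleotide runs, the remaining 12 labels
#' are phased dinucleotide units (AG and GA are distinct units). Units fall
#' into four motif groups by the strong (S = G/C) or weak (W = A/T) identity
#' of their two positions:
#' SS = \{CC, CG, GC, GG\}, WW = \{AA, AT, TA, TT\},
#' SW = \{CA, CT, GA, GT\} (strong first), WS = \{AC, AG, TC, TG\}.
#'
#' @return A data frame with columns `unit` (character, 2 letters) and
#'   `group` (factor with levels SS, WW, SW, WS), 16 rows, ordered by group
#'   (SS, WW, SW, WS) and alphabetically within group.
#' @examples
#' sstr_units()
#' table(sstr_units()$group)
#' @export
sstr_units <- function() {
  groups <- list(
    SS = c("CC", "CG", "GC", "GG"),
    WW = c("AA", "AT", "TA", "TT"),
    SW = c("CA", "CT", "GA", "GT"),
    WS = c("AC", "AG", "TC", "TG")
  )
  data.frame(
    unit = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)),
    stringsAsFactors = FALSE
  )
}

#' Track keys for all (unit, length) combinations
#'
#' @param lengths integer vector of repeat total lengths (default 2:12).
#' @return Character vector of keys of the form `"<unit>.<length>"`, ordered
#'   unit-major in the canonical unit order of [sstr_units()].
#' @export
sstr_keys <- function(lengths = 2:12) {
  units <- sstr_units()$unit
  as.vector(t(outer(units, lengths, paste, sep = ".")))
}

#' Spell out the repeat string for a unit and total length
#'
#' `(AG, 5)` gives `"AGAGA"`; homodinucleotide units give homopolymer runs
#' (`(AA, 3)` gives `"AAA"`). Odd total lengths are legal for dinucleotide
#' units.
#'
#' @param unit 2-character unit label.
#' @param length total repeat length in bp (>= 1).
#' @return Character string of the requested length.
#' @examples
#' sstr_string("AG", 6)  # "AGAGAG"
#' sstr_string("GA", 3)  # "GAG"
#' @export
sstr_string <- function(unit, length) {
  stopifnot(nchar(unit) == 1 || nchar(unit) == 2, length >= 1)
  if (nchar(unit) == 1) unit <- paste0(unit, unit)
  substr(strrep(unit, ceiling(length / 2)), 1L, length)
}

#' G+C fraction of an SSTR string
#'
#' Analytic G+C content of the spelled-out repeat: mixed-unit repeats of even
#' length are always 50% G+C, while odd lengths are slanted (length 3 of an
#' SW unit is 2/3 G+C).
#'
#' @inheritParams sstr_string
#' @return Fraction of G and C bases in the repeat string, in \[0, 1\].
#' @examples
#' sstr_gc("GA", 3)  # 2/3
#' sstr_gc("GA", 4)  # 0.5
#' @export
sstr_gc <- function(unit, length) {
  s <- strsplit(sstr_string(unit, length), "")[[1]]
  mean(s %in% c("G", "C"))
}

# Reverse complement for plain character strings (A/C/G/T/N + IUPAC codes).
#' Reverse complement of a DNA string
#' @param x character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB", s)
    intToUtf8(rev(utf8ToInt(comp)))
  }, character(1), USE.NAMES = FALSE)
}
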