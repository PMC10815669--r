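# Readers and writers for the external formats. All coordinates are
# converted at these boundaries to the single internal convention:
# 0-based, half-open intervals. GenBank and RepeatMasker files are 1-based
# inclusive on disk; BED is already 0-based half-open.

#' Read a (multi-)FASTA file
#'
#' Residues are uppercased: soft-masked (lowercase) bases are scanned like
#' any other base because SSTRs are taken from the unmasked sequence.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA file '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in FASTA file: ", path)
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

# ---- GenBank flat files ----------------------------------------------------

#' Read feature annotations from a GenBank flat file
#'
#' Parses the FEATURES table of one or more LOCUS records. GenBank 1-based
#' inclusive locations become 0-based half-open intervals; `join(...)` and
#' `order(...)` locations produce multi-interval records sharing one
#' `record_id`; `complement(...)` sets strand "-"; the `/pseudo` and
#' `/pseudogene` qualifiers set `is_pseudo`. A feature whose location cannot
#' be parsed is skipped with a warning rather than aborting the chromosome.
#' The ORIGIN sequence, when present, is returned as well.
#'
#' @param path path to a GenBank flat file.
#' @return List with elements `sequence` (named character vector, possibly
#'   empty) and `features`: a data frame with columns `chrom`, `record_id`,
#'   `feature`, `start`, `end`, `strand`, `is_pseudo` (one row per interval).
#' @export
read_genbank_features <- function(path) {
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty GenBank file: ", path)

  rec_breaks <- c(0L, which(startsWith(lines, "//")))
  seqs <- character(0)
  feats <- list()
  rid <- 0L
  for (k in seq_len(length(rec_breaks) - 1L)) {
    rec <- lines[(rec_breaks[k] + 1L):(rec_breaks[k + 1L] - 1L)]
    if (!length(rec)) next
    locus_line <- rec[startsWith(rec, "LOCUS")][1]
    if (is.na(locus_line)) next
    chrom <- strsplit(trimws(sub("^LOCUS", "", locus_line)), "\\s+")[[1]][1]

    fstart <- which(startsWith(rec, "FEATURES"))[1]
    oline <- which(startsWith(rec, "ORIGIN"))[1]
    fend <- if (!is.na(oline)) oline - 1L else length(rec)
    if (!is.na(fstart) && fend > fstart) {
      body <- rec[(fstart + 1L):fend]
      # stop at any other top-level section (non-blank in column 1)
      top <- which(grepl("^[A-Z]", body))
      if (length(top)) body <- body[seq_len(top[1] - 1L)]
      parsed <- parse_feature_table(body, chrom, rid)
      feats[[length(feats) + 1L]] <- parsed$features
      rid <- parsed$next_id
    }
    if (!is.na(oline) && oline < length(rec)) {
      sq <- gsub("[ 0-9/]", "", paste(rec[(oline + 1L):length(rec)],
                                      collapse = ""))
      if (nzchar(sq)) seqs[chrom] <- toupper(sq)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    empty_annotation()
  list(sequence = seqs, features = features)
}

empty_annotation <- function() {
  data.frame(chrom = character(0), record_id = integer(0),
             feature = character(0), start = integer(0), end = integer(0),
             strand = character(0), is_pseudo = logical(0),
             stringsAsFactors = FALSE)
}

parse_feature_table <- function(body, chrom, rid) {
  # feature header lines have a key in columns 6-20; continuation and
  # qualifier lines are indented to column 22
  is_key <- grepl("^ {5}\\S", body)
  idx <- which(is_key)
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i0 <- idx[j]
    i1 <- if (j < length(idx)) idx[j + 1] - 1L else length(body)
    block <- body[i0:i1]
    key <- sub("^\\s+", "", substr(block[1], 1, 20))
    key <- sub("\\s.*$", "", key)
    rest <- trimws(substring(block[1], 21))
    qual_start <- which(grepl("^\\s+/", block[-1]))
    loc_lines <- if (length(qual_start)) {
      block[-1][seq_len(qual_start[1] - 1L)]
    } else block[-1]
    loc <- paste0(rest, paste(trimws(loc_lines), collapse = ""))
    qualifiers <- trimws(block[-1][grepl("^\\s+/", block[-1])])
    is_pseudo <- any(grepl("^/(pseudo|pseudogene)\\b|^/(pseudo|pseudogene)$",
                           qualifiers))
    parsed <- tryCatch(parse_gb_location(loc), error = function(e) NULL)
    if (is.null(parsed)) {
      warning("skipping '", key, "' feature with unparsable location: ", loc)
      next
    }
    rid <- rid + 1L
    out[[j]] <- data.frame(chrom = chrom, record_id = rid, feature = key,
                           start = parsed$start, end = parsed$end,
                           strand = parsed$strand, is_pseudo = is_pseudo,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  features <- if (length(out)) do.call(rbind, out) else empty_annotation()
  list(features = features, next_id = rid)
}

# GenBank location string -> 0-based half-open intervals + strand
parse_gb_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",")[[1]]
  if (!length(parts)) stop("empty location")
  starts <- integer(length(parts)); ends <- integer(length(parts))
  for (i in seq_along(parts)) {
    p <- gsub("[<>]", "", parts[i])
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      ab <- c(as.integer(p), as.integer(p))
    } else stop("unsupported location part: ", parts[i])
    if (ab[1] > ab[2]) stop("inverted location: ", parts[i])
    starts[i] <- ab[1] - 1L   # 1-based inclusive -> 0-based half-open
    ends[i] <- ab[2]
  }
  ord <- order(starts)
  list(start = starts[ord], end = ends[ord], strand = strand)
}

# ---- RepeatMasker .out -----------------------------------------------------

#' Read a RepeatMasker .out annotation file
#'
#' Expects the standard dialect: two header lines and a blank line, then
#' whitespace-delimited rows (score, div, del, ins, query, qbegin, qend,
#' qleft, strand, name, class/family, ...). Query coordinates (1-based
#' inclusive) become 0-based half-open; the class/family column is split on
#' the first "/" (family empty when absent).
#'
#' @param path path to a RepeatMasker .out file.
#' @return Data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `repeat_name`, `repeat_class`, `repeat_family`.
#' @export
read_repeatmasker <- function(path) {
  if (!file.exists(path)) stop("RepeatMasker file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("RepeatMasker file '", path, "' is missing its 3 header lines")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(empty_repeat_annotation())
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("RepeatMasker file '", path, "': line with fewer than 11 columns")
  m <- do.call(rbind, lapply(fields, `[`, 1:11))
  qbegin <- suppressWarnings(as.integer(m[, 6]))
  qend <- suppressWarnings(as.integer(m[, 7]))
  if (anyNA(qbegin) || anyNA(qend))
    stop("RepeatMasker file '", path, "': non-numeric query coordinates")
  cf <- m[, 11]
  slash <- regexpr("/", cf, fixed = TRUE)
  rclass <- ifelse(slash > 0, substr(cf, 1, slash - 1), cf)
  rfamily <- ifelse(slash > 0, substring(cf, slash + 1), "")
  data.frame(chrom = m[, 5],
             start = qbegin - 1L, end = qend,
             strand = ifelse(m[, 9] == "C", "-", "+"),
             repeat_name = m[, 10],
             repeat_class = rclass, repeat_family = rfamily,
             stringsAsFactors = FALSE)
}

empty_repeat_annotation <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), repeat_name = character(0),
             repeat_class = character(0), repeat_family = character(0),
             stringsAsFactors = FALSE)
}

#' Write repeat annotations in RepeatMasker .out dialect
#'
#' Inverse of [read_repeatmasker()]: re-reading the written file yields
#' identical records.
#'
#' @param repeats data frame as returned by [read_repeatmasker()].
#' @param path output path.
#' @export
write_repeatmasker <- function(repeats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query     position in query        matching  repeat           position in repeat",
    "score   div. del. ins.  sequence  begin end      (left)    repeat    class/family   begin  end    (left)  ID",
    ""), con)
  if (nrow(repeats)) {
    cf <- ifelse(nzchar(repeats$repeat_family),
                 paste0(repeats$repeat_class, "/", repeats$repeat_family),
                 repeats$repeat_class)
    lines <- sprintf("%5d %5.1f %4.1f %4.1f  %-10s %8d %8d (%d) %s %-10s %-15s %6d %6d (%d) %5d",
                     1000L, 10.0, 1.0, 1.0, repeats$chrom,
                     repeats$start + 1L, repeats$end, 0L,
                     ifelse(repeats$strand == "-", "C", "+"),
                     repeats$repeat_name, cf,
                     1L, repeats$end - repeats$start, 0L,
                     seq_len(nrow(repeats)))
    writeLines(lines, con)
  }
  invisible(path)
}

# ---- BED -------------------------------------------------------------------

#' Read a BED3+ file of excluded regions
#'
#' @param path path to a BED file (0-based half-open, at least 3 columns).
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_exclusion_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("BED file '", path, "': line with fewer than 3 columns")
  df <- data.frame(chrom = vapply(fields, `[`, "", 1),
                   start = as.integer(vapply(fields, `[`, "", 2)),
                   end = as.integer(vapply(fields, `[`, "", 3)),
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end) || any(df$start >= df$end))
    stop("BED file '", path, "': invalid interval (requires start < end)")
  df
}

#' Write intervals as BED3
#' @param intervals data frame with columns `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
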