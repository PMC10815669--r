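# Synthetic genome generator.
#
# Produces the same four inputs the readers consume (FASTA, GenBank flat
# file, RepeatMasker .out, exclusion BED) plus a ground-truth manifest of
# every planted object. Background sequence is i.i.d. per segment with a
# target G+C (deliberately not Markov, so a first-order model fitted to it
# is correct by construction and planted runs are the only non-null
# signal). Planted SSTRs overwrite background bases in place, with breaking
# flanks, so coordinates stay stable; collisions are retried a bounded
# number of times, then skipped and logged.

#' Default planted SSTR enrichment
#'
#' Linear coupling of the per-segment Poisson insertion rate to the
#' segment's G+C: rate(s) = base_rate * (1 + beta * gcn(s)), where gcn is
#' the G+C target rescaled to \[-1, 1\] across the gradient. The default
#' plants all four SS units (G+C-coupled, beta > 0) and all four WW units
#' (anti-coupled, beta < 0) at total lengths 2--4.
#'
#' @return Data frame with columns `unit`, `length`, `base_rate` (expected
#'   insertions per segment at mid-G+C), `beta`.
#' @export
default_enrichment <- function() {
  units <- sstr_units()
  ss <- units$unit[units$group == "SS"]
  ww <- units$unit[units$group == "WW"]
  expand <- function(u, beta) {
    do.call(rbind, lapply(2:4, function(L)
      data.frame(unit = u, length = L, base_rate = 20, beta = beta,
                 stringsAsFactors = FALSE)))
  }
  rbind(expand(ss, 0.8), expand(ww, -0.8))
}

#' Specification of a synthetic genome
#'
#' The defaults define the standard validation genome: 2 chromosomes of
#' 5 Mbp (50 segments of 100 kbp each), a linear G+C gradient from 0.35 to
#' 0.55 along each chromosome, G+C-coupled/anti-coupled planted SSTRs
#' ([default_enrichment()]), three gene classes written as GenBank features,
#' five retrotransposon families (the Alu-like family carries a planted
#' poly-A linker and tail of 8--12 bp, inside the scannable range), N-runs
#' large enough to trip the 1% gap filter in one segment, and a central
#' centromere interval written to the exclusion BED.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param segment_size segment size in bp.
#' @param gc_range G+C gradient endpoints along each chromosome.
#' @param gc_jitter per-segment uniform jitter on the G+C target.
#' @param sstr_enrichment data frame as in [default_enrichment()].
#' @param genes list of per-class gene layouts (count per chromosome,
#'   length range, exon count range).
#' @param retro list of per-family layouts; the Alu-like entry carries
#'   monomer/linker/tail length ranges, the others a length range. `n` is
#'   the expected element count per chromosome, `beta` its G+C coupling.
#' @param gap_runs number and length range of planted N runs per
#'   chromosome.
#' @param centromere_fraction central fraction of each chromosome written
#'   to the exclusion BED.
#' @param seed integer seed; the seed fully determines the output files.
#' @return List of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(
    chromosomes = c(chrS1 = 5e6, chrS2 = 5e6),
    segment_size = 100000L,
    gc_range = c(0.35, 0.55),
    gc_jitter = 0.01,
    sstr_enrichment = default_enrichment(),
    genes = list(
      pc = list(n = 40, len = c(10000, 60000), exons = c(3, 8)),
      npc = list(n = 20, len = c(1000, 10000)),
      pseudo = list(n = 15, len = c(2000, 15000))
    ),
    retro = list(
      SINE_Alu = list(n = 300, monomer = c(110, 150), linker = c(8, 12),
                      tail = c(8, 12), beta = 0.8),
      SINE_MIR = list(n = 120, len = c(100, 250), beta = 0.4),
      LINE_L1 = list(n = 60, len = c(500, 3000), beta = -0.5),
      LINE_L2 = list(n = 60, len = c(300, 1500), beta = 0.2),
      LTR = list(n = 50, len = c(200, 1000), beta = 0)
    ),
    gap_runs = list(n = 2, len = c(2000, 6000)),
    centromere_fraction = 0.04,
    seed = 1L) {
  spec <- list(chromosomes = chromosomes, segment_size = segment_size,
               gc_range = gc_range, gc_jitter = gc_jitter,
               sstr_enrichment = sstr_enrichment, genes = genes,
               retro = retro, gap_runs = gap_runs,
               centromere_fraction = centromere_fraction, seed = seed)
  class(spec) <- "synthetic_genome_spec"
  spec
}

#' Build one Alu-like element sequence
#'
#' Architecture: monomer1 + poly-A linker + monomer2 + poly-A tail, the
#' linker and tail lengths drawn from the given ranges. Monomer edges are
#' forced to non-A bases so the planted poly-A runs keep their exact length
#' when scanned.
#'
#' @param params list with `monomer`, `linker`, `tail` length ranges and
#'   optionally `gc` (monomer G+C, default 0.55).
#' @param seed optional integer seed.
#' @return Character scalar.
#' @export
alu_like_element <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc <- if (is.null(params$gc)) 0.55 else params$gc
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  monomer <- function() {
    len <- sample_range(params$monomer)
    m <- sample.int(4L, len, replace = TRUE, prob = p)
    m[c(1L, len)] <- sample(2:4, 2L, replace = TRUE)  # non-A edges
    m
  }
  linker <- rep(1L, sample_range(params$linker))
  tail <- rep(1L, sample_range(params$tail))
  decode_seq(c(monomer(), linker, monomer(), tail))
}

sample_range <- function(r) {
  r <- as.integer(round(r))
  if (r[1] >= r[2]) r[1] else r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
}

#' Generate a synthetic genome on disk
#'
#' Writes `genome.fa`, `features.gbk`, `repeats.out`, `exclude.bed` and
#' `manifest.tsv` into `dir`. The manifest records every planted object
#' (type, chromosome, interval, key) for ground-truth tests. Output is
#' byte-identical for identical specs (including the seed).
#'
#' @param spec [synthetic_genome_spec()].
#' @param dir output directory (created if missing).
#' @return List with the five file paths and the manifest data frame.
#' @export
generate_genome <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  seqs <- character(0)
  manifest <- list()
  rm_rows <- list()
  gb_records <- character(0)
  bed_rows <- list()

  for (chrom in names(spec$chromosomes)) {
    g <- generate_chromosome(spec, chrom)
    seqs[chrom] <- g$seq
    manifest[[chrom]] <- g$manifest
    rm_rows[[chrom]] <- g$repeats
    gb_records[chrom] <- g$genbank
    bed_rows[[chrom]] <- g$bed
  }

  fasta <- file.path(dir, "genome.fa")
  gbk <- file.path(dir, "features.gbk")
  rmout <- file.path(dir, "repeats.out")
  bed <- file.path(dir, "exclude.bed")
  man_path <- file.path(dir, "manifest.tsv")

  write_fasta(seqs, fasta)
  writeLines(paste(gb_records, collapse = "\n"), gbk)
  write_repeatmasker(do.call(rbind, rm_rows), rmout)
  write_bed(do.call(rbind, bed_rows), bed)
  man <- do.call(rbind, manifest)
  rownames(man) <- NULL
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, genbank = gbk, repeatmasker = rmout, bed = bed,
       manifest_path = man_path, manifest = man)
}

# one chromosome: sequence (with planted structure), annotation tables
generate_chromosome <- function(spec, chrom) {
  len <- as.integer(spec$chromosomes[[chrom]])
  size <- as.integer(spec$segment_size)
  n_seg <- len %/% size
  mid <- mean(spec$gc_range)
  half <- diff(spec$gc_range) / 2

  gc_target <- seq(spec$gc_range[1], spec$gc_range[2],
                   length.out = max(n_seg, 2L))[seq_len(n_seg)] +
    stats::runif(n_seg, -spec$gc_jitter, spec$gc_jitter)
  gcn <- pmin(1, pmax(-1, (gc_target - mid) / half))

  # i.i.d. background per segment at the target G+C
  codes <- integer(len)
  for (i in seq_len(n_seg)) {
    gc <- gc_target[i]
    codes[((i - 1L) * size + 1L):(i * size)] <-
      sample.int(4L, size, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  }
  if (len > n_seg * size)
    codes[(n_seg * size + 1L):len] <-
      sample.int(4L, len - n_seg * size, replace = TRUE,
                 prob = c((1 - mid) / 2, mid / 2, mid / 2, (1 - mid) / 2))

  occupied <- logical(len)
  man <- list()

  # sequencing-gap (N) runs
  gr <- spec$gap_runs
  if (gr$n > 0) {
    for (k in seq_len(gr$n)) {
      glen <- sample_range(gr$len)
      p <- sample.int(len - glen, 1L)
      codes[p:(p + glen - 1L)] <- 0L
      occupied[p:(p + glen - 1L)] <- TRUE
      man[[length(man) + 1L]] <- man_row("gap", chrom, p - 1L,
                                         p - 1L + glen, "N")
    }
  }

  # centromere -> exclusion BED
  c_half <- round(len * spec$centromere_fraction / 2)
  c_start <- len %/% 2L - c_half
  c_end <- len %/% 2L + c_half
  bed <- data.frame(chrom = chrom, start = c_start, end = c_end,
                    stringsAsFactors = FALSE)
  man[[length(man) + 1L]] <- man_row("centromere", chrom, c_start, c_end, "")

  # retrotransposon elements (written into the sequence)
  repeats <- list()
  for (fam in names(spec$retro)) {
    lay <- spec$retro[[fam]]
    beta <- if (is.null(lay$beta)) 0 else lay$beta
    rates <- pmax(0, lay$n / n_seg * (1 + beta * gcn))
    counts <- stats::rpois(n_seg, rates)
    for (i in seq_len(n_seg)) {
      for (k in seq_len(counts[i])) {
        el <- if (fam == "SINE_Alu") encode_seq(alu_like_element(lay)) else
          sample.int(4L, sample_range(lay$len), replace = TRUE)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") el <- rev(5L - el)   # reverse complement
        elen <- length(el)
        placed <- FALSE
        for (try in 1:20) {
          p <- (i - 1L) * size + sample.int(size, 1L)
          if (p < 2L || p + elen > len - 1L) next
          span <- (p - 1L):(p + elen)   # element plus both flank bases
          if (any(occupied[span])) next
          codes[p:(p + elen - 1L)] <- el
          # keep planted edge runs (e.g. the poly-A tail) at exact length
          if (codes[p - 1L] == el[1L])
            codes[p - 1L] <- sample(setdiff(1:4, el[1L]), 1L)
          if (codes[p + elen] == el[elen])
            codes[p + elen] <- sample(setdiff(1:4, el[elen]), 1L)
          occupied[span] <- TRUE
          fam_parts <- strsplit(fam, "_")[[1]]
          repeats[[length(repeats) + 1L]] <- list(
            chrom = chrom, start = p - 1L, end = p - 1L + elen,
            strand = strand,
            repeat_name = paste0(fam_parts[length(fam_parts)], "syn"),
            repeat_class = fam_parts[1],
            repeat_family = if (length(fam_parts) > 1) fam_parts[2] else "")
          man[[length(man) + 1L]] <- man_row("retro", chrom, p - 1L,
                                             p - 1L + elen, fam)
          placed <- TRUE
          break
        }
        if (!placed)
          message("could not place ", fam, " element on ", chrom,
                  " segment ", i, "; skipped")
      }
    }
  }

  # planted SSTR insertions (overwrite background, with breaking flanks)
  enr <- spec$sstr_enrichment
  if (!is.null(enr) && nrow(enr)) {
    for (j in seq_len(nrow(enr))) {
      unit <- enr$unit[j]; L <- enr$length[j]
      ucodes <- encode_seq(sstr_string(unit, L))
      X <- ucodes[1]; Y <- ucodes[min(2L, length(ucodes))]
      left_forbid <- if (X == Y) X else Y
      right_forbid <- ucodes[L - 1L]   # second-to-last base of the run
      rates <- pmax(0, enr$base_rate[j] * (1 + enr$beta[j] * gcn))
      counts <- stats::rpois(n_seg, rates)
      for (i in seq_len(n_seg)) {
        for (k in seq_len(counts[i])) {
          placed <- FALSE
          for (try in 1:10) {
            p <- (i - 1L) * size + sample.int(size, 1L)
            if (p < 2L || p + L > len - 1L) next
            span <- (p - 1L):(p + L)
            if (any(occupied[span])) next
            codes[p:(p + L - 1L)] <- ucodes
            codes[p - 1L] <- sample(setdiff(1:4, left_forbid), 1L)
            codes[p + L] <- sample(setdiff(1:4, right_forbid), 1L)
            occupied[span] <- TRUE
            man[[length(man) + 1L]] <- man_row("sstr", chrom, p - 1L,
                                               p - 1L + L,
                                               paste(unit, L, sep = "."))
            placed <- TRUE
            break
          }
          if (!placed)
            message("could not place (", unit, ",", L, ") on ", chrom,
                    " segment ", i, "; skipped")
        }
      }
    }
  }

  # gene annotations (GenBank features; the sequence is untouched)
  genes <- place_genes(spec, chrom, len)
  man <- c(man, genes$manifest)

  rep_df <- if (length(repeats)) {
    data.frame(chrom = vapply(repeats, `[[`, "", "chrom"),
               start = vapply(repeats, `[[`, 0L, "start"),
               end = vapply(repeats, `[[`, 0L, "end"),
               strand = vapply(repeats, `[[`, "", "strand"),
               repeat_name = vapply(repeats, `[[`, "", "repeat_name"),
               repeat_class = vapply(repeats, `[[`, "", "repeat_class"),
               repeat_family = vapply(repeats, `[[`, "", "repeat_family"),
               stringsAsFactors = FALSE)
  } else empty_repeat_annotation()

  list(seq = decode_seq(codes),
       manifest = man_df(man),
       repeats = rep_df,
       genbank = genbank_record(chrom, len, genes$features),
       bed = bed)
}

man_row <- function(type, chrom, start, end, key) {
  list(type = type, chrom = chrom, start = as.integer(start),
       end = as.integer(end), key = key)
}

man_df <- function(man) {
  if (!length(man))
    return(data.frame(type = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      key = character(0), stringsAsFactors = FALSE))
  data.frame(type = vapply(man, `[[`, "", "type"),
             chrom = vapply(man, `[[`, "", "chrom"),
             start = vapply(man, `[[`, 0L, "start"),
             end = vapply(man, `[[`, 0L, "end"),
             key = vapply(man, `[[`, "", "key"),
             stringsAsFactors = FALSE)
}

# place non-overlapping genes of the three classes; returns GenBank feature
# text blocks and manifest rows
place_genes <- function(spec, chrom, len) {
  occupied_genes <- IRanges::IRanges()
  features <- character(0)
  man <- list()
  for (class in c("pc", "npc", "pseudo")) {
    lay <- spec$genes[[class]]
    if (is.null(lay) || lay$n == 0) next
    for (k in seq_len(lay$n)) {
      glen <- sample_range(lay$len)
      placed <- FALSE
      for (try in 1:30) {
        p <- sample.int(len - glen, 1L)
        cand <- IRanges::IRanges(p + 1L, p + glen)
        if (length(IRanges::findOverlaps(cand, occupied_genes))) next
        occupied_genes <- c(occupied_genes, cand)
        features <- c(features,
                      gene_feature_text(class, p, p + glen, lay))
        man[[length(man) + 1L]] <- man_row(paste0(class, "_gene"), chrom,
                                           p, p + glen, class)
        placed <- TRUE
        break
      }
      if (!placed)
        message("could not place ", class, " gene on ", chrom, "; skipped")
    }
  }
  list(features = features, manifest = man)
}

# GenBank feature text for one gene (1-based inclusive locations)
gene_feature_text <- function(class, start, end, lay) {
  loc <- function(s, e) paste0(s + 1L, "..", e)
  fmt <- function(key, location, quals = character(0)) {
    head <- sprintf("     %-16s%s", key, location)
    c(head, sprintf("                     %s", quals))
  }
  out <- fmt("gene", loc(start, end),
             if (class == "pseudo") c("/gene=\"synthetic\"", "/pseudo")
             else "/gene=\"synthetic\"")
  if (class == "pc") {
    n_ex <- sample_range(lay$exons)
    bounds <- sort(sample((start + 1L):(end - 1L), 2L * n_ex))
    ex_s <- bounds[seq(1, 2 * n_ex, 2)]
    ex_e <- bounds[seq(2, 2 * n_ex, 2)]
    join <- paste0("join(", paste(ex_s + 1L, ex_e, sep = "..",
                                  collapse = ","), ")")
    out <- c(out, fmt("mRNA", join), fmt("CDS", join))
  } else if (class == "npc") {
    pad <- max(1L, (end - start) %/% 10L)
    out <- c(out, fmt("ncRNA", loc(start + pad, end - pad)))
  } else {
    pad <- max(1L, (end - start) %/% 10L)
    out <- c(out, fmt("misc_RNA", loc(start + pad, end - pad), "/pseudo"))
  }
  paste(out, collapse = "\n")
}

genbank_record <- function(chrom, len, feature_blocks) {
  paste(c(
    sprintf("LOCUS       %s %d bp    DNA     linear   SYN", chrom, len),
    sprintf("DEFINITION  synthetic chromosome %s.", chrom),
    "FEATURES             Location/Qualifiers",
    sprintf("     %-16s%s", "source", paste0("1..", len)),
    feature_blocks,
    "//"), collapse = "\n")
}
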