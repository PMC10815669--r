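# End-to-end analysis: one fitting-style entry point returning a classed
# object, plus the file-writing orchestrator behind the command-line tool.

#' Fit the SSTR correlation landscape of a genome
#'
#' Runs the full analysis: read the inputs, scan every chromosome for
#' maximal SSTRs, derive gene categories and retrotransposon families,
#' build 100 kbp segment tracks (with centromere and sequencing-gap
#' exclusion), and correlate every (unit, length) SSTR density with G+C
#' content, gene-category coverage and retrotransposon count density per
#' chromosome and averaged.
#'
#' @param fasta path to the genome FASTA (required).
#' @param genbank path to a GenBank flat file with gene features, or NULL.
#' @param repeatmasker path to a RepeatMasker .out file, or NULL.
#' @param exclude_bed path to a BED3 of excluded regions (centromeres), or
#'   NULL; when NULL, GenBank `centromere` features are used as a fallback
#'   if present.
#' @param segment_size segment size in bp (default 100000).
#' @param gap_threshold gap-fraction exclusion threshold (default 0.01).
#' @return Object of class `sstr_landscape`: a list with `occurrences`
#'   (per chromosome), `tracks` (per chromosome), `correlations` (per
#'   chromosome), `averaged` (chromosome-averaged matrix), `retro`,
#'   `categories` and the call parameters.
#' @examples
#' \donttest{
#' spec <- synthetic_genome_spec(chromosomes = c(c1 = 6e5),
#'                               segment_size = 20000L, seed = 7)
#' files <- generate_genome(spec, tempfile("genome"))
#' fit <- sstr_landscape(files$fasta, files$genbank, files$repeatmasker,
#'                       files$bed, segment_size = 20000L)
#' summary(fit)
#' }
#' @export
sstr_landscape <- function(fasta, genbank = NULL, repeatmasker = NULL,
                           exclude_bed = NULL, segment_size = 100000L,
                           gap_threshold = 0.01) {
  seqs <- read_fasta(fasta)

  features <- if (!is.null(genbank)) read_genbank_features(genbank)$features
              else empty_annotation()
  retro_all <- if (!is.null(repeatmasker))
    classify_retrotransposons(read_repeatmasker(repeatmasker))
  else cbind(empty_repeat_annotation(), family_key = character(0))

  exclusions <- if (!is.null(exclude_bed)) read_exclusion_bed(exclude_bed)
  else {
    cen <- features[features$feature == "centromere", , drop = FALSE]
    cen[, c("chrom", "start", "end")]
  }

  occurrences <- list(); tracks <- list(); correlations <- list()
  categories <- list()
  for (chrom in names(seqs)) {
    occ <- scan_sstrs(seqs[[chrom]], chrom)
    cats <- derive_gene_categories(
      features[features$chrom == chrom, , drop = FALSE],
      nchar(seqs[[chrom]]))
    retro <- retro_all[retro_all$chrom == chrom, , drop = FALSE]
    excl <- exclusions[exclusions$chrom == chrom, , drop = FALSE]
    tr <- segment_tracks(seqs[[chrom]], chrom, occ, cats, retro, excl,
                         segment_size, gap_threshold)
    occurrences[[chrom]] <- occ
    categories[[chrom]] <- cats
    tracks[[chrom]] <- tr
    correlations[[chrom]] <- correlate_all(tr)
  }
  structure(list(
    occurrences = occurrences, tracks = tracks,
    correlations = correlations,
    averaged = average_over_chromosomes(correlations),
    categories = categories, retro = retro_all,
    segment_size = segment_size, gap_threshold = gap_threshold,
    fasta = fasta
  ), class = "sstr_landscape")
}

#' @export
print.sstr_landscape <- function(x, ...) {
  n_occ <- sum(vapply(x$occurrences, nrow, integer(1)))
  n_seg <- sum(vapply(x$tracks, function(t) nrow(t$segments), integer(1)))
  n_excl <- sum(vapply(x$tracks, function(t) sum(t$segments$excluded),
                       integer(1)))
  cat("SSTR correlation landscape\n")
  cat(sprintf("  chromosomes: %d (%s)\n", length(x$occurrences),
              paste(names(x$occurrences), collapse = ", ")))
  cat(sprintf("  maximal SSTR occurrences: %d\n", n_occ))
  cat(sprintf("  segments: %d of %d bp (%d excluded)\n", n_seg,
              x$segment_size, n_excl))
  cat(sprintf("  correlation matrix: %d SSTR keys x %d features\n",
              nrow(x$averaged), ncol(x$averaged)))
  invisible(x)
}

#' @method summary sstr_landscape
#' @export
summary.sstr_landscape <- function(object, ...) {
  print(object)
  grp <- group_of_keys(rownames(object$averaged))
  gm <- apply(object$averaged[, "gc", drop = FALSE], 2, function(col)
    tapply(col, grp, mean, na.rm = TRUE))
  cat("\nmean Pearson r with G+C by motif group:\n")
  for (g in levels(grp))
    cat(sprintf("  %s: %+.3f\n", g, gm[g, 1]))
  invisible(list(group_gc_means = gm))
}

#' @method plot sstr_landscape
#' @export
plot.sstr_landscape <- function(x, path = tempfile(fileext = ".png"),
                                features = NULL, ...) {
  m <- x$averaged
  if (!is.null(features)) m <- m[, features, drop = FALSE]
  plot_heatmap(m, path, main = "SSTR correlation (chromosome-averaged)")
  invisible(path)
}

#' Apply the retrotransposon-masking correction to a fitted landscape
#'
#' Recomputes the SSTR tracks with the SSTR content inside one family's
#' elements removed and the chromosome-average correction added, then
#' re-correlates. See [mask_family()].
#'
#' @param object `sstr_landscape` fit.
#' @param family one of SINE_Alu, SINE_MIR, LINE_L1, LINE_L2, LTR.
#' @param feature_keys feature columns for the before/after report.
#' @return List per chromosome of `before`/`after` matrices, plus averaged
#'   matrices under `before_avg` / `after_avg`.
#' @export
mask_landscape <- function(object, family = "SINE_Alu",
                           feature_keys = c("gc", RETRO_FAMILIES)) {
  stopifnot(inherits(object, "sstr_landscape"),
            family %in% RETRO_FAMILIES)
  out <- list()
  for (chrom in names(object$tracks)) {
    el <- object$retro[object$retro$chrom == chrom &
                         object$retro$family_key == family, , drop = FALSE]
    adj <- mask_family(object$occurrences[[chrom]], el,
                       object$tracks[[chrom]]$segments)
    out[[chrom]] <- masked_correlation_report(object$tracks[[chrom]], adj,
                                              feature_keys)
  }
  list(per_chromosome = out,
       before_avg = average_over_chromosomes(lapply(out, `[[`, "before")),
       after_avg = average_over_chromosomes(lapply(out, `[[`, "after")))
}

#' Markov-null significance for a fitted landscape
#'
#' Fits a first-order Markov model to every non-excluded segment, and runs
#' [markov_significance()] against the chosen feature track, per
#' chromosome.
#'
#' @param object `sstr_landscape` fit.
#' @param feature feature column to test against (default "gc").
#' @param M null realizations (default 100).
#' @param seed integer seed.
#' @param lengths repeat lengths tested (default 2:12).
#' @return Named list of per-chromosome significance tables.
#' @export
landscape_significance <- function(object, feature = "gc", M = 100L,
                                   seed = NULL, lengths = 2:12) {
  stopifnot(inherits(object, "sstr_landscape"))
  seqs <- read_fasta(object$fasta)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (chrom in names(object$tracks)) {
    tr <- object$tracks[[chrom]]
    keep <- !tr$segments$excluded
    if (sum(keep) < 2L) next
    segs <- tr$segments[keep, , drop = FALSE]
    codes <- encode_seq(seqs[[chrom]])
    models <- lapply(seq_len(nrow(segs)), function(i)
      fit_markov(codes[(segs$start[i] + 1L):segs$end[i]]))
    counts <- tr$values[keep, sstr_keys(lengths), drop = FALSE] *
      object$segment_size
    out[[chrom]] <- markov_significance(counts, segs$gc, models,
                                        object$segment_size, M = M,
                                        lengths = lengths)
  }
  out
}

#' Run the full analysis and write every stage's output
#'
#' Deterministic given the seed; writes TSV tracks, per-chromosome and
#' averaged correlation TSVs, heatmap PNGs, the masked before/after report
#' and the Markov-null significance table into `outdir`. Progress and
#' parameters are logged to standard error; nothing is printed to standard
#' output.
#'
#' @param config named list: `fasta` (required), `genbank`,
#'   `repeatmasker`, `exclude_bed`, `segment_size` (default 100000),
#'   `gap_threshold` (default 0.01), `mask_family` (optional family key),
#'   `null_realizations` (default 100; 0 disables the null), `seed`
#'   (default 1), `outdir` (required).
#' @return The output directory, invisibly.
#' @export
run_full_analysis <- function(config) {
  cfg <- function(key, default = NULL)
    if (!is.null(config[[key]])) config[[key]] else default
  fasta <- cfg("fasta"); outdir <- cfg("outdir")
  if (is.null(fasta) || is.null(outdir))
    stop("config must name 'fasta' and 'outdir'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg("seed", 1L)
  set.seed(seed)
  log_msg <- function(...) message("[sstrscape] ", ...)

  t0 <- proc.time()[3]
  log_msg("fitting landscape (segment size ",
          cfg("segment_size", 100000L), " bp, seed ", seed, ")")
  fit <- sstr_landscape(fasta, cfg("genbank"), cfg("repeatmasker"),
                        cfg("exclude_bed"),
                        segment_size = cfg("segment_size", 100000L),
                        gap_threshold = cfg("gap_threshold", 0.01))
  for (chrom in names(fit$tracks)) {
    write_tracks(fit$tracks[[chrom]],
                 file.path(outdir, paste0("tracks_", chrom, ".tsv")))
    if (!is.null(fit$correlations[[chrom]]))
      write_correlation(fit$correlations[[chrom]],
                        file.path(outdir, paste0("cor_", chrom, ".tsv")))
    write_occurrences(fit$occurrences[[chrom]],
                      file.path(outdir, paste0("sstr_", chrom, ".tsv")))
  }
  write_correlation(fit$averaged, file.path(outdir, "cor_averaged.tsv"))
  plot_heatmap(fit$averaged, file.path(outdir, "heatmap_averaged.png"))
  log_msg("landscape done in ", round(proc.time()[3] - t0, 1), " s")

  fam <- cfg("mask_family")
  if (!is.null(fam)) {
    t1 <- proc.time()[3]
    masked <- mask_landscape(fit, fam)
    write_correlation(masked$before_avg,
                      file.path(outdir, paste0("cor_", fam, "_before.tsv")))
    write_correlation(masked$after_avg,
                      file.path(outdir, paste0("cor_", fam, "_after.tsv")))
    plot_heatmap(masked$before_avg,
                 file.path(outdir, paste0("heatmap_", fam, "_before.png")),
                 main = paste("before masking", fam))
    plot_heatmap(masked$after_avg,
                 file.path(outdir, paste0("heatmap_", fam, "_after.png")),
                 main = paste("after masking", fam))
    log_msg("masking ", fam, " done in ",
            round(proc.time()[3] - t1, 1), " s")
  }

  M <- cfg("null_realizations", 100L)
  if (M >= 2) {
    t2 <- proc.time()[3]
    sig <- landscape_significance(fit, M = M, seed = seed)
    sig_df <- do.call(rbind, Map(function(ch, df)
      cbind(chrom = ch, df), names(sig), sig))
    utils::write.table(sig_df, file.path(outdir, "significance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("null model (M = ", M, ") done in ",
            round(proc.time()[3] - t2, 1), " s")
  }
  invisible(outdir)
}
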