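# Gene-category and retrotransposon-family interval sets.
#
# All coverage logic is strand-ignored: a position is genic if any gene
# annotation covers it on at least one strand. Interval arithmetic goes
# through IRanges; the 0-based half-open internal convention is converted at
# the IRanges boundary (start + 1).

#' The 11 gene-category track keys
#'
#' Genic/intergenic tile the chromosome; protein-coding (pc),
#' non-protein-coding (npc) and pseudogenes subdivide genic; each class
#' splits into exonic and intronic parts.
#' @export
GENE_CATEGORIES <- c("genic", "intergenic", "pc_gene", "npc_gene",
                     "pseudogene", "pc_exon", "pc_intron", "npc_exon",
                     "npc_intron", "pseudo_exon", "pseudo_intron")

#' The 5 retrotransposon family track keys
#'
#' Derived from RepeatMasker class/family columns: SINE/Alu, SINE/MIR,
#' LINE/L1, LINE/L2 and the LTR class as a whole.
#' @export
RETRO_FAMILIES <- c("SINE_Alu", "SINE_MIR", "LINE_L1", "LINE_L2", "LTR")

NPC_EXON_FEATURES <- c("ncRNA", "tRNA", "rRNA", "misc_RNA")

to_iranges <- function(start, end) IRanges::IRanges(start = start + 1L,
                                                    end = end)

from_iranges <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Derive the 11 gene-category interval sets for one chromosome
#'
#' Gene records are classed with precedence pseudogene > protein-coding (pc)
#' > non-protein-coding (npc): a gene is a pseudogene if it carries the
#' pseudo qualifier; otherwise protein-coding if any mRNA or CDS record
#' overlaps it; otherwise non-protein-coding (residual class). Exons are
#' defined per class as the union of the class's defining sub-features
#' clipped to the class's genes: mRNA/CDS intervals for pc, ncRNA/tRNA/rRNA/
#' misc_RNA for npc, and pseudo-qualified misc_RNA/exon records for
#' pseudogenes; introns are the gene regions not covered by the class's
#' exons. Genic is the strand-ignored union of all gene records and
#' intergenic its complement, so the two tile the chromosome exactly.
#'
#' @param records annotation data frame (see [read_genbank_features()]) for
#'   one chromosome.
#' @param chrom_length chromosome length in bp.
#' @return Named list of 11 data frames (`start`, `end`; merged, sorted,
#'   disjoint, 0-based half-open), one per category.
#' @export
derive_gene_categories <- function(records, chrom_length) {
  stopifnot(length(chrom_length) == 1L, chrom_length >= 0)
  if (nrow(records) && any(records$end > chrom_length | records$start < 0))
    stop("annotation interval outside [0, chrom_length)")
  if (nrow(records) && length(unique(records$chrom)) > 1L)
    stop("derive_gene_categories() expects records from one chromosome")

  whole <- to_iranges(0L, as.integer(chrom_length))
  sel <- function(df) to_iranges(df$start, df$end)

  genes <- records[records$feature == "gene", , drop = FALSE]
  mrna_cds <- records[records$feature %in% c("mRNA", "CDS"), , drop = FALSE]
  npc_feats <- records[records$feature %in% NPC_EXON_FEATURES, , drop = FALSE]
  pseudo_feats <- records[records$feature %in% c("misc_RNA", "exon") &
                            records$is_pseudo, , drop = FALSE]

  # classify gene records (by record_id: a joined gene keeps one class)
  gene_ids <- unique(genes$record_id)
  cls <- setNames(rep("npc", length(gene_ids)), gene_ids)
  if (nrow(genes) && nrow(mrna_cds)) {
    ov <- IRanges::findOverlaps(sel(genes), sel(mrna_cds))
    pc_ids <- unique(genes$record_id[S4Vectors::queryHits(ov)])
    cls[as.character(pc_ids)] <- "pc"
  }
  pseudo_ids <- unique(genes$record_id[genes$is_pseudo])
  cls[as.character(pseudo_ids)] <- "pseudo"   # pseudo > pc > npc

  gene_ir <- function(which_cls) {
    keep <- genes$record_id %in% gene_ids[cls == which_cls]
    IRanges::reduce(sel(genes[keep, , drop = FALSE]))
  }
  pc_g <- gene_ir("pc"); npc_g <- gene_ir("npc"); pseudo_g <- gene_ir("pseudo")

  cross <- sum(IRanges::width(IRanges::intersect(pc_g, pseudo_g))) +
    sum(IRanges::width(IRanges::intersect(pc_g, npc_g))) +
    sum(IRanges::width(IRanges::intersect(npc_g, pseudo_g)))
  if (cross > 0)
    message("gene classes overlap on ", cross,
            " bp; class coverages will not partition genic coverage")

  pc_exon <- IRanges::intersect(IRanges::reduce(sel(mrna_cds)), pc_g)
  npc_exon <- IRanges::intersect(IRanges::reduce(sel(npc_feats)), npc_g)
  pseudo_exon <- IRanges::intersect(IRanges::reduce(sel(pseudo_feats)),
                                    pseudo_g)

  genic <- IRanges::reduce(sel(genes))
  out <- list(
    genic = genic,
    intergenic = IRanges::setdiff(whole, genic),
    pc_gene = pc_g, npc_gene = npc_g, pseudogene = pseudo_g,
    pc_exon = pc_exon, pc_intron = IRanges::setdiff(pc_g, pc_exon),
    npc_exon = npc_exon, npc_intron = IRanges::setdiff(npc_g, npc_exon),
    pseudo_exon = pseudo_exon,
    pseudo_intron = IRanges::setdiff(pseudo_g, pseudo_exon)
  )
  lapply(out, from_iranges)
}

#' Classify RepeatMasker records into retrotransposon families
#'
#' Family keys are derived solely from the repeat class/family columns, with
#' prefix matching on the family (Alu matches AluY, AluSx, ...): SINE/Alu*
#' -> SINE_Alu, SINE/MIR* -> SINE_MIR, LINE/L1* -> LINE_L1, LINE/L2* ->
#' LINE_L2, and any LTR-class record -> LTR. Everything else (DNA
#' transposons, simple repeats, other LINE subfamilies, ...) is ignored.
#' Element identity is preserved: elements are not merged, so counts survive.
#'
#' @param repeats data frame from [read_repeatmasker()].
#' @return The subset of `repeats` that maps to a family, with an added
#'   `family_key` column (one of SINE_Alu, SINE_MIR, LINE_L1, LINE_L2, LTR).
#' @export
classify_retrotransposons <- function(repeats) {
  key <- rep(NA_character_, nrow(repeats))
  cl <- repeats$repeat_class
  fam <- repeats$repeat_family
  key[cl == "SINE" & startsWith(fam, "Alu")] <- "SINE_Alu"
  key[cl == "SINE" & startsWith(fam, "MIR")] <- "SINE_MIR"
  key[cl == "LINE" & startsWith(fam, "L1")] <- "LINE_L1"
  key[cl == "LINE" & startsWith(fam, "L2")] <- "LINE_L2"
  key[cl == "LTR"] <- "LTR"
  out <- repeats[!is.na(key), , drop = FALSE]
  out$family_key <- key[!is.na(key)]
  rownames(out) <- NULL
  out
}
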