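ann <- function(feature, start, end, is_pseudo = FALSE, id = NULL,
                chrom = "c1") {
  data.frame(chrom = chrom,
             record_id = if (is.null(id)) seq_along(start) else id,
             feature = feature, start = start, end = end, strand = "+",
             is_pseudo = is_pseudo, stringsAsFactors = FALSE)
}

test_that("a gene with a CDS becomes protein-coding with exons and introns", {
  recs <- rbind(ann("gene", 0L, 100L, id = 1L),
                ann("CDS", 10L, 40L, id = 2L))
  cats <- derive_gene_categories(recs, 200L)
  expect_equal(cats$pc_gene, data.frame(start = 0L, end = 100L),
               ignore_attr = TRUE)
  expect_equal(cats$pc_exon, data.frame(start = 10L, end = 40L),
               ignore_attr = TRUE)
  expect_equal(cats$pc_intron,
               data.frame(start = c(0L, 40L), end = c(10L, 100L)),
               ignore_attr = TRUE)
  expect_equal(cats$intergenic, data.frame(start = 100L, end = 200L),
               ignore_attr = TRUE)
  expect_equal(nrow(cats$npc_gene), 0L)
})

test_that("the pseudo qualifier wins over protein-coding evidence", {
  # same intervals, both record orders: a /pseudo gene containing a CDS is
  # a pseudogene, not a pc gene
  for (ord in list(1:2, 2:1)) {
    recs <- rbind(ann("gene", 0L, 100L, is_pseudo = TRUE, id = 1L),
                  ann("CDS", 10L, 40L, id = 2L))[ord, ]
    cats <- derive_gene_categories(recs, 200L)
    expect_equal(cats$pseudogene, data.frame(start = 0L, end = 100L),
                 ignore_attr = TRUE)
    expect_equal(nrow(cats$pc_gene), 0L)
  }
})

test_that("npc genes are the residual class with RNA-defined exons", {
  recs <- rbind(ann("gene", 0L, 50L, id = 1L),
                ann("ncRNA", 10L, 30L, id = 2L))
  cats <- derive_gene_categories(recs, 100L)
  expect_equal(cats$npc_gene, data.frame(start = 0L, end = 50L),
               ignore_attr = TRUE)
  expect_equal(cats$npc_exon, data.frame(start = 10L, end = 30L),
               ignore_attr = TRUE)
  expect_equal(cats$npc_intron,
               data.frame(start = c(0L, 30L), end = c(10L, 50L)),
               ignore_attr = TRUE)
})

test_that("pseudo exons require the pseudo qualifier on the sub-feature", {
  recs <- rbind(ann("gene", 0L, 60L, is_pseudo = TRUE, id = 1L),
                ann("misc_RNA", 5L, 25L, is_pseudo = TRUE, id = 2L),
                ann("misc_RNA", 30L, 40L, is_pseudo = FALSE, id = 3L))
  cats <- derive_gene_categories(recs, 100L)
  expect_equal(cats$pseudo_exon, data.frame(start = 5L, end = 25L),
               ignore_attr = TRUE)
})

test_that("an empty chromosome is entirely intergenic", {
  cats <- derive_gene_categories(empty_annotation_df(), 500L)
  expect_equal(nrow(cats$genic), 0L)
  expect_equal(cats$intergenic, data.frame(start = 0L, end = 500L),
               ignore_attr = TRUE)
})

test_that("genic and intergenic tile the chromosome on random fixtures", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(0:12, 1)
    len <- 10000L
    recs <- if (n > 0) {
      s <- sample.int(len - 200L, n)
      ann("gene", s, s + sample.int(200L, n),
          is_pseudo = sample(c(TRUE, FALSE), n, TRUE))
    } else empty_annotation_df()
    cats <- derive_gene_categories(recs, len)
    total <- function(df) sum(df$end - df$start)
    expect_equal(total(cats$genic) + total(cats$intergenic), len)
    # class coverages partition genic when classes do not overlap
    if (n > 0) {
      expect_equal(total(cats$pc_gene) + total(cats$npc_gene) +
                     total(cats$pseudogene) >= total(cats$genic), TRUE)
      # per-class exon + intron = class coverage
      for (cl in c("pc", "npc", "pseudo")) {
        g <- paste0(sub("pseudo", "pseudogene", paste0(cl, "_gene")))
        g <- if (cl == "pseudo") "pseudogene" else paste0(cl, "_gene")
        expect_equal(total(cats[[paste0(cl, "_exon")]]) +
                       total(cats[[paste0(cl, "_intron")]]),
                     total(cats[[g]]))
      }
    }
  }
})

test_that("interval beyond the chromosome is rejected", {
  expect_error(derive_gene_categories(ann("gene", 0L, 300L), 200L),
               "outside")
})

test_that("retrotransposon families follow the class/family rules", {
  rep_row <- function(class, family) {
    data.frame(chrom = "c1", start = 0L, end = 300L, strand = "+",
               repeat_name = "x", repeat_class = class,
               repeat_family = family, stringsAsFactors = FALSE)
  }
  cases <- list(
    list("SINE", "Alu", "SINE_Alu"),
    list("SINE", "AluY", "SINE_Alu"),     # prefix match on subfamily
    list("SINE", "MIR3", "SINE_MIR"),
    list("LINE", "L1", "LINE_L1"),
    list("LINE", "L2", "LINE_L2"),
    list("LTR", "ERVL", "LTR"),           # class-level rule
    list("LTR", "", "LTR"),
    list("LINE", "CR1", NA),              # other LINE families ignored
    list("DNA", "hAT", NA),
    list("Simple_repeat", "", NA))
  for (cs in cases) {
    out <- classify_retrotransposons(rep_row(cs[[1]], cs[[2]]))
    if (is.na(cs[[3]])) expect_equal(nrow(out), 0L)
    else expect_equal(out$family_key, cs[[3]])
  }
})

test_that("classification preserves element counts without merging", {
  n <- 10L
  df <- data.frame(chrom = "c1", start = rep(0L, n), end = rep(300L, n),
                   strand = "+", repeat_name = "AluSx",
                   repeat_class = "SINE", repeat_family = "Alu",
                   stringsAsFactors = FALSE)
  expect_equal(nrow(classify_retrotransposons(df)), n)
})
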