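test_that("FASTA reading normalizes case and keeps records distinct", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">c1 description", "ACGT"), f)
  s <- read_fasta(f)
  expect_equal(unname(s["c1"]), "ACGT")
  expect_equal(nchar(s[["c1"]]), 4L)

  writeLines(c(">c1", "acgt"), f)
  expect_equal(unname(read_fasta(f)), "ACGT")   # soft-mask uppercased

  writeLines(c(">c1", "ACGT", ">c2", "GGCC"), f)
  s <- read_fasta(f)
  expect_equal(names(s), c("c1", "c2"))
  expect_equal(unname(s), c("ACGT", "GGCC"))

  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty|malformed")
})

test_that("FASTA round trip preserves sequences", {
  f <- tempfile(fileext = ".fa")
  set.seed(5)
  seqs <- c(a = random_dna(500), b = random_dna(73))
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)
})

gb_fixture <- function(features) {
  c("LOCUS       tchr 1000 bp    DNA     linear   SYN",
    "DEFINITION  test record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     %-16s%s", "source", "1..1000"),
    features,
    "//")
}

test_that("GenBank locations convert to 0-based half-open intervals", {
  f <- tempfile(fileext = ".gbk")
  writeLines(gb_fixture(c(
    sprintf("     %-16s%s", "gene", "1..10"),
    sprintf("     %-16s%s", "gene", "complement(5..8)"),
    sprintf("     %-16s%s", "mRNA", "join(1..4,7..10)"))), f)
  res <- read_genbank_features(f)
  g <- res$features
  plain <- g[g$feature == "gene" & g$strand == "+", ]
  expect_equal(c(plain$start, plain$end), c(0L, 10L))
  comp <- g[g$strand == "-", ]
  expect_equal(c(comp$start, comp$end), c(4L, 8L))
  joined <- g[g$feature == "mRNA", ]
  expect_equal(joined$start, c(0L, 6L))
  expect_equal(joined$end, c(4L, 10L))
  expect_equal(length(unique(joined$record_id)), 1L)  # one record, 2 parts
})

test_that("the pseudo qualifier is picked up on genes", {
  f <- tempfile(fileext = ".gbk")
  writeLines(gb_fixture(c(
    sprintf("     %-16s%s", "gene", "1..10"),
    "                     /pseudo",
    sprintf("     %-16s%s", "gene", "21..30"),
    "                     /gene=\"x\"")), f)
  g <- read_genbank_features(f)$features
  genes <- g[g$feature == "gene", ]
  expect_equal(genes$is_pseudo[order(genes$start)], c(TRUE, FALSE))
})

test_that("an unparsable location skips the record with a warning", {
  f <- tempfile(fileext = ".gbk")
  writeLines(gb_fixture(c(
    sprintf("     %-16s%s", "gene", "bogus..location"),
    sprintf("     %-16s%s", "gene", "51..60"))), f)
  expect_warning(res <- read_genbank_features(f), "unparsable")
  expect_equal(nrow(res$features[res$features$feature == "gene", ]), 1L)
})

test_that("ORIGIN sequence is returned when present", {
  f <- tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       tchr 8 bp    DNA     linear   SYN",
               "FEATURES             Location/Qualifiers",
               sprintf("     %-16s%s", "source", "1..8"),
               "ORIGIN",
               "        1 acgtacgt",
               "//"), f)
  res <- read_genbank_features(f)
  expect_equal(unname(res$sequence["tchr"]), "ACGTACGT")
})

rm_line <- function(chrom, qbegin, qend, name, classfam) {
  sprintf("1000 10.0 1.0 1.0 %s %d %d (0) + %s %s 1 300 (0) 1",
          chrom, qbegin, qend, name, classfam)
}

rm_fixture <- function(lines) {
  c("   SW   perc perc perc  query   position in query   matching repeat",
    "score   div. del. ins.  sequence begin end (left) repeat class/family begin end (left) ID",
    "", lines)
}

test_that("RepeatMasker rows parse with coordinate conversion", {
  f <- tempfile(fileext = ".out")
  writeLines(rm_fixture(rm_line("c1", 101, 400, "AluY", "SINE/Alu")), f)
  r <- read_repeatmasker(f)
  expect_equal(r$start, 100L)
  expect_equal(r$end, 400L)
  expect_equal(r$repeat_class, "SINE")
  expect_equal(r$repeat_family, "Alu")

  writeLines(rm_fixture(rm_line("c1", 1, 50, "ERVL", "LTR")), f)
  r <- read_repeatmasker(f)
  expect_equal(r$repeat_class, "LTR")
  expect_equal(r$repeat_family, "")   # no slash, family empty

  writeLines(rm_fixture(character(0)), f)
  expect_equal(nrow(read_repeatmasker(f)), 0L)

  writeLines(c("h1", "h2"), f)
  expect_error(read_repeatmasker(f), "header")
  writeLines(rm_fixture("1000 10.0 1.0"), f)
  expect_error(read_repeatmasker(f), "column")
})

test_that("RepeatMasker round trip reproduces records exactly", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    starts <- sort(sample.int(100000, n))
    df <- data.frame(
      chrom = sample(c("c1", "c2"), n, replace = TRUE),
      start = starts, end = starts + sample.int(500, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      repeat_name = paste0("rep", seq_len(n)),
      repeat_class = sample(c("SINE", "LINE", "LTR", "DNA"), n, TRUE),
      repeat_family = sample(c("Alu", "L1", ""), n, TRUE),
      stringsAsFactors = FALSE)
    f <- tempfile(fileext = ".out")
    write_repeatmasker(df, f)
    back <- read_repeatmasker(f)
    expect_equal(back, df, ignore_attr = TRUE)
    expect_true(all(back$start >= 0 & back$start < back$end))
  }
})

test_that("BED exclusion files validate half-open intervals", {
  f <- tempfile(fileext = ".bed")
  writeLines("c1\t100\t200", f)
  b <- read_exclusion_bed(f)
  expect_equal(b, data.frame(chrom = "c1", start = 100L, end = 200L),
               ignore_attr = TRUE)
  writeLines(character(0), f)
  expect_equal(nrow(read_exclusion_bed(f)), 0L)
  writeLines("c1\t200\t100", f)
  expect_error(read_exclusion_bed(f), "start < end")
  writeLines("c1\t100\t100", f)
  expect_error(read_exclusion_bed(f), "start < end")
})

test_that("parsed intervals always satisfy the half-open invariant", {
  set.seed(11)
  for (i in 1:20) {
    f <- tempfile(fileext = ".gbk")
    n <- sample(1:6, 1)
    s <- sort(sample.int(900, n))
    writeLines(gb_fixture(
      sprintf("     %-16s%d..%d", "gene", s, s + sample.int(50, n))), f)
    g <- read_genbank_features(f)$features
    expect_true(all(g$start >= 0 & g$start < g$end & g$end <= 1000))
  }
})
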