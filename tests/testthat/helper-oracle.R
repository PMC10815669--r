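# Brute-force SSTR oracle: enumerate every interval of total length 2..12,
# test period-1 / period-2 consistency and maximality directly on the
# characters, and apply the unit rules (homopolymer intervals belong to the
# mononucleotide class; dinucleotide units are the run's first two bases).
# Deliberately quadratic and character-based, sharing no code with the
# package's run-length scanner.
oracle_scan <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  valid <- ch %in% c("A", "C", "G", "T")
  rows <- list()
  emit <- function(i, L, unit) {
    rows[[length(rows) + 1L]] <<- data.frame(
      start = i - 1L, length = L, unit = unit, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    for (L in 2:12) {
      j <- i + L - 1L
      if (j > n) break
      if (!all(valid[i:j])) next
      # period 1 (homopolymer)
      if (all(ch[i:j] == ch[i])) {
        left_break <- i == 1L || !valid[i - 1L] || ch[i - 1L] != ch[i]
        right_break <- j == n || !valid[j + 1L] || ch[j + 1L] != ch[i]
        if (left_break && right_break) emit(i, L, paste0(ch[i], ch[i]))
      }
      # period 2, first two bases differing
      if (ch[i] != ch[i + 1L] &&
          (L == 2L || all(ch[i:(j - 2L)] == ch[(i + 2L):j]))) {
        left_break <- i == 1L || !valid[i - 1L] || ch[i - 1L] != ch[i + 1L]
        right_break <- j == n || !valid[j + 1L] || ch[j + 1L] != ch[j - 1L]
        if (left_break && right_break) emit(i, L, paste0(ch[i], ch[i + 1L]))
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), length = integer(0),
                      unit = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, n_prob = 0.05) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), n_prob)), collapse = "")
}

# random row-stochastic Markov model (Dirichlet rows via gamma draws)
random_model <- function() {
  T <- matrix(stats::rgamma(16, shape = 2), 4, 4)
  T <- T / rowSums(T)
  pi <- stats::rgamma(4, shape = 2)
  pi <- pi / sum(pi)
  dimnames(T) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  names(pi) <- c("A", "C", "G", "T")
  structure(list(pi = pi, T = T), class = "markov_model")
}

iid_model <- function(p = rep(0.25, 4)) {
  T <- matrix(p, 4, 4, byrow = TRUE)
  dimnames(T) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  structure(list(pi = setNames(p, c("A", "C", "G", "T")), T = T),
            class = "markov_model")
}

# occurrence data frame without the chrom column, for comparisons
occ_core <- function(df) {
  out <- df[, c("start", "length", "unit")]
  rownames(out) <- NULL
  out
}

empty_annotation_df <- function() {
  data.frame(chrom = character(0), record_id = integer(0),
             feature = character(0), start = integer(0), end = integer(0),
             strand = character(0), is_pseudo = logical(0),
             stringsAsFactors = FALSE)
}

# memoized fixtures: one generation per (seed) per test run
.fixture_env <- new.env(parent = emptyenv())
small_files <- function(seed = 7) {
  key <- paste0("f", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_genome(small_spec(seed = seed),
                                           tempfile("fx"))
  .fixture_env[[key]]
}

# small synthetic genome spec used across tests (seconds-scale)
small_spec <- function(seed = 42, ...) {
  synthetic_genome_spec(
    chromosomes = c(cT1 = 1e6),
    segment_size = 50000L,
    genes = list(pc = list(n = 8, len = c(5000, 20000), exons = c(3, 5)),
                 npc = list(n = 5, len = c(1000, 5000)),
                 pseudo = list(n = 4, len = c(2000, 8000))),
    retro = list(
      SINE_Alu = list(n = 60, monomer = c(110, 150), linker = c(8, 12),
                      tail = c(8, 12), beta = 0.8),
      LINE_L1 = list(n = 20, len = c(500, 2000), beta = -0.5),
      LTR = list(n = 10, len = c(200, 800), beta = 0)),
    seed = seed, ...)
}
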