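# First-order Markov null model for SSTR content.
#
# Each segment gets its own model (initial distribution pi + 4x4 transition
# matrix), so the null preserves the G+C profile along the chromosome while
# destroying all repeat structure beyond nucleotide-neighbour statistics.
# Model-predicted repeat contents replace the empirical contents; the
# variance over Monte-Carlo realizations turns the difference between
# empirical and model correlations into a z-score.

#' Fit a first-order Markov model to a sequence segment
#'
#' Transition probabilities come from the observed counts of consecutive
#' ACGT pairs (a pair containing N or an ambiguity code is not counted) with
#' a pseudocount of 1 per transition cell, which keeps rows proper in short
#' or compositionally extreme segments. The initial distribution is the
#' mononucleotide frequency.
#'
#' @param seq character scalar (or integer base codes).
#' @return List of class `markov_model` with elements `pi` (length-4, names
#'   ACGT) and `T` (4x4 row-stochastic matrix).
#' @export
fit_markov <- function(seq) {
  codes <- if (is.integer(seq)) seq else encode_seq(seq)
  acgt <- tabulate(codes, nbins = 4L)
  if (sum(acgt) < 2L) stop("segment has fewer than 2 ACGT bases")
  pi <- acgt / sum(acgt)
  n <- length(codes)
  prev <- codes[-n]; nxt <- codes[-1]
  ok <- prev > 0L & nxt > 0L
  counts <- matrix(tabulate((prev[ok] - 1L) * 4L + nxt[ok], nbins = 16L),
                  nrow = 4L, byrow = TRUE)
  counts <- counts + 1  # pseudocount per cell
  T <- counts / rowSums(counts)
  dimnames(T) <- list(BASES, BASES)
  names(pi) <- BASES
  structure(list(pi = pi, T = T), class = "markov_model")
}

#' Expected number of maximal SSTR runs under a Markov model
#'
#' Closed-form expectation of the number of maximal runs of a given unit and
#' exact total length in a stationary length-`n` chain: each candidate start
#' position contributes P(breaking base before) x P(run bases via
#' transitions) x P(breaking base after), with the sequence ends acting as
#' automatic breaks. For a homodinucleotide unit XX the run factor is
#' `T[X,X]^(L-1)` and breaks require a non-X neighbour; for a mixed unit XY
#' the run factor alternates `T[X,Y]` and `T[Y,X]`, the left break requires
#' the preceding base to differ from the run's second base, and the right
#' break requires the following base to differ from the run's
#' second-to-last base. The marginal base distribution at position t is
#' `pi T^t`, computed exactly (with a convergence shortcut once the chain
#' has mixed), so the expectation is exact for any model, not only when
#' `pi` is stationary.
#'
#' @param model `markov_model` from [fit_markov()].
#' @param n sequence length in bp.
#' @param unit 2-character unit label.
#' @param length total run length, 2--12.
#' @return Expected count (numeric scalar).
#' @export
expected_sstr_counts <- function(model, n, unit, length) {
  L <- length
  if (L < 2 || L > 12) stop("length must be in 2..12")
  if (n < L) return(0)
  pi <- model$pi; T <- model$T
  b <- match(strsplit(unit, "")[[1]], BASES)
  if (length(b) != 2L || anyNA(b)) stop("invalid unit: ", unit)
  X <- b[1]; Y <- b[2]
  if (X == Y) {
    runp <- T[X, X]^(L - 1)
    b_left <- X          # preceding base must differ from X
    last <- X; b_right <- X
  } else {
    nXY <- ceiling((L - 1) / 2); nYX <- floor((L - 1) / 2)
    runp <- T[X, Y]^nXY * T[Y, X]^nYX
    b_left <- Y          # preceding base must differ from second base
    if (L %% 2 == 0) { last <- Y; b_right <- X } else { last <- X; b_right <- Y }
  }
  if (n == L) return(unname(pi[X] * runp))
  right_break <- 1 - T[last, b_right]
  # marginal sums: S = sum_{t=0}^{n-L-2} (pi T^t), m_last = pi T^{n-L-1}
  ms <- marginal_sums(pi, T, n - L - 1L)
  g_sum <- sum(ms$S[-b_left] * T[-b_left, X])     # left breaks, interior
  g_last <- sum(ms$m_last[-b_left] * T[-b_left, X])  # run ends flush right
  unname(runp * (pi[X] * right_break +            # run starts at position 0
                 g_sum * right_break +
                 g_last))
}

# sum of the chain's marginal distributions pi T^t over t = 0..k-1, plus
# the marginal at t = k; iterates with a shortcut once the chain has mixed
marginal_sums <- function(pi, T, k) {
  m <- as.numeric(pi); S <- numeric(4); t <- 0L
  while (t < k) {
    m_next <- as.numeric(m %*% T)
    if (max(abs(m_next - m)) < 1e-14) {
      return(list(S = S + m * (k - t), m_last = m))
    }
    S <- S + m
    m <- m_next
    t <- t + 1L
  }
  list(S = S, m_last = m)
}

#' Simulate a sequence from a Markov model
#'
#' First base from `pi`, each next base from the transition row of the
#' current base. Uses R's RNG; pass `seed` (or call [set.seed()] first) for
#' reproducibility.
#'
#' @param model `markov_model` from [fit_markov()].
#' @param n sequence length (>= 1).
#' @param seed optional integer seed.
#' @return Character scalar of length `n` over ACGT.
#' @export
simulate_sequence <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  decode_seq(.simulate_markov_cpp(as.integer(n), unname(model$pi),
                                  unname(model$T)))
}

# per-(unit,length)-key counts of one sequence, in sstr_keys() order
count_keys <- function(codes, lengths = 2:12) {
  keys <- sstr_keys(lengths)
  m <- mono_runs(codes); d <- di_runs(codes)
  key <- paste(c(m$unit, d$unit), c(m$length, d$length), sep = ".")
  tab <- table(factor(key, levels = keys))
  as.numeric(tab)
}

#' Significance of empirical correlations against the Markov null
#'
#' For each of `M` realizations, every segment is re-simulated from its own
#' fitted model, scanned for SSTRs, and the resulting per-segment count
#' tracks are correlated against the fixed feature track. The z-score is
#' `(r_emp - mean(r_model)) / sd(r_model)` per SSTR key, with the standard
#' deviation always taken over the Monte-Carlo realizations. With
#' `analytic_mean = TRUE`, `r_model_mean` is instead computed from the
#' closed-form expected counts of [expected_sstr_counts()].
#'
#' @param emp_counts numeric matrix of empirical per-segment counts (or
#'   densities; Pearson r is scale-invariant), rows = segments, columns =
#'   [sstr_keys()].
#' @param feature numeric feature track (one value per segment), held fixed
#'   across realizations.
#' @param models list of `markov_model`s, one per segment.
#' @param segment_size simulated segment length in bp.
#' @param M number of null realizations (default 100; >= 2).
#' @param seed optional integer seed.
#' @param lengths repeat lengths tracked (default 2:12).
#' @param analytic_mean use analytic expected counts for the null mean
#'   (Monte-Carlo still provides the variance).
#' @return Data frame with columns `sstr_key`, `r_emp`, `r_model_mean`,
#'   `r_model_sd`, `z`, `n_realizations`, `significant` (two-sided |z| >= 3;
#'   `NA` where the null sd is zero or r is undefined).
#' @export
markov_significance <- function(emp_counts, feature, models, segment_size,
                                M = 100L, seed = NULL, lengths = 2:12,
                                analytic_mean = FALSE) {
  if (M < 2L) stop("need at least 2 null realizations")
  if (M < 10L) warning("only ", M, " null realizations; ",
                       "variance estimate will be unstable")
  n_seg <- length(models)
  stopifnot(nrow(emp_counts) == n_seg, length(feature) == n_seg)
  if (!is.null(seed)) set.seed(seed)
  keys <- sstr_keys(lengths)

  r_of <- function(counts) {
    apply(counts, 2, function(x) pearson(x, feature))
  }
  r_emp <- r_of(emp_counts[, keys, drop = FALSE])

  r_model <- matrix(NA_real_, M, length(keys), dimnames = list(NULL, keys))
  for (m in seq_len(M)) {
    counts <- matrix(0, n_seg, length(keys))
    for (i in seq_len(n_seg)) {
      sim <- .simulate_markov_cpp(as.integer(segment_size),
                                  unname(models[[i]]$pi),
                                  unname(models[[i]]$T))
      counts[i, ] <- count_keys(sim, lengths)
    }
    r_model[m, ] <- r_of(counts)
  }
  r_mean <- colMeans(r_model)
  r_sd <- apply(r_model, 2, stats::sd)
  if (analytic_mean) {
    exp_counts <- matrix(0, n_seg, length(keys))
    ul <- strsplit(keys, ".", fixed = TRUE)
    for (i in seq_len(n_seg))
      exp_counts[i, ] <- vapply(ul, function(p)
        expected_sstr_counts(models[[i]], segment_size, p[1],
                             as.integer(p[2])), numeric(1))
    r_mean <- r_of(exp_counts)
  }
  z <- ifelse(!is.na(r_sd) & r_sd > 0, (r_emp - r_mean) / r_sd, NA_real_)
  data.frame(sstr_key = keys, r_emp = r_emp, r_model_mean = r_mean,
             r_model_sd = r_sd, z = z, n_realizations = M,
             significant = !is.na(z) & abs(z) >= 3,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.markov_model <- function(x, ...) {
  cat("First-order Markov model\n")
  cat("pi:", paste(sprintf("%s=%.3f", BASES, x$pi), collapse = " "), "\n")
  cat("transition matrix:\n")
  print(round(x$T, 3))
  invisible(x)
}
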