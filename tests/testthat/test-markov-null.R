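test_that("transition fitting reflects observed pairs with pseudocounts", {
  # deterministic alternating chain drives the two transitions to ~1
  m <- fit_markov(strrep("AC", 5000))
  expect_gt(m$T["A", "C"], 0.999)
  expect_gt(m$T["C", "A"], 0.999)
  expect_equal(unname(m$pi[c("A", "C")]), c(0.5, 0.5))
  expect_equal(rowSums(m$T), rep(1, 4), ignore_attr = TRUE)

  # N breaks pairs: "AANCC" counts only AA and CC
  m2 <- fit_markov("AANCC")
  # row A: counts (1+1, 1, 1, 1) -> T[A][A] = 2/5
  expect_equal(unname(m2$T["A", "A"]), 2 / 5)
  expect_equal(unname(m2$T["C", "C"]), 2 / 5)
  expect_equal(unname(m2$T["A", "C"]), 1 / 5)

  expect_error(fit_markov("AN"), "fewer than 2")
})

test_that("a uniform sequence fits a near-uniform model", {
  set.seed(61)
  s <- simulate_sequence(iid_model(), 1e5)
  m <- fit_markov(s)
  # binomial standard error for p = 0.25 over ~n/4 transitions per row
  se <- sqrt(0.25 * 0.75 / (1e5 / 4))
  expect_true(all(abs(m$T - 0.25) < 3.5 * se))
  expect_true(all(abs(m$pi - 0.25) < 3.5 * sqrt(0.25 * 0.75 / 1e5)))
})

test_that("expected counts match the closed-form i.i.d. value", {
  # i.i.d. uniform: per-interior-position probability of a maximal (AA, 2)
  # run = 0.75 * 0.25 * 0.25 * 0.75
  model <- iid_model()
  n <- 10002
  per_pos <- 0.75 * 0.25^2 * 0.75
  interior <- (n - 2 - 1) * per_pos
  boundary <- 2 * (0.25^2 * 0.75)
  expect_equal(expected_sstr_counts(model, n, "AA", 2),
               interior + boundary, tolerance = 1e-12)
  expect_equal(expected_sstr_counts(model, 4, "AA", 5), 0)  # n < L
  expect_error(expected_sstr_counts(model, 100, "AA", 13), "2..12")
})

test_that("an impossible transition gives zero expected runs", {
  T <- matrix(1 / 3, 4, 4); diag(T) <- 0
  dimnames(T) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  model <- structure(list(pi = setNames(rep(.25, 4), c("A", "C", "G", "T")),
                          T = T), class = "markov_model")
  for (L in 2:6) expect_equal(expected_sstr_counts(model, 1000, "AA", L), 0)
  expect_gt(expected_sstr_counts(model, 1000, "AG", 4), 0)
})

test_that("expected counts agree with simulation for random models", {
  set.seed(62)
  n <- 2000; reps <- 150
  for (k in 1:3) {
    model <- random_model()
    sims <- replicate(reps,
      sstrscape:::count_keys(
        sstrscape:::.simulate_markov_cpp(n, unname(model$pi),
                                         unname(model$T)), 2:4))
    keys <- sstr_keys(2:4)
    expected <- vapply(strsplit(keys, ".", fixed = TRUE), function(p)
      expected_sstr_counts(model, n, p[1], as.integer(p[2])), numeric(1))
    obs_mean <- rowMeans(sims)
    # Poisson floor keeps the SE meaningful for cells with near-zero rates
    se <- pmax(apply(sims, 1, sd), sqrt(expected)) / sqrt(reps)
    z <- (obs_mean - expected) / pmax(se, 1e-9)
    expect_true(mean(abs(z) < 3) >= 0.97,
                info = paste("model", k, "max |z| =", round(max(abs(z)), 2)))
    expect_true(all(abs(z) < 5))
  }
})

test_that("simulation is seed-reproducible and respects the model", {
  model <- random_model()
  expect_equal(simulate_sequence(model, 500, seed = 7),
               simulate_sequence(model, 500, seed = 7))
  # deterministic alternating model produces the exact alternating sequence
  T <- matrix(0, 4, 4); T[1, 2] <- 1; T[2, 1] <- 1; T[3, 1] <- 1; T[4, 1] <- 1
  det <- structure(list(pi = c(A = 1, C = 0, G = 0, T = 0), T = T),
                   class = "markov_model")
  expect_equal(simulate_sequence(det, 8, seed = 1), "ACACACAC")
  # dinucleotide frequencies approach pi * T
  set.seed(63)
  model <- iid_model(c(0.4, 0.1, 0.1, 0.4))
  s <- simulate_sequence(model, 2e5)
  m <- fit_markov(s)
  expect_true(all(abs(m$T - matrix(model$pi, 4, 4, byrow = TRUE)) < 0.01))
})

test_that("planted enrichment beyond the null yields extreme z-scores", {
  set.seed(64)
  n_seg <- 60; seg_len <- 4000
  gc <- seq(0.35, 0.55, length.out = n_seg)
  models <- lapply(gc, function(g)
    iid_model(c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)))
  emp <- t(vapply(seq_len(n_seg), function(i)
    sstrscape:::count_keys(
      sstrscape:::.simulate_markov_cpp(seg_len, unname(models[[i]]$pi),
                                       unname(models[[i]]$T)), 2:4),
    numeric(length(sstr_keys(2:4)))))
  colnames(emp) <- sstr_keys(2:4)
  # plant extra (CC,3) counts strongly coupled to gc, beyond composition
  emp[, "CC.3"] <- emp[, "CC.3"] + round(200 * (gc - 0.35))
  sig <- markov_significance(emp, gc, models, seg_len, M = 40, seed = 65,
                             lengths = 2:4)
  expect_gt(sig$z[sig$sstr_key == "CC.3"], 3)
  expect_true(sig$significant[sig$sstr_key == "CC.3"])
  # untouched keys stay mostly unflagged
  expect_lt(mean(sig$significant[sig$sstr_key != "CC.3"], na.rm = TRUE),
            0.2)
})

test_that("low replicate counts warn and zero-sd cells give missing z", {
  set.seed(66)
  models <- replicate(10, iid_model(), simplify = FALSE)
  emp <- matrix(5, 10, length(sstr_keys(2:3)),
                dimnames = list(NULL, sstr_keys(2:3)))
  expect_warning(
    sig <- markov_significance(emp, runif(10), models, 500, M = 2,
                               seed = 67, lengths = 2:3),
    "realizations")
  expect_error(markov_significance(emp, runif(10), models, 500, M = 1),
               "at least 2")
  # constant empirical track: r_emp undefined -> z missing
  expect_true(all(is.na(sig$z) | is.finite(sig$z)))
})

test_that("analytic null mean agrees with the Monte-Carlo mean", {
  set.seed(68)
  n_seg <- 40; seg_len <- 3000
  gc <- seq(0.3, 0.6, length.out = n_seg)
  models <- lapply(gc, function(g)
    iid_model(c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)))
  emp <- t(vapply(models, function(m)
    sstrscape:::count_keys(
      sstrscape:::.simulate_markov_cpp(seg_len, unname(m$pi), unname(m$T)),
      2:3),
    numeric(length(sstr_keys(2:3)))))
  colnames(emp) <- sstr_keys(2:3)
  mc <- markov_significance(emp, gc, models, seg_len, M = 60, seed = 69,
                            lengths = 2:3)
  an <- markov_significance(emp, gc, models, seg_len, M = 60, seed = 69,
                            lengths = 2:3, analytic_mean = TRUE)
  ok <- !is.na(mc$r_model_mean) & !is.na(an$r_model_mean)
  expect_gt(stats::cor(mc$r_model_mean[ok], an$r_model_mean[ok]), 0.98)
})
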