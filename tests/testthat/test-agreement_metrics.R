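test_that("hand-computed metric values on the (1,1,0,8) table", {
  ref <- c(TRUE, rep(FALSE, 9))
  cod <- c(TRUE, TRUE, rep(FALSE, 8))
  r <- matrix_from_vectors("ref", ref, 10, 1)
  m <- matrix_from_vectors("cod", cod, 10, 1)
  cc <- confusion_counts(r, m)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 0, tn = 8))
  expect_equal(percent_agreement(cc), 0.9)
  expect_equal(cohen_kappa(cc), 0.16 / 0.26, tolerance = 1e-12)
  expect_equal(gwet_ac1(cc), 0.645 / 0.745, tolerance = 1e-12)
  expect_equal(jaccard(cc), 0.5)
  expect_equal(f1_score(cc), 2 / 3, tolerance = 1e-12)
  expect_equal(sensitivity(cc), 1)
  expect_equal(specificity(cc), 8 / 9, tolerance = 1e-12)
})

test_that("identity and complement coders hit the degenerate corners", {
  set.seed(1)
  cells <- runif(40) < 0.3
  r <- matrix_from_vectors("ref", cells, 20, 2)
  same <- matrix_from_vectors("same", cells, 20, 2)
  opp <- matrix_from_vectors("opp", !cells, 20, 2)
  cc_same <- confusion_counts(r, same)
  expect_equal(cc_same$fp + cc_same$fn, 0)
  expect_equal(cohen_kappa(cc_same), 1)
  expect_equal(gwet_ac1(cc_same), 1)
  cc_opp <- confusion_counts(r, opp)
  expect_equal(cc_opp$tp + cc_opp$tn, 0)
  expect_equal(percent_agreement(cc_opp), 0)
})

test_that("kappa and AC1 match the first-principles oracle on every 2x2 table with n <= 6", {
  for (tab in all_tables_up_to(6)) {
    cc <- confusion(tab$tp, tab$fp, tab$fn, tab$tn)
    k_pkg <- cohen_kappa(cc)
    k_orc <- kappa_oracle(tab$ref, tab$cod)
    if (is.na(k_orc)) expect_true(is.na(k_pkg)) else
      expect_equal(as.numeric(k_pkg), k_orc, tolerance = 1e-12)
    expect_equal(as.numeric(gwet_ac1(cc)), ac1_oracle(tab$ref, tab$cod),
                 tolerance = 1e-12)
  }
})

test_that("jaccard = f1 / (2 - f1) wherever both are defined", {
  set.seed(7)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(5:200, 1), runif(4)))
    cc <- confusion(cells[1], cells[2], cells[3], cells[4])
    j <- jaccard(cc); f <- f1_score(cc)
    if (!is.na(j) && !is.na(f))
      expect_equal(as.numeric(j), as.numeric(f) / (2 - as.numeric(f)),
                   tolerance = 1e-12)
  }
})

test_that("AC1 dominates kappa in the low-prevalence simulated regime", {
  # with both positive rates below one half the AC1 chance term is below
  # the kappa chance term, so AC1 >= kappa; the synthetic defaults
  # (prevalence ~ 0.078) sit deep inside that regime
  checked <- 0L
  for (seed in 1:20) {
    spec <- deductive_sim_spec(seed = seed)
    ref <- generate_reference(spec)
    cod <- simulate_coder(ref, 0.30, 0.98, seed + 1000)
    cc <- confusion_counts(ref, cod)
    p <- codagree:::marginals(cc)
    if (max(p) <= 0.5 && !is.na(cohen_kappa(cc))) {
      expect_gte(gwet_ac1(cc), as.numeric(cohen_kappa(cc)))
      checked <- checked + 1L
    }
  }
  expect_equal(checked, 20L)  # the regime holds in every seeded batch
})

test_that("population plug-in reproduces the kappa attenuation at the LLM operating point", {
  pop <- population_metrics(0.30, 0.98, 0.078)
  expect_equal(round(pop[["kappa"]], 3), 0.355)
  expect_equal(round(pop[["ac1"]], 3), 0.918)
  expect_gt(pop[["ac1"]] - pop[["kappa"]], 0.5)
})

test_that("per-code kappa separates identical, independent and degenerate codes", {
  set.seed(11)
  n <- 400
  a <- runif(n) < 0.3
  b_ref <- runif(n) < 0.3
  b_cod <- runif(n) < 0.3  # independent of b_ref
  ref <- matrix_from_vectors("ref", c(a, b_ref), n, 2)
  cod <- matrix_from_vectors("cod", c(a, b_cod), n, 2)
  k <- per_code_kappa(ref, cod)
  expect_equal(unname(k["C01"]), 1)
  expect_lt(abs(k[["C02"]]), 0.12)

  zero <- matrix_from_vectors("z", rep(FALSE, n), n, 1)
  expect_true(is.na(per_code_kappa(zero, zero)[["C01"]]))
  expect_equal(unname(per_code_kappa(ref, ref)), c(1, 1))
})

test_that("all metrics are invariant to segment order", {
  set.seed(3)
  spec <- deductive_sim_spec(n_segments = 50, seed = 3)
  ref <- generate_reference(spec)
  cod <- simulate_coder(ref, 0.4, 0.95, 99)
  base <- agreement_metrics(ref, cod)
  perm <- sample(nrow(ref$labels))
  ref_p <- coding_matrix("reference", ref$labels[perm, ])
  cod_p <- coding_matrix(cod$coder_id, cod$labels[perm, ])
  expect_equal(agreement_metrics(ref_p, cod_p), base, tolerance = 1e-12)
})

test_that("universe mismatch is reported with the disjoint ids", {
  a <- matrix_from_vectors("a", rep(FALSE, 4), 2, 2)
  b <- coding_matrix("b", matrix(FALSE, 2, 2,
                                 dimnames = list(c("S001", "S999"),
                                                 c("C01", "C02"))))
  expect_error(confusion_counts(a, b), "S999")
})

test_that("bootstrap CI is deterministic under seed and degenerate at zero variance", {
  set.seed(5)
  spec <- deductive_sim_spec(n_segments = 60, seed = 5)
  ref <- generate_reference(spec)
  cod <- simulate_coder(ref, 0.4, 0.95, 55)
  a <- bootstrap_ci(gwet_ac1, ref, cod, B = 300, seed = 17)
  b <- bootstrap_ci(gwet_ac1, ref, cod, B = 300, seed = 17)
  expect_identical(a, b)
  expect_true(a$ci_low <= a$point && a$point <= a$ci_high)

  ident <- bootstrap_ci(percent_agreement, ref, ref, B = 100, seed = 1)
  expect_equal(ident$ci_low, 1)
  expect_equal(ident$ci_high, 1)
  expect_equal(ident$point, 1)
})

test_that("an identity (full-weight) resample reproduces the point estimate", {
  set.seed(9)
  spec <- deductive_sim_spec(n_segments = 40, seed = 9)
  ref <- generate_reference(spec)
  cod <- simulate_coder(ref, 0.35, 0.96, 77)
  sc <- segment_confusion(ref, cod)
  idx <- matrix(seq_len(nrow(sc)), ncol = 1)
  rep1 <- codagree:::bootstrap_metric_reps(gwet_ac1, sc, idx)
  expect_equal(rep1, as.numeric(gwet_ac1(confusion_counts(ref, cod))),
               tolerance = 1e-12)
})

test_that("mostly-degenerate resamples fail with a diagnostic", {
  # all-false reference and coder: kappa undefined in every replicate
  r <- matrix_from_vectors("ref", rep(FALSE, 20), 10, 2)
  expect_error(bootstrap_ci(cohen_kappa, r, r, B = 20, seed = 1),
               "undefined")
})

test_that("group-mean bootstrap averages coders on a shared resample", {
  set.seed(21)
  spec <- deductive_sim_spec(n_segments = 60, seed = 21)
  ref <- generate_reference(spec)
  c1 <- simulate_coder(ref, 0.4, 0.95, 31, "c1")
  c2 <- simulate_coder(ref, 0.3, 0.97, 32, "c2")
  res <- bootstrap_mean_ci(gwet_ac1, ref, list(c1, c2), B = 200, seed = 8)
  pt <- mean(c(agreement_metrics(ref, c1)[["ac1"]],
               agreement_metrics(ref, c2)[["ac1"]]))
  expect_equal(res$point, pt, tolerance = 1e-12)
  expect_true(res$ci_low <= res$point && res$point <= res$ci_high)
})
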