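test_that("holm_adjust reproduces the step-down rule by hand", {
  p <- c(0.0143, 0.0877, 0.20)
  adj <- holm_adjust(p)
  expect_equal(round(adj[1], 3), 0.043)
  expect_equal(adj, c(3 * 0.0143, 2 * 0.0877, 0.20), tolerance = 1e-12)
  expect_equal(holm_adjust(1), 1)
  # permutation invariance and elementwise dominance
  set.seed(4)
  q <- runif(8)
  perm <- sample(8)
  expect_equal(holm_adjust(q)[perm], holm_adjust(q[perm]))
  expect_true(all(holm_adjust(q) >= q))
})

test_that("likert_mean_ci reproduces the study column means and 95% CIs", {
  lt <- read_likert_table(study_likert_path())
  expected <- list(
    human_analyst_1 = c(3.643, 3.157, 4.129),
    human_analyst_2 = c(4.071, 3.542, 4.601),
    chatgpt_5       = c(4.071, 3.593, 4.550),
    claude_4_sonnet = c(3.643, 2.941, 4.345),
    qualigpt        = c(3.929, 3.232, 4.625))
  for (col in names(expected))
    expect_equal(round(unname(likert_mean_ci(lt$scores[, col])), 3),
                 expected[[col]], tolerance = 1e-8)
  expect_equal(unname(likert_mean_ci(rep(4, 6))), c(4, 4, 4))
  expect_error(likert_mean_ci(numeric(0)), "no scores")
  expect_equal(unname(likert_mean_ci(5)), c(5, 5, 5))
})

test_that("inductive non-inferiority singles out one model at the 0.5 margin", {
  lt <- read_likert_table(study_likert_path())
  res <- inductive_noninferiority(
    lt, c("chatgpt_5", "claude_4_sonnet", "qualigpt"),
    c("human_analyst_1", "human_analyst_2"), margin = 0.5)
  gpt <- res[res$model_id == "chatgpt_5", ]
  expect_equal(gpt$effect, 3 / 14, tolerance = 1e-12)
  expect_equal(gpt$t_noninferior, 2.459, tolerance = 1e-3)
  expect_equal(gpt$p_raw_noninferior, 0.0143, tolerance = 1e-2)
  expect_equal(round(gpt$p_holm_noninferior, 3), 0.043)
  expect_true(gpt$verdict_noninferior)
  others <- res[res$model_id != "chatgpt_5", ]
  expect_true(all(others$p_holm_noninferior > 0.05))
  expect_false(any(others$verdict_noninferior))
})

test_that("adding the margin to every model score turns non-inferiority into superiority", {
  sc <- matrix(c(4L, 3L, 2L, 4L, 3L, 5L,      # human
                 3L, 2L, 3L, 4L, 2L, 3L),     # model (headroom for +1)
               ncol = 2, dimnames = list(paste0("c", 1:6), c("h", "m")))
  lt <- likert_table(sc)
  sc2 <- sc; sc2[, "m"] <- sc2[, "m"] + 1L
  lt2 <- likert_table(sc2)
  ni <- inductive_noninferiority(lt, "m", "h", margin = 1)
  sup <- inductive_noninferiority(lt2, "m", "h", margin = 1)
  expect_equal(ni$p_raw_noninferior, sup$p_raw_superior, tolerance = 1e-12)
})

test_that("a model equal to the human mean everywhere has p below one half", {
  # human mean is 3 per code; model matches it on average with spread
  sc <- matrix(c(2L, 4L, 2L, 4L,   # h1
                 4L, 2L, 4L, 2L,   # h2
                 2L, 4L, 3L, 3L),  # m: d = (-1, 1, 0, 0)
               ncol = 3, dimnames = list(paste0("c", 1:4), c("h1", "h2", "m")))
  lt <- likert_table(sc)
  res <- inductive_noninferiority(lt, "m", c("h1", "h2"), margin = 0.5)
  expect_equal(res$effect, 0)
  expect_lt(res$p_raw_noninferior, 0.5)
  expect_gt(res$p_raw_noninferior, 0)
})

test_that("zero-variance differences are flagged degenerate with one-sided p 0 or 1", {
  sc <- matrix(c(3L, 3L, 3L, 4L, 4L, 4L), ncol = 2,
               dimnames = list(paste0("c", 1:3), c("h", "m")))
  res <- inductive_noninferiority(likert_table(sc), "m", "h", margin = 0.5)
  expect_true(res$degenerate)
  expect_equal(res$p_raw_noninferior, 0)  # dbar = +1 > -margin
  sc[, "m"] <- c(1L, 1L, 1L)              # dbar = -2 <= -margin
  res2 <- inductive_noninferiority(likert_table(sc), "m", "h", margin = 0.5)
  expect_equal(res2$p_raw_noninferior, 1)
})

test_that("inductive type-I error sits near alpha at the margin boundary", {
  set.seed(2026)
  n <- 14; margin <- 0.5; alpha <- 0.05
  rejections <- vapply(seq_len(2000), function(i) {
    d <- rnorm(n, mean = -margin, sd = 0.9)
    codagree:::likert_shift_test(d, margin)$p < alpha
  }, logical(1))
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("a model identical to the reference and single human is trivially non-inferior", {
  spec <- deductive_sim_spec(n_segments = 40, seed = 12)
  ref <- generate_reference(spec)
  res <- deductive_noninferiority(list(m = ref), list(ref), ref,
                                  margin = 0.03, B = 200, seed = 3)
  expect_equal(res$effect, 0)
  expect_equal(res$p_raw_noninferior, 1 / 201)  # add-one rule floor
  expect_true(res$verdict_noninferior)
})

test_that("deductive bootstrap p-values are deterministic under seed and monotone in the margin", {
  spec <- deductive_sim_spec(seed = 31)
  ref <- generate_reference(spec)
  h1 <- simulate_coder(ref, 0.34, 0.97, 41, "h1")
  h2 <- simulate_coder(ref, 0.34, 0.97, 42, "h2")
  m1 <- simulate_coder(ref, 0.30, 0.98, 43, "m1")
  run <- function(margin) deductive_noninferiority(
    list(m1 = m1), list(h1, h2), ref, margin = margin, B = 300, seed = 9)
  a <- run(0.03); b <- run(0.03)
  expect_identical(a, b)
  p_by_margin <- vapply(c(0.01, 0.03, 0.06),
                        function(d) run(d)$p_raw_noninferior, numeric(1))
  expect_true(all(diff(p_by_margin) <= 0))
  expect_error(deductive_noninferiority(list(m1 = m1), list(), ref),
               "human")
})

test_that("with humans = {reference} the effect is AC1(model) - 1, never positive", {
  spec <- deductive_sim_spec(n_segments = 60, seed = 77)
  ref <- generate_reference(spec)
  m1 <- simulate_coder(ref, 0.5, 0.95, 78, "m1")
  res <- deductive_noninferiority(list(m1 = m1), list(ref), ref,
                                  B = 100, seed = 2)
  ac1 <- agreement_metrics(ref, m1)[["ac1"]]
  expect_equal(res$effect, ac1 - 1, tolerance = 1e-12)
  expect_lte(res$effect, 0)
})

test_that("deductive non-inferiority holds at the study operating points", {
  # humans (0.34, 0.97), model (0.30, 0.98): population AC1 difference ~ +0.01
  hits <- 0L
  for (seed in 1:10) {
    spec <- deductive_sim_spec(seed = seed)
    ref <- generate_reference(spec)
    h1 <- simulate_coder(ref, 0.34, 0.97, seed * 10 + 1, "h1")
    h2 <- simulate_coder(ref, 0.34, 0.97, seed * 10 + 2, "h2")
    m1 <- simulate_coder(ref, 0.30, 0.98, seed * 10 + 3, "m1")
    res <- deductive_noninferiority(list(m1 = m1), list(h1, h2), ref,
                                    margin = 0.03, B = 400, seed = seed)
    hits <- hits + res$verdict_noninferior
  }
  expect_gte(hits, 8L)  # non-inferiority in the large majority of runs
})
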