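#' Holm step-down adjustment
#'
#' Controls the family-wise error rate across the model comparisons of one
#' task (deductive and inductive families are adjusted separately).
#' Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Mean and parametric confidence interval for Likert scores
#'
#' Scores on the 1–5 agreement scale are treated as approximately interval
#' data: the interval is `mean +/- t_{1-(1-level)/2, n-1} * sd / sqrt(n)`
#' with the sample (n-1) standard deviation. With a single score the point
#' is returned with a degenerate interval.
#'
#' @param scores integer scores in 1..5.
#' @param ci_level confidence level, default 0.95.
#' @return Named numeric vector `mean`, `ci_low`, `ci_high`.
#' @export
likert_mean_ci <- function(scores, ci_level = 0.95) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (n == 0) stop("no scores supplied")
  m <- mean(scores)
  if (n == 1) return(c(mean = m, ci_low = m, ci_high = m))
  half <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1) *
    stats::sd(scores) / sqrt(n)
  c(mean = m, ci_low = m - half, ci_high = m + half)
}

new_comparison_result <- function(model_id, effect, margin, p_raw,
                                  ci_low, ci_high, degenerate = FALSE)
  data.frame(model_id = model_id, effect = effect, margin = margin,
             p_raw = p_raw, p_holm = NA_real_,
             ci_low = ci_low, ci_high = ci_high,
             degenerate = degenerate, stringsAsFactors = FALSE)

finalize_comparisons <- function(noninf, sup, alpha) {
  noninf$p_holm <- holm_adjust(noninf$p_raw)
  sup$p_holm <- holm_adjust(sup$p_raw)
  out <- noninf
  names(out)[names(out) == "p_raw"] <- "p_raw_noninferior"
  names(out)[names(out) == "p_holm"] <- "p_holm_noninferior"
  out$p_raw_superior <- sup$p_raw
  out$p_holm_superior <- sup$p_holm
  out$verdict_noninferior <- out$p_holm_noninferior < alpha
  out$verdict_superior <- out$p_holm_superior < alpha
  out
}

#' Deductive non-inferiority of models against the human mean (AC1)
#'
#' For each model, the effect is `Delta = AC1(model vs reference) -
#' mean_h AC1(human_h vs reference)` on the pooled segment-by-code vector.
#' A one-sided non-parametric bootstrap test with segment-level resampling
#' evaluates `H0: Delta <= -margin`: every replicate draws one shared
#' segment resample (the model and all humans are recomputed on the same
#' drawn segments, so the difference is paired), and
#' `p_raw = (1 + #{Delta* <= -margin}) / (B + 1)` (add-one rule, so a
#' reported p is never exactly zero). Superiority reuses the machinery with
#' margin 0. Holm adjustment is applied across models, separately for the
#' non-inferiority and superiority families.
#'
#' @param models named list of [coding_matrix()] objects (the automated
#'   coders under test).
#' @param humans list of [coding_matrix()] objects (the blinded human
#'   comparators); must be non-empty.
#' @param reference the adjudicated [coding_matrix()].
#' @param margin non-inferiority margin on the AC1 scale (study value 0.03).
#' @param B bootstrap replicates (study value 1000).
#' @param seed integer RNG seed.
#' @param alpha significance level for the verdicts, default 0.05.
#' @param ci_level level of the percentile CI reported for `Delta`.
#' @return Data frame, one row per model: `effect` (Delta), `margin`,
#'   raw/Holm p for non-inferiority and superiority, percentile `ci_low` /
#'   `ci_high` for Delta, and logical verdicts at `alpha`.
#' @export
deductive_noninferiority <- function(models, humans, reference,
                                     margin = 0.03, B = 1000, seed = 1,
                                     alpha = 0.05, ci_level = 0.95) {
  stopifnot(margin > 0, B >= 1)
  if (length(humans) == 0) stop("at least one human comparator is required")
  if (is.null(names(models)))
    names(models) <- paste0("model_", seq_along(models))
  sc_models <- lapply(models, function(m) segment_confusion(reference, m))
  sc_humans <- lapply(humans, function(m) segment_confusion(reference, m))
  ac1_of <- function(sc) metric_from_cells(gwet_ac1, colSums(sc))
  human_mean <- mean(vapply(sc_humans, ac1_of, numeric(1)))
  ns <- nrow(sc_models[[1]])
  set.seed(seed)
  idx <- matrix(sample.int(ns, ns * B, replace = TRUE), nrow = ns)
  reps_h <- vapply(sc_humans, function(sc)
    bootstrap_metric_reps(gwet_ac1, sc, idx), numeric(B))
  human_mean_reps <- rowMeans(matrix(reps_h, nrow = B))
  qlo <- (1 - ci_level) / 2
  noninf <- list(); sup <- list()
  for (id in names(models)) {
    delta <- ac1_of(sc_models[[id]]) - human_mean
    d_reps <- bootstrap_metric_reps(gwet_ac1, sc_models[[id]], idx) -
      human_mean_reps
    ok <- !is.na(d_reps)
    if (mean(ok) < 0.5)
      stop("AC1 undefined in most bootstrap replicates for model ", id)
    d_ok <- d_reps[ok]; b_ok <- length(d_ok)
    p_ni <- (1 + sum(d_ok <= -margin)) / (b_ok + 1)
    p_sup <- (1 + sum(d_ok <= 0)) / (b_ok + 1)
    ci <- stats::quantile(d_ok, c(qlo, 1 - qlo), names = FALSE, type = 7)
    noninf[[id]] <- new_comparison_result(id, delta, margin, p_ni,
                                          ci[1], ci[2])
    sup[[id]] <- new_comparison_result(id, delta, 0, p_sup, ci[1], ci[2])
  }
  finalize_comparisons(do.call(rbind, noninf), do.call(rbind, sup), alpha)
}

# one-sided one-sample t-test of H0: mean(d) <= -margin
likert_shift_test <- function(d, margin) {
  n <- length(d)
  dbar <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    # degenerate: all mass at dbar
    p <- if (dbar > -margin) 0 else 1
    return(list(p = p, t = NA_real_, degenerate = TRUE))
  }
  t_stat <- (dbar + margin) / (s / sqrt(n))
  list(p = stats::pt(t_stat, df = n - 1, lower.tail = FALSE),
       t = t_stat, degenerate = FALSE)
}

#' Inductive non-inferiority of models against the human mean (Likert)
#'
#' For model `m`, the per-code difference is `d_i = score(m, i) - mean over
#' humans of score(h, i)`. `H0: mean(d) <= -margin` is tested with a
#' one-sample one-sided t-test, `t = (dbar + margin) / (s_d / sqrt(n))` on
#' `n - 1` degrees of freedom (scores treated as interval data).
#' Superiority uses margin 0; Holm adjusts each family across models. A
#' zero-variance difference vector is flagged degenerate with p 0 or 1
#' according to the side of the margin.
#'
#' @param table a [likert_table()].
#' @param model_ids,human_ids column (analyst) names of `table`.
#' @param margin non-inferiority margin in Likert points (study value 0.5).
#' @param alpha significance level for verdicts.
#' @param ci_level level of the t-based CI for `dbar`.
#' @return Data frame as in [deductive_noninferiority()], plus `t_noninferior`.
#' @export
inductive_noninferiority <- function(table, model_ids, human_ids,
                                     margin = 0.5, alpha = 0.05,
                                     ci_level = 0.95) {
  stopifnot(inherits(table, "likert_table"), margin > 0)
  sc <- table$scores
  missing_ids <- setdiff(c(model_ids, human_ids), colnames(sc))
  if (length(missing_ids))
    stop("unknown analyst id(s): ", paste(missing_ids, collapse = ", "))
  if (nrow(sc) < 2) stop("need at least two codes")
  human_mean <- rowMeans(sc[, human_ids, drop = FALSE])
  noninf <- list(); sup <- list(); tstats <- numeric(0)
  for (id in model_ids) {
    d <- sc[, id] - human_mean
    n <- length(d)
    ni <- likert_shift_test(d, margin)
    su <- likert_shift_test(d, 0)
    half <- if (stats::sd(d) == 0) 0 else
      stats::qt(1 - (1 - ci_level) / 2, n - 1) * stats::sd(d) / sqrt(n)
    noninf[[id]] <- new_comparison_result(id, mean(d), margin, ni$p,
                                          mean(d) - half, mean(d) + half,
                                          ni$degenerate)
    sup[[id]] <- new_comparison_result(id, mean(d), 0, su$p,
                                       mean(d) - half, mean(d) + half,
                                       su$degenerate)
    tstats[id] <- ni$t
  }
  out <- finalize_comparisons(do.call(rbind, noninf), do.call(rbind, sup),
                              alpha)
  out$t_noninferior <- unname(tstats[out$model_id])
  out
}
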