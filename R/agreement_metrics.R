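#' Confusion counts of a coder against the reference standard
#'
#' Cross-tabulates a coder's binary labels against the adjudicated
#' reference (the reference is the truth axis). With `code = "ALL"` the
#' full segment-by-code rectangle is pooled into one binary vector; with a
#' single code id only that column is compared.
#'
#' @param reference,coder [coding_matrix()] objects sharing the same
#'   segment and code universes.
#' @param code a code id, or `"ALL"` to pool every cell.
#' @return An object of class `"confusion_counts"`: a list with integer
#'   fields `tp`, `fp`, `fn`, `tn` and `n = tp + fp + fn + tn`.
#' @export
confusion_counts <- function(reference, coder, code = "ALL") {
  check_same_universe(reference, coder)
  r <- reference$labels
  m <- coder$labels[rownames(r), colnames(r), drop = FALSE]
  if (!identical(code, "ALL")) {
    if (!code %in% colnames(r)) stop("unknown code id: ", code)
    r <- r[, code, drop = FALSE]
    m <- m[, code, drop = FALSE]
  }
  confusion_from_logical(as.vector(r), as.vector(m))
}

confusion_from_logical <- function(ref, cod) {
  structure(list(tp = sum(ref & cod), fp = sum(!ref & cod),
                 fn = sum(ref & !cod), tn = sum(!ref & !cod),
                 n = length(ref)),
            class = "confusion_counts")
}

#' Build a confusion_counts object from its four cells
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return A `"confusion_counts"` object.
#' @export
confusion <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("confusion cells must be non-negative integers")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

check_same_universe <- function(a, b) {
  ds <- c(setdiff(segment_ids(a), segment_ids(b)),
          setdiff(segment_ids(b), segment_ids(a)))
  dc <- c(setdiff(code_ids(a), code_ids(b)),
          setdiff(code_ids(b), code_ids(a)))
  if (length(ds) || length(dc))
    stop("matrices do not share a universe; disjoint ids: ",
         paste(unique(c(ds, dc)), collapse = ", "))
  invisible(TRUE)
}

undefined_metric <- function(reason)
  structure(NA_real_, undefined_reason = reason)

check_n <- function(c) if (c$n <= 0) stop("empty confusion table (n = 0)")

#' Observed percentage agreement
#' @param c a `"confusion_counts"` object.
#' @return `(tp + tn) / n`, the raw proportion of concordant cells.
#' @export
percent_agreement <- function(c) {
  check_n(c)
  (c$tp + c$tn) / c$n
}

marginals <- function(c)
  c(p1 = (c$tp + c$fn) / c$n,   # reference positive rate
    p2 = (c$tp + c$fp) / c$n)   # coder positive rate

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement with marginal-product expected agreement:
#' `kappa = (p_o - p_e) / (1 - p_e)` where `p_e = p1 p2 + (1-p1)(1-p2)`,
#' `p1` the reference positive rate and `p2` the coder positive rate.
#' Kappa is strongly attenuated when code prevalence is low even at high
#' raw agreement (the prevalence paradox); compare [gwet_ac1()].
#'
#' When both raters are constant and equal (`p_e = 1`) kappa is undefined
#' and `NA` is returned, tagged with an `undefined_reason` attribute, so
#' bootstrap replicates can skip degenerate resamples rather than fail.
#'
#' @param c a `"confusion_counts"` object.
#' @return Kappa in `[-1, 1]`, or tagged `NA` when undefined.
#' @export
cohen_kappa <- function(c) {
  check_n(c)
  p <- marginals(c)
  p_e <- p[["p1"]] * p[["p2"]] + (1 - p[["p1"]]) * (1 - p[["p2"]])
  if (p_e >= 1)
    return(undefined_metric("degenerate marginals: both raters constant and equal"))
  p_o <- percent_agreement(c)
  (p_o - p_e) / (1 - p_e)
}

#' Gwet's AC1 for two binary raters
#'
#' Chance-corrected agreement whose chance term depends on the mean
#' positive propensity: `AC1 = (p_o - g_e) / (1 - g_e)` with
#' `g_e = 2 pi (1 - pi)` and `pi = (p1 + p2) / 2`. Because `g_e <= 0.5`
#' for binary labels, AC1 resists the low-prevalence attenuation that
#' afflicts Cohen's kappa.
#'
#' @param c a `"confusion_counts"` object.
#' @return AC1 in `[-1, 1]`.
#' @export
gwet_ac1 <- function(c) {
  check_n(c)
  p <- marginals(c)
  pi_hat <- (p[["p1"]] + p[["p2"]]) / 2
  g_e <- 2 * pi_hat * (1 - pi_hat)
  (percent_agreement(c) - g_e) / (1 - g_e)
}

#' Accuracy-style agreement metrics
#'
#' `jaccard = tp / (tp + fp + fn)`, `f1 = 2 tp / (2 tp + fp + fn)`,
#' `sensitivity = tp / (tp + fn)`, `specificity = tn / (tn + fp)`, all
#' taking the reference as truth. A zero denominator yields a tagged `NA`
#' (reason in the `undefined_reason` attribute).
#'
#' @param c a `"confusion_counts"` object.
#' @return A proportion in `[0, 1]`, or tagged `NA`.
#' @name accuracy_metrics
NULL

#' @rdname accuracy_metrics
#' @export
jaccard <- function(c) {
  check_n(c)
  d <- c$tp + c$fp + c$fn
  if (d == 0) return(undefined_metric("no positive cells in either rater"))
  c$tp / d
}

#' @rdname accuracy_metrics
#' @export
f1_score <- function(c) {
  check_n(c)
  d <- 2 * c$tp + c$fp + c$fn
  if (d == 0) return(undefined_metric("no positive cells in either rater"))
  2 * c$tp / d
}

#' @rdname accuracy_metrics
#' @export
sensitivity <- function(c) {
  check_n(c)
  d <- c$tp + c$fn
  if (d == 0) return(undefined_metric("reference has no positive cells"))
  c$tp / d
}

#' @rdname accuracy_metrics
#' @export
specificity <- function(c) {
  check_n(c)
  d <- c$tn + c$fp
  if (d == 0) return(undefined_metric("reference has no negative cells"))
  c$tn / d
}

#' The seven reported agreement metrics, by name
#'
#' @return Named list of metric functions, each mapping a
#'   `"confusion_counts"` object to a number, in the reporting order
#'   agreement / kappa / AC1 / Jaccard / sensitivity / specificity / F1.
#' @export
agreement_metric_set <- function()
  list(agreement = percent_agreement, kappa = cohen_kappa, ac1 = gwet_ac1,
       jaccard = jaccard, sensitivity = sensitivity,
       specificity = specificity, f1 = f1_score)

#' Point values of all agreement metrics for one coder
#'
#' @inheritParams confusion_counts
#' @return Named numeric vector over the seven metrics of
#'   [agreement_metric_set()].
#' @export
agreement_metrics <- function(reference, coder, code = "ALL") {
  cc <- confusion_counts(reference, coder, code)
  vapply(agreement_metric_set(), function(f) as.numeric(f(cc)), numeric(1))
}

#' Cohen's kappa computed independently per code
#'
#' @param reference,coder [coding_matrix()] objects on the same universe.
#' @return Named numeric vector, one kappa per code; codes with degenerate
#'   marginals are `NA`.
#' @export
per_code_kappa <- function(reference, coder) {
  check_same_universe(reference, coder)
  codes <- code_ids(reference)
  out <- vapply(codes, function(k)
    as.numeric(cohen_kappa(confusion_counts(reference, coder, k))), numeric(1))
  names(out) <- codes
  out
}

#' Per-segment confusion cell counts
#'
#' For segment-level bootstrap resampling: row `s` holds the (tp, fp, fn,
#' tn) contribution of segment `s` pooled across the selected codes, so a
#' resample's confusion table is just a column sum over drawn rows. All
#' codes of a drawn segment move together, preserving within-segment
#' dependence.
#'
#' @inheritParams confusion_counts
#' @return Integer matrix, `n_segments` x 4, columns `tp`, `fp`, `fn`, `tn`.
#' @export
segment_confusion <- function(reference, coder, code = "ALL") {
  check_same_universe(reference, coder)
  r <- reference$labels
  m <- coder$labels[rownames(r), colnames(r), drop = FALSE]
  if (!identical(code, "ALL")) {
    if (!code %in% colnames(r)) stop("unknown code id: ", code)
    r <- r[, code, drop = FALSE]; m <- m[, code, drop = FALSE]
  }
  cbind(tp = rowSums(r & m), fp = rowSums(!r & m),
        fn = rowSums(r & !m), tn = rowSums(!r & !m))
}

metric_from_cells <- function(metric_fn, cells)
  as.numeric(metric_fn(confusion(cells[[1]], cells[[2]], cells[[3]], cells[[4]])))

#' Segment-level percentile bootstrap confidence interval for a metric
#'
#' Resamples whole segments with replacement (all codes of a drawn segment
#' move together), recomputes the metric on each replicate, and returns the
#' percentile interval. Replicates where the metric is undefined (e.g.
#' kappa under degenerate resampled marginals, expected at low prevalence)
#' are dropped and counted; more than 50% undefined replicates is an error.
#'
#' @param metric_fn a metric function over `"confusion_counts"`, e.g.
#'   [gwet_ac1()].
#' @param reference,coder [coding_matrix()] objects on the same universe.
#' @param code code id or `"ALL"` (pooled).
#' @param B number of bootstrap replicates (study default 1000).
#' @param seed integer RNG seed; the same seed reproduces the interval.
#' @param ci_level confidence level, default 0.95.
#' @return List with `point`, `ci_low`, `ci_high`, `B`, `n_undefined`.
#' @export
bootstrap_ci <- function(metric_fn, reference, coder, code = "ALL",
                         B = 1000, seed = 1, ci_level = 0.95) {
  stopifnot(B >= 1, ci_level > 0, ci_level < 1)
  sc <- segment_confusion(reference, coder, code)
  point <- metric_from_cells(metric_fn, colSums(sc))
  ns <- nrow(sc)
  set.seed(seed)
  idx <- matrix(sample.int(ns, ns * B, replace = TRUE), nrow = ns)
  reps <- bootstrap_metric_reps(metric_fn, sc, idx)
  ok <- !is.na(reps)
  if (mean(ok) < 0.5)
    stop(sprintf("metric undefined in %d of %d bootstrap replicates", sum(!ok), B))
  qs <- stats::quantile(reps[ok], probs = c((1 - ci_level) / 2,
                                            1 - (1 - ci_level) / 2),
                        names = FALSE, type = 7)
  list(point = point, ci_low = qs[1], ci_high = qs[2],
       B = B, n_undefined = sum(!ok))
}

# replicate metric values for an index matrix (segments x B)
bootstrap_metric_reps <- function(metric_fn, sc, idx) {
  B <- ncol(idx); ns <- nrow(idx)
  tp <- colSums(matrix(sc[, 1][idx], ns, B))
  fp <- colSums(matrix(sc[, 2][idx], ns, B))
  fn <- colSums(matrix(sc[, 3][idx], ns, B))
  tn <- colSums(matrix(sc[, 4][idx], ns, B))
  vapply(seq_len(B), function(b)
    metric_from_cells(metric_fn, c(tp[b], fp[b], fn[b], tn[b])), numeric(1))
}

#' Bootstrap CI for the mean of a metric over several coders
#'
#' The "human mean" / "LLM mean" rows of an agreement table: the point
#' value is the arithmetic mean of the per-coder metric, and every
#' bootstrap replicate applies one shared segment resample to all coders
#' before averaging (paired resampling).
#'
#' @param metric_fn metric over `"confusion_counts"`.
#' @param reference a [coding_matrix()].
#' @param coders list of [coding_matrix()] objects.
#' @inheritParams bootstrap_ci
#' @return List with `point`, `ci_low`, `ci_high`, `B`, `n_undefined`.
#' @export
bootstrap_mean_ci <- function(metric_fn, reference, coders, code = "ALL",
                              B = 1000, seed = 1, ci_level = 0.95) {
  stopifnot(length(coders) >= 1, B >= 1)
  scs <- lapply(coders, function(m) segment_confusion(reference, m, code))
  point <- mean(vapply(scs, function(sc)
    metric_from_cells(metric_fn, colSums(sc)), numeric(1)))
  ns <- nrow(scs[[1]])
  set.seed(seed)
  idx <- matrix(sample.int(ns, ns * B, replace = TRUE), nrow = ns)
  per <- vapply(scs, function(sc) bootstrap_metric_reps(metric_fn, sc, idx),
                numeric(B))
  reps <- rowMeans(matrix(per, nrow = B))
  ok <- !is.na(reps)
  if (mean(ok) < 0.5)
    stop("metric undefined in most bootstrap replicates")
  qs <- stats::quantile(reps[ok], probs = c((1 - ci_level) / 2,
                                            1 - (1 - ci_level) / 2),
                        names = FALSE, type = 7)
  list(point = point, ci_low = qs[1], ci_high = qs[2],
       B = B, n_undefined = sum(!ok))
}

#' Agreement table for a panel of coders (study Table-1 layout)
#'
#' One row per coder plus optional group-mean rows, each metric given as
#' point estimate with a segment-level percentile bootstrap CI.
#'
#' @param reference a [coding_matrix()] (the adjudicated standard).
#' @param coders named list of [coding_matrix()] objects.
#' @param groups optional named list of character vectors of coder names;
#'   each group adds a "<name> mean" row averaging the member coders.
#' @inheritParams bootstrap_ci
#' @return A data frame with columns `coder`, then `<metric>`,
#'   `<metric>_low`, `<metric>_high` for the seven metrics.
#' @export
agreement_table <- function(reference, coders, groups = NULL,
                            B = 1000, seed = 1, ci_level = 0.95) {
  mets <- agreement_metric_set()
  one_row <- function(label, fetch) {
    vals <- lapply(names(mets), function(nm) fetch(mets[[nm]]))
    row <- data.frame(coder = label, stringsAsFactors = FALSE)
    for (i in seq_along(mets)) {
      nm <- names(mets)[i]
      row[[nm]] <- vals[[i]]$point
      row[[paste0(nm, "_low")]] <- vals[[i]]$ci_low
      row[[paste0(nm, "_high")]] <- vals[[i]]$ci_high
    }
    row
  }
  rows <- lapply(names(coders), function(id)
    one_row(id, function(f)
      bootstrap_ci(f, reference, coders[[id]], B = B, seed = seed,
                   ci_level = ci_level)))
  if (!is.null(groups)) {
    rows <- c(rows, lapply(names(groups), function(g)
      one_row(paste(g, "mean"), function(f)
        bootstrap_mean_ci(f, reference, coders[groups[[g]]], B = B,
                          seed = seed, ci_level = ci_level))))
  }
  do.call(rbind, rows)
}
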