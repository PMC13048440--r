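# Independent first-principles implementations of the chance-corrected
# coefficients, computed from the two rating vectors in their general
# K-category form. These never touch the package's confusion-count path.

kappa_oracle <- function(x, y) {
  lev <- unique(c(x, y))
  px <- vapply(lev, function(l) mean(x == l), numeric(1))
  py <- vapply(lev, function(l) mean(y == l), numeric(1))
  p_o <- mean(x == y)
  p_e <- sum(px * py)
  if (p_e >= 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

ac1_oracle <- function(x, y) {
  lev <- unique(c(x, y))
  K <- max(length(lev), 2L)
  px <- vapply(lev, function(l) mean(x == l), numeric(1))
  py <- vapply(lev, function(l) mean(y == l), numeric(1))
  pi_k <- (px + py) / 2
  # pad unobserved categories of the binary design (propensity 0 adds 0)
  g_e <- sum(pi_k * (1 - pi_k)) / (K - 1)
  p_o <- mean(x == y)
  (p_o - g_e) / (1 - g_e)
}

# all 2x2 confusion tables with tp+fp+fn+tn = n, as rating-vector pairs
all_tables_up_to <- function(n_max) {
  out <- list()
  for (n in 1:n_max)
    for (tp in 0:n) for (fp in 0:(n - tp)) for (fn in 0:(n - tp - fp)) {
      tn <- n - tp - fp - fn
      ref <- c(rep(TRUE, tp), rep(FALSE, fp), rep(TRUE, fn), rep(FALSE, tn))
      cod <- c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, fn), rep(FALSE, tn))
      out[[length(out) + 1L]] <- list(tp = tp, fp = fp, fn = fn, tn = tn,
                                      ref = ref, cod = cod)
    }
  out
}

# small deterministic coding matrices from explicit logical vectors
matrix_from_vectors <- function(coder_id, cells, n_segments, n_codes) {
  lab <- matrix(cells, nrow = n_segments, ncol = n_codes,
                dimnames = list(sprintf("S%03d", seq_len(n_segments)),
                                sprintf("C%02d", seq_len(n_codes))))
  coding_matrix(coder_id, lab)
}

study_likert_path <- function()
  system.file("extdata", "inductive_likert_scores.csv", package = "codagree")

study_quote_counts_path <- function()
  system.file("extdata", "quote_verification_counts.csv", package = "codagree")
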