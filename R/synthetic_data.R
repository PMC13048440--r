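#' Simulation design for a deductive coding study
#'
#' Defaults emulate the study conditions: 124 participant segments by 10
#' codes (1240 cells per coder), per-code prevalences drawn once from a
#' normal with mean 0.078 and SD 0.032, clipped to (0.005, 0.5), and then
#' frozen into the spec; coder operating points (sensitivity, specificity)
#' default to the observed human mean (0.34, 0.97) and LLM mean
#' (0.30, 0.98). Cells are independent across segments and codes.
#'
#' @param n_segments number of participant segments.
#' @param n_codes number of deductive codes.
#' @param prevalence optional explicit per-code prevalence vector; when
#'   `NULL`, drawn from the clipped normal and frozen.
#' @param prevalence_mean,prevalence_sd parameters of the prevalence draw.
#' @param human_profile,model_profile named numeric vectors with
#'   `sensitivity` and `specificity`.
#' @param seed integer seed governing the prevalence draw and, by default,
#'   downstream generation.
#' @return A list of class `"deductive_sim_spec"` with the frozen
#'   prevalence vector.
#' @export
deductive_sim_spec <- function(n_segments = 124, n_codes = 10,
                               prevalence = NULL,
                               prevalence_mean = 0.078,
                               prevalence_sd = 0.032,
                               human_profile = c(sensitivity = 0.34,
                                                 specificity = 0.97),
                               model_profile = c(sensitivity = 0.30,
                                                 specificity = 0.98),
                               seed = 1) {
  stopifnot(n_segments >= 1, n_codes >= 1, n_segments * n_codes >= 30)
  if (is.null(prevalence)) {
    set.seed(seed)
    prevalence <- pmin(pmax(stats::rnorm(n_codes, prevalence_mean,
                                         prevalence_sd), 0.005), 0.5)
  } else {
    stopifnot(length(prevalence) == n_codes, all(prevalence >= 0),
              all(prevalence < 1))
  }
  structure(list(n_segments = n_segments, n_codes = n_codes,
                 prevalence = prevalence, human_profile = human_profile,
                 model_profile = model_profile, seed = seed),
            class = "deductive_sim_spec")
}

sim_ids <- function(n, prefix) sprintf("%s%03d", prefix, seq_len(n))

#' Generate an adjudicated reference coding matrix
#'
#' Independent Bernoulli cells per code at that code's frozen prevalence.
#'
#' @param spec a [deductive_sim_spec()].
#' @param seed seed for the cell draws (defaults to `spec$seed`).
#' @return A [coding_matrix()] with coder id `"reference"`.
#' @export
generate_reference <- function(spec, seed = spec$seed) {
  set.seed(seed)
  lab <- vapply(seq_len(spec$n_codes), function(k)
    stats::runif(spec$n_segments) < spec$prevalence[k],
    logical(spec$n_segments))
  lab <- matrix(lab, nrow = spec$n_segments,
                dimnames = list(sim_ids(spec$n_segments, "S"),
                                sim_ids(spec$n_codes, "C")))
  coding_matrix("reference", lab)
}

#' Simulate a coder from the reference via an operating point
#'
#' Each true reference cell is kept with probability `sensitivity`; each
#' false cell is flipped on with probability `1 - specificity`;
#' independent across cells. This is the measurement model behind the
#' sensitivity/specificity columns of an agreement table.
#'
#' @param reference a [coding_matrix()].
#' @param sensitivity,specificity probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @param coder_id id for the simulated coder.
#' @return A [coding_matrix()].
#' @export
simulate_coder <- function(reference, sensitivity, specificity, seed,
                           coder_id = "sim_coder") {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  set.seed(seed)
  r <- reference$labels
  u <- matrix(stats::runif(length(r)), nrow = nrow(r),
              dimnames = dimnames(r))
  lab <- ifelse(r, u < sensitivity, u < 1 - specificity)
  coding_matrix(coder_id, lab)
}

#' Population values of the agreement metrics at an operating point
#'
#' Closed-form large-sample limits of the pooled metrics for a coder with
#' the given sensitivity and specificity against a reference with the given
#' per-code prevalence (a vector is pooled through its mean, matching the
#' concatenated-cell construction). Used as the independent oracle for
#' simulation tests and to exhibit the low-prevalence attenuation of kappa
#' relative to AC1.
#'
#' @param sensitivity,specificity coder operating point.
#' @param prevalence scalar or per-code vector of reference positive rates.
#' @return Named numeric vector: `agreement`, `kappa`, `ac1`, `jaccard`,
#'   `sensitivity`, `specificity`, `f1`.
#' @export
population_metrics <- function(sensitivity, specificity, prevalence) {
  prev <- mean(prevalence)
  p11 <- prev * sensitivity
  p10 <- prev * (1 - sensitivity)
  p01 <- (1 - prev) * (1 - specificity)
  p00 <- (1 - prev) * specificity
  p_o <- p11 + p00
  p1 <- prev
  p2 <- p11 + p01
  p_e <- p1 * p2 + (1 - p1) * (1 - p2)
  pi_hat <- (p1 + p2) / 2
  g_e <- 2 * pi_hat * (1 - pi_hat)
  c(agreement = p_o,
    kappa = (p_o - p_e) / (1 - p_e),
    ac1 = (p_o - g_e) / (1 - g_e),
    jaccard = p11 / (p11 + p01 + p10),
    sensitivity = sensitivity,
    specificity = specificity,
    f1 = 2 * p11 / (2 * p11 + p01 + p10))
}

#' Operating-point component achieving a target population AC1
#'
#' Inverts [population_metrics()] in one operating-point coordinate at
#' fixed values of the other; used to place a simulated coder exactly on a
#' non-inferiority margin boundary. At low prevalence AC1 is dominated by
#' specificity (a coder with perfect specificity cannot fall far below a
#' high-specificity human whatever its sensitivity), so boundary scenarios
#' are usually constructed by calibrating specificity at the coder's
#' sensitivity.
#'
#' @param target_ac1 desired population AC1; must lie in the range
#'   attainable by the varied coordinate, else an error.
#' @param sensitivity,specificity the fixed coordinate (supply exactly the
#'   one not being solved for).
#' @param prevalence reference positive rate (scalar or per-code vector).
#' @return The solved coordinate in `[0, 1]`.
#' @name calibrate_ac1
NULL

#' @rdname calibrate_ac1
#' @export
calibrate_sensitivity_to_ac1 <- function(target_ac1, specificity, prevalence) {
  f <- function(s) population_metrics(s, specificity, prevalence)[["ac1"]] -
    target_ac1
  if (f(0) * f(1) > 0)
    stop("target AC1 unattainable by varying sensitivity at this specificity")
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

#' @rdname calibrate_ac1
#' @export
calibrate_specificity_to_ac1 <- function(target_ac1, sensitivity, prevalence) {
  f <- function(p) population_metrics(sensitivity, p, prevalence)[["ac1"]] -
    target_ac1
  if (f(0) * f(1) > 0)
    stop("target AC1 unattainable by varying specificity at this sensitivity")
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

#' Simulation design for an inductive Likert comparison
#'
#' Emulates a codes-by-analysts agreement table: per-code human base means
#' drawn once (uniform on 3–4.5, the observed range of adjudicated
#' agreement) and frozen; each analyst's score is
#' `round(base + shift + noise)` clamped to 1..5, with normal noise (the
#' interval-scale treatment) and `model_shift` added for model analysts
#' only.
#'
#' @param n_codes number of inductive codes (study value 14).
#' @param n_humans,n_models analyst counts (study values 2 and 3).
#' @param base_means optional explicit per-code base means.
#' @param model_shift additive effect for model analysts (Likert points).
#' @param noise_sd SD of the pre-rounding normal noise.
#' @param seed integer seed (governs the base-mean draw).
#' @return A list of class `"likert_sim_spec"`.
#' @export
likert_sim_spec <- function(n_codes = 14, n_humans = 2, n_models = 3,
                            base_means = NULL, model_shift = 0,
                            noise_sd = 0.8, seed = 1) {
  stopifnot(n_codes >= 1, n_humans >= 1, n_models >= 0, noise_sd >= 0)
  if (is.null(base_means)) {
    set.seed(seed)
    base_means <- stats::runif(n_codes, 3, 4.5)
  } else stopifnot(length(base_means) == n_codes)
  structure(list(n_codes = n_codes, n_humans = n_humans,
                 n_models = n_models, base_means = base_means,
                 model_shift = model_shift, noise_sd = noise_sd,
                 seed = seed),
            class = "likert_sim_spec")
}

#' Generate a Likert agreement table
#'
#' @param spec a [likert_sim_spec()].
#' @param seed seed for the noise draws (defaults to `spec$seed`).
#' @return A [likert_table()] with analysts `human_1..h, model_1..m`.
#' @export
generate_likert <- function(spec, seed = spec$seed) {
  set.seed(seed)
  n <- spec$n_codes
  cols <- c(if (spec$n_humans) paste0("human_", seq_len(spec$n_humans)),
            if (spec$n_models) paste0("model_", seq_len(spec$n_models)))
  shift <- c(rep(0, spec$n_humans), rep(spec$model_shift, spec$n_models))
  sc <- vapply(seq_along(cols), function(j) {
    raw <- spec$base_means + shift[j] + stats::rnorm(n, 0, spec$noise_sd)
    pmin(pmax(round(raw), 1), 5)
  }, numeric(n))
  sc <- matrix(as.integer(sc), nrow = n,
               dimnames = list(sim_ids(n, "code_"), cols))
  likert_table(sc)
}

#' Simulation design for a transcript with quote records
#'
#' Emulates the audited structure of a quote-verification table: a
#' transcript mixing participant and facilitator segments, and model quote
#' records generated to realize each audit class at the injected rates —
#' verbatim participant substrings (exact), truncated quotes with appended
#' fabricated tokens (partial, built to sit above the similarity threshold
#' but below 1), fully fabricated digit-token text (no_match, far below the
#' threshold), and verbatim facilitator quotes (researcher_segment). The
#' generating class is stored as hidden truth for closed-loop testing.
#'
#' @param n_segments transcript length (default 40).
#' @param facilitator_fraction fraction of facilitator segments.
#' @param rates named numeric vector over
#'   `c("exact","partial","no_match","researcher_segment")` summing to 1.
#' @param n_records number of quote records to emit.
#' @param seed integer seed.
#' @return A list of class `"transcript_sim_spec"`.
#' @export
transcript_sim_spec <- function(n_segments = 40,
                                facilitator_fraction = 0.2,
                                rates = c(exact = 0.85, partial = 0.05,
                                          no_match = 0.03,
                                          researcher_segment = 0.07),
                                n_records = 100, seed = 1) {
  stopifnot(n_segments >= 2, facilitator_fraction > 0,
            facilitator_fraction < 1, n_records >= 1)
  rates <- rates[match_classes()]
  if (anyNA(rates)) stop("rates must name all four classes")
  if (any(rates < 0) || abs(sum(rates) - 1) > 1e-8)
    stop("rates must be non-negative and sum to 1")
  structure(list(n_segments = n_segments,
                 facilitator_fraction = facilitator_fraction,
                 rates = rates, n_records = n_records, seed = seed),
            class = "transcript_sim_spec")
}

sim_vocabulary <- function()
  c("the", "care", "people", "health", "support", "community", "advice",
    "condition", "exercise", "personal", "treatment", "system", "trust",
    "experience", "doctor", "patient", "service", "activity", "change",
    "information", "research", "question", "feedback", "technology",
    "access", "barrier", "routine", "local", "group", "meaning",
    "different", "important", "together", "individual", "flexible",
    "monitor", "respond", "connect", "understand", "manage", "listen",
    "improve", "adapt", "share", "often", "really", "maybe", "because",
    "would", "could", "think", "about", "through", "between", "around")

sim_sentence <- function(n_words)
  paste(sample(sim_vocabulary(), n_words, replace = TRUE), collapse = " ")

fabricated_tokens <- function(n_tokens)
  paste(vapply(seq_len(n_tokens), function(i)
    paste(sample(0:9, 4, replace = TRUE), collapse = ""), character(1)),
    collapse = " ")

word_span <- function(text, lo_frac, hi_frac) {
  w <- strsplit(text, " ", fixed = TRUE)[[1]]
  n <- length(w)
  len <- max(3L, round(stats::runif(1, lo_frac, hi_frac) * n))
  len <- min(len, n)
  start <- sample.int(n - len + 1L, 1)
  paste(w[start:(start + len - 1L)], collapse = " ")
}

#' Generate a transcript with quote records of known audit classes
#'
#' @param spec a [transcript_sim_spec()].
#' @param enumerate when `TRUE`, realize class counts deterministically as
#'   `round(rates * n_records)` (largest-remainder adjusted) instead of
#'   sampling classes; use this to reproduce an exact count table.
#' @param model_id id recorded on the quote records.
#' @return List with `transcript` (a [transcript()]) and `records` (a
#'   [quote_records()] data frame carrying a hidden `truth_class` column).
#' @export
generate_transcript_with_quotes <- function(spec, enumerate = FALSE,
                                            model_id = "sim_model") {
  set.seed(spec$seed)
  n <- spec$n_segments
  n_fac <- max(1L, round(spec$facilitator_fraction * n))
  roles <- rep("participant", n)
  roles[sample.int(n, n_fac)] <- "facilitator"
  texts <- vapply(seq_len(n), function(i)
    sim_sentence(sample(12:24, 1)), character(1))
  tr <- transcript(sim_ids(n, "T"), roles, texts)
  part_idx <- which(roles == "participant")
  fac_idx <- which(roles == "facilitator")

  nr <- spec$n_records
  if (enumerate) {
    cnt <- floor(spec$rates * nr)
    rem <- nr - sum(cnt)
    if (rem > 0) {
      extra <- order(spec$rates * nr - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1
    }
    classes <- rep(match_classes(), times = cnt)
  } else {
    classes <- sample(match_classes(), nr, replace = TRUE, prob = spec$rates)
  }

  seg <- character(nr); qt <- character(nr)
  for (i in seq_len(nr)) {
    cl <- classes[i]
    if (cl == "researcher_segment") {
      j <- sample(fac_idx, 1)
      seg[i] <- tr$id[j]
      qt[i] <- word_span(tr$text[j], 0.4, 0.8)
    } else if (cl == "exact") {
      j <- sample(part_idx, 1)
      seg[i] <- tr$id[j]
      qt[i] <- word_span(tr$text[j], 0.4, 0.9)
    } else if (cl == "partial") {
      j <- sample(part_idx, 1)
      seg[i] <- tr$id[j]
      core <- word_span(tr$text[j], 0.55, 0.75)
      # append ~20% fabricated tokens: similarity ~ 0.8, safely in
      # (threshold, 1) for the default policy
      qt[i] <- paste(core, fabricated_tokens(max(1L, round(
        length(strsplit(core, " ")[[1]]) * 0.2))))
    } else {
      j <- sample(part_idx, 1)
      seg[i] <- tr$id[j]
      qt[i] <- fabricated_tokens(sample(6:10, 1))
    }
  }
  rec <- quote_records(model_id, seg, qt, sprintf("code_%02d",
                                                  sample.int(14, nr, TRUE)))
  rec$truth_class <- classes
  list(transcript = tr, records = rec)
}
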