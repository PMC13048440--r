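#' Quote-matching policy
#'
#' Normalization plus a reproducible partial-match criterion. Text is
#' case-folded, typographic quotes and dashes are mapped to ASCII, runs of
#' whitespace collapse to one space, and terminal punctuation is stripped.
#' Similarity between a quote and a segment is the length of their longest
#' common substring divided by the length of the shorter normalized string,
#' so a verbatim quote scores exactly 1. The published audits were manual
#' judgements; a `match_override` on a record replays such a verdict and
#' always wins over this automatic rule.
#'
#' @param partial_threshold similarity in (0, 1) at or above which a
#'   non-exact quote counts as a partial match; default 0.5.
#' @return A list of class `"match_policy"`.
#' @export
match_policy <- function(partial_threshold = 0.5) {
  stopifnot(partial_threshold > 0, partial_threshold < 1)
  structure(list(partial_threshold = partial_threshold),
            class = "match_policy")
}

#' Normalize quoted text for matching
#'
#' @param x character vector.
#' @return Normalized character vector (lower case, ASCII quotes/dashes,
#'   collapsed whitespace, no terminal punctuation).
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("‘|’", "'", x)
  x <- gsub("“|”", "\"", x)
  x <- gsub("–|—", "-", x)
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  gsub("^[\"']+|[[:punct:]]+$", "", x)
}

#' Longest common substring length of two strings
#'
#' Contiguous-substring (not subsequence) dynamic programme; the building
#' block of the partial-match similarity.
#'
#' @param a,b character scalars.
#' @return Integer length of the longest common contiguous substring.
#' @export
lcs_substring_length <- function(a, b) {
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  na <- length(ia); nb <- length(ib)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb)
  best <- 0L
  for (i in seq_len(na)) {
    cur <- integer(nb)
    hit <- which(ib == ia[i])
    if (length(hit)) {
      cur[hit] <- c(0L, prev)[hit] + 1L
      m <- max(cur[hit])
      if (m > best) best <- m
    }
    prev <- cur
  }
  best
}

#' Similarity of a quote to a segment text
#'
#' Normalized longest-common-substring ratio relative to the shorter
#' string: `LCS(normalize(quote), normalize(text)) / min(nchar)`.
#'
#' @param quote,text character scalars.
#' @return Similarity in `[0, 1]`; 0 if either normalizes to empty.
#' @export
quote_similarity <- function(quote, text) {
  q <- normalize_text(quote); s <- normalize_text(text)
  if (!nzchar(q) || !nzchar(s)) return(0)
  lcs_substring_length(q, s) / min(nchar(q), nchar(s))
}

classify_one <- function(segment_id, quote, override, transcript, policy) {
  if (!is.na(override)) return(override)
  q <- normalize_text(quote)
  texts <- normalize_text(transcript$text)
  target <- NULL
  if (!is.na(segment_id) && nzchar(segment_id)) {
    hit <- match(segment_id, transcript$id)
    if (is.na(hit)) return("no_match")  # unknown claimed segment, logged upstream
    target <- hit
  }
  if (!nzchar(q)) return("no_match")
  if (is.null(target)) {
    # no claimed segment: locate the best-matching segment in the transcript
    exact_hits <- which(vapply(texts, function(s)
      grepl(q, s, fixed = TRUE), logical(1)))
    if (length(exact_hits)) {
      target <- exact_hits[1]
    } else {
      sims <- vapply(seq_len(nrow(transcript)), function(i)
        quote_similarity(quote, transcript$text[i]), numeric(1))
      target <- which.max(sims)
    }
  }
  # researcher-segment precedence: a verbatim facilitator quote is a
  # violation, not an exact match (keeps the four classes disjoint)
  if (transcript$speaker_role[target] == "facilitator")
    return("researcher_segment")
  s <- texts[target]
  if (grepl(q, s, fixed = TRUE)) return("exact")
  if (quote_similarity(quote, transcript$text[target]) >=
      policy$partial_threshold) return("partial")
  "no_match"
}

#' Classify every quote record against the transcript
#'
#' Each record gets exactly one of the four classes of [match_classes()]:
#' `researcher_segment` if the claimed (or best-matching) segment is
#' facilitator speech (checked first — coding researcher speech is an
#' instruction violation, not a hallucination); otherwise `exact` if the
#' normalized quote is a substring of the segment text (of the
#' best-matching segment when no id is claimed); otherwise `partial` when
#' similarity reaches the policy threshold; otherwise `no_match`
#' (fabricated evidence). A claimed segment id absent from the transcript
#' classifies as `no_match` and is reported in the `unknown_segments`
#' attribute rather than raising.
#'
#' @param records a [quote_records()] data frame.
#' @param transcript a [transcript()] (facilitator segments included).
#' @param policy a [match_policy()].
#' @return `records` with `match_class` filled in.
#' @export
audit_quotes <- function(records, transcript, policy = match_policy()) {
  if (nrow(transcript) == 0) stop("empty transcript")
  cls <- vapply(seq_len(nrow(records)), function(i)
    classify_one(records$segment_id[i], records$quote[i],
                 records$match_override[i], transcript, policy),
    character(1))
  records$match_class <- cls
  unknown <- records$segment_id[!is.na(records$segment_id) &
                                  !(records$segment_id %in% transcript$id)]
  attr(records, "unknown_segments") <- unique(unknown)
  records
}

count_classes <- function(classes) {
  k <- match_classes()
  out <- vapply(k, function(x) sum(classes == x), integer(1))
  names(out) <- k
  out
}

#' Strict, expanded and comprehensive error rates for one model
#'
#' From the audited class counts: strict hallucination rate =
#' no-match / total (fabricated evidence); expanded = (no-match +
#' researcher-segments-coded) / total (adds instruction violations);
#' comprehensive = (no-match + researcher-segments-coded + partial) /
#' total (adds borderline evidence). Rates are percentages at full
#' precision; rounding happens only at report time.
#'
#' @param x an audited [quote_records()] data frame (all `match_class` set),
#'   or a named count vector/list with entries `exact`, `partial`,
#'   `no_match`, `researcher_segment`.
#' @return List with `model_id`, integer `counts`, `total`, and `strict`,
#'   `expanded`, `comprehensive` (percent).
#' @export
error_rates <- function(x) {
  if (is.data.frame(x)) {
    if (anyNA(x$match_class))
      stop("records must be classified first (see audit_quotes)")
    counts <- count_classes(x$match_class)
    model_id <- if (nrow(x)) x$model_id[1] else NA_character_
  } else {
    counts <- unlist(x)[match_classes()]
    counts[is.na(counts)] <- 0
    names(counts) <- match_classes()
    model_id <- attr(x, "model_id") %||% NA_character_
  }
  total <- sum(counts)
  if (total == 0) stop("no records: error rates undefined")
  list(model_id = model_id, counts = counts, total = total,
       strict = 100 * counts[["no_match"]] / total,
       expanded = 100 * (counts[["no_match"]] +
                           counts[["researcher_segment"]]) / total,
       comprehensive = 100 * (counts[["no_match"]] +
                                counts[["researcher_segment"]] +
                                counts[["partial"]]) / total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize error rates across models
#'
#' Unweighted mean and sample (n-1) standard deviation of the per-model
#' percentages for each rate, plus mean/SD of the raw class counts. With a
#' single model the SDs are `NA`.
#'
#' @param per_model list of [error_rates()] results.
#' @return List of class `"error_rate_summary"` with elements `per_model`
#'   (data frame), `count_summary` (mean/SD per class and total) and
#'   `rate_summary` (mean/SD per rate, in percent).
#' @export
summarize_across_models <- function(per_model) {
  stopifnot(length(per_model) >= 1)
  pm <- do.call(rbind, lapply(per_model, function(r)
    data.frame(model_id = r$model_id, t(r$counts), total = r$total,
               strict = r$strict, expanded = r$expanded,
               comprehensive = r$comprehensive, stringsAsFactors = FALSE)))
  sd_or_na <- function(v) if (length(v) > 1) stats::sd(v) else NA_real_
  count_cols <- c(match_classes(), "total")
  count_summary <- data.frame(
    class = count_cols,
    mean = vapply(count_cols, function(k) mean(pm[[k]]), numeric(1)),
    sd = vapply(count_cols, function(k) sd_or_na(pm[[k]]), numeric(1)),
    stringsAsFactors = FALSE)
  rate_cols <- c("strict", "expanded", "comprehensive")
  rate_summary <- data.frame(
    rate = rate_cols,
    mean = vapply(rate_cols, function(k) mean(pm[[k]]), numeric(1)),
    sd = vapply(rate_cols, function(k) sd_or_na(pm[[k]]), numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(per_model = pm, count_summary = count_summary,
                 rate_summary = rate_summary),
            class = "error_rate_summary")
}

#' @export
print.error_rate_summary <- function(x, ...) {
  cat("<error_rate_summary>\n")
  print(x$per_model, row.names = FALSE)
  cat("across models (rates in %):\n")
  print(transform(x$rate_summary, mean = round(mean, 1), sd = round(sd, 1)),
        row.names = FALSE)
  invisible(x)
}
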