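audit_transcript <- function() {
  transcript(
    c("T001", "T002", "T003"),
    c("facilitator", "participant", "participant"),
    c("Thank you all for joining the session today to discuss the proposal",
      "We as individuals monitor how we respond to changes in our care",
      "You can often read things and then you do a little bit of research"))
}

test_that("quotes classify into the four-class taxonomy with researcher precedence", {
  tr <- audit_transcript()
  pol <- match_policy()
  rec <- quote_records("m",
    segment_id = c("T002", "T002", "T002", "T001", "T999", NA),
    quote = c("We as individuals monitor how we respond",
              # first ~60% of T002 plus invented trailing words
              "We as individuals monitor how we respond to 0000 1111 2222",
              "completely 4871 0392 fabricated 7privacy55 answer",
              "Thank you all for joining the session",
              "We as individuals monitor",
              "you do a little bit of research"),
    code_id = "c1")
  out <- audit_quotes(rec, tr, pol)
  expect_equal(out$match_class,
               c("exact", "partial", "no_match", "researcher_segment",
                 "no_match", "exact"))
  expect_equal(attr(out, "unknown_segments"), "T999")
  # classes are exhaustive and mutually exclusive
  expect_true(all(out$match_class %in% match_classes()))
})

test_that("a verbatim facilitator quote with no claimed segment is still a violation", {
  tr <- audit_transcript()
  rec <- quote_records("m", NA, "Thank you all for joining the session", "c1")
  out <- audit_quotes(rec, tr)
  expect_equal(out$match_class, "researcher_segment")
})

test_that("manual overrides win over the automatic classifier", {
  tr <- audit_transcript()
  rec <- quote_records("m", "T002", "We as individuals monitor how we respond",
                       "c1", match_override = "no_match")
  out <- audit_quotes(rec, tr)
  expect_equal(out$match_class, "no_match")
})

test_that("classification is invariant to normalization-equivalent rewritings", {
  tr <- audit_transcript()
  variants <- c("We as individuals monitor how we respond",
                "we as individuals MONITOR how   we respond",
                "We as individuals monitor how we respond.",
                "“We as individuals monitor how we respond”")
  for (q in variants) {
    out <- audit_quotes(quote_records("m", "T002", q, "c1"), tr)
    expect_equal(out$match_class, "exact", info = q)
  }
  expect_equal(normalize_text("  A’s   b—c! "), "a's b-c")
})

test_that("similarity is the LCS ratio relative to the shorter string", {
  expect_equal(lcs_substring_length("abcdef", "zabcq"), 3L)
  expect_equal(lcs_substring_length("", "abc"), 0L)
  expect_equal(quote_similarity("hello world", "well hello world today"), 1)
  seg <- "one two three four five six seven eight nine ten"
  q <- paste(substr(seg, 1, 30), "0000 1111")  # 60% prefix + invented tail
  sim <- quote_similarity(q, seg)
  expect_gte(sim, 0.5)
  expect_lt(sim, 1)
  expect_equal(sim, 30 / nchar(normalize_text(q)), tolerance = 1e-12)
})

test_that("error rates reproduce the published per-model arithmetic", {
  gpt <- error_rates(c(exact = 31, partial = 2, no_match = 0,
                       researcher_segment = 1))
  expect_equal(gpt$total, 34)
  expect_equal(round(gpt$strict, 1), 0.0)
  expect_equal(round(gpt$expanded, 1), 2.9)
  expect_equal(round(gpt$comprehensive, 1), 8.8)
  quali <- error_rates(c(exact = 45, partial = 3, no_match = 2,
                         researcher_segment = 5))
  expect_equal(round(quali$strict, 1), 3.6)
  expect_equal(round(quali$expanded, 1), 12.7)
  expect_equal(round(quali$comprehensive, 1), 18.2)
  all_exact <- error_rates(c(exact = 10, partial = 0, no_match = 0,
                             researcher_segment = 0))
  expect_equal(c(all_exact$strict, all_exact$expanded,
                 all_exact$comprehensive), c(0, 0, 0))
  expect_error(error_rates(c(exact = 0, partial = 0, no_match = 0,
                             researcher_segment = 0)), "no records")
})

test_that("strict <= expanded <= comprehensive on random count tables", {
  set.seed(13)
  for (i in 1:100) {
    counts <- as.integer(rmultinom(1, sample(1:200, 1), runif(4)))
    names(counts) <- match_classes()
    r <- error_rates(counts)
    expect_lte(r$strict, r$expanded)
    expect_lte(r$expanded, r$comprehensive)
    expect_equal(sum(r$counts), r$total)
  }
})

test_that("across-model summary matches the published means and SDs", {
  counts <- utils::read.csv(study_quote_counts_path())
  per_model <- lapply(seq_len(nrow(counts)), function(i) {
    x <- c(exact = counts$exact[i], partial = counts$partial[i],
           no_match = counts$no_match[i],
           researcher_segment = counts$researcher_segment[i])
    attr(x, "model_id") <- counts$model_id[i]
    error_rates(x)
  })
  s <- summarize_across_models(per_model)
  rs <- s$rate_summary
  expect_equal(round(rs$mean[rs$rate == "strict"], 1), 1.2)
  expect_equal(round(rs$sd[rs$rate == "strict"], 1), 2.1)
  expect_equal(round(rs$mean[rs$rate == "expanded"], 1), 8.6)
  expect_equal(round(rs$sd[rs$rate == "expanded"], 1), 5.1)
  expect_equal(round(rs$mean[rs$rate == "comprehensive"], 1), 12.4)
  expect_equal(round(rs$sd[rs$rate == "comprehensive"], 1), 5.1)

  same <- summarize_across_models(per_model[c(1, 1, 1)])
  expect_true(all(same$rate_summary$sd == 0))
  lone <- summarize_across_models(per_model[1])
  expect_true(all(is.na(lone$rate_summary$sd)))
})
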