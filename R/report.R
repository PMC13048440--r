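fmt_pct <- function(x) sprintf("%.1f", x)
fmt_coef <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
fmt_likert <- function(x) sprintf("%.3f", x)

fmt_ci <- function(point, lo, hi, fmt)
  sprintf("%s (%s–%s)", fmt(point), fmt(lo), fmt(hi))

#' Render an agreement table in the published layout
#'
#' One row per coder, seven metric columns, each "point (low-high)";
#' percentages to 1 decimal, coefficients to 2.
#'
#' @param df output of [agreement_table()].
#' @return A character data frame ready for CSV.
#' @export
format_agreement_table <- function(df) {
  out <- data.frame(coder = df$coder, stringsAsFactors = FALSE)
  out[["Agreement %"]] <- fmt_ci(100 * df$agreement, 100 * df$agreement_low,
                                 100 * df$agreement_high, fmt_pct)
  lab <- c(kappa = "Cohen's κ", ac1 = "Gwet's AC1", jaccard = "Jaccard",
           sensitivity = "Sensitivity", specificity = "Specificity",
           f1 = "F1")
  for (nm in names(lab))
    out[[lab[[nm]]]] <- fmt_ci(df[[nm]], df[[paste0(nm, "_low")]],
                               df[[paste0(nm, "_high")]], fmt_coef)
  out
}

#' Render an error-rate summary in the published layout
#'
#' Count block (per-model n and column-wise %) over the four classes plus
#' the total row, then the three error-rate rows, with across-model
#' mean (SD) — of counts for the count block and of percentages for the
#' rate block.
#'
#' @param summary an [summarize_across_models()] result.
#' @return A character data frame ready for CSV.
#' @export
format_error_table <- function(summary) {
  pm <- summary$per_model
  models <- pm$model_id
  class_label <- c(exact = "Exact match", partial = "Partial match",
                   no_match = "No match",
                   researcher_segment = "Researcher segments coded")
  rows <- list()
  for (k in match_classes()) {
    vals <- vapply(seq_along(models), function(i)
      sprintf("%d (%s%%)", pm[[k]][i], fmt_pct(100 * pm[[k]][i] / pm$total[i])),
      character(1))
    cs <- summary$count_summary
    ms <- sprintf("%.1f (%.1f)", cs$mean[cs$class == k], cs$sd[cs$class == k])
    rows[[k]] <- c(class_label[[k]], vals, ms)
  }
  cs <- summary$count_summary
  rows$total <- c("Total segments coded",
                  sprintf("%d (100%%)", pm$total),
                  sprintf("%.1f (%.1f)", cs$mean[cs$class == "total"],
                          cs$sd[cs$class == "total"]))
  rate_label <- c(strict = "Strict hallucination rate",
                  expanded = "Expanded hallucination rate",
                  comprehensive = "Comprehensive error rate")
  rs <- summary$rate_summary
  for (k in rs$rate) {
    num <- switch(k, strict = pm$no_match,
                  expanded = pm$no_match + pm$researcher_segment,
                  comprehensive = pm$no_match + pm$researcher_segment +
                    pm$partial)
    vals <- sprintf("%d/%d (%s%%)", num, pm$total, fmt_pct(pm[[k]]))
    ms <- sprintf("%s%% (%s%%)", fmt_pct(rs$mean[rs$rate == k]),
                  fmt_pct(rs$sd[rs$rate == k]))
    rows[[k]] <- c(rate_label[[k]], vals, ms)
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("Metric", models, "Mean (SD)")
  rownames(out) <- NULL
  out
}

#' Render a Likert table with the column mean (95% CI) footer row
#'
#' @param table a [likert_table()].
#' @param ci_level confidence level for the footer.
#' @return A character data frame ready for CSV (means to 3 decimals).
#' @export
format_likert_report <- function(table, ci_level = 0.95) {
  sc <- table$scores
  out <- data.frame(code = rownames(sc), stringsAsFactors = FALSE)
  for (a in colnames(sc)) out[[a]] <- as.character(sc[, a])
  footer <- c("Mean (95% CI)", vapply(colnames(sc), function(a) {
    ci <- likert_mean_ci(sc[, a], ci_level)
    fmt_ci(ci[["mean"]], ci[["ci_low"]], ci[["ci_high"]], fmt_likert)
  }, character(1)))
  rbind(out, stats::setNames(as.list(footer), names(out)))
}

#' Render a comparison-result table (forest-plot style summary)
#'
#' @param df output of [deductive_noninferiority()] or
#'   [inductive_noninferiority()].
#' @return A character data frame with effect, CI, margin and p columns.
#' @export
format_comparison_table <- function(df) {
  data.frame(
    model = df$model_id,
    `effect (95% CI)` = fmt_ci(df$effect, df$ci_low, df$ci_high,
                               function(x) sprintf("%.3f", x)),
    margin = sprintf("-%.3g", df$margin),
    `p (non-inferiority, Holm)` = sprintf("%.3f", df$p_holm_noninferior),
    `p (superiority, Holm)` = sprintf("%.3f", df$p_holm_superior),
    noninferior = df$verdict_noninferior,
    superior = df$verdict_superior,
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write all available result tables to CSV
#'
#' Recognized elements of `results`: `agreement` ([agreement_table()]
#' output), `likert` (a [likert_table()]), `audit`
#' ([summarize_across_models()] output), `deductive` / `inductive`
#' (comparison-result data frames), `kappa_by_code` (a data frame). Each is
#' rendered in its published layout and written as `<name>.csv`; an empty
#' element yields a header-only file.
#'
#' @param results named list of computed results.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report_tables <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    written[[name]] <<- path
  }
  if (!is.null(results$agreement))
    emit(format_agreement_table(results$agreement), "agreement")
  if (!is.null(results$kappa_by_code))
    emit(results$kappa_by_code, "kappa_by_code")
  if (!is.null(results$likert))
    emit(format_likert_report(results$likert), "likert")
  if (!is.null(results$deductive))
    emit(format_comparison_table(results$deductive), "deductive_comparison")
  if (!is.null(results$inductive))
    emit(format_comparison_table(results$inductive), "inductive_comparison")
  if (!is.null(results$audit))
    emit(format_error_table(results$audit), "error_audit")
  invisible(written)
}

config_hash <- function(config) {
  # hash the scientific configuration only: output locations do not affect
  # results, so re-runs into different directories hash identically
  cfg <- config[setdiff(names(config), c("out_dir", "fixtures_dir"))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run pipeline stages over simulated or supplied inputs
#'
#' A thin stage runner: `"simulate"` writes a complete fixture set
#' (transcript, reference and coder matrices, Likert table, quote records)
#' under `out_dir/fixtures`; the analysis stages (`"agreement"`,
#' `"compare-deductive"`, `"compare-inductive"`, `"audit"`) read those
#' fixtures (or the paths in `config`), compute, and write report tables, a
#' machine-readable `results.json` and a `run.log` recording the seed, the
#' config hash and input hashes. `"all"` runs everything.
#'
#' @param config list with `task` (one of simulate, agreement,
#'   compare-deductive, compare-inductive, audit, all), `seed`, `B`,
#'   `margin_ac1`, `margin_likert`, `alpha`, `out_dir`, and optional input
#'   paths `fixtures_dir`, `likert_path`.
#' @return Named list of computed results, invisibly.
#' @export
run_pipeline <- function(config) {
  defaults <- list(task = "all", seed = 1, B = 1000, margin_ac1 = 0.03,
                   margin_likert = 0.5, alpha = 0.05, out_dir = "results")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  tasks <- c("simulate", "agreement", "compare-deductive",
             "compare-inductive", "audit", "all")
  if (!config$task %in% tasks)
    stop("invalid config field 'task': must be one of ",
         paste(tasks, collapse = ", "))
  if (config$margin_ac1 <= 0 || config$margin_likert <= 0)
    stop("invalid config field 'margin': margins must be positive")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fix_dir <- config$fixtures_dir %||% file.path(config$out_dir, "fixtures")
  log_path <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  cat(sprintf("seed=%d config_hash=%s\n", config$seed, config_hash(config)),
      file = log_path)

  want <- function(t) config$task %in% c(t, "all")
  results <- list(seed = config$seed, config_hash = config_hash(config))

  if (want("simulate")) {
    dir.create(fix_dir, recursive = TRUE, showWarnings = FALSE)
    dspec <- deductive_sim_spec(seed = config$seed)
    ref <- generate_reference(dspec)
    write_coding_matrix(ref, file.path(fix_dir, "reference.json"))
    profiles <- list(human_1 = dspec$human_profile,
                     human_2 = dspec$human_profile,
                     model_1 = dspec$model_profile,
                     model_2 = dspec$model_profile,
                     model_3 = dspec$model_profile)
    for (i in seq_along(profiles)) {
      id <- names(profiles)[i]
      cm <- simulate_coder(ref, profiles[[i]][["sensitivity"]],
                           profiles[[i]][["specificity"]],
                           seed = config$seed + i, coder_id = id)
      write_coding_matrix(cm, file.path(fix_dir, paste0(id, ".json")))
    }
    lt <- generate_likert(likert_sim_spec(seed = config$seed))
    write_likert_table(lt, file.path(fix_dir, "likert.csv"))
    sim <- generate_transcript_with_quotes(
      transcript_sim_spec(seed = config$seed))
    write_transcript(sim$transcript, file.path(fix_dir, "transcript.json"))
    write_quote_records(sim$records, file.path(fix_dir, "quotes_model_1.json"))
    logline("stage=simulate fixtures=%s", fix_dir)
  }

  load_matrix <- function(name) {
    path <- file.path(fix_dir, paste0(name, ".json"))
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    segs <- unlist(raw$segments)
    tr <- transcript(segs, rep("participant", length(segs)),
                     rep("(simulated)", length(segs)))
    cb <- codebook(unlist(raw$codes))
    read_coding_matrix(path, cb, tr)
  }

  if (want("agreement") || want("compare-deductive")) {
    ref <- load_matrix("reference")
    coders <- stats::setNames(
      lapply(c("human_1", "human_2", "model_1", "model_2", "model_3"),
             load_matrix),
      c("human_1", "human_2", "model_1", "model_2", "model_3"))
    if (want("agreement")) {
      results$agreement <- agreement_table(
        ref, coders,
        groups = list(human = c("human_1", "human_2"),
                      model = c("model_1", "model_2", "model_3")),
        B = config$B, seed = config$seed)
      logline("stage=agreement coders=%d B=%d", length(coders), config$B)
    }
    if (want("compare-deductive")) {
      results$deductive <- deductive_noninferiority(
        coders[c("model_1", "model_2", "model_3")],
        coders[c("human_1", "human_2")], ref,
        margin = config$margin_ac1, B = config$B, seed = config$seed,
        alpha = config$alpha)
      logline("stage=compare-deductive B=%d margin=%g", config$B,
              config$margin_ac1)
    }
  }

  if (want("compare-inductive")) {
    lik_path <- config$likert_path %||% file.path(fix_dir, "likert.csv")
    lt <- read_likert_table(lik_path)
    ids <- colnames(lt$scores)
    results$likert <- lt
    results$inductive <- inductive_noninferiority(
      lt, grep("^human", ids, value = TRUE, invert = TRUE),
      grep("^human", ids, value = TRUE),
      margin = config$margin_likert, alpha = config$alpha)
    logline("stage=compare-inductive input=%s hash=%s", lik_path,
            unname(tools::md5sum(lik_path)))
  }

  if (want("audit")) {
    tr <- read_transcript(file.path(fix_dir, "transcript.json"))
    rec <- read_quote_records(file.path(fix_dir, "quotes_model_1.json"))
    audited <- audit_quotes(rec, tr)
    results$audit <- summarize_across_models(list(error_rates(audited)))
    logline("stage=audit records=%d", nrow(audited))
  }

  write_report_tables(results, config$out_dir)
  json <- list(seed = config$seed, config_hash = results$config_hash)
  if (!is.null(results$inductive))
    json$inductive <- results$inductive[,
      c("model_id", "effect", "p_holm_noninferior", "p_holm_superior")]
  if (!is.null(results$deductive))
    json$deductive <- results$deductive[,
      c("model_id", "effect", "p_holm_noninferior", "p_holm_superior")]
  if (!is.null(results$audit)) json$audit <- results$audit$rate_summary
  jsonlite::write_json(json, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  invisible(results)
}
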