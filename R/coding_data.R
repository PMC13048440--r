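#' Construct a transcript of speaker-turn segments
#'
#' A transcript is an ordered set of segments, each with a unique id, a
#' speaker role (`"participant"` or `"facilitator"`) and non-empty text.
#' Facilitator (researcher) segments are retained — the quote audit needs
#' them — but deductive coding matrices may only label participant segments.
#'
#' @param id character vector of unique segment ids (e.g. `"T037"`).
#' @param speaker_role character vector, each `"participant"` or
#'   `"facilitator"`.
#' @param text character vector of non-empty segment texts.
#' @return A data frame of class `"transcript"` with columns `id`,
#'   `speaker_role`, `text`.
#' @export
transcript <- function(id, speaker_role, text) {
  id <- as.character(id)
  speaker_role <- as.character(speaker_role)
  text <- as.character(text)
  if (length(id) != length(speaker_role) || length(id) != length(text))
    stop("id, speaker_role and text must have equal length")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate segment id(s): ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(speaker_role), c("participant", "facilitator"))
  if (length(bad))
    stop("unknown speaker_role(s): ", paste(bad, collapse = ", "))
  if (any(is.na(text) | !nzchar(trimws(text))) && length(text))
    stop("segment text must be non-empty")
  out <- data.frame(id = id, speaker_role = speaker_role, text = text,
                    stringsAsFactors = FALSE)
  class(out) <- c("transcript", "data.frame")
  out
}

#' Read a transcript from JSON
#'
#' The expected dialect is an array of objects with fields `"id"`,
#' `"speaker_role"` and `"text"`. An empty array yields an empty transcript
#' (downstream operations that need segments reject it themselves).
#'
#' @param path path to a JSON file.
#' @return A `"transcript"` data frame; see [transcript()].
#' @export
read_transcript <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(raw) == 0)
    return(transcript(character(), character(), character()))
  if (!is.data.frame(raw))
    stop("transcript JSON must be an array of objects")
  need <- c("id", "speaker_role", "text")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("transcript records missing field(s): ", paste(miss, collapse = ", "))
  transcript(raw$id, raw$speaker_role, raw$text)
}

#' Write a transcript to JSON
#' @param x a `"transcript"` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(x, path) {
  jsonlite::write_json(data.frame(id = x$id, speaker_role = x$speaker_role,
                                  text = x$text),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Construct a codebook
#'
#' Codes are the unit of deductive labelling; each code belongs to exactly
#' one theme. The deductive study design used 10 codes in 6 themes, the
#' inductive reference 14 codes in 5 themes, but any sizes are accepted.
#'
#' @param code_id unique code identifiers.
#' @param label short human-readable labels (defaults to `code_id`).
#' @param definition free-text definitions (optional).
#' @param theme_label theme each code belongs to (defaults to one theme).
#' @return A data frame of class `"codebook"`.
#' @export
codebook <- function(code_id, label = code_id, definition = "",
                     theme_label = "theme") {
  code_id <- as.character(code_id)
  dup <- unique(code_id[duplicated(code_id)])
  if (length(dup))
    stop("duplicate code id(s): ", paste(dup, collapse = ", "))
  out <- data.frame(code_id = code_id,
                    label = rep_len(as.character(label), length(code_id)),
                    definition = rep_len(as.character(definition), length(code_id)),
                    theme_label = rep_len(as.character(theme_label), length(code_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("codebook", "data.frame")
  out
}

#' Construct a deductive coding matrix
#'
#' One coder's binary labels over participant segments crossed with codes: a
#' complete logical rectangle. The study instance is 124 participant
#' segments by 10 codes, i.e. 1240 cells per coder.
#'
#' @param coder_id single string identifying the coder.
#' @param labels logical matrix, rows = segments, columns = codes, with
#'   dimnames set to segment and code ids.
#' @return An object of class `"coding_matrix"`.
#' @export
coding_matrix <- function(coder_id, labels) {
  stopifnot(is.character(coder_id), length(coder_id) == 1L)
  if (!is.matrix(labels) || !is.logical(labels))
    stop("labels must be a logical matrix")
  if (is.null(rownames(labels)) || is.null(colnames(labels)))
    stop("labels must carry segment ids as rownames and code ids as colnames")
  if (anyNA(labels))
    stop("labels must not contain NA")
  if (anyDuplicated(rownames(labels)) || anyDuplicated(colnames(labels)))
    stop("duplicate segment or code ids in labels")
  structure(list(coder_id = coder_id, labels = labels),
            class = "coding_matrix")
}

#' @export
print.coding_matrix <- function(x, ...) {
  cat(sprintf("<coding_matrix> coder '%s': %d segments x %d codes (%d cells, %d positive)\n",
              x$coder_id, nrow(x$labels), ncol(x$labels),
              length(x$labels), sum(x$labels)))
  invisible(x)
}

#' @export
dim.coding_matrix <- function(x) dim(x$labels)

segment_ids <- function(m) rownames(m$labels)
code_ids <- function(m) colnames(m$labels)

#' Read a deductive coding matrix from JSON
#'
#' Dense dialect: `{"coder_id", "codes": [...], "segments": [...],
#' "labels": {segment: {code: bool}}}` with every cell present. Sparse
#' dialect: the same envelope with `"mode": "sparse"` and `"true_cells":
#' [{"segment", "code"}]`; unlisted cells default to `FALSE`. Without the
#' explicit sparse declaration, a missing cell is an error.
#'
#' Only participant segments may be labelled: a `TRUE` label on a
#' facilitator segment violates the rule that researcher segments are not
#' coded, and is rejected.
#'
#' @param path path to a JSON coding file.
#' @param codebook a [codebook()]; the file's codes must match.
#' @param segments a [transcript()]; the file's segments must be known and
#'   the resulting matrix is restricted to participant segments.
#' @return A [coding_matrix()].
#' @export
read_coding_matrix <- function(path, codebook, segments) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("coder_id", "codes", "segments"))
    if (is.null(raw[[f]])) stop("coding file missing field: ", f)
  codes <- unlist(raw$codes)
  segs <- unlist(raw$segments)
  unknown_codes <- setdiff(codes, codebook$code_id)
  if (length(unknown_codes))
    stop("unknown code id(s): ", paste(unknown_codes, collapse = ", "))
  unknown_segs <- setdiff(segs, segments$id)
  if (length(unknown_segs))
    stop("unknown segment id(s): ", paste(unknown_segs, collapse = ", "))
  role <- segments$speaker_role[match(segs, segments$id)]
  sparse <- identical(raw$mode, "sparse")
  lab <- matrix(FALSE, nrow = length(segs), ncol = length(codes),
                dimnames = list(segs, codes))
  if (sparse) {
    for (cell in raw$true_cells) {
      s <- cell$segment; k <- cell$code
      if (is.null(s) || is.null(k) || !(s %in% segs) || !(k %in% codes))
        stop("sparse true_cell references unknown segment/code: ",
             paste(c(s, k), collapse = "/"))
      lab[s, k] <- TRUE
    }
  } else {
    for (s in segs) {
      row <- raw$labels[[s]]
      if (is.null(row)) stop("missing labels for segment ", s)
      for (k in codes) {
        v <- row[[k]]
        if (is.null(v) || !is.logical(v) && !is.numeric(v))
          stop("missing label for cell (", s, ", ", k, ")")
        lab[s, k] <- as.logical(v)
      }
    }
  }
  viol <- segs[role == "facilitator" & rowSums(lab) > 0]
  if (length(viol))
    stop("facilitator segment(s) carry code labels (researcher segments ",
         "are not coded): ", paste(viol, collapse = ", "))
  keep <- role == "participant"
  coding_matrix(as.character(raw$coder_id), lab[keep, , drop = FALSE])
}

#' Write a coding matrix to JSON
#'
#' @param x a [coding_matrix()].
#' @param path output path.
#' @param sparse write the sparse dialect (true cells plus declared
#'   universe) instead of the dense cell map.
#' @return `path`, invisibly.
#' @export
write_coding_matrix <- function(x, path, sparse = FALSE) {
  segs <- segment_ids(x); codes <- code_ids(x)
  if (sparse) {
    idx <- which(x$labels, arr.ind = TRUE)
    cells <- lapply(seq_len(nrow(idx)), function(i)
      list(segment = segs[idx[i, 1]], code = codes[idx[i, 2]]))
    doc <- list(coder_id = x$coder_id, mode = "sparse",
                codes = as.list(codes), segments = as.list(segs),
                true_cells = cells)
  } else {
    labels <- lapply(segs, function(s) {
      row <- as.list(x$labels[s, ])
      names(row) <- codes
      row
    })
    names(labels) <- segs
    doc <- list(coder_id = x$coder_id, codes = as.list(codes),
                segments = as.list(segs), labels = labels)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Construct a Likert agreement table
#'
#' Integer agreement scores 1–5 over a complete codes-by-analysts
#' rectangle, as used for the inductive coding comparison (5 = complete
#' alignment with the adjudicated reference themes, 1 = poor agreement).
#'
#' @param scores integer matrix, rows = codes, columns = analysts, with
#'   dimnames; every entry in 1..5.
#' @return An object of class `"likert_table"`.
#' @export
likert_table <- function(scores) {
  if (!is.matrix(scores)) stop("scores must be a matrix")
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores must carry code labels as rownames and analyst ids as colnames")
  if (anyNA(scores)) stop("scores must be complete (no NA)")
  if (any(scores != round(scores)))
    stop("Likert scores must be integers")
  if (any(scores < 1 | scores > 5))
    stop("Likert scores must lie in 1..5")
  storage.mode(scores) <- "integer"
  structure(list(scores = scores), class = "likert_table")
}

#' @export
print.likert_table <- function(x, ...) {
  cat(sprintf("<likert_table> %d codes x %d analysts\n",
              nrow(x$scores), ncol(x$scores)))
  print(x$scores, ...)
  invisible(x)
}

#' Read a Likert table from CSV
#'
#' First column: code label; remaining columns: one integer score (1–5) per
#' analyst. Ragged or non-integer input is rejected.
#'
#' @param path path to a CSV file.
#' @return A [likert_table()].
#' @export
read_likert_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("Likert CSV needs a code column plus >=1 analyst column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("Likert scores must be numeric integers 1..5")
  rownames(m) <- df[[1]]
  likert_table(m)
}

#' Write a Likert table to CSV
#' @param x a [likert_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_likert_table <- function(x, path) {
  df <- data.frame(code = rownames(x$scores), x$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct quote-verification records
#'
#' One record per evidence claim emitted by a model: the claimed segment id
#' (possibly `NA`), the verbatim quote, and the assigned code. The audit
#' ([audit_quotes()]) fills `match_class`; a non-`NA` `match_override`
#' replays a manual audit verdict and wins over the automatic classifier.
#'
#' @param model_id single string.
#' @param segment_id character vector (NA allowed).
#' @param quote character vector of quoted evidence text.
#' @param code_id character vector of assigned codes.
#' @param match_override optional character vector with entries in
#'   `c("exact", "partial", "no_match", "researcher_segment")` or `NA`.
#' @return A data frame of class `"quote_records"`.
#' @export
quote_records <- function(model_id, segment_id, quote, code_id,
                          match_override = NA_character_) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  n <- max(length(segment_id), length(quote), length(code_id))
  ov <- rep_len(as.character(match_override), n)
  bad <- setdiff(ov[!is.na(ov)], match_classes())
  if (length(bad))
    stop("invalid match_override value(s): ", paste(bad, collapse = ", "))
  out <- data.frame(model_id = model_id,
                    segment_id = rep_len(as.character(segment_id), n),
                    quote = rep_len(as.character(quote), n),
                    code_id = rep_len(as.character(code_id), n),
                    match_override = ov,
                    match_class = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("quote_records", "data.frame")
  out
}

#' The four mutually exclusive quote audit classes
#' @return Character vector of the class names, in reporting order.
#' @export
match_classes <- function()
  c("exact", "partial", "no_match", "researcher_segment")

#' Read quote-verification records from JSON
#'
#' Dialect: `{"model_id", "records": [{"segment_id", "quote", "code_id",
#' "match_override"?}]}`.
#'
#' @param path path to a JSON file.
#' @return A [quote_records()] data frame.
#' @export
read_quote_records <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$model_id)) stop("quote file missing model_id")
  rec <- raw$records
  if (is.null(rec) || length(rec) == 0)
    return(quote_records(raw$model_id, character(), character(), character()))
  quote_records(raw$model_id,
                if (is.null(rec$segment_id)) NA_character_ else rec$segment_id,
                rec$quote, rec$code_id,
                if (is.null(rec$match_override)) NA_character_ else rec$match_override)
}

#' Write quote-verification records to JSON
#' @param x a [quote_records()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quote_records <- function(x, path) {
  doc <- list(model_id = x$model_id[1],
              records = data.frame(segment_id = x$segment_id,
                                   quote = x$quote, code_id = x$code_id,
                                   match_override = x$match_override,
                                   stringsAsFactors = FALSE))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
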