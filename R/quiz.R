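# The nine-item comprehension battery, its brute-force answer oracle, the
# 0-10 grading rubric, and the pre-task tutorial gate.
#
# Battery shape (fixed):
#   Q1, Q2  count fill-ins
#   Q3-Q5   comparison choices over {Greater than, Equal to, Less than,
#           I don't know}
#   Q6      open response naming variants worth discussing with a clinician
#   Q7, Q8  condition-risk choices (same four options)
#   Q9      select-all-that-apply over condition names
#
# Rubric (totals 10): Q1-Q5, Q7, Q8 one point each on exact match; Q6 one
# point, partial credit (hits minus false names, floored at zero, over the
# key size), gene symbols matched case-insensitively; Q9 two points scaled
# by option-level agreement with the key. Blanks score zero; a response
# token outside an item's option set scores zero for that item.

CHOICE_OPTIONS <- c("Greater than", "Equal to", "Less than", "I don't know")
QUESTION_IDS <- paste0("Q", 1:9)
QUESTION_KINDS <- c(Q1 = "count_fill", Q2 = "count_fill",
                    Q3 = "comparison_choice", Q4 = "comparison_choice",
                    Q5 = "comparison_choice", Q6 = "open_variants",
                    Q7 = "risk_choice", Q8 = "risk_choice",
                    Q9 = "multi_select")
LIKERT_IDS <- paste0("Q", 10:16)

# Signed risk score of each linked condition: sum over linked variants of
# sign(impact) x importance weight (pathogenic +, protective -, benign 0).
signed_risk_scores <- function(dataset) {
  v <- dataset$variants
  pool <- sort(unique(unlist(v$conditions)))
  if (!length(pool)) return(setNames(numeric(0), character(0)))
  sgn <- c(pathogenic = 1, benign = 0, protective = -1)[v$impact]
  wt <- IMPORTANCE_WEIGHTS[v$importance]
  scores <- vapply(pool, function(cond) {
    linked <- vapply(v$conditions, function(el) cond %in% el, logical(1))
    sum(sgn[linked] * wt[linked])
  }, numeric(1))
  scores
}

# Deterministic choice of the two risk-item conditions: the condition with
# the largest signed score (ties alphabetical) and the one with the
# smallest. Datasets meant for the battery should make these unambiguous.
risk_conditions <- function(dataset) {
  scores <- signed_risk_scores(dataset)
  if (length(scores) < 2L) {
    stop("battery needs at least 2 linked conditions in the dataset",
         call. = FALSE)
  }
  nm <- names(scores)  # already alphabetical
  c(positive = nm[which.max(scores)], negative = nm[which.min(scores)])
}

#' Build the nine-question comprehension battery for a dataset
#'
#' Prompts are templated on the dataset's subject name; the two risk items
#' are instantiated on the dataset's most risk-increasing and most
#' risk-decreasing linked conditions, and the select-all item's options are
#' the remaining pool conditions (alphabetical, at most eight).
#'
#' @param dataset a `report_dataset` with at least two linked conditions.
#' @return list of class `quiz_battery`; each element has `id`, `kind`,
#'   `prompt`, and where applicable `options` / `condition`.
#' @export
build_battery <- function(dataset) {
  subj <- dataset$subject
  rc <- risk_conditions(dataset)
  pool <- sort(unique(unlist(dataset$variants$conditions)))
  q9_options <- setdiff(pool, unname(rc))
  q9_options <- q9_options[seq_len(min(8L, length(q9_options)))]
  if (!length(q9_options)) q9_options <- sort(unname(rc))
  q <- function(id, prompt, options = NULL, condition = NULL) {
    list(id = id, kind = unname(QUESTION_KINDS[id]), prompt = prompt,
         options = options, condition = condition)
  }
  battery <- list(
    q("Q1", "The number of variants with high clinical importance: _______"),
    q("Q2", "The number of variants that are well-established pathogenic: _______"),
    q("Q3", sprintf(paste0("Based on the information above, the number of ",
                           "variants in %s's report with low clinical ",
                           "importance is ________ the number of variants ",
                           "with high clinical importance."), subj),
      CHOICE_OPTIONS),
    q("Q4", sprintf(paste0("Based on the information above, the number of ",
                           "uncertain pathogenic variants in %s's report is ",
                           "________ the number of well-established ",
                           "pathogenic variants."), subj), CHOICE_OPTIONS),
    q("Q5", sprintf(paste0("Based on the information above, the number of ",
                           "potentially pathogenic variants in %s's report ",
                           "is ________ the number of potentially benign or ",
                           "protective variants."), subj), CHOICE_OPTIONS),
    q("Q6", sprintf(paste0("Which variants would %s be most likely to ",
                           "discuss with a health care provider?"), subj)),
    q("Q7", sprintf("Based on the information above, %s's risk of developing %s is ________ the average person.",
                    subj, rc[["positive"]]), CHOICE_OPTIONS,
      rc[["positive"]]),
    q("Q8", sprintf("Based on the information above, %s's risk of developing %s is ________ the average person.",
                    subj, rc[["negative"]]), CHOICE_OPTIONS,
      rc[["negative"]]),
    q("Q9", sprintf(paste0("If you were %s, knowing this information, which ",
                           "of the following conditions would you be ",
                           "interested in learning more about? Select all ",
                           "that apply."), subj), q9_options)
  )
  names(battery) <- QUESTION_IDS
  structure(battery, class = "quiz_battery")
}

cmp_token <- function(a, b) {
  if (a > b) "Greater than" else if (a < b) "Less than" else "Equal to"
}

risk_token <- function(score) {
  if (score > 0) "Greater than" else if (score < 0) "Less than"
  else "Equal to"
}

#' Ground-truth answer key, derived from the dataset by brute force
#'
#' Every answer is recomputed directly from the variant table: counts for
#' Q1/Q2, count comparisons for Q3-Q5, the high-importance pathogenic
#' variants for Q6, the signed risk rule for Q7/Q8 (positive total ->
#' "Greater than", negative -> "Less than", zero or unlinked -> "Equal to"),
#' and for Q9 the option conditions linked to at least one pathogenic
#' variant of medium or high importance.
#'
#' @param dataset a `report_dataset`.
#' @param battery optional battery (rebuilt when omitted).
#' @return list of class `answer_key` with entries `q1`..`q9` plus the
#'   grading context `q6_genes`, `q6_labels`, `q9_options`.
#' @export
oracle_answers <- function(dataset, battery = build_battery(dataset)) {
  v <- dataset$variants
  n_high <- sum(v$importance == "high")
  n_low <- sum(v$importance == "low")
  n_wep <- sum(v$impact == "pathogenic" & v$evidence == "well-established")
  n_up <- sum(v$impact == "pathogenic" & v$evidence == "uncertain")
  n_path <- sum(v$impact == "pathogenic")
  n_other <- sum(v$impact %in% c("benign", "protective"))
  q6_rows <- v$importance == "high" & v$impact == "pathogenic"
  scores <- signed_risk_scores(dataset)
  risk_of <- function(cond) risk_token(if (cond %in% names(scores))
    scores[[cond]] else 0)
  q9_options <- battery$Q9$options
  q9_key <- vapply(q9_options, function(cond) {
    any(vapply(seq_len(nrow(v)), function(i) {
      cond %in% v$conditions[[i]] && v$impact[i] == "pathogenic" &&
        v$importance[i] %in% c("medium", "high")
    }, logical(1)))
  }, logical(1))
  structure(list(
    q1 = n_high,
    q2 = n_wep,
    q3 = cmp_token(n_low, n_high),
    q4 = cmp_token(n_up, n_wep),
    q5 = cmp_token(n_path, n_other),
    q6_labels = v$label[q6_rows],
    q6_genes = toupper(v$gene[q6_rows]),
    q7 = risk_of(battery$Q7$condition),
    q8 = risk_of(battery$Q8$condition),
    q9 = q9_options[q9_key],
    q9_options = q9_options
  ), class = "answer_key")
}

# First whitespace-separated word, uppercased: the gene symbol of a named
# variant label ("GENE004 p.R12W" -> "GENE004").
response_genes <- function(tokens) {
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  unique(toupper(sub("\\s.*$", "", tokens)))
}

split_resp <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

grade_one <- function(id, response, key) {
  resp <- if (is.na(response)) "" else trimws(as.character(response))
  switch(id,
    Q1 = , Q2 = {
      keyval <- if (id == "Q1") key$q1 else key$q2
      num <- suppressWarnings(as.numeric(resp))
      if (nzchar(resp) && !is.na(num) && num == keyval) 1 else 0
    },
    Q3 = , Q4 = , Q5 = , Q7 = , Q8 = {
      keyval <- key[[tolower(id)]]
      if (!nzchar(resp)) return(0)
      if (!(resp %in% CHOICE_OPTIONS)) return(0)  # out-of-option token
      if (resp == keyval) 1 else 0
    },
    Q6 = {
      named <- response_genes(split_resp(resp))
      k <- length(key$q6_genes)
      if (k == 0L) return(if (length(named)) 0 else 1)
      hits <- length(intersect(named, key$q6_genes))
      misses <- length(setdiff(named, key$q6_genes))
      max(0, hits - misses) / k
    },
    Q9 = {
      sel <- split_resp(resp)
      # an empty selection only counts as an answer when the key itself is
      # the empty set; against a non-empty key it is a blank (0)
      if (!length(sel) && length(key$q9)) return(0)
      opts <- key$q9_options
      if (length(setdiff(sel, opts))) return(0)  # out-of-option token
      agree <- sum((opts %in% sel) == (opts %in% key$q9))
      2 * agree / length(opts)
    })
}

#' Grade one participant's response sheet
#'
#' Applies the 0-10 rubric against an answer key. Blank items score zero;
#' response tokens outside an item's option set score zero for that item.
#'
#' @param sheet one-row data.frame (or list) with elements `participant`,
#'   `condition` and `q1`..`q9` (character; `q6`/`q9` ";"-joined).
#' @param key an `answer_key`.
#' @return list of class `score_record`: `participant`, `condition`,
#'   `score` in \[0, 10\], and the per-question `credits` vector.
#' @export
grade_response <- function(sheet, key) {
  credits <- vapply(QUESTION_IDS, function(id) {
    grade_one(id, sheet[[tolower(id)]], key)
  }, numeric(1))
  score <- min(10, max(0, sum(credits)))
  structure(list(participant = as.character(sheet$participant %||% NA),
                 condition = as.character(sheet$condition %||% NA),
                 score = score, credits = credits),
            class = "score_record")
}

#' Grade a cohort of response sheets
#'
#' @param sheets data.frame of response sheets (one row each; see
#'   [simulate_responses()] / [read_responses()]).
#' @param key an `answer_key`.
#' @return data.frame with `participant`, `condition`, `score` and one
#'   credit column per question.
#' @export
grade_cohort <- function(sheets, key) {
  recs <- lapply(seq_len(nrow(sheets)), function(i) {
    r <- grade_response(sheets[i, , drop = FALSE], key)
    c(list(participant = r$participant, condition = r$condition,
           score = r$score), as.list(setNames(r$credits,
                                              tolower(QUESTION_IDS))))
  })
  out <- do.call(rbind, lapply(recs, as.data.frame,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Tutorial exclusion gate
#'
#' Participants first work through an introductory tutorial and answer a
#' six-item check; a participant is included in the analysis only when at
#' least three of the six answers are correct.
#'
#' @param result logical (or 0/1) vector of length six.
#' @return `TRUE` (include) or `FALSE` (exclude).
#' @export
tutorial_gate <- function(result) {
  result <- as.logical(result)
  if (length(result) != 6L || anyNA(result)) {
    stop("tutorial result must be six TRUE/FALSE items", call. = FALSE)
  }
  sum(result) >= 3L
}

# ---------------------------------------------------------------------------
# Battery / key / response-sheet serialization

#' Export a battery and key as JSON
#'
#' @param battery a `quiz_battery`.
#' @param key an `answer_key`.
#' @param path optional output file.
#' @return JSON text.
#' @export
quiz_json <- function(battery, key, path = NULL) {
  doc <- list(
    battery = lapply(unclass(battery), function(qq) {
      out <- list(id = jsonlite::unbox(qq$id), kind = jsonlite::unbox(qq$kind),
                  prompt = jsonlite::unbox(qq$prompt))
      if (!is.null(qq$options)) out$options <- as.list(qq$options)
      if (!is.null(qq$condition)) {
        out$condition <- jsonlite::unbox(qq$condition)
      }
      out
    }),
    key = list(q1 = jsonlite::unbox(key$q1), q2 = jsonlite::unbox(key$q2),
               q3 = jsonlite::unbox(key$q3), q4 = jsonlite::unbox(key$q4),
               q5 = jsonlite::unbox(key$q5),
               q6_labels = as.list(key$q6_labels),
               q6_genes = as.list(key$q6_genes),
               q7 = jsonlite::unbox(key$q7), q8 = jsonlite::unbox(key$q8),
               q9 = as.list(key$q9), q9_options = as.list(key$q9_options)))
  out <- paste0(jsonlite::toJSON(doc, pretty = TRUE), "\n")
  if (!is.null(path)) writeLines(out, path, sep = "")
  out
}

#' Read an answer key back from quiz JSON
#'
#' @param source path or JSON text produced by [quiz_json()].
#' @return an `answer_key`.
#' @export
read_quiz_key <- function(source) {
  doc <- jsonlite::fromJSON(read_source_text(source), simplifyVector = FALSE)
  k <- doc$key
  chr <- function(x) as.character(unlist(x) %||% character(0))
  structure(list(
    q1 = as.numeric(k$q1), q2 = as.numeric(k$q2),
    q3 = as.character(k$q3), q4 = as.character(k$q4),
    q5 = as.character(k$q5),
    q6_labels = chr(k$q6_labels), q6_genes = chr(k$q6_genes),
    q7 = as.character(k$q7), q8 = as.character(k$q8),
    q9 = chr(k$q9), q9_options = chr(k$q9_options)), class = "answer_key")
}

RESPONSE_COLUMNS <- c("participant", "condition", tolower(QUESTION_IDS),
                      tolower(LIKERT_IDS), "started_at", "finished_at")

#' Read / write participant response sheets
#'
#' CSV with columns `participant,condition,q1..q9,q10..q16,started_at,
#' finished_at`; `q6` and `q9` are ";"-joined. Likert items q10..q16 are
#' integers 1..5 or blank.
#'
#' @param source file path or CSV text.
#' @return data.frame of response sheets.
#' @export
read_responses <- function(source) {
  txt <- read_source_text(source)
  df <- read.csv(text = txt, stringsAsFactors = FALSE,
                 colClasses = "character")
  missing_cols <- setdiff(RESPONSE_COLUMNS, names(df))
  if (length(missing_cols)) {
    parse_error(paste0("response sheet missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  for (l in tolower(LIKERT_IDS)) {
    val <- suppressWarnings(as.integer(df[[l]]))
    bad <- which(!is.na(val) & (val < 1L | val > 5L))
    if (length(bad)) {
      validation_error(violation(l, paste0("row ", bad[1]),
                                 "Likert responses must be 1..5 or blank"))
    }
    df[[l]] <- val
  }
  df[RESPONSE_COLUMNS]
}

#' @rdname read_responses
#' @param sheets data.frame of response sheets.
#' @param path optional output file.
#' @return `write_responses`: the CSV text, invisibly when `path` is given.
#' @export
write_responses <- function(sheets, path = NULL) {
  df <- sheets[RESPONSE_COLUMNS]
  con <- textConnection("out", "w", local = TRUE)
  write.csv(df, con, row.names = FALSE, na = "")
  close(con)
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
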