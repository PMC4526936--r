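# Data model, validation and I/O for annotated gene-variant reports.
#
# A report is a collection of gene variants, each carrying the reading-level
# annotation fields of consumer variant-interpretation reports: the variant's
# potential impact (pathogenic / benign / protective), the certainty of the
# evidence behind that call (well-established / likely / uncertain), its
# clinical importance (low / medium / high), population allele frequency,
# linked medical conditions, a free-text summary, and external links.

# Normalize an enumeration token: case-insensitive, with space/underscore
# runs treated as hyphens ("Well established" -> "well-established").
# Anything that then fails to match is an error, never a silent guess.
normalize_enum <- function(x, levels) {
  y <- tolower(trimws(x))
  y <- gsub("[ _]+", "-", y)
  y[!(y %in% levels)] <- NA_character_
  y
}

#' Construct a validated report dataset
#'
#' Builds the package's central container from a variant table, normalizes
#' enumeration tokens, validates every invariant of the model, and stores
#' variants in canonical order (clinical importance descending, then effect
#' rank, then label, then id; see [sort_variants()]).
#'
#' @param variants data.frame with columns `variant_id`, `gene`, `label`,
#'   `zygosity`, `frequency`, `impact`, `evidence`, `importance`,
#'   `conditions` (list of character vectors or ";"-joined strings),
#'   `summary`, `links` (list or ";"-joined).
#' @param subject display name of the report's subject.
#' @param glossary optional data.frame with columns `term`, `definition`.
#' @return an object of class `report_dataset`.
#' @export
report_dataset <- function(variants, subject = "Jamie", glossary = NULL) {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(REPORT_COLUMNS, names(variants))
  if (length(missing_cols)) {
    parse_error(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  v <- variants[REPORT_COLUMNS]
  for (col in c("variant_id", "gene", "label", "summary")) {
    v[[col]] <- as.character(v[[col]])
  }
  v$frequency <- as.numeric(v$frequency)
  split_semi <- function(col) {
    if (is.list(col)) {
      lapply(col, function(el) as.character(el[nzchar(el)]))
    } else {
      lapply(as.character(col), function(s) {
        if (is.na(s) || s == "" || s == ".") character(0)
        else strsplit(s, ";", fixed = TRUE)[[1]]
      })
    }
  }
  v$conditions <- split_semi(v$conditions)
  v$links <- split_semi(v$links)

  viol <- violation(character(0), character(0), character(0))
  norm_col <- function(col, levels) {
    raw <- as.character(v[[col]])
    norm <- normalize_enum(raw, levels)
    bad <- which(is.na(norm))
    for (i in bad) {
      viol <<- rbind(viol, violation(
        col, paste0("variant ", i, " (", v$variant_id[i], ")"),
        paste0("invalid token '", raw[i], "'; expected one of: ",
               paste(levels, collapse = ", "))))
    }
    norm
  }
  v$impact <- norm_col("impact", IMPACT_LEVELS)
  v$evidence <- norm_col("evidence", EVIDENCE_LEVELS)
  v$importance <- norm_col("importance", IMPORTANCE_LEVELS)
  v$zygosity <- norm_col("zygosity", ZYGOSITY_LEVELS)

  dup <- v$variant_id[duplicated(v$variant_id)]
  for (d in unique(dup)) {
    viol <- rbind(viol, violation("variant_id", d, "duplicate variant_id"))
  }
  bad_freq <- which(is.na(v$frequency) | v$frequency < 0 | v$frequency > 1)
  for (i in bad_freq) {
    viol <- rbind(viol, violation(
      "frequency", paste0("variant ", i, " (", v$variant_id[i], ")"),
      paste0("allele frequency must lie in [0,1], got ", v$frequency[i])))
  }
  blank_id <- which(is.na(v$variant_id) | !nzchar(v$variant_id))
  for (i in blank_id) {
    viol <- rbind(viol, violation("variant_id", paste0("variant ", i),
                                  "variant_id must be non-empty"))
  }
  # Strings must stay serializable in the canonical TSV dialect.
  for (col in c("variant_id", "gene", "label", "summary")) {
    bad <- which(grepl("[\t\n]", v[[col]]))
    for (i in bad) {
      viol <- rbind(viol, violation(
        col, paste0("variant ", i, " (", v$variant_id[i], ")"),
        "field must not contain tab or newline characters"))
    }
  }
  for (col in c("conditions", "links")) {
    bad <- which(vapply(v[[col]], function(el) any(grepl("[;\t\n]", el)),
                        logical(1)))
    for (i in bad) {
      viol <- rbind(viol, violation(
        col, paste0("variant ", i, " (", v$variant_id[i], ")"),
        "list elements must not contain ';', tab or newline"))
    }
  }

  if (is.null(glossary)) {
    glossary <- data.frame(term = character(0), definition = character(0),
                           stringsAsFactors = FALSE)
  }
  glossary$term <- as.character(glossary$term)
  glossary$definition <- as.character(glossary$definition)
  if (anyDuplicated(glossary$term) || any(!nzchar(glossary$term))) {
    viol <- rbind(viol, violation("glossary", "glossary",
                                  "terms must be unique and non-empty"))
  }

  if (nrow(viol)) validation_error(viol)

  ds <- structure(list(subject = as.character(subject), variants = v,
                       glossary = glossary),
                  class = "report_dataset")
  ds$variants <- sort_variants(ds)   # canonical order
  rownames(ds$variants) <- NULL
  ds
}

#' Validate a report dataset
#'
#' Re-runs the full constructor validation. Returns the dataset invisibly on
#' success; signals a `varreport_validation_error` (carrying a machine-
#' readable `violations` data.frame) listing *all* violations otherwise.
#'
#' @param dataset a `report_dataset`.
#' @return the dataset, invisibly.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "report_dataset"))
  invisible(report_dataset(dataset$variants, dataset$subject,
                           dataset$glossary))
}

#' @export
print.report_dataset <- function(x, ...) {
  cat("<report_dataset> subject:", x$subject, "-", nrow(x$variants),
      "variants,", nrow(x$glossary), "glossary terms\n")
  tab <- table(factor(x$variants$importance, levels = rev(IMPORTANCE_LEVELS)))
  cat("  importance:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

n_variants <- function(dataset) nrow(dataset$variants)

# ---------------------------------------------------------------------------
# Serialization

fmt_freq <- function(x) sprintf("%.6f", x)
dot_if_empty <- function(x) ifelse(is.na(x) | !nzchar(x), ".", x)
join_semi <- function(lst) {
  vapply(lst, function(el) if (length(el)) paste(el, collapse = ";") else ".",
         character(1))
}

#' Serialize a report dataset
#'
#' Canonical, deterministic serialization. The TSV dialect is UTF-8,
#' tab-separated, `\n` line ends, fixed column order
#' (`variant_id gene label zygosity frequency impact evidence importance
#' conditions summary links`), lowercase enums, `conditions`/`links`
#' ";"-joined, `.` for empty fields and frequencies printed at six decimals.
#' JSON output has alphabetically sorted keys. Identical datasets serialize
#' to identical bytes.
#'
#' @param dataset a valid `report_dataset`.
#' @param format `"tsv"` or `"json"`.
#' @param path optional file path; when given the text is also written there.
#' @return the serialized document as a single string, invisibly when `path`
#'   is given.
#' @export
write_report <- function(dataset, format = c("tsv", "json"), path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "report_dataset"))
  v <- dataset$variants
  if (format == "tsv") {
    header <- paste(REPORT_COLUMNS, collapse = "\t")
    if (nrow(v) == 0L) {
      out <- paste0(header, "\n")
    } else {
      rows <- paste(
        dot_if_empty(v$variant_id), dot_if_empty(v$gene),
        dot_if_empty(v$label), v$zygosity, fmt_freq(v$frequency),
        v$impact, v$evidence, v$importance,
        join_semi(v$conditions), dot_if_empty(v$summary),
        join_semi(v$links), sep = "\t")
      out <- paste0(paste(c(header, rows), collapse = "\n"), "\n")
    }
  } else {
    variants <- lapply(seq_len(nrow(v)), function(i) {
      list(conditions = as.list(v$conditions[[i]]),
           evidence = jsonlite::unbox(v$evidence[i]),
           frequency = jsonlite::unbox(as.numeric(fmt_freq(v$frequency[i]))),
           gene = jsonlite::unbox(v$gene[i]),
           impact = jsonlite::unbox(v$impact[i]),
           importance = jsonlite::unbox(v$importance[i]),
           label = jsonlite::unbox(v$label[i]),
           links = as.list(v$links[[i]]),
           summary = jsonlite::unbox(v$summary[i]),
           variant_id = jsonlite::unbox(v$variant_id[i]),
           zygosity = jsonlite::unbox(v$zygosity[i]))
    })
    g <- dataset$glossary
    glossary <- lapply(seq_len(nrow(g)), function(i) {
      list(definition = jsonlite::unbox(g$definition[i]),
           term = jsonlite::unbox(g$term[i]))
    })
    doc <- list(glossary = glossary,
                subject = jsonlite::unbox(dataset$subject),
                variants = variants)
    out <- paste0(jsonlite::toJSON(doc, digits = I(6), pretty = FALSE), "\n")
  }
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(out), con)
    return(invisible(out))
  }
  out
}

read_source_text <- function(source) {
  if (is.character(source) && length(source) == 1L && !grepl("\n", source) &&
      file.exists(source)) {
    return(readChar(source, file.info(source)$size, useBytes = TRUE))
  }
  paste(as.character(source), collapse = "\n")
}

#' Parse a report from TSV or JSON
#'
#' Reads the canonical serialization (see [write_report()]) from a file path
#' or literal text. Enumeration tokens are matched case-insensitively (with
#' space/hyphen tolerance) and normalized to the lowercase canonical forms.
#' Unknown columns/keys are ignored with a warning. Rows with the wrong
#' number of fields raise a parse error naming the line; invalid enum
#' tokens, out-of-range frequencies and duplicate ids raise a validation
#' error listing every violation.
#'
#' @param source file path, or the document text itself.
#' @param format `"tsv"` or `"json"`.
#' @param subject subject name to attach when parsing TSV (the TSV dialect
#'   carries variants only); ignored for JSON, which embeds the subject.
#' @param glossary optional glossary data.frame to attach (TSV only).
#' @return a validated `report_dataset`.
#' @export
parse_report <- function(source, format = c("tsv", "json"),
                         subject = "Jamie", glossary = NULL) {
  format <- match.arg(format)
  txt <- read_source_text(source)
  if (format == "tsv") {
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    if (!length(lines)) parse_error("empty TSV source: header row required")
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    unknown <- setdiff(header, REPORT_COLUMNS)
    if (length(unknown)) {
      warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "),
              call. = FALSE)
    }
    missing_cols <- setdiff(REPORT_COLUMNS, header)
    if (length(missing_cols)) {
      parse_error(paste0("header is missing required column(s): ",
                         paste(missing_cols, collapse = ", ")))
    }
    body <- lines[-1]
    cells <- strsplit(body, "\t", fixed = TRUE)
    nfield <- lengths(cells)
    # a trailing empty field is dropped by strsplit; pad one short
    short1 <- nfield == length(header) - 1L & endsWith(body, "\t")
    cells[short1] <- lapply(cells[short1], function(x) c(x, ""))
    nfield <- lengths(cells)
    bad <- which(nfield != length(header))
    if (length(bad)) {
      parse_error(paste0("malformed row at line ", bad[1] + 1L, ": expected ",
                         length(header), " fields, found ", nfield[bad[1]]))
    }
    if (length(cells) == 0L) {
      df <- data.frame(variant_id = character(0), gene = character(0),
                       label = character(0), zygosity = character(0),
                       frequency = numeric(0), impact = character(0),
                       evidence = character(0), importance = character(0),
                       conditions = I(list()), summary = character(0),
                       links = I(list()), stringsAsFactors = FALSE)
    } else {
      m <- do.call(rbind, c(cells, list(deparse.level = 0)))
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- header
      df <- df[REPORT_COLUMNS]
      undot <- function(x) ifelse(x == ".", "", x)
      for (col in c("variant_id", "gene", "label", "summary")) {
        df[[col]] <- undot(df[[col]])
      }
      df$frequency <- suppressWarnings(as.numeric(df$frequency))
    }
    report_dataset(df, subject = subject, glossary = glossary)
  } else {
    doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
    known <- c("glossary", "subject", "variants")
    unknown <- setdiff(names(doc), known)
    if (length(unknown)) {
      warning("ignoring unknown key(s): ", paste(unknown, collapse = ", "),
              call. = FALSE)
    }
    pick <- function(rec, key) {
      val <- rec[[key]]
      if (is.null(val)) "" else as.character(val)
    }
    vs <- doc$variants %||% list()
    df <- data.frame(
      variant_id = vapply(vs, pick, character(1), "variant_id"),
      gene = vapply(vs, pick, character(1), "gene"),
      label = vapply(vs, pick, character(1), "label"),
      zygosity = vapply(vs, pick, character(1), "zygosity"),
      frequency = vapply(vs, function(r) as.numeric(r$frequency %||% NA_real_),
                         numeric(1)),
      impact = vapply(vs, pick, character(1), "impact"),
      evidence = vapply(vs, pick, character(1), "evidence"),
      importance = vapply(vs, pick, character(1), "importance"),
      stringsAsFactors = FALSE)
    df$conditions <- lapply(vs, function(r) unlist(r$conditions) %||% character(0))
    df$summary <- vapply(vs, pick, character(1), "summary")
    df$links <- lapply(vs, function(r) unlist(r$links) %||% character(0))
    gl <- doc$glossary %||% list()
    glossary <- data.frame(
      term = vapply(gl, pick, character(1), "term"),
      definition = vapply(gl, pick, character(1), "definition"),
      stringsAsFactors = FALSE)
    report_dataset(df, subject = as.character(doc$subject %||% "Jamie"),
                   glossary = glossary)
  }
}

#' Read a glossary file
#'
#' Glossary files are two-column TSV: `term<TAB>definition`, no header.
#'
#' @param source file path or literal text.
#' @return data.frame with columns `term`, `definition`.
#' @export
read_glossary <- function(source) {
  txt <- read_source_text(source)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != 2L)
  if (length(bad)) {
    parse_error(paste0("malformed glossary row at line ", bad[1],
                       ": expected 2 fields"))
  }
  data.frame(term = vapply(cells, `[`, character(1), 1),
             definition = vapply(cells, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Sort / filter / search semantics of the tabular report

#' Sort the variants of a report
#'
#' The default ordering — clinical importance descending — is the canonical
#' order of a report. Ties are always broken by potential-effect rank (see
#' [effect_category()]), then label (code-point order), then variant id, so
#' every sort is total, stable and deterministic.
#'
#' @param dataset a `report_dataset`.
#' @param key one of `"importance"`, `"impact_evidence"` (potential-effect
#'   rank), `"frequency"`, `"name"` (label).
#' @param descending sort direction of the primary key; defaults to `TRUE`
#'   for `importance` and `FALSE` otherwise.
#' @return the variants data.frame in the requested order.
#' @export
sort_variants <- function(dataset, key = "importance", descending = NULL) {
  keys <- c("importance", "impact_evidence", "frequency", "name")
  if (!(is.character(key) && length(key) == 1L && key %in% keys)) {
    stop("unknown sort key: ", paste(key, collapse = ", "), call. = FALSE)
  }
  if (is.null(descending)) descending <- identical(key, "importance")
  v <- dataset$variants
  if (nrow(v) == 0L) return(v)
  rank <- effect_rank(v$impact, v$evidence)
  # ascending reading of each key; `descending` flips the primary key only
  primary <- switch(key,
    importance = match(v$importance, IMPORTANCE_LEVELS),  # low=1 < high=3
    impact_evidence = rank,   # rank 1 (strongest effect) first
    frequency = v$frequency,
    name = v$label)
  ord <- order(primary, rank, v$label, v$variant_id,
               decreasing = c(descending, FALSE, FALSE, FALSE),
               method = "radix")
  out <- v[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter variants by a conjunction of field = value clauses
#'
#' Each named argument is one clause; a variant is kept when every clause
#' holds. For the list-valued fields `conditions` and `links` a clause holds
#' when the value is an element of the list. Order is preserved; the result
#' may be empty.
#'
#' @param dataset a `report_dataset`.
#' @param ... named clauses, e.g. `importance = "high"`,
#'   `impact = "pathogenic"`.
#' @return a `report_dataset` containing the matching subset.
#' @export
filter_variants <- function(dataset, ...) {
  clauses <- list(...)
  v <- dataset$variants
  if (length(clauses) == 0L) return(dataset)
  fields <- names(clauses)
  if (is.null(fields) || any(!nzchar(fields))) {
    stop("filter clauses must be named", call. = FALSE)
  }
  bad <- setdiff(fields, REPORT_COLUMNS)
  if (length(bad)) {
    stop("unknown field(s) in filter: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(v))
  for (f in fields) {
    val <- clauses[[f]]
    if (f %in% c("impact", "evidence", "importance", "zygosity")) {
      lv <- switch(f, impact = IMPACT_LEVELS, evidence = EVIDENCE_LEVELS,
                   importance = IMPORTANCE_LEVELS, zygosity = ZYGOSITY_LEVELS)
      val <- normalize_enum(val, lv)
    }
    keep <- keep & if (f %in% c("conditions", "links")) {
      vapply(v[[f]], function(el) val %in% el, logical(1))
    } else if (f == "frequency") {
      v[[f]] == as.numeric(val)
    } else {
      v[[f]] == as.character(val)
    }
  }
  out <- dataset
  out$variants <- v[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out
}

#' Search variants by free text
#'
#' Case-insensitive substring match over label, gene symbol, linked
#' condition names and the detailed summary text. The empty query matches
#' every variant. Order is preserved.
#'
#' @param dataset a `report_dataset`.
#' @param query search string.
#' @return the matching variants data.frame.
#' @export
search_variants <- function(dataset, query) {
  v <- dataset$variants
  if (!nzchar(query)) return(v)
  q <- tolower(query)
  hay <- paste(tolower(v$label), tolower(v$gene),
               tolower(vapply(v$conditions, paste, character(1), collapse = " ")),
               tolower(v$summary), sep = "\n")
  out <- v[grepl(q, hay, fixed = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
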