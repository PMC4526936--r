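# Seeded synthetic report datasets and simulated participant cohorts.
#
# The generator emulates the kind of fictional single-subject dataset used
# to compare report designs on identical data: a configurable number of
# variants in every (importance, impact, evidence) cell, fictional gene
# symbols (deliberately not real gene names, so the fixtures cannot be
# mistaken for medical content), plausible allele frequencies per impact
# class, and condition links drawn from a named pool. The response simulator
# plants a per-design answer accuracy so the downstream statistics can be
# exercised end to end with known ground truth.

GENE_POOL <- sprintf("GENE%03d", 1:400)
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")

DEFAULT_FREQ_RANGES <- list(pathogenic = c(0.0001, 0.05),
                            protective = c(0.001, 0.10),
                            benign = c(0.05, 0.50))

DEFAULT_CONDITION_POOL <- c("Alzheimer's disease", "Parkinson's disease",
                           "liver disease", "colon cancer", "diabetes",
                           "emphysema", "tuberculosis", "eye disease",
                           "stomach flu", "age-related macular degeneration")

#' Specification of a synthetic report dataset
#'
#' @param counts named numeric vector or 3-d array of per-cell variant
#'   counts. As a vector, names are `"importance.impact.evidence"` (e.g.
#'   `"high.pathogenic.well-established" = 2`); unnamed cells default to 0.
#' @param condition_pool condition names that variants may link to.
#' @param links_per_variant integer range `c(lo, hi)` of conditions linked
#'   per variant.
#' @param frequency_ranges named list of `c(lo, hi)` allele-frequency ranges
#'   per impact class.
#' @param seed integer seed driving all sampling.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(counts,
                       condition_pool = DEFAULT_CONDITION_POOL,
                       links_per_variant = c(1L, 3L),
                       frequency_ranges = DEFAULT_FREQ_RANGES,
                       seed = 1L) {
  cells <- expand.grid(importance = IMPORTANCE_LEVELS,
                       impact = IMPACT_LEVELS,
                       evidence = EVIDENCE_LEVELS,
                       stringsAsFactors = FALSE)
  cells$key <- paste(cells$importance, cells$impact, cells$evidence, sep = ".")
  cells$n <- 0L
  if (!is.null(names(counts))) {
    idx <- match(names(counts), cells$key)
    if (anyNA(idx)) {
      stop("unknown count cell(s): ",
           paste(names(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    cells$n[idx] <- as.integer(counts)
  } else {
    stopifnot(length(counts) == nrow(cells))
    cells$n <- as.integer(counts)
  }
  if (any(cells$n < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (sum(cells$n) < 1L) stop("at least one variant is required", call. = FALSE)
  for (rng in frequency_ranges) {
    stopifnot(length(rng) == 2L, rng[1] >= 0, rng[2] <= 1, rng[1] <= rng[2])
  }
  stopifnot(length(links_per_variant) == 2L,
            links_per_variant[1] >= 0,
            links_per_variant[1] <= links_per_variant[2])
  structure(list(cells = cells, condition_pool = condition_pool,
                 links_per_variant = as.integer(links_per_variant),
                 frequency_ranges = frequency_ranges,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic report dataset
#'
#' Produces exactly the requested number of variants in every
#' (importance, impact, evidence) cell. Gene symbols are drawn without
#' replacement from a fixed fictional pool; allele frequencies are uniform
#' within the impact class's range (rounded to the model's six-decimal
#' carrying precision); condition links are sampled from the pool. The same
#' spec and seed always give byte-identical serialized output.
#'
#' @param spec a `synth_spec`.
#' @return a validated `report_dataset`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  total <- sum(spec$cells$n)
  if (total > length(GENE_POOL)) {
    stop("gene symbol pool exhausted: ", total, " variants requested, pool ",
         "size ", length(GENE_POOL), call. = FALSE)
  }
  with_seed(spec$seed, {
    genes <- sample(GENE_POOL, total)
    rows <- spec$cells[rep(seq_len(nrow(spec$cells)), spec$cells$n), ]
    k <- nrow(rows)
    change <- paste0("p.", sample(AA_LETTERS, k, replace = TRUE),
                     sample(10:999, k, replace = TRUE),
                     sample(AA_LETTERS, k, replace = TRUE))
    lo_hi <- spec$links_per_variant
    nlinks <- if (lo_hi[1] == lo_hi[2]) rep(lo_hi[1], k) else
      sample(lo_hi[1]:lo_hi[2], k, replace = TRUE)
    nlinks <- pmin(nlinks, length(spec$condition_pool))
    conditions <- lapply(nlinks, function(m) {
      if (m == 0L) character(0) else sort(sample(spec$condition_pool, m))
    })
    freq <- vapply(rows$impact, function(im) {
      rng <- spec$frequency_ranges[[im]] %||% c(0, 1)
      round(runif(1, rng[1], rng[2]), 6)
    }, numeric(1))
    zyg <- sample(ZYGOSITY_LEVELS, k, replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
    ids <- sprintf("v%04d", seq_len(k))
    df <- data.frame(
      variant_id = ids, gene = genes,
      label = paste(genes, change),
      zygosity = zyg, frequency = freq,
      impact = rows$impact, evidence = rows$evidence,
      importance = rows$importance, stringsAsFactors = FALSE)
    df$conditions <- conditions
    df$summary <- sprintf(
      "%s is a %s %s variant (population frequency %s) linked to %s.",
      df$label, df$evidence, df$impact, fmt_freq(freq),
      vapply(conditions, function(el) {
        if (length(el)) paste(el, collapse = ", ") else "no known condition"
      }, character(1)))
    df$links <- lapply(ids, function(id)
      paste0("https://example.org/variant/", id))
    report_dataset(df, subject = "Jamie", glossary = starter_glossary())
  })
}

#' Starter glossary
#'
#' Small glossary covering the terms non-expert readers most often ask
#' about, shipped as a convenience fixture (callers may supply their own).
#'
#' @return data.frame with columns `term`, `definition`.
#' @export
starter_glossary <- function() {
  data.frame(
    term = c("allele frequency", "homozygous", "heterozygous", "pathogenic",
             "benign", "protective", "well-established", "uncertain"),
    definition = c(
      "How common a variant is: the fraction of chromosomes in the population carrying it.",
      "The variant is present on both inherited copies of the gene.",
      "The variant is present on only one of the two inherited copies.",
      "Reported to increase the risk of a disease or harmful trait.",
      "Not expected to affect health.",
      "Reported to decrease the risk of a disease.",
      "Supported by strong, repeatedly confirmed scientific evidence.",
      "Supported by preliminary or conflicting scientific evidence."),
    stringsAsFactors = FALSE)
}

#' The packaged canonical example dataset
#'
#' A deterministic fictional report for subject "Jamie": 26 variants across
#' all three importance tiers, all three impacts and mixed evidence levels.
#' Condition links are arranged so the two risk-quiz conditions are
#' unambiguous: "stomach flu" is linked only to well-established pathogenic
#' variants of high importance (risk clearly above average) and
#' "age-related macular degeneration" only to protective variants (risk
#' clearly below average).
#'
#' @return a `report_dataset`.
#' @export
jamie_fixture <- function() {
  counts <- c(
    "high.pathogenic.well-established" = 2,
    "high.pathogenic.uncertain" = 1,
    "high.protective.well-established" = 1,
    "medium.pathogenic.well-established" = 2,
    "medium.pathogenic.likely" = 2,
    "medium.benign.likely" = 2,
    "medium.protective.likely" = 1,
    "medium.protective.uncertain" = 1,
    "low.pathogenic.uncertain" = 4,
    "low.benign.well-established" = 2,
    "low.benign.likely" = 1,
    "low.benign.uncertain" = 4,
    "low.protective.well-established" = 1,
    "low.protective.uncertain" = 2)
  spec <- synth_spec(counts, seed = 20150612L)
  ds <- generate_dataset(spec)
  v <- ds$variants
  # deterministic condition links: round-robin over the non-risk pool
  q9pool <- setdiff(DEFAULT_CONDITION_POOL,
                    c("stomach flu", "age-related macular degeneration"))
  v$conditions <- lapply(seq_len(nrow(v)), function(i) {
    q9pool[((i - 1L) %% length(q9pool)) + 1L]
  })
  hi_path_we <- which(v$importance == "high" & v$impact == "pathogenic" &
                        v$evidence == "well-established")
  for (i in hi_path_we) {
    v$conditions[[i]] <- sort(c(v$conditions[[i]], "stomach flu"))
  }
  amd <- which(v$impact == "protective" &
                 v$importance %in% c("high", "medium"))[1:2]
  for (i in amd) v$conditions[[i]] <- "age-related macular degeneration"
  v$summary <- sprintf(
    "%s is a %s %s variant (population frequency %s) linked to %s.",
    v$label, v$evidence, v$impact, fmt_freq(v$frequency),
    vapply(v$conditions, paste, character(1), collapse = ", "))
  report_dataset(v, subject = "Jamie", glossary = starter_glossary())
}

#' A ten-variant toy dataset
#'
#' Two high-importance (both well-established pathogenic), three
#' medium-importance (likely benign) and five low-importance variants
#' (three uncertain benign, two well-established protective). Used
#' throughout the documentation and tests where tiny, hand-checkable
#' numbers are wanted.
#'
#' @return a `report_dataset`.
#' @export
toy_fixture <- function() {
  n <- 10
  df <- data.frame(
    variant_id = sprintf("t%02d", 1:n),
    gene = sprintf("GENE9%02d", 1:n),
    label = paste(sprintf("GENE9%02d", 1:n), "p.A100T"),
    zygosity = rep("heterozygous", n),
    frequency = round(seq(0.01, 0.10, length.out = n), 6),
    impact = c("pathogenic", "pathogenic", "benign", "benign", "benign",
               "benign", "benign", "benign", "protective", "protective"),
    evidence = c("well-established", "well-established", "likely", "likely",
                 "likely", "uncertain", "uncertain", "uncertain",
                 "well-established", "well-established"),
    importance = c("high", "high", "medium", "medium", "medium", "low",
                   "low", "low", "low", "low"),
    stringsAsFactors = FALSE)
  df$conditions <- c(rep(list("stomach flu"), 2), rep(list("diabetes"), 6),
                     rep(list("age-related macular degeneration"), 2))
  df$summary <- paste("Toy variant", df$gene, "with", df$evidence,
                      df$impact, "impact.")
  df$links <- lapply(df$variant_id, function(id)
    paste0("https://example.org/variant/", id))
  report_dataset(df, subject = "Jamie", glossary = starter_glossary())
}

# ---------------------------------------------------------------------------
# Participant response simulation

#' Responder model for simulated cohorts
#'
#' @param p named numeric vector of per-design probabilities of answering
#'   any given item correctly. Defaults are the study-condition accuracies
#'   implied by published per-design comprehension means on the 0-10 scale
#'   (mean / 10).
#' @param count_noise integer offsets a wrong count fill-in adds to the true
#'   count (truncated at zero).
#' @param seed default seed for [simulate_responses()].
#' @return list of class `responder_model`.
#' @export
responder_model <- function(p = c(table = 0.565, bar = 0.621, bubble = 0.630,
                                  treemap = 0.574, heatmap = 0.625,
                                  zoom_treemap = 0.463,
                                  zoom_partition = 0.508),
                            count_noise = c(-2L, -1L, 1L, 2L),
                            seed = 1L) {
  stopifnot(all(REPORT_DESIGNS %in% names(p)),
            all(p >= 0 & p <= 1), length(count_noise) >= 1L)
  structure(list(p = p[REPORT_DESIGNS], count_noise = as.integer(count_noise),
                 seed = as.integer(seed)),
            class = "responder_model")
}

wrong_count <- function(true, noise) {
  out <- max(0L, true + sample(noise, 1L))
  if (out == true) out <- true + 1L  # truncation collided with the key
  out
}

wrong_choice <- function(keyval) {
  sample(setdiff(CHOICE_OPTIONS, keyval), 1L)
}

#' Simulate participant response sheets
#'
#' Participants are assigned to the seven designs in balanced round-robin
#' order after a seeded shuffle of the design order. Each quiz item is
#' answered correctly with the design's planted probability, otherwise with
#' a uniformly random wrong answer (counts: true value plus integer noise,
#' truncated at zero and never equal to the key; choices: a random other
#' option; the open/multi items: the key perturbed by one element). Likert
#' items are `1 + Binomial(4, p)` so perceived understanding tracks the
#' planted accuracy. Deterministic under the model seed.
#'
#' @param dataset the report dataset the cohort is quizzed on.
#' @param key the dataset's `answer_key`.
#' @param model a `responder_model`.
#' @param n_per_condition participants per design.
#' @param seed optional seed override.
#' @return data.frame of response sheets (see [read_responses()]).
#' @export
simulate_responses <- function(dataset, key, model, n_per_condition,
                               seed = model$seed) {
  stopifnot(inherits(model, "responder_model"), n_per_condition >= 1L)
  n <- as.integer(n_per_condition) * length(REPORT_DESIGNS)
  with_seed(seed, {
    design_order <- sample(REPORT_DESIGNS)
    condition <- design_order[((seq_len(n) - 1L) %% length(REPORT_DESIGNS)) + 1L]
    p <- unname(model$p[condition])
    sheets <- data.frame(participant = sprintf("p%05d", seq_len(n)),
                         condition = condition, stringsAsFactors = FALSE)
    correct <- matrix(runif(n * 9L) < p, nrow = n)  # recycled by column

    fill_item <- function(id, col) {
      keyval <- key[[tolower(id)]]
      ok <- correct[, col]
      out <- rep(as.character(keyval), n)
      bad <- which(!ok)
      out[bad] <- vapply(bad, function(i)
        as.character(wrong_count(keyval, model$count_noise)), character(1))
      out
    }
    choice_item <- function(id, col) {
      keyval <- key[[tolower(id)]]
      ok <- correct[, col]
      out <- rep(keyval, n)
      bad <- which(!ok)
      out[bad] <- vapply(bad, function(i) wrong_choice(keyval), character(1))
      out
    }
    sheets$q1 <- fill_item("Q1", 1L)
    sheets$q2 <- fill_item("Q2", 2L)
    sheets$q3 <- choice_item("Q3", 3L)
    sheets$q4 <- choice_item("Q4", 4L)
    sheets$q5 <- choice_item("Q5", 5L)

    key_q6 <- paste(key$q6_labels, collapse = ";")
    all_labels <- dataset$variants$label
    non_key <- setdiff(all_labels, key$q6_labels)
    sheets$q6 <- vapply(seq_len(n), function(i) {
      if (correct[i, 6L]) return(key_q6)
      if (length(key$q6_labels)) {
        drop <- sample(seq_along(key$q6_labels), 1L)
        paste(key$q6_labels[-drop], collapse = ";")
      } else if (length(non_key)) {
        sample(non_key, 1L)
      } else ""
    }, character(1))

    sheets$q7 <- choice_item("Q7", 7L)
    sheets$q8 <- choice_item("Q8", 8L)

    opts <- key$q9_options
    key_set <- key$q9
    sheets$q9 <- vapply(seq_len(n), function(i) {
      sel <- key_set
      if (!correct[i, 9L]) {
        flip <- sample(opts, 1L)
        sel <- if (flip %in% sel) setdiff(sel, flip) else sort(c(sel, flip))
      }
      paste(sel, collapse = ";")
    }, character(1))

    for (l in tolower(LIKERT_IDS)) {
      sheets[[l]] <- 1L + rbinom(n, 4L, p)
    }
    sheets$started_at <- sprintf("2026-01-01T%02d:%02d:00Z",
                                 (seq_len(n) - 1L) %/% 60 %% 24,
                                 (seq_len(n) - 1L) %% 60)
    sheets$finished_at <- sprintf("2026-01-01T%02d:%02d:00Z",
                                  (seq_len(n) - 1L + 12L) %/% 60 %% 24,
                                  (seq_len(n) - 1L + 12L) %% 60)
    sheets
  })
}
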