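# Independent reference implementations and fixture builders used across
# the suite. Everything here is deliberately naive (plain loops, direct
# counting) so it cannot share a defect with the package code it checks.

CELL_KEYS <- {
  g <- expand.grid(importance = c("low", "medium", "high"),
                   impact = c("pathogenic", "benign", "protective"),
                   evidence = c("well-established", "likely", "uncertain"),
                   stringsAsFactors = FALSE)
  paste(g$importance, g$impact, g$evidence, sep = ".")
}

# A random synthetic-dataset spec with small per-cell counts.
random_spec <- function(seed, max_per_cell = 2L, links = c(1L, 3L)) {
  counts <- withr_seed_int(seed, length(CELL_KEYS), max_per_cell)
  names(counts) <- CELL_KEYS
  counts <- counts[counts > 0]
  if (!length(counts)) {
    counts <- c(2L)
    names(counts) <- CELL_KEYS[1 + seed %% length(CELL_KEYS)]
  }
  synth_spec(counts, links_per_variant = links, seed = seed)
}

withr_seed_int <- function(seed, n, max) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(0:max, n, replace = TRUE)
}

# Naive comparison-sort oracle over a variant data.frame.
naive_sort <- function(v, key, descending) {
  rank <- integer(nrow(v))
  for (i in seq_len(nrow(v))) {
    blk <- match(v$impact[i], c("pathogenic", "benign", "protective"))
    ev <- match(v$evidence[i], c("well-established", "likely", "uncertain"))
    rank[i] <- (blk - 1L) * 3L + ev
  }
  primary <- switch(key,
    importance = match(v$importance, c("low", "medium", "high")),
    impact_evidence = rank,
    frequency = v$frequency,
    name = v$label)
  ord <- order(primary, rank, v$label, v$variant_id,
               decreasing = c(descending, FALSE, FALSE, FALSE),
               method = "radix")
  out <- v[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Naive double-loop filter oracle (scalar equality clauses only).
naive_filter <- function(v, clauses) {
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    ok <- TRUE
    for (f in names(clauses)) {
      if (!identical(as.character(v[[f]][i]), clauses[[f]])) ok <- FALSE
    }
    keep[i] <- ok
  }
  v[keep, , drop = FALSE]
}

# Independent brute-force recount of the full answer key.
naive_key <- function(dataset, battery) {
  v <- dataset$variants
  count_if <- function(test) {
    n <- 0L
    for (i in seq_len(nrow(v))) if (test(i)) n <- n + 1L
    n
  }
  cmp <- function(a, b) if (a > b) "Greater than" else if (a < b) "Less than" else "Equal to"
  n_high <- count_if(function(i) v$importance[i] == "high")
  n_low <- count_if(function(i) v$importance[i] == "low")
  n_wep <- count_if(function(i) v$impact[i] == "pathogenic" &&
                      v$evidence[i] == "well-established")
  n_up <- count_if(function(i) v$impact[i] == "pathogenic" &&
                     v$evidence[i] == "uncertain")
  n_path <- count_if(function(i) v$impact[i] == "pathogenic")
  n_np <- count_if(function(i) v$impact[i] %in% c("benign", "protective"))
  q6 <- character(0)
  for (i in seq_len(nrow(v))) {
    if (v$importance[i] == "high" && v$impact[i] == "pathogenic") {
      q6 <- c(q6, toupper(v$gene[i]))
    }
  }
  risk <- function(cond) {
    s <- 0
    for (i in seq_len(nrow(v))) {
      if (cond %in% v$conditions[[i]]) {
        w <- c(low = 1, medium = 2, high = 4)[[v$importance[i]]]
        if (v$impact[i] == "pathogenic") s <- s + w
        if (v$impact[i] == "protective") s <- s - w
      }
    }
    if (s > 0) "Greater than" else if (s < 0) "Less than" else "Equal to"
  }
  q9 <- character(0)
  for (opt in battery$Q9$options) {
    hit <- FALSE
    for (i in seq_len(nrow(v))) {
      if (opt %in% v$conditions[[i]] && v$impact[i] == "pathogenic" &&
          v$importance[i] %in% c("medium", "high")) hit <- TRUE
    }
    if (hit) q9 <- c(q9, opt)
  }
  list(q1 = n_high, q2 = n_wep, q3 = cmp(n_low, n_high),
       q4 = cmp(n_up, n_wep), q5 = cmp(n_path, n_np),
       q6_genes = sort(q6), q7 = risk(battery$Q7$condition),
       q8 = risk(battery$Q8$condition), q9 = sort(q9))
}

# A tiny dataset built directly from enum triples (importance, impact,
# evidence), each variant linked to two fixed conditions so the battery
# always instantiates.
dataset_from_cells <- function(cells, conditions = NULL) {
  n <- nrow(cells)
  if (is.null(conditions)) {
    conditions <- rep(list(c("condition alpha", "condition beta")), n)
  }
  df <- data.frame(
    variant_id = sprintf("c%02d", seq_len(n)),
    gene = sprintf("GENE8%02d", seq_len(n)),
    label = sprintf("GENE8%02d p.K%dR", seq_len(n), seq_len(n)),
    zygosity = "heterozygous",
    frequency = round(seq(0.1, 0.5, length.out = n), 6),
    impact = cells$impact, evidence = cells$evidence,
    importance = cells$importance, stringsAsFactors = FALSE)
  df$conditions <- conditions
  df$summary <- sprintf("Synthetic cell variant %d.", seq_len(n))
  df$links <- rep(list(character(0)), n)
  report_dataset(df)
}

# A 9-variant dataset covering every (impact, evidence) cell once.
full_coverage_fixture <- function() {
  cells <- expand.grid(evidence = c("well-established", "likely", "uncertain"),
                       impact = c("pathogenic", "benign", "protective"),
                       stringsAsFactors = FALSE)
  cells$importance <- rep(c("high", "medium", "low"), 3)
  dataset_from_cells(cells)
}

# ---------------------------------------------------------------------------
# Geometry audits

rect_overlap_area <- function(a, b) {
  w <- min(a$x + a$w, b$x + b$w) - max(a$x, b$x)
  h <- min(a$y + a$h, b$y + b$h) - max(a$y, b$y)
  if (w <= 0 || h <= 0) return(0)
  w * h
}

# Maximum pairwise interior overlap among rect rows of a shapes frame.
max_pairwise_overlap <- function(rects) {
  n <- nrow(rects)
  worst <- 0
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      worst <- max(worst, rect_overlap_area(rects[i, ], rects[j, ]))
    }
  }
  worst
}

circles_disjoint <- function(sh, tol = 1e-9) {
  n <- nrow(sh)
  if (n < 2) return(TRUE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((sh$cx[i] - sh$cx[j])^2 + (sh$cy[i] - sh$cy[j])^2)
      if (d + tol < sh$r[i] + sh$r[j]) return(FALSE)
    }
  }
  TRUE
}

# Correct/blank/perfect response sheets for a key.
perfect_sheet <- function(key) {
  data.frame(participant = "p1", condition = "table",
             q1 = as.character(key$q1), q2 = as.character(key$q2),
             q3 = key$q3, q4 = key$q4, q5 = key$q5,
             q6 = paste(key$q6_labels, collapse = ";"),
             q7 = key$q7, q8 = key$q8,
             q9 = paste(key$q9, collapse = ";"),
             stringsAsFactors = FALSE)
}

blank_sheet <- function() {
  data.frame(participant = "p1", condition = "table",
             q1 = "", q2 = "", q3 = "", q4 = "", q5 = "", q6 = "",
             q7 = "", q8 = "", q9 = "", stringsAsFactors = FALSE)
}

# Analytic expected comprehension score of the response simulator at
# accuracy p (used as the planted value in recovery tests).
expected_sim_score <- function(p, key) {
  k6 <- length(key$q6_genes)
  q6_wrong <- if (k6 > 0) (k6 - 1) / k6 else 0
  no <- length(key$q9_options)
  q9_wrong <- 2 * (no - 1) / no
  7 * p + (p + (1 - p) * q6_wrong) + (2 * p + (1 - p) * q9_wrong)
}
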