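# Between-condition analysis pipeline: per-condition summaries, one-way
# ANOVA, Tukey-Kramer all-pairs comparisons on the studentized range
# distribution, and Likert item summaries.

#' Per-condition comprehension score summaries
#'
#' @param scores data.frame with columns `condition` and `score` (e.g. from
#'   [grade_cohort()]).
#' @return data.frame of class `condition_summary` with `condition`, `n`,
#'   `mean`, `sd` (sample SD, n-1 denominator), conditions in canonical
#'   design order; unrecognized condition tokens follow alphabetically.
#' @export
summarize_scores <- function(scores) {
  stopifnot(all(c("condition", "score") %in% names(scores)))
  conds <- unique(scores$condition)
  conds <- c(intersect(REPORT_DESIGNS, conds),
             sort(setdiff(conds, REPORT_DESIGNS)))
  out <- do.call(rbind, lapply(conds, function(cc) {
    x <- scores$score[scores$condition == cc]
    if (length(x) < 2L) {
      stop("condition '", cc, "' has fewer than 2 records", call. = FALSE)
    }
    data.frame(condition = cc, n = length(x), mean = mean(x), sd = sd(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Build condition summaries directly from (n, mean, sd) triples
#'
#' Convenience constructor for published summary tables.
#'
#' @param condition,n,mean,sd parallel vectors.
#' @return a `condition_summary` data.frame.
#' @export
condition_summary <- function(condition, n, mean, sd) {
  stopifnot(all(n >= 2), all(sd >= 0))
  out <- data.frame(condition = as.character(condition), n = as.integer(n),
                    mean = as.numeric(mean), sd = as.numeric(sd),
                    stringsAsFactors = FALSE)
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition with the p-value from the upper
#' tail of the F distribution. All groups identical gives F = 0, p = 1;
#' zero within-group variance with unequal means is a degenerate error
#' (infinite F).
#'
#' @param groups list of numeric score vectors, one per condition (k >= 2,
#'   each of length >= 2).
#' @return object of class `anova_oneway`: `F`, `df_between`, `df_within`,
#'   `p`.
#' @export
anova_oneway <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2L)
  n_i <- lengths(groups)
  if (any(n_i < 2L)) stop("each group needs at least 2 observations",
                          call. = FALSE)
  all_x <- unlist(groups)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- k - 1L
  df_w <- sum(n_i) - k
  if (ss_within <= 0) {
    if (ss_between <= 0) {
      res <- list(F = 0, df_between = df_b, df_within = df_w, p = 1)
      class(res) <- "anova_oneway"
      return(res)
    }
    stop("degenerate: infinite F (zero within-group variance with unequal ",
         "means)", call. = FALSE)
  }
  Fstat <- (ss_between / df_b) / (ss_within / df_w)
  res <- list(F = Fstat, df_between = df_b, df_within = df_w,
              p = pf(Fstat, df_b, df_w, lower.tail = FALSE))
  class(res) <- "anova_oneway"
  res
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Studentized range distribution
#
# Q = range of k iid standard normal group means divided by an independent
# pooled scale estimate S with df error degrees of freedom. The CDF is the
# classic double integral: conditioned on the scale S = s,
#   P(range <= q s) = k * Int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz,
# then the outer integral averages over the density of S = sqrt(chi^2_df/df).
# Both integrals use fixed Gauss-Legendre rules (inner over the location z,
# outer over the scale s), giving absolute accuracy well below 1e-6 over the
# (q, k, df) ranges the pipeline uses.

GL_CACHE <- new.env(parent = emptyenv())

gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(GL_CACHE[[key]])) {
    GL_CACHE[[key]] <- pracma::gaussLegendre(n, 0, 1)  # nodes on [0, 1]
  }
  GL_CACHE[[key]]
}

SR_INNER_N <- 192L
SR_OUTER_N <- 128L
SR_Z_PAD <- 8.5       # integration half-width for the location integral
SR_S_TAIL <- 1e-12    # scale-density probability mass left outside

# log density of S = sqrt(chi^2_df / df)
log_scale_density <- function(s, df) {
  log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
    (df - 1) * log(s) - df * s^2 / 2
}

# Shared quadrature grid; `tail = FALSE` integrates the CDF form,
# `tail = TRUE` the survival form (numerically stable for small p).
srange_integral <- function(q, k, df, tail) {
  if (q <= 0) return(if (tail) 1 else 0)
  gl_s <- gl_nodes(SR_OUTER_N)
  gl_z <- gl_nodes(SR_INNER_N)
  s_lo <- sqrt(qchisq(SR_S_TAIL, df) / df)
  s_hi <- sqrt(qchisq(SR_S_TAIL, df, lower.tail = FALSE) / df)
  s <- s_lo + (s_hi - s_lo) * gl_s$x          # outer nodes
  ws <- (s_hi - s_lo) * gl_s$w
  u <- q * s                                   # conditional range bound
  # inner nodes per outer node: z in [-PAD, PAD + u]
  zlo <- -SR_Z_PAD
  zspan <- 2 * SR_Z_PAD + u                    # length SR_OUTER_N
  Z <- outer(zspan, gl_z$x) + zlo              # outer_n x inner_n
  WZ <- outer(zspan, gl_z$w)
  PZ <- pnorm(Z)
  DZ <- dnorm(Z)
  B <- PZ - pnorm(Z - u)                       # u recycles down columns
  inner <- if (tail) {
    rowSums(WZ * DZ * (PZ^(k - 1) - B^(k - 1))) * k +
      # location mass outside [-PAD, PAD + u] under k phi Phi^(k-1)
      (pnorm(zlo)^k + 1 - pnorm(SR_Z_PAD + u)^k)
  } else {
    rowSums(WZ * DZ * B^(k - 1)) * k
  }
  val <- sum(ws * exp(log_scale_density(s, df)) * inner)
  min(1, max(0, val))
}

#' CDF of the studentized range distribution
#'
#' P(Q <= q) for the studentized range of `k` groups with `df` error
#' degrees of freedom, by fixed-rule numerical integration (outer integral
#' over the pooled scale, inner over location); absolute accuracy <= 1e-6.
#'
#' @param q quantile(s), q >= 0 (vectorized).
#' @param k number of groups (>= 2).
#' @param df error degrees of freedom (>= 1).
#' @return probabilities.
#' @export
studentized_range_cdf <- function(q, k, df) {
  stopifnot(k >= 2, df >= 1, all(q >= 0 | is.na(q)))
  vapply(q, function(qq) {
    if (is.na(qq)) return(NA_real_)
    srange_integral(qq, k, df, tail = FALSE)
  }, numeric(1))
}

# Upper tail, integrated directly so p-values of order 1e-15 do not drown
# in 1 - CDF cancellation.
studentized_range_sf <- function(q, k, df) {
  vapply(q, function(qq) {
    if (is.na(qq)) return(NA_real_)
    srange_integral(qq, k, df, tail = TRUE)
  }, numeric(1))
}

#' Tukey-Kramer all-pairs comparisons from condition summaries
#'
#' Pools the within-group variance across conditions
#' (MSE = sum((n_i - 1) s_i^2) / sum(n_i - 1)), forms the Tukey-Kramer
#' unequal-n standard error `sqrt(MSE/2 (1/n_i + 1/n_j))` for each pair,
#' and adjusts via the studentized range distribution with `k` groups and
#' `sum(n_i - 1)` degrees of freedom.
#'
#' @param summaries a `condition_summary` data.frame (k >= 2 rows).
#' @param alpha familywise significance level for the `significant` flag.
#' @return data.frame of class `tukey_kramer`, one row per unordered pair:
#'   `cond1`, `cond2`, `diff` (mean1 - mean2), `se`, `q`, `p_adj`,
#'   `significant`. Attributes `mse`, `df`, `k`.
#' @export
tukey_kramer <- function(summaries, alpha = 0.05) {
  stopifnot(nrow(summaries) >= 2L, all(summaries$n >= 2L))
  k <- nrow(summaries)
  df <- sum(summaries$n - 1L)
  mse <- sum((summaries$n - 1L) * summaries$sd^2) / df
  if (mse <= 0) stop("degenerate: zero pooled within-group variance",
                     call. = FALSE)
  pairs <- which(upper.tri(matrix(NA, k, k)), arr.ind = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, "row"]; j <- pairs[r, "col"]
    diff <- summaries$mean[i] - summaries$mean[j]
    se <- sqrt(mse / 2 * (1 / summaries$n[i] + 1 / summaries$n[j]))
    qstat <- abs(diff) / se
    p_adj <- studentized_range_sf(qstat, k, df)
    data.frame(cond1 = summaries$condition[i],
               cond2 = summaries$condition[j],
               diff = diff, se = se, q = qstat, p_adj = p_adj,
               significant = p_adj < alpha, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "mse") <- mse
  attr(out, "df") <- df
  attr(out, "k") <- k
  class(out) <- c("tukey_kramer", "data.frame")
  out
}

#' @export
print.tukey_kramer <- function(x, ...) {
  cat(sprintf("Tukey-Kramer comparisons: k = %d, df = %d, MSE = %.4g\n",
              attr(x, "k"), attr(x, "df"), attr(x, "mse")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Summarize one Likert item over a cohort
#'
#' @param sheets response-sheet data.frame (see [read_responses()]).
#' @param item one of `"Q10"`..`"Q16"` (case-insensitive).
#' @return list with `item`, `n` (non-blank responses), `mean`, `sd`.
#' @export
likert_summary <- function(sheets, item) {
  item <- toupper(item)
  stopifnot(item %in% LIKERT_IDS)
  x <- suppressWarnings(as.integer(sheets[[tolower(item)]]))
  x <- x[!is.na(x)]
  if (!length(x)) stop("no non-blank responses for ", item, call. = FALSE)
  list(item = item, n = length(x), mean = mean(x),
       sd = if (length(x) > 1L) sd(x) else 0)
}

#' Run the full between-condition analysis
#'
#' Per-condition summaries, one-way ANOVA across conditions, the complete
#' pairwise Tukey-Kramer table and (when response sheets are supplied)
#' per-item Likert summaries, optionally written as one JSON document.
#'
#' @param scores graded score data.frame (`condition`, `score`).
#' @param sheets optional response sheets for the Likert table.
#' @param alpha significance level.
#' @param path optional JSON output file.
#' @return list with `summaries`, `anova`, `tukey`, `likert`.
#' @export
analyze_study <- function(scores, sheets = NULL, alpha = 0.05, path = NULL) {
  summaries <- summarize_scores(scores)
  groups <- split(scores$score, factor(scores$condition,
                                       levels = summaries$condition))
  res <- list(
    summaries = summaries,
    anova = anova_oneway(groups),
    tukey = tukey_kramer(summaries, alpha = alpha),
    likert = if (!is.null(sheets)) {
      do.call(rbind, lapply(LIKERT_IDS, function(it) {
        s <- likert_summary(sheets, it)
        data.frame(item = s$item, n = s$n, mean = s$mean, sd = s$sd,
                   stringsAsFactors = FALSE)
      }))
    })
  if (!is.null(path)) {
    a <- res$anova
    doc <- list(
      summaries = res$summaries,
      anova = list(F = jsonlite::unbox(a$F),
                   df_between = jsonlite::unbox(a$df_between),
                   df_within = jsonlite::unbox(a$df_within),
                   p = jsonlite::unbox(a$p)),
      tukey = as.data.frame(res$tukey),
      likert = res$likert)
    writeLines(paste0(jsonlite::toJSON(doc, dataframe = "rows", digits = NA,
                                       pretty = TRUE, na = "null"), "\n"),
               path, sep = "")
  }
  res
}

#' Published per-condition comprehension summaries
#'
#' Loads the packaged fixture of per-condition comprehension score
#' summaries (mean, SD, n for each of the seven report designs) from a
#' published evaluation of these designs, ready for [tukey_kramer()].
#'
#' @return a `condition_summary` data.frame with seven rows.
#' @export
study_condition_summaries <- function() {
  path <- system.file("extdata", "study_condition_summaries.tsv",
                      package = "varreport")
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  condition_summary(df$condition, df$n, df$mean, df$sd)
}
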