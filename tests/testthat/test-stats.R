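test_that("condition summaries use the sample SD and canonical order", {
  scores <- data.frame(condition = c("bubble", "bubble", "table", "table"),
                       score = c(4, 6, 5, 5))
  s <- summarize_scores(scores)
  expect_equal(s$condition, c("table", "bubble"))
  expect_equal(s$mean[s$condition == "bubble"], 5)
  expect_equal(s$sd[s$condition == "bubble"], sqrt(2))
  # invariant to record order
  expect_equal(summarize_scores(scores[c(3, 1, 4, 2), ]), s)
  expect_error(summarize_scores(data.frame(condition = "bar", score = 1)),
               "fewer than 2")
  # agreement with a naive two-pass computation on a large random cohort
  set.seed(8)
  big <- data.frame(condition = sample(REPORT_DESIGNS, 2e4, TRUE),
                    score = runif(2e4, 0, 10))
  s2 <- summarize_scores(big)
  for (i in seq_len(nrow(s2))) {
    x <- big$score[big$condition == s2$condition[i]]
    m <- sum(x) / length(x)
    expect_equal(s2$mean[i], m)
    expect_equal(s2$sd[i], sqrt(sum((x - m)^2) / (length(x) - 1)))
  }
})

test_that("one-way ANOVA matches stats::oneway.test and handles degenerate inputs", {
  expect_equal(anova_oneway(list(1:3, 1:3, 1:3))$F, 0)
  expect_equal(anova_oneway(list(1:3, 1:3, 1:3))$p, 1)
  expect_error(anova_oneway(list(c(0, 0), c(1, 1))), "degenerate")
  set.seed(5)
  g <- list(rnorm(12), rnorm(15, 0.5), rnorm(9, 1))
  a <- anova_oneway(g)
  ref <- stats::oneway.test(
    y ~ grp, data = data.frame(y = unlist(g),
                               grp = rep(letters[1:3], lengths(g))),
    var.equal = TRUE)
  expect_equal(a$F, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(a$p, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 33L)
})

test_that("the studentized range CDF satisfies the distribution axioms", {
  expect_equal(studentized_range_cdf(0, 4, 10), 0)
  q <- seq(0, 12, by = 0.5)
  p <- studentized_range_cdf(q, 5, 20)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(studentized_range_cdf(50, 5, 20), 1 - 1e-9)
})

test_that("k = 2 reduces the studentized range to the |t| distribution", {
  for (df in c(1, 2, 5, 17, 60, 400)) {
    q <- c(0.2, 0.9, 1.7, 2.6, 4, 7)
    expect_equal(studentized_range_cdf(q, 2, df),
                 2 * pt(q / sqrt(2), df) - 1, tolerance = 1e-6)
  }
})

test_that("the CDF agrees with R's ptukey within that routine's accuracy", {
  # base ptukey is the independent oracle here; its own absolute accuracy
  # is limited (~1e-4 at small df), hence the looser tolerance
  grid <- expand.grid(q = c(0.5, 1.5, 3, 4.5, 8),
                      k = c(3, 5, 7, 10), df = c(5, 30, 120, 723))
  for (i in seq_len(nrow(grid))) {
    expect_equal(studentized_range_cdf(grid$q[i], grid$k[i], grid$df[i]),
                 ptukey(grid$q[i], grid$k[i], grid$df[i]),
                 tolerance = 2e-4,
                 info = paste(grid[i, ], collapse = " "))
  }
})

test_that("Tukey-Kramer reduces to the pooled t-test at k = 2", {
  expect_equal(
    tukey_kramer(condition_summary(c("a", "b"), c(10, 12), c(3, 3),
                                   c(1, 1.2)))$p_adj, 1)
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:50, 2)
    s <- condition_summary(c("a", "b"), n, runif(2, 0, 10),
                           runif(2, 0.5, 3))
    tk <- tukey_kramer(s)
    se_t <- sqrt(attr(tk, "mse") * (1 / n[1] + 1 / n[2]))
    tstat <- abs(s$mean[1] - s$mean[2]) / se_t
    expect_equal(tk$p_adj, 2 * pt(tstat, sum(n) - 2, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
  expect_error(tukey_kramer(condition_summary(c("a", "b"), c(4, 4),
                                              c(1, 2), c(0, 0))),
               "degenerate")
})

test_that("Tukey adjustment is symmetric, relabel-invariant and conservative", {
  set.seed(7)
  s <- condition_summary(letters[1:4], c(12, 9, 15, 11), runif(4, 3, 7),
                         runif(4, 0.8, 2.5))
  tk <- tukey_kramer(s)
  expect_equal(nrow(tk), 6L)
  # relabeling (row permutation) keeps each pair's adjusted p
  perm <- s[c(3, 1, 4, 2), ]
  tk2 <- tukey_kramer(perm)
  key1 <- paste(pmin(tk$cond1, tk$cond2), pmax(tk$cond1, tk$cond2))
  key2 <- paste(pmin(tk2$cond1, tk2$cond2), pmax(tk2$cond1, tk2$cond2))
  expect_equal(tk2$p_adj[match(key1, key2)], tk$p_adj, tolerance = 1e-12)
  expect_equal(abs(tk2$diff[match(key1, key2)]), abs(tk$diff),
               tolerance = 1e-12)
  # adjusted p never below the unadjusted pairwise pooled-t p for k > 2
  df <- attr(tk, "df")
  p_t <- 2 * pt(tk$q / sqrt(2), df, lower.tail = FALSE)
  expect_true(all(tk$p_adj >= p_t - 1e-9))
})

test_that("Likert summaries exclude blanks and use the sample SD", {
  sheets <- data.frame(q11 = c(5L, 5L, 5L), q12 = c(3L, 5L, NA))
  s <- likert_summary(sheets, "Q11")
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  s2 <- likert_summary(sheets, "q12")
  expect_equal(s2$n, 2L)
  expect_equal(s2$mean, 4)
  expect_equal(s2$sd, sqrt(2))
  expect_error(likert_summary(data.frame(q10 = NA_integer_), "Q10"),
               "no non-blank")
})

test_that("analyze_study assembles summaries, ANOVA, Tukey and Likert output", {
  ds <- toy_fixture()
  key <- oracle_answers(ds)
  sheets <- simulate_responses(ds, key, responder_model(seed = 6L), 12L)
  scores <- grade_cohort(sheets, key)
  path <- withr::local_tempfile(fileext = ".json")
  res <- analyze_study(scores, sheets = sheets, path = path)
  expect_equal(nrow(res$summaries), 7L)
  expect_equal(nrow(res$tukey), 21L)
  expect_equal(nrow(res$likert), 7L)
  doc <- jsonlite::fromJSON(path)
  expect_equal(nrow(doc$tukey), 21L)
  expect_true(all(doc$tukey$p_adj >= 0 & doc$tukey$p_adj <= 1))
})

test_that("estimated condition means recover the planted values at nominal coverage", {
  ds <- jamie_fixture()
  key <- oracle_answers(ds)
  model <- responder_model()
  planted <- vapply(model$p, expected_sim_score, numeric(1), key = key)
  n_rep <- 60L
  n_per <- 30L
  covered <- 0L
  total <- 0L
  for (rep in seq_len(n_rep)) {
    sheets <- simulate_responses(ds, key, model, n_per_condition = n_per,
                                 seed = 7000L + rep)
    s <- summarize_scores(grade_cohort(sheets, key))
    for (i in seq_len(nrow(s))) {
      half <- qt(0.975, s$n[i] - 1) * s$sd[i] / sqrt(s$n[i])
      total <- total + 1L
      if (abs(s$mean[i] - planted[[s$condition[i]]]) <= half) {
        covered <- covered + 1L
      }
    }
  }
  expect_gte(covered / total, 0.93)
})
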