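test_that("the battery has nine items with the fixed kinds and option sets", {
  b <- build_battery(jamie_fixture())
  expect_s3_class(b, "quiz_battery")
  expect_equal(length(b), 9L)
  expect_equal(vapply(b, `[[`, character(1), "kind"),
               c(Q1 = "count_fill", Q2 = "count_fill",
                 Q3 = "comparison_choice", Q4 = "comparison_choice",
                 Q5 = "comparison_choice", Q6 = "open_variants",
                 Q7 = "risk_choice", Q8 = "risk_choice",
                 Q9 = "multi_select"))
  for (id in c("Q3", "Q4", "Q5", "Q7", "Q8")) {
    expect_equal(b[[id]]$options,
                 c("Greater than", "Equal to", "Less than", "I don't know"))
  }
  expect_match(b$Q7$prompt, "risk of developing stomach flu")
  expect_match(b$Q8$prompt, "age-related macular degeneration")
  expect_match(b$Q1$prompt, "high clinical importance")
  expect_equal(length(b$Q9$options), 8L)
  # prompts are templated on the subject
  expect_match(b$Q6$prompt, "Jamie")
  # fewer than two linked conditions cannot instantiate the risk items
  cells <- data.frame(importance = "high", impact = "pathogenic",
                      evidence = "likely", stringsAsFactors = FALSE)
  ds1 <- dataset_from_cells(cells, conditions = list("only one"))
  expect_error(build_battery(ds1), "at least 2 linked conditions")
})

test_that("the oracle answers the toy fixture by direct counting", {
  toy <- toy_fixture()
  key <- oracle_answers(toy)
  expect_equal(key$q1, 2L)
  expect_equal(key$q2, 2L)   # both high variants are well-established pathogenic
  expect_equal(key$q3, "Greater than")
  expect_equal(key$q5, "Less than")
  expect_equal(sort(key$q6_genes), c("GENE901", "GENE902"))
  expect_equal(key$q7, "Greater than")   # stomach flu: pathogenic links only
  expect_equal(key$q8, "Less than")      # AMD: protective links only
})

test_that("risk items follow the signed polarity of a condition's links", {
  cells <- data.frame(
    importance = c("high", "low", "medium"),
    impact = c("protective", "pathogenic", "benign"),
    evidence = c("well-established", "uncertain", "likely"),
    stringsAsFactors = FALSE)
  ds <- dataset_from_cells(cells, conditions = list(
    "condition shield", "condition sword", "condition shrug"))
  b <- build_battery(ds)
  expect_equal(b$Q7$condition, "condition sword")
  expect_equal(b$Q8$condition, "condition shield")
  key <- oracle_answers(ds, b)
  expect_equal(key$q7, "Greater than")
  expect_equal(key$q8, "Less than")
})

test_that("oracle matches the independent naive counter on many datasets", {
  # every single-cell dataset, exhaustively
  for (ck in CELL_KEYS) {
    parts <- strsplit(ck, ".", fixed = TRUE)[[1]]
    ds <- dataset_from_cells(data.frame(importance = parts[1],
                                        impact = parts[2],
                                        evidence = parts[3],
                                        stringsAsFactors = FALSE))
    b <- build_battery(ds)
    key <- oracle_answers(ds, b)
    want <- naive_key(ds, b)
    expect_equal(key$q1, want$q1)
    expect_equal(key$q3, want$q3)
    expect_equal(key$q7, want$q7)
  }
  # sampled multi-variant datasets
  for (seed in 1:60) {
    ds <- generate_dataset(random_spec(seed))
    b <- build_battery(ds)
    key <- oracle_answers(ds, b)
    want <- naive_key(ds, b)
    expect_equal(key$q1, want$q1, info = seed)
    expect_equal(key$q2, want$q2, info = seed)
    expect_equal(key$q3, want$q3, info = seed)
    expect_equal(key$q4, want$q4, info = seed)
    expect_equal(key$q5, want$q5, info = seed)
    expect_equal(sort(key$q6_genes), want$q6_genes, info = seed)
    expect_equal(key$q7, want$q7, info = seed)
    expect_equal(key$q8, want$q8, info = seed)
    expect_equal(sort(key$q9), want$q9, info = seed)
  }
})

test_that("grading implements the 0-10 rubric", {
  ds <- jamie_fixture()
  key <- oracle_answers(ds)
  expect_equal(grade_response(perfect_sheet(key), key)$score, 10)
  expect_equal(grade_response(blank_sheet(), key)$score, 0)
  # correct on Q1-Q8, fully wrong on Q9 -> 8 points
  s <- perfect_sheet(key)
  s$q9 <- paste(setdiff(key$q9_options, key$q9), collapse = ";")
  expect_equal(grade_response(s, key)$score, 8)
  # Q6 partial credit: one of three named plus one false name
  s <- perfect_sheet(key)
  s$q6 <- paste(c(key$q6_labels[1], "GENE999 p.A1B"), collapse = ";")
  r <- grade_response(s, key)
  expect_equal(unname(r$credits["Q6"]), 0)   # 1 hit - 1 miss, floored
  s$q6 <- paste(key$q6_labels[1:2], collapse = ";")
  expect_equal(unname(grade_response(s, key)$credits["Q6"]), 2 / 3)
  # gene match is case-insensitive
  s$q6 <- tolower(paste(key$q6_labels, collapse = ";"))
  expect_equal(unname(grade_response(s, key)$credits["Q6"]), 1)
  # out-of-option tokens score zero for that item
  s <- perfect_sheet(key)
  s$q3 <- "Way more"
  expect_equal(unname(grade_response(s, key)$credits["Q3"]), 0)
  s <- perfect_sheet(key)
  s$q9 <- paste(c(key$q9, "made-up condition"), collapse = ";")
  expect_equal(unname(grade_response(s, key)$credits["Q9"]), 0)
})

test_that("correcting any single wrong answer never lowers the score", {
  ds <- jamie_fixture()
  key <- oracle_answers(ds)
  model <- responder_model(seed = 3L)
  sheets <- simulate_responses(ds, key, model, n_per_condition = 10L)
  correct_value <- list(
    q1 = as.character(key$q1), q2 = as.character(key$q2),
    q3 = key$q3, q4 = key$q4, q5 = key$q5,
    q6 = paste(key$q6_labels, collapse = ";"),
    q7 = key$q7, q8 = key$q8, q9 = paste(key$q9, collapse = ";"))
  for (i in seq_len(nrow(sheets))) {
    base <- grade_response(sheets[i, , drop = FALSE], key)$score
    for (q in names(correct_value)) {
      if (identical(sheets[[q]][i], correct_value[[q]])) next
      fixed <- sheets[i, , drop = FALSE]
      fixed[[q]] <- correct_value[[q]]
      expect_gte(grade_response(fixed, key)$score, base)
    }
  }
})

test_that("the tutorial gate includes at three or more correct answers", {
  expect_true(tutorial_gate(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  expect_false(tutorial_gate(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)))
  expect_true(tutorial_gate(rep(TRUE, 6)))
  expect_error(tutorial_gate(c(TRUE, FALSE)), "six")
})

test_that("quiz JSON and response CSV round-trip their grading content", {
  ds <- toy_fixture()
  b <- build_battery(ds)
  key <- oracle_answers(ds, b)
  path <- withr::local_tempfile(fileext = ".json")
  quiz_json(b, key, path = path)
  key2 <- read_quiz_key(path)
  expect_equal(key2$q1, key$q1)
  expect_equal(key2$q9, key$q9)
  expect_equal(key2$q9_options, key$q9_options)
  sheets <- simulate_responses(ds, key, responder_model(seed = 2L), 3L)
  csv <- write_responses(sheets)
  back <- read_responses(csv)
  expect_equal(back$q9, sheets$q9)
  expect_equal(grade_cohort(back, key)$score,
               grade_cohort(sheets, key)$score)
})
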