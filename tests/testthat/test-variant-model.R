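test_that("a minimal well-formed TSV parses with normalized enums", {
  tsv <- paste(
    "variant_id\tgene\tlabel\tzygosity\tfrequency\timpact\tevidence\timportance\tconditions\tsummary\tlinks",
    "v1\tGENE001\tGENE001 p.A5T\tHeterozygous\t0.010000\tPathogenic\tWell established\tHIGH\tstomach flu;diabetes\tA test variant.\t.",
    sep = "\n")
  ds <- parse_report(tsv, "tsv")
  expect_s3_class(ds, "report_dataset")
  expect_equal(nrow(ds$variants), 1L)
  expect_equal(ds$variants$impact, "pathogenic")
  expect_equal(ds$variants$evidence, "well-established")
  expect_equal(ds$variants$importance, "high")
  expect_equal(ds$variants$conditions[[1]], c("stomach flu", "diabetes"))
  expect_equal(ds$variants$links[[1]], character(0))
  # canonical re-serialization is byte-stable
  expect_identical(write_report(parse_report(write_report(ds, "tsv"), "tsv"),
                                "tsv"),
                   write_report(ds, "tsv"))
})

test_that("empty dataset serializes to a header-only TSV", {
  tsv <- "variant_id\tgene\tlabel\tzygosity\tfrequency\timpact\tevidence\timportance\tconditions\tsummary\tlinks\n"
  ds <- parse_report(tsv, "tsv")
  expect_equal(nrow(ds$variants), 0L)
  expect_identical(write_report(ds, "tsv"), tsv)
})

test_that("parse-write round trips hold for seeded synthetic datasets in both formats", {
  for (seed in 1:40) {
    ds <- generate_dataset(random_spec(seed))
    tsv <- write_report(ds, "tsv")
    json <- write_report(ds, "json")
    expect_identical(write_report(parse_report(tsv, "tsv"), "tsv"), tsv)
    expect_identical(write_report(parse_report(json, "json"), "json"), json)
    # the two serializations describe the same dataset
    expect_identical(write_report(parse_report(json, "json"), "tsv"), tsv)
  }
})

test_that("every class of invalid input is rejected with a named violation", {
  base <- toy_fixture()$variants
  corrupt <- list(
    list(col = "impact", val = "Pathogenic-ish"),
    list(col = "impact", val = "deleterious"),
    list(col = "evidence", val = "very sure"),
    list(col = "importance", val = "critical"),
    list(col = "zygosity", val = "triploid"),
    list(col = "frequency", val = 1.5),
    list(col = "frequency", val = -0.1))
  for (cs in corrupt) {
    v <- base
    v[[cs$col]][2] <- cs$val
    err <- tryCatch(report_dataset(v), varreport_validation_error = identity)
    expect_s3_class(err, "varreport_validation_error")
    expect_true(any(err$violations$field == cs$col),
                info = paste(cs$col, cs$val))
    expect_match(err$violations$where[err$violations$field == cs$col][1],
                 "variant")
  }
  # duplicate id: all violations are reported together
  v <- base
  v$variant_id[2] <- v$variant_id[1]
  v$impact[3] <- "bogus"
  err <- tryCatch(report_dataset(v), varreport_validation_error = identity)
  expect_setequal(unique(err$violations$field), c("variant_id", "impact"))
})

test_that("malformed rows and unknown columns are handled at parse time", {
  good <- write_report(toy_fixture(), "tsv")
  lines <- strsplit(good, "\n")[[1]]
  lines[3] <- paste(lines[3], "extra", sep = "\t")
  err <- tryCatch(parse_report(paste(lines, collapse = "\n"), "tsv"),
                  varreport_parse_error = identity)
  expect_s3_class(err, "varreport_parse_error")
  expect_match(conditionMessage(err), "line 3")
  lines <- strsplit(good, "\n")[[1]]
  lines[1] <- paste0(lines[1], "\tmystery")
  lines[-1] <- paste0(lines[-1], "\tx")
  expect_warning(parse_report(paste(lines, collapse = "\n"), "tsv"),
                 "unknown column")
})

test_that("default sort is importance descending with deterministic tie-breaks", {
  cells <- data.frame(importance = c("low", "high", "medium"),
                      impact = "benign", evidence = "likely",
                      stringsAsFactors = FALSE)
  ds <- dataset_from_cells(cells)
  expect_equal(sort_variants(ds)$importance, c("high", "medium", "low"))
  # identical-importance variants keep label order on repeated calls
  s1 <- sort_variants(toy_fixture())
  s2 <- sort_variants(toy_fixture())
  expect_identical(s1, s2)
  expect_equal(s1$label[1:2], sort(s1$label[1:2], method = "radix"))
})

test_that("sorting agrees with a naive comparison sort on random variants", {
  ds <- generate_dataset(random_spec(99, max_per_cell = 4L))
  for (key in c("importance", "impact_evidence", "frequency", "name")) {
    for (desc in c(TRUE, FALSE)) {
      expect_identical(sort_variants(ds, key, desc),
                       naive_sort(ds$variants, key, desc),
                       info = paste(key, desc))
    }
  }
  expect_error(sort_variants(ds, "bogus"), "unknown sort key")
})

test_that("filtering matches direct counts and a naive double loop", {
  toy <- toy_fixture()
  expect_equal(nrow(filter_variants(toy, importance = "high")$variants), 2L)
  expect_identical(filter_variants(toy)$variants, toy$variants)
  expect_equal(nrow(filter_variants(toy, importance = "high",
                                    impact = "protective")$variants), 0L)
  for (seed in 1:25) {
    ds <- generate_dataset(random_spec(seed))
    got <- filter_variants(ds, impact = "pathogenic",
                           evidence = "well-established")$variants
    want <- naive_filter(ds$variants, list(impact = "pathogenic",
                                           evidence = "well-established"))
    expect_equal(got$variant_id, want$variant_id)
  }
  expect_error(filter_variants(toy, nonsense = 1), "unknown field")
})

test_that("search covers label, gene, conditions and summary text", {
  toy <- toy_fixture()
  hit <- search_variants(toy, "GENE903")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$gene, "GENE903")
  expect_equal(nrow(search_variants(toy, "")), 10L)
  # a token present only inside summaries
  v <- toy$variants
  v$summary[4] <- "Carries a distinctive PHRASEMARKER in the literature."
  ds <- report_dataset(v)
  hit <- search_variants(ds, "phrasemarker")
  expect_equal(nrow(hit), 1L)
  # condition text is searchable
  expect_equal(nrow(search_variants(toy, "macular")), 2L)
})

test_that("glossary files read and validate", {
  gl <- read_glossary("allele frequency\tHow common a variant is.\npathogenic\tHarmful.")
  expect_equal(gl$term, c("allele frequency", "pathogenic"))
  err <- tryCatch(read_glossary("only-one-field"),
                  varreport_parse_error = identity)
  expect_match(conditionMessage(err), "line 1")
})
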