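test_that("squarify handles the canonical examples exactly", {
  one <- squarify(1)
  expect_equal(unlist(one), c(x = 0, y = 0, w = 1, h = 1))
  four <- squarify(c(1, 1, 1, 1))
  expect_equal(four$w * four$h, rep(0.25, 4), tolerance = 1e-12)
  expect_equal(max_pairwise_overlap(four), 0, tolerance = 1e-12)
  # the classic seven-weight example in a 6 x 4 container
  sq <- squarify(c(6, 6, 4, 3, 2, 2, 1), c(0, 0, 6, 4))
  expect_equal(sq$w * sq$h, c(6, 6, 4, 3, 2, 2, 1), tolerance = 1e-9)
  expect_equal(sum(sq$w * sq$h), 24, tolerance = 1e-9)
  expect_equal(max_pairwise_overlap(sq), 0, tolerance = 1e-12)
  expect_error(squarify(c(1, 0)), "positive")
  expect_error(squarify(c(1, -2)), "positive")
})

test_that("empty datasets lay out with zero shapes and three group frames where applicable", {
  empty <- parse_report(paste0(
    "variant_id\tgene\tlabel\tzygosity\tfrequency\timpact\tevidence\t",
    "importance\tconditions\tsummary\tlinks\n"), "tsv")
  for (design in REPORT_DESIGNS) {
    g <- layout_report(empty, design)
    expect_equal(nrow(g$shapes), 0L, info = design)
    if (design != "table") {
      expect_equal(nrow(g$group_frames), 3L, info = design)
      expect_setequal(g$group_frames$label, c("high", "medium", "low"))
    }
  }
})

test_that("heat map places the per-importance counts in the three boxes", {
  g <- layout_report(toy_fixture(), "heatmap")
  counts <- table(g$shapes$group)
  expect_equal(unname(counts[c("high", "medium", "low")]),
               c(2L, 3L, 5L), ignore_attr = TRUE)
  # cells live inside their gray frame
  for (i in seq_len(nrow(g$shapes))) {
    fr <- g$group_frames[g$group_frames$label == g$shapes$group[i], ]
    expect_gte(g$shapes$x[i], fr$x - 1e-12)
    expect_lte(g$shapes$x[i] + g$shapes$w[i], fr$x + fr$w + 1e-12)
  }
})

test_that("partition level-1 band widths are proportional to group counts", {
  g <- layout_report(toy_fixture(), "zoom_partition")
  top <- g$group_frames[g$group_frames$label %in% c("high", "medium", "low"), ]
  widths <- top$w[match(c("high", "medium", "low"), top$label)]
  expect_equal(widths / widths[1], c(2, 3, 5) / 2, tolerance = 1e-12)
  expect_equal(sum(widths), 1, tolerance = 1e-12)
  # level-2 widths partition each level-1 band exactly
  for (imp in c("high", "medium", "low")) {
    l2 <- g$group_frames[startsWith(g$group_frames$label, paste0(imp, "/")), ]
    expect_equal(sum(l2$w), widths[match(imp, c("high", "medium", "low"))],
                 tolerance = 1e-15)
  }
})

test_that("bar heights follow the potential-effect rank and bubbles sit in rank bands", {
  ds <- full_coverage_fixture()
  gb <- layout_report(ds, "bar")
  v <- ds$variants
  ranks <- effect_rank(v$impact, v$evidence)
  hts <- gb$shapes$h[match(v$variant_id, gb$shapes$id)]
  # taller bar <=> stronger effect (smaller rank), per panel height scale
  expect_equal(order(hts, decreasing = TRUE), order(ranks))
  gc <- layout_report(ds, "bubble")
  expect_true(all(gc$shapes$kind == "circle"))
  expect_true(circles_disjoint(gc$shapes))
  cys <- gc$shapes$cy[match(v$variant_id, gc$shapes$id)]
  # vertical band position increases with rank within a panel
  for (imp in c("high", "medium", "low")) {
    sel <- v$importance == imp
    if (sum(sel) > 1) expect_equal(order(cys[sel]), order(ranks[sel]))
  }
})

test_that("zoom state enumeration is exhaustive and valid", {
  toy <- toy_fixture()
  expect_equal(enumerate_zoom_states(toy, "bar"), list(character(0)))
  states <- enumerate_zoom_states(toy, "zoom_treemap")
  expect_equal(length(states), 8L)   # 1 overview + 3 importance + 4 cells
  expect_equal(anyDuplicated(vapply(states, paste, character(1),
                                    collapse = "/")), 0L)
  for (st in states) {
    expect_silent(layout_report(toy, "zoom_treemap", st))
  }
  expect_equal(length(enumerate_zoom_states(toy, "treemap")), 4L)
})

test_that("zoom navigation honours select/back/reset and rejects invalid moves", {
  toy <- toy_fixture()
  expect_equal(zoom_navigate(toy, "zoom_treemap", c("high"), "reset"),
               character(0))
  st <- zoom_navigate(toy, "zoom_treemap", character(0), "select",
                      node = "medium")
  expect_equal(st, "medium")
  expect_equal(zoom_navigate(toy, "zoom_treemap", st, "back"), character(0))
  expect_error(zoom_navigate(toy, "zoom_treemap", character(0), "back"),
               "overview")
  expect_error(zoom_navigate(toy, "zoom_treemap", character(0), "select",
                             node = "benign.likely"), "invalid zoom")
  expect_error(layout_report(toy, "bar", zoom = "high"), "invalid zoom")
  expect_error(layout_report(toy, "bogus"), "unknown design")
})

test_that("a random walk of valid zoom actions never leaves the state space", {
  toy <- toy_fixture()
  ds <- generate_dataset(random_spec(5))
  for (dataset in list(toy, ds)) {
    for (design in c("treemap", "zoom_treemap", "zoom_partition")) {
      st <- character(0)
      set.seed(11)
      states <- enumerate_zoom_states(dataset, design)
      keys <- vapply(states, paste, character(1), collapse = "/")
      for (step in 1:250) {
        depth <- length(st)
        max_depth <- if (design == "treemap") 1L else 2L
        choices <- c("reset", if (depth > 0) "back",
                     if (depth < max_depth) "select")
        act <- sample(choices, 1)
        if (act == "select") {
          children <- if (depth == 0) {
            unique(dataset$variants$importance)
          } else {
            sub <- dataset$variants[dataset$variants$importance == st[1], ]
            unique(paste(sub$impact, sub$evidence, sep = "."))
          }
          st <- zoom_navigate(dataset, design, st, "select",
                              node = sample(children, 1))
        } else {
          st <- zoom_navigate(dataset, design, st, act)
        }
        expect_true(paste(st, collapse = "/") %in% keys)
      }
    }
  }
})

test_that("treemap descent shows exactly the selected group's variants", {
  toy <- toy_fixture()
  g0 <- layout_report(toy, "treemap")
  expect_equal(nrow(g0$shapes), 0L)
  expect_equal(nrow(g0$group_frames), 3L)
  g1 <- layout_report(toy, "treemap", zoom = "low")
  expect_equal(nrow(g1$shapes), 5L)
  expect_equal(sum(g1$shapes$w * g1$shapes$h) /
                 (g1$group_frames$w * g1$group_frames$h - 0), 1,
               tolerance = 0.2)  # inset padding only
  expect_equal(max_pairwise_overlap(g1$shapes), 0, tolerance = 1e-12)
})

test_that("table geometry exposes one row per variant plus sortable columns", {
  g <- layout_report(toy_fixture(), "table")
  expect_equal(nrow(g$shapes), 10L)
  expect_true(all(c("label", "gene", "frequency", "importance") %in%
                    g$columns))
  expect_equal(max_pairwise_overlap(g$shapes), 0, tolerance = 1e-12)
})
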