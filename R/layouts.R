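# Deterministic geometry for the seven report designs.
#
# All geometry lives on the unit square (origin top-left, y increasing
# downward); renderers scale to pixels. Layouts are pure functions of
# (dataset, design, zoom state): identical inputs give identical geometry.
#
# The three zoom-capable designs share one hierarchy:
#   level 1: clinical importance (high, medium, low)
#   level 2: potential-effect cell (impact.evidence, ranks 1..9)
#   level 3: individual variants
# The plain treemap design navigates one level deep (importance only); the
# zoomable treemap and zoomable partition navigate two levels.

# Named layout constants (fractions of the unit canvas).
LAYOUT_GAP <- 0.02      # gap between importance panels
FRAME_INSET <- 0.012    # inset of content inside a group frame
CELL_INSET <- 0.10      # heat-map cell inset, fraction of the cell
TABLE_HEADER_H <- 0.06  # table design header band
BUBBLE_SHRINK <- 0.8    # bubble radius = 0.8 x half the cell's smaller side
HEATMAP_FRAME_FILL <- "cccccc"  # gray importance boxes of the heat map

rect_df <- function(x = numeric(0), y = numeric(0), w = numeric(0),
                    h = numeric(0)) {
  data.frame(x = x, y = y, w = w, h = h)
}

#' Squarified treemap layout
#'
#' Tiles a container rectangle with one rectangle per weight, areas exactly
#' proportional to the weights (summing to the container area), pairwise
#' non-overlapping. Rows are laid greedily along the shorter side of the
#' remaining free rectangle, fixing each row when adding the next item would
#' worsen the row's worst aspect ratio (the squarified criterion). Rectangles
#' are returned in input order; for the classic visual quality, pass weights
#' sorted in decreasing order.
#'
#' @param weights positive numeric vector.
#' @param container numeric `c(x, y, w, h)`; defaults to the unit square.
#' @return data.frame with columns `x`, `y`, `w`, `h`, one row per weight.
#' @export
squarify <- function(weights, container = c(0, 0, 1, 1)) {
  if (length(weights) == 0L) return(rect_df())
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("squarify: all weights must be positive and finite", call. = FALSE)
  }
  if (container[3] <= 0 || container[4] <= 0) {
    stop("squarify: degenerate container", call. = FALSE)
  }
  areas <- weights / sum(weights) * (container[3] * container[4])
  n <- length(areas)
  out <- matrix(NA_real_, n, 4)
  free <- container  # (x, y, w, h) of the remaining free rectangle

  worst <- function(row_areas, s) {
    # worst aspect ratio of a row of areas laid along a side of length s
    total <- sum(row_areas)
    mx <- max(row_areas); mn <- min(row_areas)
    max((s^2 * mx) / total^2, total^2 / (s^2 * mn))
  }
  place_row <- function(idx, free) {
    total <- sum(areas[idx])
    if (free[3] >= free[4]) {
      # vertical strip on the left, items stacked top to bottom
      strip_w <- total / free[4]
      edges <- free[2] + cumsum(c(0, areas[idx])) / strip_w
      for (j in seq_along(idx)) {
        out[idx[j], ] <<- c(free[1], edges[j], strip_w, edges[j + 1] - edges[j])
      }
      c(free[1] + strip_w, free[2], free[3] - strip_w, free[4])
    } else {
      # horizontal strip on top, items left to right
      strip_h <- total / free[3]
      edges <- free[1] + cumsum(c(0, areas[idx])) / strip_h
      for (j in seq_along(idx)) {
        out[idx[j], ] <<- c(edges[j], free[2], edges[j + 1] - edges[j], strip_h)
      }
      c(free[1], free[2] + strip_h, free[3], free[4] - strip_h)
    }
  }

  row <- integer(0)
  for (i in seq_len(n)) {
    s <- min(free[3], free[4])
    if (length(row) == 0L ||
        worst(areas[c(row, i)], s) <= worst(areas[row], s)) {
      row <- c(row, i)
    } else {
      free <- place_row(row, free)
      row <- i
    }
  }
  if (length(row)) {
    # the last row's total area equals the remaining free area, so this
    # strip fills the free rectangle (up to floating-point rounding)
    place_row(row, free)
  }
  df <- as.data.frame(out)
  names(df) <- c("x", "y", "w", "h")
  df
}

# ---------------------------------------------------------------------------
# Hierarchy helpers

effect_key <- function(impact, evidence) paste(impact, evidence, sep = ".")

# Variants of a dataset annotated with hierarchy keys, in canonical order.
hier_variants <- function(dataset) {
  v <- dataset$variants
  v$rank <- if (nrow(v)) effect_rank(v$impact, v$evidence) else integer(0)
  v$ekey <- if (nrow(v)) effect_key(v$impact, v$evidence) else character(0)
  v$weight <- if (nrow(v)) unname(IMPORTANCE_WEIGHTS[v$importance]) else numeric(0)
  v
}

IMPORTANCE_ORDER <- c("high", "medium", "low")  # display order, left to right

# Non-empty effect keys of an importance group, in rank order.
group_effect_keys <- function(v, imp) {
  sub <- v[v$importance == imp, , drop = FALSE]
  if (!nrow(sub)) return(character(0))
  unique(sub$ekey[order(sub$rank)])
}

validate_zoom <- function(dataset, design, zoom) {
  zoom <- as.character(zoom %||% character(0))
  max_depth <- switch(design, treemap = 1L, zoom_treemap = 2L,
                      zoom_partition = 2L, 0L)
  if (length(zoom) > max_depth) {
    stop("invalid zoom state for design '", design, "': path too deep",
         call. = FALSE)
  }
  v <- hier_variants(dataset)
  if (length(zoom) >= 1L) {
    if (!(zoom[1] %in% IMPORTANCE_ORDER) ||
        !any(v$importance == zoom[1])) {
      stop("invalid zoom state: unknown or empty importance node '",
           zoom[1], "'", call. = FALSE)
    }
  }
  if (length(zoom) >= 2L) {
    if (!(zoom[2] %in% group_effect_keys(v, zoom[1]))) {
      stop("invalid zoom state: '", zoom[2],
           "' is not a non-empty effect node under '", zoom[1], "'",
           call. = FALSE)
    }
  }
  zoom
}

# Three side-by-side importance panels with gaps; returns frame data.frame.
importance_panels <- function() {
  w <- (1 - 4 * LAYOUT_GAP) / 3
  rect_df(x = LAYOUT_GAP + (0:2) * (w + LAYOUT_GAP),
          y = rep(LAYOUT_GAP, 3), w = rep(w, 3),
          h = rep(1 - 2 * LAYOUT_GAP, 3))
}

shape_row <- function(kind, id, group, fill, x = NA_real_, y = NA_real_,
                      w = NA_real_, h = NA_real_, cx = NA_real_,
                      cy = NA_real_, r = NA_real_) {
  data.frame(kind = kind, id = id, group = group, fill = fill,
             x = x, y = y, w = w, h = h, cx = cx, cy = cy, r = r,
             stringsAsFactors = FALSE)
}

empty_shapes <- function() shape_row(character(0), character(0), character(0),
                                     character(0), numeric(0), numeric(0),
                                     numeric(0), numeric(0), numeric(0),
                                     numeric(0), numeric(0))

frame_row <- function(label, x, y, w, h, fill = NA_character_) {
  data.frame(label = label, x = x, y = y, w = w, h = h, fill = fill,
             stringsAsFactors = FALSE)
}

empty_frames <- function() frame_row(character(0), numeric(0), numeric(0),
                                     numeric(0), numeric(0), character(0))

inset <- function(fr, by = FRAME_INSET) {
  c(fr$x + by, fr$y + by, max(fr$w - 2 * by, 0), max(fr$h - 2 * by, 0))
}

# Squarify importance groups by total weight inside the unit canvas.
# Zero-weight groups get zero-area frames; if every group is empty the
# canvas is split into three equal vertical panels.
importance_frames_by_weight <- function(weights) {
  stopifnot(length(weights) == 3L)
  if (all(weights == 0)) {
    p <- importance_panels()
    return(frame_row(IMPORTANCE_ORDER, p$x, p$y, p$w, p$h))
  }
  pos <- which(weights > 0)
  sq <- squarify(weights[pos], c(0, 0, 1, 1))
  out <- frame_row(IMPORTANCE_ORDER, rep(1, 3), rep(1, 3), rep(0, 3), rep(0, 3))
  out[pos, c("x", "y", "w", "h")] <- sq
  out
}

# ---------------------------------------------------------------------------
# Per-design layouts

layout_table <- function(v, scheme) {
  n <- nrow(v)
  frames <- empty_frames()
  if (n == 0L) {
    return(list(shapes = empty_shapes(), frames = frames))
  }
  row_h <- (1 - TABLE_HEADER_H) / n
  shapes <- shape_row(
    kind = "rect", id = v$variant_id, group = "table",
    fill = fill_hex(v$impact, v$evidence, scheme),
    x = 0, y = TABLE_HEADER_H + (seq_len(n) - 1) * row_h, w = 1, h = row_h)
  list(shapes = shapes, frames = frames)
}

TABLE_SORTABLE_COLUMNS <- c("label", "gene", "zygosity", "frequency",
                            "impact", "evidence", "importance", "conditions")

layout_bar <- function(v, scheme) {
  panels <- importance_panels()
  frames <- frame_row(IMPORTANCE_ORDER, panels$x, panels$y, panels$w, panels$h)
  shapes <- empty_shapes()
  for (g in seq_along(IMPORTANCE_ORDER)) {
    sub <- v[v$importance == IMPORTANCE_ORDER[g], , drop = FALSE]
    m <- nrow(sub)
    if (!m) next
    inner <- inset(panels[g, ])
    slot_w <- inner[3] / m
    bar_w <- BUBBLE_SHRINK * slot_w
    bar_h <- (10 - sub$rank) / 9 * inner[4]
    x <- inner[1] + (seq_len(m) - 1) * slot_w + (slot_w - bar_w) / 2
    shapes <- rbind(shapes, shape_row(
      kind = "bar", id = sub$variant_id, group = IMPORTANCE_ORDER[g],
      fill = fill_hex(sub$impact, sub$evidence, scheme),
      x = x, y = inner[2] + inner[4] - bar_h, w = bar_w, h = bar_h))
  }
  list(shapes = shapes, frames = frames)
}

layout_bubble <- function(v, scheme) {
  panels <- importance_panels()
  frames <- frame_row(IMPORTANCE_ORDER, panels$x, panels$y, panels$w, panels$h)
  shapes <- empty_shapes()
  for (g in seq_along(IMPORTANCE_ORDER)) {
    sub <- v[v$importance == IMPORTANCE_ORDER[g], , drop = FALSE]
    m <- nrow(sub)
    if (!m) next
    inner <- inset(panels[g, ])
    band_h <- inner[4] / 9
    slot_w <- inner[3] / m
    r <- BUBBLE_SHRINK * min(slot_w, band_h) / 2
    shapes <- rbind(shapes, shape_row(
      kind = "circle", id = sub$variant_id, group = IMPORTANCE_ORDER[g],
      fill = fill_hex(sub$impact, sub$evidence, scheme),
      cx = inner[1] + (seq_len(m) - 0.5) * slot_w,
      cy = inner[2] + (sub$rank - 0.5) * band_h, r = r))
  }
  list(shapes = shapes, frames = frames)
}

layout_heatmap <- function(v, scheme) {
  panels <- importance_panels()
  frames <- frame_row(IMPORTANCE_ORDER, panels$x, panels$y, panels$w, panels$h,
                      fill = HEATMAP_FRAME_FILL)
  shapes <- empty_shapes()
  for (g in seq_along(IMPORTANCE_ORDER)) {
    sub <- v[v$importance == IMPORTANCE_ORDER[g], , drop = FALSE]
    m <- nrow(sub)
    if (!m) next
    inner <- inset(panels[g, ])
    ncol_ <- ceiling(sqrt(m))
    nrow_ <- ceiling(m / ncol_)
    cw <- inner[3] / ncol_
    ch <- inner[4] / nrow_
    idx <- seq_len(m) - 1
    col <- idx %% ncol_
    row <- idx %/% ncol_
    shapes <- rbind(shapes, shape_row(
      kind = "rect", id = sub$variant_id, group = IMPORTANCE_ORDER[g],
      fill = fill_hex(sub$impact, sub$evidence, scheme),
      x = inner[1] + col * cw + CELL_INSET * cw,
      y = inner[2] + row * ch + CELL_INSET * ch,
      w = cw * (1 - 2 * CELL_INSET), h = ch * (1 - 2 * CELL_INSET)))
  }
  list(shapes = shapes, frames = frames)
}

layout_treemap <- function(v, scheme, zoom) {
  if (length(zoom) == 0L) {
    weights <- vapply(IMPORTANCE_ORDER,
                      function(imp) sum(v$weight[v$importance == imp]),
                      numeric(1))
    frames <- importance_frames_by_weight(weights)
    return(list(shapes = empty_shapes(), frames = frames))
  }
  imp <- zoom[1]
  sub <- v[v$importance == imp, , drop = FALSE]
  frames <- frame_row(imp, 0, 0, 1, 1)
  inner <- inset(frames[1, ])
  sq <- squarify(sub$weight, inner)
  shapes <- shape_row(kind = "rect", id = sub$variant_id, group = imp,
                      fill = fill_hex(sub$impact, sub$evidence, scheme),
                      x = sq$x, y = sq$y, w = sq$w, h = sq$h)
  list(shapes = shapes, frames = frames)
}

layout_zoom_treemap <- function(v, scheme, zoom) {
  if (length(zoom) == 0L) {
    weights <- vapply(IMPORTANCE_ORDER,
                      function(imp) sum(v$weight[v$importance == imp]),
                      numeric(1))
    return(list(shapes = empty_shapes(),
                frames = importance_frames_by_weight(weights)))
  }
  imp <- zoom[1]
  sub <- v[v$importance == imp, , drop = FALSE]
  if (length(zoom) == 1L) {
    keys <- group_effect_keys(v, imp)
    wts <- vapply(keys, function(k) sum(sub$weight[sub$ekey == k]), numeric(1))
    sq <- squarify(wts, c(0, 0, 1, 1))
    return(list(shapes = empty_shapes(),
                frames = frame_row(keys, sq$x, sq$y, sq$w, sq$h)))
  }
  cell <- sub[sub$ekey == zoom[2], , drop = FALSE]
  frames <- frame_row(zoom[2], 0, 0, 1, 1)
  sq <- squarify(cell$weight, inset(frames[1, ]))
  shapes <- shape_row(kind = "rect", id = cell$variant_id, group = zoom[2],
                      fill = fill_hex(cell$impact, cell$evidence, scheme),
                      x = sq$x, y = sq$y, w = sq$w, h = sq$h)
  list(shapes = shapes, frames = frames)
}

# Partition (icicle) bands: widths exactly proportional to descendant
# variant counts. Band edges are computed from cumulative counts so child
# widths sum exactly to the parent width.
partition_bands <- function(x0, w, counts) {
  total <- sum(counts)
  if (total == 0) return(rect_df())
  edges <- x0 + w * cumsum(c(0, counts)) / total
  rect_df(x = edges[-length(edges)], y = NA_real_,
          w = diff(edges), h = NA_real_)
}

layout_zoom_partition <- function(v, scheme, zoom) {
  rows_y <- c(0, 1 / 3, 2 / 3)
  row_h <- 1 / 3
  shapes <- empty_shapes()
  frames <- empty_frames()

  if (length(zoom) == 0L) {
    counts <- vapply(IMPORTANCE_ORDER,
                     function(imp) sum(v$importance == imp), numeric(1))
    if (sum(counts) == 0) {
      b <- partition_bands(0, 1, c(1, 1, 1))
      return(list(shapes = empty_shapes(),
                  frames = frame_row(IMPORTANCE_ORDER, b$x, rows_y[1], b$w,
                                     row_h)))
    }
    b <- partition_bands(0, 1, counts)
    frames <- frame_row(IMPORTANCE_ORDER, b$x, rows_y[1], b$w, row_h)
    for (g in seq_along(IMPORTANCE_ORDER)) {
      imp <- IMPORTANCE_ORDER[g]
      keys <- group_effect_keys(v, imp)
      if (!length(keys)) next
      kc <- vapply(keys, function(k) sum(v$ekey == k & v$importance == imp),
                   numeric(1))
      eb <- partition_bands(frames$x[g], frames$w[g], kc)
      frames <- rbind(frames, frame_row(paste(imp, keys, sep = "/"),
                                        eb$x, rows_y[2], eb$w, row_h))
      for (j in seq_along(keys)) {
        cell <- v[v$importance == imp & v$ekey == keys[j], , drop = FALSE]
        vb <- partition_bands(eb$x[j], eb$w[j], rep(1, nrow(cell)))
        shapes <- rbind(shapes, shape_row(
          kind = "rect", id = cell$variant_id, group = paste(imp, keys[j],
                                                             sep = "/"),
          fill = fill_hex(cell$impact, cell$evidence, scheme),
          x = vb$x, y = rows_y[3], w = vb$w, h = row_h))
      }
    }
    return(list(shapes = shapes, frames = frames))
  }

  imp <- zoom[1]
  sub <- v[v$importance == imp, , drop = FALSE]
  keys <- if (length(zoom) == 2L) zoom[2] else group_effect_keys(v, imp)
  frames <- frame_row(imp, 0, rows_y[1], 1, row_h)
  kc <- vapply(keys, function(k) sum(sub$ekey == k), numeric(1))
  eb <- partition_bands(0, 1, kc)
  frames <- rbind(frames, frame_row(paste(imp, keys, sep = "/"), eb$x,
                                    rows_y[2], eb$w, row_h))
  for (j in seq_along(keys)) {
    cell <- sub[sub$ekey == keys[j], , drop = FALSE]
    vb <- partition_bands(eb$x[j], eb$w[j], rep(1, nrow(cell)))
    shapes <- rbind(shapes, shape_row(
      kind = "rect", id = cell$variant_id,
      group = paste(imp, keys[j], sep = "/"),
      fill = fill_hex(cell$impact, cell$evidence, scheme),
      x = vb$x, y = rows_y[3], w = vb$w, h = row_h))
  }
  list(shapes = shapes, frames = frames)
}

#' Compute the geometry of a report design
#'
#' Places one shape per visible variant (plus labelled group frames) on the
#' unit canvas for the requested design and zoom state. Geometry is a pure
#' function of its inputs: identical dataset, design, zoom and scheme give
#' identical output.
#'
#' @param dataset a `report_dataset`.
#' @param design one of `r paste0('"', REPORT_DESIGNS, '"', collapse = ", ")`.
#' @param zoom zoom state: `NULL`/`character(0)` for the overview, an
#'   importance token for a level-1 descent, or
#'   `c(importance, "impact.evidence")` for a level-2 descent (zoomable
#'   designs only).
#' @param scheme color scheme for shape fills.
#' @return object of class `layout_geometry`: list with `design`, `zoom`,
#'   `shapes` (kind, id, group, fill and rect/circle geometry columns),
#'   `group_frames`, and for the table design a `columns` attribute naming
#'   the sortable columns.
#' @export
layout_report <- function(dataset, design, zoom = NULL, scheme = "study3") {
  if (!(is.character(design) && length(design) == 1L &&
        design %in% REPORT_DESIGNS)) {
    stop("unknown design token: ", paste(design, collapse = ", "),
         call. = FALSE)
  }
  scheme <- match.arg(scheme, COLOR_SCHEMES)
  zoom <- validate_zoom(dataset, design, zoom)
  v <- hier_variants(dataset)
  res <- switch(design,
    table = layout_table(v, scheme),
    bar = layout_bar(v, scheme),
    bubble = layout_bubble(v, scheme),
    treemap = layout_treemap(v, scheme, zoom),
    heatmap = layout_heatmap(v, scheme),
    zoom_treemap = layout_zoom_treemap(v, scheme, zoom),
    zoom_partition = layout_zoom_partition(v, scheme, zoom))
  rownames(res$shapes) <- NULL
  rownames(res$frames) <- NULL
  geom <- structure(list(design = design, zoom = zoom, scheme = scheme,
                         shapes = res$shapes, group_frames = res$frames),
                    class = "layout_geometry")
  if (design == "table") geom$columns <- TABLE_SORTABLE_COLUMNS
  geom
}

#' @export
print.layout_geometry <- function(x, ...) {
  cat("<layout_geometry>", x$design,
      if (length(x$zoom)) paste0("[", paste(x$zoom, collapse = " > "), "]")
      else "[overview]",
      "-", nrow(x$shapes), "shapes,", nrow(x$group_frames), "frames\n")
  invisible(x)
}

#' Enumerate every zoom state of a design
#'
#' Returns the exhaustive, duplicate-free list of valid zoom states:
#' the overview, each non-empty level-1 node, and (for the two-level
#' designs) each non-empty (importance, effect) pair. Non-zoomable designs
#' yield only the overview.
#'
#' @param dataset a `report_dataset`.
#' @param design design token.
#' @return list of character vectors (`character(0)` is the overview).
#' @export
enumerate_zoom_states <- function(dataset, design) {
  stopifnot(design %in% REPORT_DESIGNS)
  states <- list(character(0))
  max_depth <- switch(design, treemap = 1L, zoom_treemap = 2L,
                      zoom_partition = 2L, 0L)
  if (max_depth == 0L) return(states)
  v <- hier_variants(dataset)
  for (imp in IMPORTANCE_ORDER) {
    if (!any(v$importance == imp)) next
    states <- c(states, list(imp))
    if (max_depth >= 2L) {
      for (k in group_effect_keys(v, imp)) {
        states <- c(states, list(c(imp, k)))
      }
    }
  }
  states
}

#' Navigate the zoom state machine
#'
#' `select` descends into a child node of the current path, `back` removes
#' the last element, `reset` returns to the overview. Invalid actions
#' (selecting a non-child, backing out of the overview) are errors.
#'
#' @param dataset a `report_dataset`.
#' @param design design token (must be zoom-capable for `select`).
#' @param state current zoom state (character vector).
#' @param action `"select"`, `"back"` or `"reset"`.
#' @param node child key for `select`: an importance token at the overview,
#'   an `impact.evidence` key one level down.
#' @return the new zoom state.
#' @export
zoom_navigate <- function(dataset, design, state, action = c("select", "back",
                                                             "reset"),
                          node = NULL) {
  action <- match.arg(action)
  state <- validate_zoom(dataset, design, state)
  if (action == "reset") return(character(0))
  if (action == "back") {
    if (!length(state)) stop("cannot go back from the overview", call. = FALSE)
    return(state[-length(state)])
  }
  if (is.null(node)) stop("select requires a node", call. = FALSE)
  validate_zoom(dataset, design, c(state, node))
}
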