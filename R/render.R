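# Self-contained document rendering: SVG per layout, single-file HTML per
# (dataset, design) embedding every zoom state, tooltip blocks in a fixed
# side panel (never over the plot area), the color legend and a clickable
# glossary. Documents are generated from static templates with no
# timestamps and no randomness, so identical inputs give identical bytes.

SVG_W <- 1200
SVG_H <- 800

fmt_px <- function(x, scale) sprintf("%.3f", x * scale)

#' Tooltip content for a variant
#'
#' Deterministic tooltip block: the variant's label as title, then the
#' effect phrase (evidence + impact), clinical importance, population
#' frequency, linked conditions and the summary verbatim (omitted when
#' empty), plus the external links. Glossary terms occurring in the body
#' are reported so renderers can mark them as glossary links.
#'
#' @param variant one row of a report's variants data.frame.
#' @param glossary optional glossary data.frame (`term`, `definition`).
#' @return list of class `tooltip_block`: `title`, `fields` (named
#'   character), `links`, `glossary_terms`.
#' @export
tooltip_content <- function(variant, glossary = NULL) {
  fields <- c(
    effect = paste(variant$evidence, variant$impact),
    importance = paste(variant$importance, "clinical importance"),
    frequency = paste0("allele frequency ", fmt_freq(variant$frequency)),
    conditions = {
      cond <- variant$conditions[[1]]
      if (length(cond)) paste(cond, collapse = ", ") else "no linked conditions"
    })
  if (nzchar(variant$summary)) fields <- c(fields, summary = variant$summary)
  body <- paste(fields, collapse = " ")
  terms <- character(0)
  if (!is.null(glossary) && nrow(glossary)) {
    hit <- vapply(glossary$term, function(tm) {
      grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tm), "\\b"),
            body, ignore.case = TRUE)
    }, logical(1))
    terms <- glossary$term[hit]
  }
  structure(list(title = variant$label, fields = fields,
                 links = variant$links[[1]], glossary_terms = terms),
            class = "tooltip_block")
}

gloss_slug <- function(term) gsub("[^a-z0-9]+", "-", tolower(term))

# Wrap glossary-term occurrences in an (already HTML-escaped) string with
# anchors into the glossary section.
mark_glossary <- function(html, glossary) {
  if (is.null(glossary) || !nrow(glossary)) return(html)
  for (tm in glossary$term[order(-nchar(glossary$term))]) {
    pat <- paste0("\\b(", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                               xml_escape(tm)), ")\\b")
    html <- gsub(pat, sprintf("<a class=\"gloss\" href=\"#gl-%s\">\\1</a>",
                              gloss_slug(tm)), html, ignore.case = TRUE)
  }
  html
}

#' Render a layout as SVG
#'
#' One drawable element per shape, filled with the encoded color of the
#' variant's effect category; group frames are drawn beneath the variant
#' shapes. Output is well-formed XML and byte-identical across runs.
#'
#' @param geometry a `layout_geometry`.
#' @param dataset optional dataset used for hover titles (variant labels).
#' @return SVG document text.
#' @export
render_svg <- function(geometry, dataset = NULL) {
  stopifnot(inherits(geometry, "layout_geometry"))
  labels <- NULL
  if (!is.null(dataset)) {
    labels <- setNames(dataset$variants$label, dataset$variants$variant_id)
  }
  out <- c(sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                          "viewBox=\"0 0 %d %d\" ",
                          "data-design=\"%s\" data-zoom=\"%s\">"),
                   SVG_W, SVG_H, geometry$design,
                   xml_escape(paste(geometry$zoom, collapse = "/"))))
  fr <- geometry$group_frames
  for (i in seq_len(nrow(fr))) {
    fill <- if (!is.na(fr$fill[i])) paste0("#", fr$fill[i]) else "none"
    out <- c(out, sprintf(paste0("<rect class=\"frame\" data-group=\"%s\" ",
                                 "x=\"%s\" y=\"%s\" width=\"%s\" ",
                                 "height=\"%s\" fill=\"%s\" ",
                                 "stroke=\"#888888\" stroke-width=\"1\"/>"),
                          xml_escape(fr$label[i]),
                          fmt_px(fr$x[i], SVG_W), fmt_px(fr$y[i], SVG_H),
                          fmt_px(fr$w[i], SVG_W), fmt_px(fr$h[i], SVG_H),
                          fill))
  }
  sh <- geometry$shapes
  for (i in seq_len(nrow(sh))) {
    title <- if (!is.null(labels)) {
      sprintf("<title>%s</title>", xml_escape(labels[[sh$id[i]]]))
    } else ""
    if (sh$kind[i] == "circle") {
      out <- c(out, sprintf(paste0("<circle class=\"variant\" ",
                                   "data-variant-id=\"%s\" cx=\"%s\" ",
                                   "cy=\"%s\" r=\"%s\" fill=\"#%s\">%s",
                                   "</circle>"),
                            xml_escape(sh$id[i]),
                            fmt_px(sh$cx[i], SVG_W), fmt_px(sh$cy[i], SVG_H),
                            fmt_px(sh$r[i], min(SVG_W, SVG_H)),
                            sh$fill[i], title))
    } else {
      out <- c(out, sprintf(paste0("<rect class=\"variant\" ",
                                   "data-variant-id=\"%s\" x=\"%s\" ",
                                   "y=\"%s\" width=\"%s\" height=\"%s\" ",
                                   "fill=\"#%s\" stroke=\"#ffffff\" ",
                                   "stroke-width=\"0.5\">%s</rect>"),
                            xml_escape(sh$id[i]),
                            fmt_px(sh$x[i], SVG_W), fmt_px(sh$y[i], SVG_H),
                            fmt_px(sh$w[i], SVG_W), fmt_px(sh$h[i], SVG_H),
                            sh$fill[i], title))
    }
  }
  paste0(paste(c(out, "</svg>"), collapse = "\n"), "\n")
}

tooltip_html <- function(variant, glossary) {
  tb <- tooltip_content(variant, glossary)
  fields <- vapply(names(tb$fields), function(nm) {
    sprintf("<div class=\"tip-field tip-%s\">%s</div>", nm,
            mark_glossary(xml_escape(tb$fields[[nm]]), glossary))
  }, character(1))
  links <- if (length(tb$links)) {
    sprintf("<div class=\"tip-links\">%s</div>",
            paste(sprintf("<a href=\"%s\">%s</a>", xml_escape(tb$links),
                          xml_escape(tb$links)), collapse = " "))
  } else ""
  sprintf(paste0("<div class=\"tooltip-block\" id=\"tip-%s\">",
                 "<h4>%s</h4>%s%s</div>"),
          xml_escape(variant$variant_id), xml_escape(tb$title),
          paste(fields, collapse = ""), links)
}

legend_html <- function(scheme) {
  leg <- report_legend(scheme)
  rows <- sprintf(paste0("<tr><td><span class=\"swatch\" style=\"background:",
                         "#%s\"></span></td><td>%s</td></tr>"),
                  leg$hex, xml_escape(leg$label))
  sprintf("<table class=\"legend\">%s</table>", paste(rows, collapse = ""))
}

table_html <- function(dataset) {
  v <- dataset$variants
  head_cells <- sprintf(paste0("<th data-col=\"%s\" onclick=\"sortTable(",
                               "this)\">%s &#x25B4;&#x25BE;</th>"),
                        TABLE_SORTABLE_COLUMNS, TABLE_SORTABLE_COLUMNS)
  rows <- vapply(seq_len(nrow(v)), function(i) {
    cells <- c(v$label[i], v$gene[i], v$zygosity[i], fmt_freq(v$frequency[i]),
               v$impact[i], v$evidence[i], v$importance[i],
               paste(v$conditions[[i]], collapse = "; "))
    sprintf("<tr data-variant-id=\"%s\">%s</tr>", xml_escape(v$variant_id[i]),
            paste(sprintf("<td>%s</td>", xml_escape(cells)), collapse = ""))
  }, character(1))
  sprintf(paste0("<table id=\"report-table\"><thead><tr>%s</tr></thead>",
                 "<tbody>%s</tbody></table>"),
          paste(head_cells, collapse = ""), paste(rows, collapse = ""))
}

HTML_CSS <- paste(
  "body{font-family:sans-serif;margin:1em;}",
  ".layout{display:flex;gap:1em;}",
  ".plot{flex:3;}",
  ".side-panel{flex:1;border-left:1px solid #ccc;padding-left:1em;",
  "min-width:16em;}",
  ".tooltip-block{display:none;}",
  ".tooltip-block.active{display:block;}",
  ".swatch{display:inline-block;width:1em;height:1em;border:1px solid #999;}",
  ".view{display:none;} .view.active{display:block;}",
  "table#report-table{border-collapse:collapse;}",
  "table#report-table td,table#report-table th{border:1px solid #ccc;",
  "padding:2px 6px;} th{cursor:pointer;}",
  "dt{font-weight:bold;}", sep = "\n")

HTML_JS <- paste(
  "function showView(k){",
  "  document.querySelectorAll('.view').forEach(function(v){",
  "    v.classList.toggle('active', v.id === 'view-' + k);});",
  "}",
  "function wireTips(){",
  "  document.querySelectorAll('.view').forEach(function(view){",
  "    view.querySelectorAll('[data-variant-id]').forEach(function(el){",
  "      el.addEventListener('mouseover', function(){",
  "        view.querySelectorAll('.tooltip-block').forEach(function(t){",
  "          t.classList.toggle('active',",
  "            t.id === 'tip-' + el.getAttribute('data-variant-id'));});",
  "      });",
  "    });",
  "  });",
  "}",
  "function sortTable(th){",
  "  var table = document.getElementById('report-table');",
  "  var idx = Array.prototype.indexOf.call(th.parentNode.children, th);",
  "  var rows = Array.prototype.slice.call(table.tBodies[0].rows);",
  "  var dir = th.dataset.dir === 'asc' ? -1 : 1;",
  "  th.dataset.dir = dir === 1 ? 'asc' : 'desc';",
  "  rows.sort(function(a, b){",
  "    var x = a.cells[idx].textContent, y = b.cells[idx].textContent;",
  "    var nx = parseFloat(x), ny = parseFloat(y);",
  "    if (!isNaN(nx) && !isNaN(ny)) return dir * (nx - ny);",
  "    return dir * x.localeCompare(y);",
  "  });",
  "  rows.forEach(function(r){ table.tBodies[0].appendChild(r); });",
  "}",
  "document.addEventListener('DOMContentLoaded', function(){",
  "  wireTips();",
  "  var first = document.querySelector('.view');",
  "  if (first) first.classList.add('active');",
  "});", sep = "\n")

zoom_state_label <- function(zoom) {
  if (!length(zoom)) "overview" else paste(zoom, collapse = " / ")
}

#' Render a self-contained interactive HTML report
#'
#' Emits one single-file document for a (dataset, design) pair: an embedded
#' SVG for every zoom state (precomputed by [enumerate_zoom_states()]), the
#' per-view tooltip blocks in a fixed side panel beside (never over) the
#' plot, the nine-color legend, the clickable glossary, and - for the table
#' design - the sortable data table. All interactivity only toggles
#' precomputed content; nothing is fetched from the network.
#'
#' @param dataset a `report_dataset`.
#' @param design design token.
#' @param scheme color scheme.
#' @param path optional output file.
#' @return the HTML text; invisibly when `path` is given.
#' @export
render_html <- function(dataset, design, scheme = "study3", path = NULL) {
  states <- enumerate_zoom_states(dataset, design)
  glossary <- dataset$glossary
  views <- vapply(seq_along(states), function(si) {
    zoom <- states[[si]]
    geom <- layout_report(dataset, design, zoom, scheme)
    visible <- geom$shapes$id
    vis_rows <- dataset$variants[dataset$variants$variant_id %in% visible, ,
                                 drop = FALSE]
    tips <- vapply(seq_len(nrow(vis_rows)), function(i) {
      tooltip_html(vis_rows[i, , drop = FALSE], glossary)
    }, character(1))
    nav <- if (length(states) > 1L) {
      btns <- vapply(seq_along(states), function(sj) {
        sprintf("<button onclick=\"showView(%d)\">%s</button>", sj,
                xml_escape(zoom_state_label(states[[sj]])))
      }, character(1))
      sprintf("<nav class=\"zoom-nav\">%s</nav>", paste(btns, collapse = ""))
    } else ""
    extra <- if (design == "table" && !length(zoom)) table_html(dataset) else ""
    sprintf(paste0("<section class=\"view\" id=\"view-%d\" ",
                   "data-zoom=\"%s\"><h3>%s</h3>%s",
                   "<div class=\"layout\"><div class=\"plot\">%s%s</div>",
                   "<aside class=\"side-panel\"><h4>Details</h4>",
                   "<p class=\"hint\">Hover over a variant to pin its ",
                   "details here.</p>%s</aside></div></section>"),
            si, xml_escape(paste(zoom, collapse = "/")),
            xml_escape(zoom_state_label(zoom)), nav,
            render_svg(geom, dataset), extra,
            paste(tips, collapse = ""))
  }, character(1))
  gl_items <- if (nrow(glossary)) {
    paste(sprintf("<dt id=\"gl-%s\">%s</dt><dd>%s</dd>",
                  gloss_slug(glossary$term), xml_escape(glossary$term),
                  xml_escape(glossary$definition)), collapse = "")
  } else ""
  html <- paste0(
    "<!DOCTYPE html>\n<html lang=\"en\">\n<head>\n",
    "<meta charset=\"utf-8\"/>\n",
    sprintf("<title>%s&#39;s genome report (%s)</title>\n",
            xml_escape(dataset$subject), design),
    "<style>\n", HTML_CSS, "\n</style>\n</head>\n<body>\n",
    sprintf("<h1>%s&#39;s genome report</h1>\n<h2>Design: %s</h2>\n",
            xml_escape(dataset$subject), design),
    "<section id=\"legend\"><h3>Color key</h3>", legend_html(scheme),
    "</section>\n",
    paste(views, collapse = "\n"), "\n",
    "<section id=\"glossary\"><h3>Glossary</h3><dl>", gl_items,
    "</dl></section>\n",
    "<script>\n", HTML_JS, "\n</script>\n</body>\n</html>\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(html), con)
    return(invisible(html))
  }
  html
}
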