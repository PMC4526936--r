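# Impact-by-certainty color encoding and the 9-level potential-effect scale.
#
# Every variant falls into one of nine (impact, evidence) cells. The cells
# are totally ordered into "potential effect" ranks 1..9: the pathogenic
# block first, then benign, then protective, and within each block
# well-established > likely > uncertain. Rank 1 is therefore
# well-established pathogenic and rank 9 uncertain protective. (The relative
# position of benign vs protective on this axis is a package decision; see
# the methods vignette.)
#
# Two fixed palettes encode the cells. The primary scheme maps impact to
# hue - pathogenic red, benign neutral white/gray, protective blue - and
# evidence certainty to saturation (high certainty = saturated). Red-blue
# was chosen over the older red-green scheme because it remains legible
# under red-green color-vision deficiency. The legacy red-green palette
# (pathogenic red, protective green) is retained solely for reproducing the
# original two-level treemap prototype.

EFFECT_TABLE <- data.frame(
  rank = 1:9,
  impact = rep(IMPACT_LEVELS, each = 3),
  evidence = rep(EVIDENCE_LEVELS, 3),
  stringsAsFactors = FALSE
)

COLOR_SCHEMES <- c("study3", "legacy_redgreen")

# Saturation steps for well-established / likely / uncertain; benign cells
# use lightness steps instead (a neutral family has no usable saturation).
SATURATION_STEPS <- c(`well-established` = 0.90, likely = 0.55, uncertain = 0.25)
BENIGN_LIGHTNESS <- c(`well-established` = 0.92, likely = 0.95, uncertain = 0.98)
HUE_PATHOGENIC <- 0 / 360
HUE_PROTECTIVE <- 220 / 360
HUE_PROTECTIVE_LEGACY <- 120 / 360

hex6 <- function(col) tolower(substring(col, 2))

build_palette <- function(scheme) {
  ev <- EFFECT_TABLE$evidence
  im <- EFFECT_TABLE$impact
  sat <- unname(SATURATION_STEPS[ev])
  hue <- switch(scheme,
    study3 = ifelse(im == "pathogenic", HUE_PATHOGENIC, HUE_PROTECTIVE),
    legacy_redgreen = ifelse(im == "pathogenic", HUE_PATHOGENIC,
                             HUE_PROTECTIVE_LEGACY))
  hex <- ifelse(im == "benign",
                hex6(gray(unname(BENIGN_LIGHTNESS[ev]))),
                hex6(hsv(hue, sat, 1)))
  family <- switch(scheme,
    study3 = c(pathogenic = "red", benign = "neutral", protective = "blue"),
    legacy_redgreen = c(pathogenic = "red", benign = "neutral",
                        protective = "green"))
  data.frame(
    rank = EFFECT_TABLE$rank, impact = im, evidence = ev,
    hue_family = unname(family[im]),
    saturation_level = unname(c(`well-established` = "high", likely = "mid",
                                uncertain = "low")[ev]),
    hex = hex, stringsAsFactors = FALSE)
}

PALETTES <- list(study3 = build_palette("study3"),
                 legacy_redgreen = build_palette("legacy_redgreen"))

#' Potential-effect rank of (impact, evidence) pairs
#'
#' Vectorized mapping of the nine (impact, evidence) cells onto ranks 1..9
#' (1 = well-established pathogenic ... 9 = uncertain protective).
#'
#' @param impact,evidence canonical tokens.
#' @return integer ranks.
#' @export
effect_rank <- function(impact, evidence) {
  i <- match(impact, IMPACT_LEVELS)
  j <- match(evidence, EVIDENCE_LEVELS)
  if (anyNA(i) || anyNA(j)) stop("invalid impact/evidence token", call. = FALSE)
  as.integer((i - 1L) * 3L + j)
}

#' Potential-effect category of a variant
#'
#' @param variant one row of a report's variants data.frame (or any list
#'   with `impact` and `evidence` fields).
#' @return list with `impact`, `evidence` and `rank` (1..9).
#' @export
effect_category <- function(variant) {
  rank <- effect_rank(variant$impact, variant$evidence)
  structure(list(impact = variant$impact, evidence = variant$evidence,
                 rank = rank), class = "effect_category")
}

#' Color assignment for an effect category
#'
#' Deterministic (scheme, impact, evidence) -> color lookup. In the primary
#' scheme pathogenic maps to the red family, benign to neutral
#' white/gray, protective to the blue family; saturation is high/mid/low for
#' well-established/likely/uncertain evidence. The legacy scheme replaces
#' blue with green. All nine hex values of a scheme are distinct.
#'
#' @param category an `effect_category` (or list with `impact`, `evidence`).
#' @param scheme `"study3"` (red-white-blue) or `"legacy_redgreen"`.
#' @return list with `hue_family`, `saturation_level` and `hex` (6-digit
#'   lowercase hex, no `#`).
#' @export
encode_color <- function(category, scheme = c("study3", "legacy_redgreen")) {
  scheme <- match.arg(scheme)
  pal <- PALETTES[[scheme]]
  row <- pal[pal$impact == category$impact & pal$evidence == category$evidence, ]
  if (nrow(row) != 1L) stop("invalid effect category", call. = FALSE)
  list(hue_family = row$hue_family, saturation_level = row$saturation_level,
       hex = row$hex)
}

#' Recover the effect category encoded by a hex color
#'
#' Inverse of [encode_color()] within a scheme.
#'
#' @param hex 6-digit lowercase hex string.
#' @param scheme color scheme name.
#' @return an `effect_category`.
#' @export
decode_color <- function(hex, scheme = c("study3", "legacy_redgreen")) {
  scheme <- match.arg(scheme)
  pal <- PALETTES[[scheme]]
  row <- pal[pal$hex == hex, ]
  if (nrow(row) != 1L) stop("hex value not in scheme palette: ", hex,
                            call. = FALSE)
  effect_category(list(impact = row$impact, evidence = row$evidence))
}

# Vectorized fill lookup used by the layout engines.
fill_hex <- function(impact, evidence, scheme) {
  pal <- PALETTES[[scheme]]
  key <- paste(impact, evidence)
  pal$hex[match(key, paste(pal$impact, pal$evidence))]
}

NONTECH_IMPACT <- c(pathogenic = "potentially harmful", benign = "neutral",
                    protective = "protective")
NONTECH_EVIDENCE <- c(`well-established` = "strong evidence",
                      likely = "moderate evidence",
                      uncertain = "weak evidence")

#' Color legend of a scheme
#'
#' The nine categories in potential-effect rank order with their colors and
#' reader-facing labels. Labels lead with non-technical wording and append
#' the canonical term, e.g. "potentially harmful, strong evidence
#' (well-established pathogenic)".
#'
#' @param scheme color scheme name.
#' @return data.frame with columns `rank`, `impact`, `evidence`,
#'   `hue_family`, `saturation_level`, `hex`, `label`.
#' @export
report_legend <- function(scheme = c("study3", "legacy_redgreen")) {
  scheme <- match.arg(scheme)
  pal <- PALETTES[[scheme]]
  pal$label <- sprintf("%s, %s (%s %s)",
                       NONTECH_IMPACT[pal$impact],
                       NONTECH_EVIDENCE[pal$evidence],
                       pal$evidence, pal$impact)
  rownames(pal) <- NULL
  pal[order(pal$rank), ]
}

#' Export a legend as JSON
#'
#' @param scheme color scheme name.
#' @param path optional output file.
#' @return JSON text (category, hex, label per entry).
#' @export
legend_json <- function(scheme = "study3", path = NULL) {
  leg <- report_legend(scheme)
  out <- paste0(jsonlite::toJSON(leg, dataframe = "rows", pretty = TRUE), "\n")
  if (!is.null(path)) writeLines(out, path, sep = "")
  out
}
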