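# Shared enumeration levels and model constants.

#' Enumeration levels of the data model
#'
#' Canonical lowercase tokens of the three annotation axes, zygosity, the
#' seven report designs, and the per-variant importance weights used by the
#' area-proportional layouts (low = 1, medium = 2, high = 4).
#'
#' @name model-constants
#' @keywords internal
NULL

IMPACT_LEVELS <- c("pathogenic", "benign", "protective")
EVIDENCE_LEVELS <- c("well-established", "likely", "uncertain")
IMPORTANCE_LEVELS <- c("low", "medium", "high")   # total order low < medium < high
ZYGOSITY_LEVELS <- c("heterozygous", "homozygous", "unknown")

#' @rdname model-constants
#' @format NULL
#' @export
REPORT_DESIGNS <- c("table", "bar", "bubble", "treemap", "heatmap",
                    "zoom_treemap", "zoom_partition")

IMPORTANCE_WEIGHTS <- c(low = 1, medium = 2, high = 4)

REPORT_COLUMNS <- c("variant_id", "gene", "label", "zygosity", "frequency",
                    "impact", "evidence", "importance", "conditions",
                    "summary", "links")

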