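# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a named, portable PRNG stream
#'
#' All randomness in the package flows through one explicitly configured
#' generator (Mersenne-Twister, inversion normals, rejection sampling) so
#' that identical seeds give identical bytes across platforms and R
#' versions. The caller's RNG state is restored afterwards.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Code-point (C locale) ordering, the package-wide tie-break.
cp_order <- function(...) order(..., method = "radix")

# Signal a validation failure carrying a machine-readable violation table.
validation_error <- function(violations) {
  msg <- paste0(
    "validation failed (", nrow(violations), " violation(s)):\n",
    paste0("  - [", violations$field, "] ", violations$where, ": ",
           violations$message, collapse = "\n")
  )
  stop(structure(
    class = c("varreport_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), violations = violations)
  ))
}

parse_error <- function(msg) {
  stop(structure(
    class = c("varreport_parse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

violation <- function(field, where, message) {
  data.frame(field = field, where = as.character(where), message = message,
             stringsAsFactors = FALSE)
}

# Escape the five XML/HTML special characters.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&#39;", x, fixed = TRUE)
}
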