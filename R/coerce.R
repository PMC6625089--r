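#' Coerce a raw VCF value string to its declared type
#'
#' Applies the header metadata to one raw value: numeric types are parsed,
#' comma-separated lists are split when the field is declared multi-valued,
#' `"."` maps to missing (`NA`), and Flag fields map to a presence marker
#' (`TRUE`). A value that fails numeric coercion is kept as a string, tagged
#' with the attribute `degraded = TRUE`, and a warning is raised — the record
#' is never dropped.
#'
#' @param raw The text after `KEY=` (ignored for Flag fields).
#' @param def The [field_def()] for the key.
#' @return Typed value: `TRUE` for Flag; otherwise an integer, double or
#'   character vector (length > 1 for multi-valued fields) with `NA` for
#'   missing elements, or `NA` for a wholly missing value.
#' @export
coerce_value <- function(raw, def) {
  if (def$type == "Flag") return(TRUE)
  if (is.na(raw) || raw == "." || raw == "") return(NA)
  parts <- if (is_multi(def)) strsplit(raw, ",", fixed = TRUE)[[1]] else raw
  parts[parts == "."] <- NA_character_
  if (is_numeric_type(def)) {
    num <- suppressWarnings(as.numeric(parts))
    bad <- !is.na(parts) & is.na(num)
    if (any(bad)) {
      warning("field ", def$id, ": non-numeric value '",
              paste(parts[bad], collapse = ","),
              "' under declared type ", def$type,
              "; kept as string (degraded)", call. = FALSE)
      return(structure(parts, degraded = TRUE))
    }
    if (def$type == "Integer" && all(is.na(num) | num == floor(num))) {
      return(as.integer(num))
    }
    return(num)
  }
  parts
}

# Render a typed value back to VCF text. Inverse of coerce_value for
# round-trip purposes (numeric formatting via as.character, NA -> ".").
render_value <- function(value, def) {
  if (def$type == "Flag") return(NULL)  # flags render as the bare key
  if (length(value) == 0 || (length(value) == 1 && is.na(value))) return(".")
  txt <- ifelse(is.na(value), ".", as.character(value))
  paste(txt, collapse = ",")
}

value_is_missing <- function(value) {
  is.null(value) || length(value) == 0 || all(is.na(value))
}
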