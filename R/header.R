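#' Field definition for an INFO or FORMAT key
#'
#' A `field_def` captures one `##INFO=<...>` or `##FORMAT=<...>` header line:
#' the key identifier, its cardinality (`Number=`), its value type and its
#' free-text description. Field definitions drive two things downstream:
#' how raw strings are coerced ([coerce_value()]) and which filter operators
#' a field admits ([operators_for()]).
#'
#' @param id Key identifier (e.g. `"AF"`).
#' @param source `"INFO"` or `"FORMAT"`.
#' @param number Cardinality spec: a non-negative integer, or one of
#'   `"A"` (one value per alternate allele), `"R"` (per allele including the
#'   reference), `"G"` (per genotype), `"."` (unknown). Stored as character.
#' @param type One of `"Integer"`, `"Float"`, `"Flag"`, `"String"`,
#'   `"Character"`. `Flag` is only legal for INFO with `number = 0`.
#' @param description Free-text description.
#' @return An object of class `field_def`.
#' @export
field_def <- function(id, source = c("INFO", "FORMAT"), number = ".",
                      type = c("String", "Integer", "Float", "Flag", "Character"),
                      description = "") {
  source <- match.arg(source)
  type <- match.arg(type)
  number <- as.character(number)
  if (!grepl("^([0-9]+|[ARG.])$", number)) {
    stop("invalid Number spec '", number, "' for field ", id, call. = FALSE)
  }
  if (type == "Flag" && (number != "0" || source != "INFO")) {
    stop("Flag fields must be INFO with Number=0 (field ", id, ")", call. = FALSE)
  }
  structure(
    list(id = id, source = source, number = number, type = type,
         description = description),
    class = "field_def"
  )
}

#' @export
print.field_def <- function(x, ...) {
  cat(sprintf("<%s %s Number=%s Type=%s> %s\n",
              x$source, x$id, x$number, x$type, x$description))
  invisible(x)
}

is_numeric_type <- function(def) def$type %in% c("Integer", "Float")

#' Is a field declared multi-valued?
#'
#' Number other than 0 and 1 means the value is a comma-separated list.
#' @noRd
is_multi <- function(def) !(def$number %in% c("0", "1"))

# Split the key=value pairs inside ##INFO=<...>, honouring quoted strings.
split_meta_pairs <- function(body) {
  out <- character(0)
  buf <- ""
  in_quote <- FALSE
  for (ch in strsplit(body, "", fixed = TRUE)[[1]]) {
    if (ch == "\"") in_quote <- !in_quote
    if (ch == "," && !in_quote) {
      out <- c(out, buf)
      buf <- ""
    } else {
      buf <- paste0(buf, ch)
    }
  }
  c(out, buf)
}

parse_structured_line <- function(line, source) {
  body <- sub("^##[A-Za-z]+=<", "", line)
  body <- sub(">$", "", body)
  pairs <- split_meta_pairs(body)
  kv <- list()
  for (p in pairs) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) next
    key <- substr(p, 1, eq - 1)
    val <- substr(p, eq + 1, nchar(p))
    val <- sub("^\"", "", sub("\"$", "", val))
    kv[[key]] <- val
  }
  if (is.null(kv$ID) || is.null(kv$Type) || is.null(kv$Number)) {
    stop("malformed ", source, " header line (need ID, Number, Type): ", line,
         call. = FALSE)
  }
  field_def(id = kv$ID, source = source, number = kv$Number, type = kv$Type,
            description = if (is.null(kv$Description)) "" else kv$Description)
}

#' Parse VCF header lines into structured metadata
#'
#' Reads the `##` metadata block plus the `#CHROM` column line of a VCF and
#' returns a `vcf_header`: typed definitions for every INFO and FORMAT key,
#' the ordered sample names, and all other `##` lines preserved verbatim so
#' they survive a round trip.
#'
#' @param lines Character vector of header lines, starting with
#'   `##fileformat=` and containing exactly one `#CHROM` line.
#' @return A `vcf_header`: list with `fileformat`, `info_defs`,
#'   `format_defs` (named lists of [field_def()]), `sample_names`,
#'   `other_lines`.
#' @export
parse_header <- function(lines) {
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0 || !startsWith(lines[[1]], "##fileformat=")) {
    stop("malformed header: first line must be ##fileformat=", call. = FALSE)
  }
  chrom_idx <- which(startsWith(lines, "#CHROM"))
  if (length(chrom_idx) != 1) {
    stop("malformed header: expected exactly one #CHROM line, found ",
         length(chrom_idx), call. = FALSE)
  }
  fileformat <- sub("^##fileformat=", "", lines[[1]])
  info_defs <- list()
  format_defs <- list()
  other_lines <- character(0)
  for (line in lines[-c(1, chrom_idx)]) {
    if (startsWith(line, "##INFO=<")) {
      def <- parse_structured_line(line, "INFO")
      if (!is.null(info_defs[[def$id]])) {
        stop("duplicate INFO definition for ", def$id, call. = FALSE)
      }
      info_defs[[def$id]] <- def
    } else if (startsWith(line, "##FORMAT=<")) {
      def <- parse_structured_line(line, "FORMAT")
      if (!is.null(format_defs[[def$id]])) {
        stop("duplicate FORMAT definition for ", def$id, call. = FALSE)
      }
      format_defs[[def$id]] <- def
    } else if (startsWith(line, "##")) {
      other_lines <- c(other_lines, line)
    } else {
      stop("malformed header: unexpected line before #CHROM: ", line,
           call. = FALSE)
    }
  }
  cols <- strsplit(lines[[chrom_idx]], "\t", fixed = TRUE)[[1]]
  fixed <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(cols) < 8 || !identical(cols[1:8], fixed)) {
    stop("malformed header: #CHROM line must start with the 8 fixed columns",
         call. = FALSE)
  }
  sample_names <- if (length(cols) >= 10) cols[-(1:9)] else character(0)
  structure(
    list(fileformat = fileformat, info_defs = info_defs,
         format_defs = format_defs, sample_names = sample_names,
         other_lines = other_lines),
    class = "vcf_header"
  )
}

#' @export
print.vcf_header <- function(x, ...) {
  cat("VCF header (fileformat=", x$fileformat, ")\n", sep = "")
  cat("  INFO fields:  ", paste(names(x$info_defs), collapse = ", "), "\n")
  cat("  FORMAT fields:", paste(names(x$format_defs), collapse = ", "), "\n")
  cat("  samples:      ",
      if (length(x$sample_names)) paste(x$sample_names, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

render_field_def <- function(def) {
  sprintf("##%s=<ID=%s,Number=%s,Type=%s,Description=\"%s\">",
          def$source, def$id, def$number, def$type, def$description)
}

#' Render a `vcf_header` back to text lines
#'
#' Inverse of [parse_header()]: writing then re-parsing is the identity on
#' field definitions and sample names. Extra `##` provenance lines may be
#' appended just before the `#CHROM` line.
#'
#' @param header A `vcf_header`.
#' @param provenance Optional character vector of `##` lines to append.
#' @return Character vector of header lines.
#' @export
render_header <- function(header, provenance = character(0)) {
  if (length(provenance) && !all(startsWith(provenance, "##"))) {
    stop("provenance lines must start with '##'", call. = FALSE)
  }
  chrom <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO",
                   if (length(header$sample_names)) "FORMAT",
                   header$sample_names),
                 collapse = "\t")
  c(paste0("##fileformat=", header$fileformat),
    header$other_lines,
    vapply(header$info_defs, render_field_def, character(1), USE.NAMES = FALSE),
    vapply(header$format_defs, render_field_def, character(1), USE.NAMES = FALSE),
    provenance,
    chrom)
}

# Look up a field definition across INFO defs, FORMAT defs and the fixed
# columns. Fixed columns get pseudo-defs so operator generation is uniform.
fixed_column_def <- function(field) {
  switch(field,
    CHROM  = field_def("CHROM", "INFO", 1, "String"),
    POS    = field_def("POS", "INFO", 1, "Integer"),
    ID     = field_def("ID", "INFO", 1, "String"),
    QUAL   = field_def("QUAL", "INFO", 1, "Float"),
    FILTER = field_def("FILTER", "INFO", ".", "String"),
    NULL
  )
}
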