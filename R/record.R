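#' Parse depth levels
#'
#' Records can be parsed at three nested depths, trading completeness for
#' speed and memory:
#' \describe{
#'   \item{L0}{fixed columns (CHROM..QUAL), FILTER and typed INFO; no
#'     per-sample data.}
#'   \item{L1}{L0 plus the FORMAT key list.}
#'   \item{L2}{everything: all per-sample values, typed via the FORMAT
#'     definitions.}
#' }
#' FILTER is retained at every level so that pass-status queries work
#' regardless of depth.
#' @name parse_levels
NULL

check_level <- function(level) {
  if (!level %in% c("L0", "L1", "L2")) {
    stop("level must be one of L0, L1, L2", call. = FALSE)
  }
  level
}

#' Parse one VCF body line into a variant record
#'
#' @param line One tab-separated body line.
#' @param header A `vcf_header`; undeclared INFO/FORMAT keys are coerced as
#'   String (Number=".") and reported via the `"unknown_keys"` attribute of
#'   the result so the caller can auto-register them.
#' @param level Parse depth, see [parse_levels].
#' @param line_num Optional line number used in error messages.
#' @return A `vcf_record`: list with `chrom`, `pos`, `id`, `ref`, `alt`
#'   (character vector), `qual`, `filter` (character vector, `NULL` when
#'   missing), `info` (named list of typed values), `format_keys`, `samples`
#'   (named list of named lists).
#' @export
parse_record <- function(line, header, level = "L2", line_num = NA) {
  check_level(level)
  cols <- strsplit(sub("\r$", "", line), "\t", fixed = TRUE)[[1]]
  where <- if (is.na(line_num)) "" else paste0(" at line ", line_num)
  if (length(cols) < 8) {
    stop("malformed record", where, ": expected >= 8 columns, got ",
         length(cols), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(cols[[2]]))
  if (is.na(pos) || pos < 1) {
    stop("malformed record", where, ": POS '", cols[[2]],
         "' is not a positive integer", call. = FALSE)
  }
  unknown <- character(0)

  info <- list()
  if (cols[[8]] != ".") {
    for (item in strsplit(cols[[8]], ";", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", item, fixed = TRUE)
      key <- if (eq > 0) substr(item, 1, eq - 1) else item
      raw <- if (eq > 0) substr(item, eq + 1, nchar(item)) else NA_character_
      def <- header$info_defs[[key]]
      if (is.null(def)) {
        unknown <- c(unknown, key)
        def <- if (eq > 0) field_def(key, "INFO", ".", "String")
               else field_def(key, "INFO", 0, "Flag")
      }
      info[[key]] <- coerce_value(raw, def)
    }
  }

  format_keys <- character(0)
  samples <- list()
  if (level %in% c("L1", "L2") && length(cols) >= 9 && cols[[9]] != ".") {
    format_keys <- strsplit(cols[[9]], ":", fixed = TRUE)[[1]]
  }
  if (level == "L2" && length(cols) >= 10 && length(format_keys)) {
    snames <- header$sample_names
    n_sample_cols <- length(cols) - 9
    if (n_sample_cols > length(snames)) {
      stop("malformed record", where, ": ", n_sample_cols,
           " sample columns but header declares ", length(snames),
           " samples", call. = FALSE)
    }
    for (i in seq_len(n_sample_cols)) {
      vals <- strsplit(cols[[9 + i]], ":", fixed = TRUE)[[1]]
      entry <- list()
      for (k in seq_along(format_keys)) {
        key <- format_keys[[k]]
        raw <- if (k <= length(vals)) vals[[k]] else "."   # trailing drop
        def <- header$format_defs[[key]]
        if (is.null(def)) {
          unknown <- c(unknown, paste0("FORMAT:", key))
          def <- field_def(key, "FORMAT", ".", "String")
        }
        entry[[key]] <- coerce_value(raw, def)
      }
      samples[[snames[[i]]]] <- entry
    }
  }

  rec <- structure(
    list(chrom = cols[[1]], pos = pos,
         id = if (cols[[3]] == ".") NA_character_ else cols[[3]],
         ref = cols[[4]],
         alt = strsplit(cols[[5]], ",", fixed = TRUE)[[1]],
         qual = if (cols[[6]] == ".") NA_real_
                else suppressWarnings(as.numeric(cols[[6]])),
         filter = if (cols[[7]] == ".") NULL
                  else strsplit(cols[[7]], ";", fixed = TRUE)[[1]],
         info = info, format_keys = format_keys, samples = samples),
    class = "vcf_record"
  )
  if (length(unknown)) attr(rec, "unknown_keys") <- unique(unknown)
  rec
}

#' @export
print.vcf_record <- function(x, ...) {
  cat(sprintf("%s:%d %s>%s", x$chrom, x$pos, x$ref,
              paste(x$alt, collapse = ",")),
      if (!is.na(x$id)) paste0(" (", x$id, ")") else "",
      "\n", sep = "")
  invisible(x)
}

# Render one record back to a VCF body line.
render_record <- function(rec, header) {
  info_txt <- if (length(rec$info) == 0) "." else {
    parts <- character(0)
    for (key in names(rec$info)) {
      def <- header$info_defs[[key]]
      if (is.null(def)) def <- field_def(key, "INFO", ".", "String")
      if (def$type == "Flag") {
        if (isTRUE(rec$info[[key]])) parts <- c(parts, key)
      } else {
        parts <- c(parts, paste0(key, "=", render_value(rec$info[[key]], def)))
      }
    }
    if (length(parts)) paste(parts, collapse = ";") else "."
  }
  fixed <- c(rec$chrom, as.character(rec$pos),
             if (is.na(rec$id)) "." else rec$id,
             rec$ref, paste(rec$alt, collapse = ","),
             if (is.na(rec$qual)) "." else as.character(rec$qual),
             if (is.null(rec$filter)) "." else paste(rec$filter, collapse = ";"),
             info_txt)
  if (length(rec$format_keys) == 0 || length(rec$samples) == 0) {
    return(paste(fixed, collapse = "\t"))
  }
  cells <- character(0)
  for (s in names(rec$samples)) {
    entry <- rec$samples[[s]]
    vals <- vapply(rec$format_keys, function(key) {
      def <- header$format_defs[[key]]
      if (is.null(def)) def <- field_def(key, "FORMAT", ".", "String")
      v <- render_value(entry[[key]], def)
      if (is.null(v)) "." else v
    }, character(1))
    cells <- c(cells, paste(vals, collapse = ":"))
  }
  paste(c(fixed, paste(rec$format_keys, collapse = ":"), cells),
        collapse = "\t")
}
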