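#' Read a VCF file (plain or gzip) into header metadata and records
#'
#' Compression is detected from the leading magic bytes (`1f 8b`), never from
#' the file extension, so a gzipped file named `*.vcf` parses identically to
#' its uncompressed form. Undeclared INFO or FORMAT keys encountered in the
#' body are auto-registered as String fields with `Number="."` and reported
#' once per key via a message.
#'
#' @param path Path to a VCF file, plain or gzip-compressed.
#' @param level Parse depth, see [parse_levels]. Default `"L2"`.
#' @return List with `header` (a `vcf_header`, including any auto-registered
#'   definitions) and `records` (list of `vcf_record` in file order).
#' @export
read_vcf <- function(path, level = "L2") {
  check_level(level)
  if (!file.exists(path)) stop("input error: no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("input error: empty file: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 2)
  con <- if (length(magic) == 2 && magic[1] == as.raw(0x1f) &&
             magic[2] == as.raw(0x8b)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- sub("\r$", "", lines)
  is_header <- startsWith(lines, "#")
  hdr_end <- match(FALSE, is_header, nomatch = length(lines) + 1) - 1
  if (hdr_end < 2 || any(!is_header[seq_len(hdr_end)])) {
    stop("input error: no header block found in ", path, call. = FALSE)
  }
  header <- parse_header(lines[seq_len(hdr_end)])
  body <- lines[seq.int(hdr_end + 1, length.out = length(lines) - hdr_end)]
  body <- body[nzchar(body)]
  records <- vector("list", length(body))
  seen_unknown <- character(0)
  for (i in seq_along(body)) {
    rec <- parse_record(body[[i]], header, level, line_num = hdr_end + i)
    new <- setdiff(attr(rec, "unknown_keys"), seen_unknown)
    for (key in new) {
      if (startsWith(key, "FORMAT:")) {
        id <- sub("^FORMAT:", "", key)
        header$format_defs[[id]] <- field_def(id, "FORMAT", ".", "String")
      } else {
        header$info_defs[[key]] <- field_def(key, "INFO", ".", "String")
      }
      message("auto-registered undeclared key ", key, " as String")
    }
    seen_unknown <- c(seen_unknown, new)
    attr(rec, "unknown_keys") <- NULL
    records[[i]] <- rec
  }
  list(header = header, records = records)
}

#' Write records to a VCF file
#'
#' Provenance strings (e.g. canonical filter serializations) are emitted as
#' `##` lines immediately before the `#CHROM` line, so an exported file
#' documents how it was produced. Reading back a written file reproduces the
#' records field for field.
#'
#' @param header A `vcf_header`.
#' @param records List of `vcf_record`s consistent with `header`.
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @param provenance Character vector of `##` lines to embed.
#' @return Number of records written, invisibly.
#' @export
write_vcf <- function(header, records, path, provenance = character(0)) {
  for (rec in records) {
    extra <- setdiff(names(rec$samples), header$sample_names)
    if (length(extra)) {
      stop("consistency error: record ", rec$chrom, ":", rec$pos,
           " references sample(s) absent from header: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  lines <- c(render_header(header, provenance),
             vapply(records, render_record, character(1), header = header))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(length(records))
}

resolve_column <- function(spec, header) {
  if (spec %in% c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER")) {
    return(list(kind = "fixed", name = spec))
  }
  if (spec %in% names(header$info_defs)) {
    return(list(kind = "info", name = spec))
  }
  if (grepl(".", spec, fixed = TRUE)) {
    parts <- strsplit(spec, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[[1]] %in% header$sample_names &&
        parts[[2]] %in% names(header$format_defs)) {
      return(list(kind = "sample", sample = parts[[1]], key = parts[[2]]))
    }
  }
  valid <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
             names(header$info_defs),
             as.vector(outer(header$sample_names, names(header$format_defs),
                             paste, sep = ".")))
  stop("unknown column '", spec, "'; valid columns: ",
       paste(valid, collapse = ", "), call. = FALSE)
}

cell_value <- function(rec, col) {
  v <- switch(col$kind,
    fixed = switch(col$name,
      CHROM = rec$chrom, POS = rec$pos, ID = rec$id, REF = rec$ref,
      ALT = rec$alt, QUAL = rec$qual, FILTER = rec$filter),
    info = rec$info[[col$name]],
    sample = rec$samples[[col$sample]][[col$key]]
  )
  if (value_is_missing(v)) return(".")
  if (isTRUE(v)) return("1")
  paste(ifelse(is.na(v), ".", as.character(v)), collapse = ",")
}

quote_csv <- function(x) {
  needs <- grepl("[\",\n]", x)
  x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs]), "\"")
  x
}

#' Export records as a delimited table (CSV or TSV)
#'
#' Flattens selected fields into a spreadsheet-friendly table: one header row
#' then one row per record. Column specs name a fixed column (`CHROM`, `POS`,
#' ...), an INFO key (`AF`), or a per-sample FORMAT value (`CHILD.GT`).
#' List values are joined with `","`; missing values render as `"."`. CSV
#' fields containing the delimiter, quotes or newlines are quoted
#' (RFC-4180 style); TSV values may not contain tabs — any tab is replaced
#' by a space with a warning.
#'
#' @param header A `vcf_header`.
#' @param records List of `vcf_record`s.
#' @param columns Character vector of column specs.
#' @param path Output path.
#' @param dialect `"CSV"` or `"TSV"`.
#' @return Number of data rows written, invisibly.
#' @export
write_table <- function(header, records, columns, path,
                        dialect = c("CSV", "TSV")) {
  dialect <- match.arg(dialect)
  cols <- lapply(columns, resolve_column, header = header)
  sep <- if (dialect == "CSV") "," else "\t"
  rows <- vapply(records, function(rec) {
    cells <- vapply(cols, cell_value, character(1), rec = rec)
    if (dialect == "CSV") {
      cells <- quote_csv(cells)
    } else if (any(grepl("\t", cells, fixed = TRUE))) {
      warning("tab character in TSV value replaced by space", call. = FALSE)
      cells <- gsub("\t", " ", cells, fixed = TRUE)
    }
    paste(cells, collapse = sep)
  }, character(1))
  head_cells <- if (dialect == "CSV") quote_csv(columns) else columns
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(head_cells, collapse = sep), rows), con, sep = "\n")
  invisible(length(rows))
}
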