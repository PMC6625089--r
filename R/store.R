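#' Normalize a chromosome name for matching
#'
#' Strips a leading `chr`/`Chr`/`CHR` prefix and uppercases, so `"chr1"`,
#' `"Chr1"` and `"1"` compare equal and `"chrx"` matches `"X"`. The original
#' spelling is preserved on records and only normalized for comparisons.
#'
#' @param chrom Character vector of chromosome names.
#' @return Normalized character vector.
#' @export
normalize_chrom <- function(chrom) {
  toupper(sub("^[Cc][Hh][Rr]", "", chrom))
}

#' Build a queryable in-memory variant store
#'
#' Holds parsed records under dense, stable integer ids (1..n in insertion
#' order) together with the header metadata and any field indexes. All
#' queries answered through an index are guaranteed to equal the same query
#' by full scan; indexes are purely an access path.
#'
#' @param header A `vcf_header`.
#' @param records List of `vcf_record`s from one parse.
#' @return A `variant_store`.
#' @export
variant_store <- function(header, records) {
  structure(
    list(header = header, records = records, n = length(records),
         level = NULL, indexes = list()),
    class = "variant_store"
  )
}

#' Load a VCF file straight into a store
#'
#' Convenience wrapper: [read_vcf()] then [variant_store()].
#' @param path VCF path (plain or gzip).
#' @param level Parse depth, see [parse_levels].
#' @return A `variant_store`.
#' @export
load_vcf <- function(path, level = "L2") {
  parsed <- read_vcf(path, level)
  st <- variant_store(parsed$header, parsed$records)
  st$level <- level
  st
}

#' @export
print.variant_store <- function(x, ...) {
  cat("Variant store:", x$n, "records,",
      length(x$header$sample_names), "samples,",
      length(x$indexes), "indexes\n")
  if (length(x$indexes)) {
    cat("  indexes:", paste(names(x$indexes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.variant_store <- function(object, ...) {
  cat("Variant store\n")
  cat("  records:      ", object$n, "\n")
  cat("  samples:      ", paste(object$header$sample_names, collapse = ", "),
      "\n")
  cat("  INFO fields:  ", paste(names(object$header$info_defs),
                                collapse = ", "), "\n")
  cat("  FORMAT fields:", paste(names(object$header$format_defs),
                                collapse = ", "), "\n")
  invisible(object)
}

# Extract a field's scalar index key for every record; NA when absent.
index_keys <- function(store, field) {
  recs <- store$records
  switch(field,
    "CHROM+POS" = {
      ch <- vapply(recs, function(r) normalize_chrom(r$chrom), character(1))
      pos <- vapply(recs, function(r) r$pos, integer(1))
      sprintf("%s:%010d", ch, pos)
    },
    "REF+ALT" = vapply(recs, function(r)
      paste0(r$ref, ">", paste(r$alt, collapse = ",")), character(1)),
    "ID" = vapply(recs, function(r)
      if (is.na(r$id)) NA_character_ else r$id, character(1)),
    "QUAL" = vapply(recs, function(r)
      if (is.na(r$qual)) NA_character_ else as.character(r$qual), character(1)),
    "FILTER" = vapply(recs, function(r)
      if (is.null(r$filter)) NA_character_
      else paste(r$filter, collapse = ";"), character(1)),
    "CHROM" = vapply(recs, function(r) normalize_chrom(r$chrom), character(1)),
    "POS" = vapply(recs, function(r) as.character(r$pos), character(1)),
    {
      def <- store$header$info_defs[[field]]
      if (is.null(def)) {
        stop("unknown field '", field, "'; known fields: ",
             paste(c("CHROM", "POS", "ID", "QUAL", "FILTER", "CHROM+POS",
                     "REF+ALT", names(store$header$info_defs)),
                   collapse = ", "), call. = FALSE)
      }
      if (def$type == "Flag") {
        vapply(recs, function(r)
          if (isTRUE(r$info[[field]])) "present" else NA_character_,
          character(1))
      } else {
        vapply(recs, function(r) {
          v <- r$info[[field]]
          if (value_is_missing(v)) NA_character_
          else paste(as.character(v), collapse = ",")
        }, character(1))
      }
    }
  )
}

make_index <- function(store, field) {
  keys <- index_keys(store, field)
  present <- which(!is.na(keys))
  entries <- split(present, keys[present])          # ids sorted within group
  entries <- entries[order(names(entries))]
  structure(list(field = field, entries = entries), class = "store_index")
}

#' Build the default index set
#'
#' Creates the five standard indexes — `CHROM+POS`, `ID`, `REF+ALT`, `QUAL`
#' and `FILTER` — covering the commonly queried fields. Idempotent.
#'
#' @param store A `variant_store`.
#' @return The store with indexes attached.
#' @export
build_default_indexes <- function(store) {
  for (f in c("CHROM+POS", "ID", "REF+ALT", "QUAL", "FILTER")) {
    store <- build_index(store, f)
  }
  store
}

#' Index an arbitrary field
#'
#' Adds an equality index on a fixed column or declared INFO key. Queries on
#' the field may then use the index; results never change.
#'
#' @param store A `variant_store`.
#' @param field Field name (fixed column, composite `CHROM+POS`/`REF+ALT`,
#'   or INFO key).
#' @return The store with the index added.
#' @export
build_index <- function(store, field) {
  store$indexes[[field]] <- make_index(store, field)
  store
}

#' Query records by genomic region
#'
#' Returns ids of records on the (normalization-matched) chromosome with
#' `start <= POS <= end`, 1-based inclusive on both ends, in ascending id
#' order.
#'
#' @param store A `variant_store`.
#' @param chrom Chromosome name (any `chr` prefix convention).
#' @param start,end 1-based inclusive bounds.
#' @return Integer vector of record ids.
#' @export
query_region <- function(store, chrom, start, end) {
  if (start > end) stop("argument error: start > end", call. = FALSE)
  want <- normalize_chrom(chrom)
  hits <- vapply(store$records, function(r) {
    normalize_chrom(r$chrom) == want && r$pos >= start && r$pos <= end
  }, logical(1))
  which(hits)
}
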