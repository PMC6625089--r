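#' Create an empty LIFO filter stack over a store
#'
#' The stack is an ordered conjunction: each pushed filter is applied only
#' to the survivors of all previous filters, and removal is last-in
#' first-out. Survivor sets are therefore strictly nested down the stack,
#' and the final set equals the set of records satisfying all filters
#' independently — so it is invariant to filter order even though the
#' intermediate counts are not.
#'
#' @param store A `variant_store`.
#' @return A `filter_stack` whose base set is all record ids.
#' @export
filter_stack <- function(store) {
  structure(
    list(base = seq_len(store$n), levels = list()),
    class = "filter_stack"
  )
}

#' @export
print.filter_stack <- function(x, ...) {
  cat("Filter stack:", length(x$levels), "filter(s), base",
      length(x$base), "records\n")
  for (lev in x$levels) {
    cat("  ", render_filter(lev$filter), "->", lev$count, "survivors\n")
  }
  invisible(x)
}

top_ids <- function(stack) {
  n <- length(stack$levels)
  if (n == 0) stack$base else stack$levels[[n]]$ids
}

# Index-assisted candidate id set for a filter, or NULL when no index
# applies. Any returned set is exact for the filter's semantics, so the
# caller only needs to intersect with the current survivors.
index_candidates <- function(store, filter) {
  if (filter$category == "format" || filter$elementwise == "all") return(NULL)
  field <- filter$field
  idx <- store$indexes[[field]]
  if (filter$category == "basic" && field == "FILTER") {
    idx <- store$indexes[["FILTER"]]
    if (is.null(idx) || filter$op != "==") return(NULL)
    keys <- names(idx$entries)
    hit <- vapply(keys, function(k)
      filter$operand %in% strsplit(k, ";", fixed = TRUE)[[1]], logical(1))
    return(sort(unlist(idx$entries[hit], use.names = FALSE)))
  }
  if (is.null(idx)) return(NULL)
  def <- field_def_for(store$header, filter$category, field)
  if (def$type == "Flag") {
    if (filter$op != "present") return(NULL)
    return(sort(unlist(idx$entries["present"], use.names = FALSE)))
  }
  if (is_multi(def)) return(NULL)   # joint keys can't serve ANY semantics
  keys <- names(idx$entries)
  operand <- filter$operand
  if (field == "CHROM" && is.character(operand)) {
    operand <- normalize_chrom(operand)   # index keys are normalized
  }
  hit <- switch(filter$op,
    "==" = if (is_numeric_type(def))
             suppressWarnings(as.numeric(keys)) == operand
           else keys == operand,
    ">"  = suppressWarnings(as.numeric(keys)) >  filter$operand,
    "<"  = suppressWarnings(as.numeric(keys)) <  filter$operand,
    ">=" = suppressWarnings(as.numeric(keys)) >= filter$operand,
    "<=" = suppressWarnings(as.numeric(keys)) <= filter$operand,
    return(NULL)
  )
  hit[is.na(hit)] <- FALSE
  sort(unlist(idx$entries[hit], use.names = FALSE))
}

#' Push a filter onto the stack
#'
#' The new survivor set is the subset of the current survivors passing the
#' filter. When an applicable index exists on the filtered field it is used
#' as the access path; the result is identical to a full scan.
#'
#' @param stack A `filter_stack`.
#' @param filter A `vcf_filter`.
#' @param store The `variant_store` the stack was created over.
#' @return The new stack; the survivor count of the new top is available as
#'   `survivor_count(stack)`.
#' @export
push_filter <- function(stack, filter, store) {
  prev <- top_ids(stack)
  cand <- index_candidates(store, filter)
  ids <- if (!is.null(cand)) {
    intersect(prev, cand)
  } else {
    prev[vapply(prev, function(i)
      record_passes(store$records[[i]], filter, store$header), logical(1))]
  }
  ids <- sort(ids)
  stack$levels[[length(stack$levels) + 1]] <-
    list(filter = filter, ids = ids, count = length(ids))
  stack
}

#' Pop the most recently pushed filter
#'
#' Restores exactly the survivor set that was on top before the
#' corresponding push.
#'
#' @param stack A non-empty `filter_stack`.
#' @return The stack with the top filter removed.
#' @export
pop_filter <- function(stack) {
  n <- length(stack$levels)
  if (n == 0) stop("stack-empty error: no filter to pop", call. = FALSE)
  stack$levels[[n]] <- NULL
  stack
}

#' Survivor count at the top of the stack
#' @param stack A `filter_stack`.
#' @return Integer count.
#' @export
survivor_count <- function(stack) length(top_ids(stack))

#' Survivor ids at the top of the stack (ascending)
#' @param stack A `filter_stack`.
#' @return Integer vector of record ids.
#' @export
survivor_ids <- function(stack) sort(top_ids(stack))

# Order record ids genomically: normalized chromosome (lexicographic),
# position (numeric), then REF and joined ALT as tie-breaks.
genomic_order <- function(store, ids) {
  recs <- store$records[ids]
  ch <- vapply(recs, function(r) normalize_chrom(r$chrom), character(1))
  pos <- vapply(recs, function(r) r$pos, integer(1))
  ref <- vapply(recs, function(r) r$ref, character(1))
  alt <- vapply(recs, function(r) paste(r$alt, collapse = ","), character(1))
  ids[order(ch, pos, ref, alt)]
}

#' Surviving records in genomic order
#'
#' @param stack A `filter_stack`.
#' @param store The backing `variant_store`.
#' @return List of `vcf_record`s ordered by (normalized chrom, pos, ref, alt).
#' @export
survivors <- function(stack, store) {
  store$records[genomic_order(store, top_ids(stack))]
}
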