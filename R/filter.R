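NUMERIC_OPS <- c(">", "<", ">=", "<=", "==", "!=", "is_missing", "not_missing")
FLAG_OPS    <- c("present", "absent")
STRING_OPS  <- c("==", "!=", "in_set", "is_missing", "not_missing")
GT_OPS      <- c("is_hom_ref", "is_het", "is_hom_alt", "is_hemi",
                 "is_missing", "has_alt")
NO_OPERAND_OPS <- c("is_missing", "not_missing", "present", "absent", GT_OPS)

#' Operators applicable to a field
#'
#' Filter operators are derived from the declared metadata type, mirroring
#' how an interactive filter panel would offer only the comparisons that make
#' sense: relational operators for numeric fields, presence/absence for
#' flags, equality and set membership for strings. The FORMAT `GT` field is
#' special-cased to genotype-class operators, because genotype classes
#' (het, hom-alt, ...) cannot be expressed as string equality across phased
#' and unphased encodings (`0/1` vs `1|0`).
#'
#' @param def A [field_def()].
#' @return Character vector of operator symbols.
#' @export
operators_for <- function(def) {
  if (def$source == "FORMAT" && def$id == "GT") return(GT_OPS)
  if (def$type == "Flag") return(FLAG_OPS)
  if (is_numeric_type(def)) return(NUMERIC_OPS)
  STRING_OPS
}

field_def_for <- function(header, category, field) {
  def <- switch(category,
    basic = {
      if (!field %in% c("CHROM", "POS", "ID", "QUAL", "FILTER")) {
        stop("basic filters apply to CHROM, POS, ID, QUAL or FILTER ",
             "(REF/ALT are excluded), not '", field, "'", call. = FALSE)
      }
      fixed_column_def(field)
    },
    info = header$info_defs[[field]],
    format = header$format_defs[[field]]
  )
  if (is.null(def)) {
    stop("unknown ", category, " field '", field, "'", call. = FALSE)
  }
  def
}

#' Construct a typed variant filter
#'
#' A filter is one predicate on one field: a category (`basic` for the fixed
#' columns, `info` for INFO keys, `format` for per-sample keys), an operator
#' drawn from [operators_for()] the field's type, an operand where the
#' operator takes one, and — for format filters — a sample scope. Operand
#' type errors are caught here, at construction time, never at evaluation
#' time.
#'
#' Multi-valued fields (Number=A/R/`.`) pass a test if \emph{any} element
#' satisfies it; set `elementwise = "all"` to require every element to pass.
#' A missing value fails every operator except `is_missing`.
#'
#' @param category `"basic"`, `"info"` or `"format"`.
#' @param field Field name.
#' @param op Operator symbol.
#' @param operand Typed operand (numeric scalar, string, or character vector
#'   for `in_set`); omit for presence/genotype-class operators.
#' @param sample_scope Character vector of sample names a format filter
#'   applies to; empty means all samples. All scoped samples must satisfy
#'   the predicate (AND within one filter).
#' @param elementwise `"any"` (default) or `"all"`: how multi-valued fields
#'   are reduced.
#' @param header The `vcf_header` to validate against.
#' @return A `vcf_filter`.
#' @export
vcf_filter <- function(category = c("basic", "info", "format"), field, op,
                       operand = NULL, sample_scope = character(0),
                       elementwise = c("any", "all"), header) {
  category <- match.arg(category)
  elementwise <- match.arg(elementwise)
  def <- field_def_for(header, category, field)
  ops <- operators_for(def)
  if (!op %in% ops) {
    stop("operator '", op, "' not applicable to ", field, " (", def$type,
         "); applicable: ", paste(ops, collapse = ", "), call. = FALSE)
  }
  if (op %in% NO_OPERAND_OPS) {
    if (!is.null(operand)) {
      stop("operator '", op, "' takes no operand", call. = FALSE)
    }
  } else if (def$source == "FORMAT" && def$id == "GT") {
    # unreachable: GT ops are all operand-free
  } else if (is_numeric_type(def)) {
    if (!is.numeric(operand) || length(operand) != 1 || is.na(operand)) {
      stop("operator '", op, "' on numeric field ", field,
           " needs a single numeric operand", call. = FALSE)
    }
  } else if (op == "in_set") {
    if (!is.character(operand) || length(operand) < 1) {
      stop("in_set needs a non-empty character vector operand", call. = FALSE)
    }
  } else {
    if (!is.character(operand) || length(operand) != 1) {
      stop("operator '", op, "' on string field ", field,
           " needs a single string operand", call. = FALSE)
    }
  }
  if (category != "format" && length(sample_scope)) {
    stop("sample_scope only applies to format filters", call. = FALSE)
  }
  bad <- setdiff(sample_scope, header$sample_names)
  if (length(bad)) {
    stop("unknown sample(s) in scope: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(category = category, field = field, op = op, operand = operand,
         sample_scope = sample_scope, elementwise = elementwise),
    class = "vcf_filter"
  )
}

#' @export
print.vcf_filter <- function(x, ...) {
  cat(render_filter(x), "\n")
  invisible(x)
}

# Reduce a per-element logical vector under any/all semantics.
reduce_hits <- function(hits, elementwise) {
  if (elementwise == "all") all(hits) else any(hits)
}

eval_scalar_op <- function(value, op, operand, elementwise) {
  # value: typed vector (possibly multi-valued); NA elements never satisfy.
  if (op == "is_missing") return(value_is_missing(value))
  if (value_is_missing(value)) return(FALSE)
  if (op == "not_missing") return(TRUE)
  v <- value[!is.na(value)]
  hits <- switch(op,
    ">"  = suppressWarnings(as.numeric(v) >  operand),
    "<"  = suppressWarnings(as.numeric(v) <  operand),
    ">=" = suppressWarnings(as.numeric(v) >= operand),
    "<=" = suppressWarnings(as.numeric(v) <= operand),
    "==" = if (is.numeric(operand)) suppressWarnings(as.numeric(v) == operand)
           else as.character(v) == operand,
    "!=" = if (is.numeric(operand)) suppressWarnings(as.numeric(v) != operand)
           else as.character(v) != operand,
    "in_set" = as.character(v) %in% operand,
    stop("unhandled operator ", op)
  )
  hits[is.na(hits)] <- FALSE   # degraded strings under numeric ops fail
  reduce_hits(hits, elementwise)
}

eval_gt_op <- function(gt_string, op) {
  cls <- gt_class(parse_genotype(gt_string))
  switch(op,
    is_missing = cls == "missing",
    is_hom_ref = cls == "hom_ref",
    is_het     = cls == "het",
    is_hom_alt = cls == "hom_alt",
    is_hemi    = cls %in% c("hemi_ref", "hemi_alt"),
    has_alt    = cls %in% c("het", "hom_alt", "hemi_alt", "multi_alt_het"),
    stop("unhandled genotype operator ", op)
  )
}

basic_value <- function(rec, field) {
  switch(field,
    CHROM  = normalize_chrom(rec$chrom),
    POS    = rec$pos,
    ID     = rec$id,
    QUAL   = rec$qual,
    FILTER = rec$filter   # already split on ";"; NULL when missing
  )
}

#' Does a record pass a filter?
#'
#' Evaluation semantics: basic and info filters evaluate on the record's
#' field value; multi-valued fields pass if any element satisfies (or all,
#' under the `elementwise = "all"` modifier); a missing field fails every
#' operator except `is_missing`; Flag `present` is true iff the key is set.
#' `FILTER == v` passes if `v` equals any semicolon-separated member; `PASS`
#' only matches the literal `PASS`. `CHROM` comparisons are
#' chromosome-normalized on both sides. Format filters require every sample
#' in scope (all samples when the scope is empty) to satisfy the predicate.
#'
#' @param rec A `vcf_record` (parsed at L2 for format filters).
#' @param filter A `vcf_filter`.
#' @param header The `vcf_header`.
#' @return `TRUE` or `FALSE`.
#' @export
record_passes <- function(rec, filter, header) {
  if (filter$category %in% c("basic", "info")) {
    def <- field_def_for(header, filter$category, filter$field)
    if (def$type == "Flag") {
      present <- isTRUE(rec$info[[filter$field]])
      return(if (filter$op == "present") present else !present)
    }
    value <- if (filter$category == "basic") basic_value(rec, filter$field)
             else rec$info[[filter$field]]
    operand <- filter$operand
    if (filter$field == "CHROM" && !is.null(operand)) {
      operand <- if (is.character(operand)) normalize_chrom(operand) else operand
    }
    return(eval_scalar_op(value, filter$op, operand, filter$elementwise))
  }
  # format filter: AND over scoped samples
  scope <- filter$sample_scope
  if (length(scope) == 0) scope <- header$sample_names
  for (s in scope) {
    v <- rec$samples[[s]][[filter$field]]
    ok <- if (filter$field == "GT") {
      eval_gt_op(if (value_is_missing(v)) NA_character_ else v, filter$op)
    } else {
      eval_scalar_op(v, filter$op, filter$operand, filter$elementwise)
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Observed value domain of a string field
#'
#' Returns the sorted distinct values observed for a string-typed field,
#' splitting multi-valued entries into members first (semicolon members for
#' FILTER, comma elements for multi-valued INFO). This is what an
#' interactive panel would offer in a select box.
#'
#' @param store A `variant_store`.
#' @param field A string-typed field (includes CHROM, ID and FILTER).
#' @param category Filter category the field belongs to.
#' @return Sorted character vector of observed values.
#' @export
value_domain <- function(store, field, category = c("basic", "info", "format")) {
  category <- match.arg(category)
  def <- field_def_for(store$header, category, field)
  if (is_numeric_type(def) || def$type == "Flag") {
    stop("value_domain applies to string fields; ", field, " is ", def$type,
         call. = FALSE)
  }
  vals <- character(0)
  for (rec in store$records) {
    v <- if (category == "basic") basic_value(rec, field)
         else if (category == "info") rec$info[[field]]
         else unlist(lapply(rec$samples, function(s) s[[field]]),
                     use.names = FALSE)
    if (value_is_missing(v)) next
    vals <- c(vals, as.character(v[!is.na(v)]))
  }
  sort(unique(vals))
}

#' Canonical one-line serialization of a filter
#'
#' Renders `category:field op operand [@sample1,sample2]`; the `all:` prefix
#' on the operator marks all-element semantics for multi-valued fields.
#' [parse_filter()] is the exact inverse. Used in CLI flags, logs and export
#' provenance lines.
#'
#' @param filter A `vcf_filter`.
#' @return A single string.
#' @export
render_filter <- function(filter) {
  op_txt <- if (filter$elementwise == "all") paste0("all:", filter$op)
            else filter$op
  parts <- c(paste0(filter$category, ":", filter$field), op_txt)
  if (!filter$op %in% NO_OPERAND_OPS) {
    parts <- c(parts, paste(as.character(filter$operand), collapse = ","))
  }
  if (length(filter$sample_scope)) {
    parts <- c(parts, paste0("@", paste(filter$sample_scope, collapse = ",")))
  }
  paste(parts, collapse = " ")
}

#' Parse the canonical filter string
#'
#' Inverse of [render_filter()]. Grammar:
#' `category:field op [operand] [@sample1,sample2]` where category is
#' `basic|info|format`, the operator may carry an `all:` prefix, and the
#' operand for `in_set` is a comma-separated list.
#'
#' @param text Filter string.
#' @param header The `vcf_header` to validate against.
#' @return A `vcf_filter`.
#' @export
parse_filter <- function(text, header) {
  toks <- strsplit(trimws(text), " +")[[1]]
  if (length(toks) < 2 || !grepl("^(basic|info|format):", toks[[1]])) {
    stop("unparsable filter '", text, "'; expected ",
         "\"category:field op [operand] [@samples]\" with category one of ",
         "basic|info|format", call. = FALSE)
  }
  category <- sub(":.*$", "", toks[[1]])
  field <- sub("^[a-z]+:", "", toks[[1]])
  op_txt <- toks[[2]]
  elementwise <- "any"
  if (startsWith(op_txt, "all:")) {
    elementwise <- "all"
    op_txt <- sub("^all:", "", op_txt)
  }
  rest <- toks[-(1:2)]
  sample_scope <- character(0)
  if (length(rest) && startsWith(rest[[length(rest)]], "@")) {
    sample_scope <- strsplit(sub("^@", "", rest[[length(rest)]]), ",")[[1]]
    rest <- rest[-length(rest)]
  }
  operand <- NULL
  if (!op_txt %in% NO_OPERAND_OPS) {
    if (length(rest) == 0) {
      stop("operator '", op_txt, "' needs an operand in '", text, "'",
           call. = FALSE)
    }
    raw <- paste(rest, collapse = " ")
    def <- field_def_for(header, category, field)
    operand <- if (is_numeric_type(def) && !(def$id == "GT")) as.numeric(raw)
               else if (op_txt == "in_set") strsplit(raw, ",")[[1]]
               else raw
  }
  vcf_filter(category, field, op_txt, operand, sample_scope,
             elementwise, header)
}
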