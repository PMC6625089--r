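#' Normalize an allele representation
#'
#' Produces the matching key used for annotation transfer: the longest
#' common suffix of REF and ALT is trimmed (keeping both non-empty), then
#' the common prefix is trimmed while both alleles stay non-empty, advancing
#' the position by one base per trimmed prefix base. The chromosome is
#' normalized with [normalize_chrom()]. No reference-genome left-alignment
#' is attempted (that would require a FASTA); equivalent padded
#' representations of the same SNV/indel compare equal under this scheme.
#' Alleles containing characters outside ACGTN (symbolic or breakend
#' alleles) are passed through unmodified with a warning.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref Reference allele string.
#' @param alt One alternate allele string (not comma-joined).
#' @return An `allele_key`: list with normalized `chrom`, `pos`, `ref`,
#'   `alt`, plus a `key` string `chrom:pos:ref:alt`.
#' @export
normalize_allele <- function(chrom, pos, ref, alt) {
  chrom <- normalize_chrom(chrom)
  if (!grepl("^[ACGTNacgtn]+$", ref) || !grepl("^[ACGTNacgtn]+$", alt)) {
    warning("symbolic or non-ACGTN allele left unnormalized: ",
            ref, ">", alt, call. = FALSE)
  } else {
    r <- strsplit(toupper(ref), "")[[1]]
    a <- strsplit(toupper(alt), "")[[1]]
    # trim longest common suffix, keeping both alleles non-empty
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # trim common prefix while both stay non-empty, advancing pos
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos <- pos + 1L
    }
    ref <- paste(r, collapse = "")
    alt <- paste(a, collapse = "")
  }
  structure(
    list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
         key = paste(chrom, pos, ref, alt, sep = ":")),
    class = "allele_key"
  )
}

# All normalized keys of a record, one per alternate allele, in ALT order.
record_allele_keys <- function(rec) {
  vapply(rec$alt, function(a)
    normalize_allele(rec$chrom, rec$pos, rec$ref, a)$key, character(1),
    USE.NAMES = FALSE)
}

# Positional value of a source INFO field for alt allele j of n_alt.
allele_slice <- function(value, def, j, n_alt) {
  if (value_is_missing(value)) return(NA)
  switch(def$number,
    "A" = if (j <= length(value)) value[[j]] else NA,
    "R" = if (j + 1 <= length(value)) value[[j + 1]] else NA,
    value[[1]]    # Number=1 / '.' apply to the site as a whole
  )
}

#' Build an allele-keyed annotation source from a VCF
#'
#' In `keyed` mode, selected INFO keys of the annotation VCF are collected
#' into a lookup keyed on the normalized (chrom, pos, ref, alt) of each
#' alternate allele — multi-allelic source records are decomposed per
#' allele, with `Number=A`/`R` values distributed positionally. In `list`
#' mode (whitelists/blacklists) only presence is recorded. Genotype-shaped
#' fields (`Number=G`) are sample-dependent and never copied; selecting one
#' drops it with a warning.
#'
#' @param ann_vcf Path to the annotation VCF (plain or gzip).
#' @param selected_keys Character vector of INFO keys to transfer, or
#'   `"ALL"` for every (non-`Number=G`) key. Ignored in `list` mode.
#' @param mode `"keyed"` or `"list"`.
#' @param name Source name used to namespace transferred keys (keyed) or as
#'   the flag id (list).
#' @return An `annotation_source`.
#' @export
build_annotation_source <- function(ann_vcf, selected_keys = "ALL",
                                    mode = c("keyed", "list"),
                                    name = "ann") {
  mode <- match.arg(mode)
  parsed <- read_vcf(ann_vcf, level = "L0")
  header <- parsed$header
  defs <- list()
  if (mode == "keyed") {
    avail <- names(header$info_defs)
    keys <- if (identical(selected_keys, "ALL")) avail else selected_keys
    absent <- setdiff(keys, avail)
    if (length(absent)) {
      stop("unknown-key error: ", paste(absent, collapse = ", "),
           " not in annotation source; available: ",
           paste(avail, collapse = ", "), call. = FALSE)
    }
    g_shaped <- keys[vapply(keys, function(k)
      header$info_defs[[k]]$number == "G", logical(1))]
    if (length(g_shaped)) {
      warning("Number=G field(s) never transferred, dropped: ",
              paste(g_shaped, collapse = ", "), call. = FALSE)
      keys <- setdiff(keys, g_shaped)
    }
    if (length(keys) == 0) {
      stop("keyed mode needs at least one transferable key", call. = FALSE)
    }
    defs <- header$info_defs[keys]
  } else {
    keys <- character(0)
  }
  lookup <- new.env(parent = emptyenv())
  for (rec in parsed$records) {
    n_alt <- length(rec$alt)
    for (j in seq_len(n_alt)) {
      k <- normalize_allele(rec$chrom, rec$pos, rec$ref, rec$alt[[j]])$key
      if (mode == "list") {
        assign(k, TRUE, envir = lookup)
      } else {
        vals <- lapply(defs, function(def)
          allele_slice(rec$info[[def$id]], def, j, n_alt))
        names(vals) <- keys
        assign(k, vals, envir = lookup)
      }
    }
  }
  structure(
    list(name = name, mode = mode, selected_keys = keys, defs = defs,
         lookup = lookup),
    class = "annotation_source"
  )
}

#' @export
print.annotation_source <- function(x, ...) {
  cat("Annotation source '", x$name, "' (", x$mode, "): ",
      length(ls(x$lookup)), " allele keys",
      if (x$mode == "keyed")
        paste0("; keys: ", paste(x$selected_keys, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

# Declared number/type of the namespaced INFO field added to targets.
transferred_def <- function(source, key) {
  src <- source$defs[[key]]
  field_def(paste0(source$name, "_", key), "INFO", "A", src$type,
            paste0("transferred from source '", source$name, "' key ", key))
}

#' Annotate a store from an allele-keyed source
#'
#' Matches every record x alternate-allele against the source lookup on
#' normalized keys. In keyed mode, matched values are copied into INFO under
#' `name_key`, aligned per alternate allele (`Number=A`, missing for
#' unmatched alleles). In list mode, a Flag named after the source is set on
#' any record with a matching allele. The header gains the new field
#' definitions exactly once; re-annotating with the same source is
#' idempotent. Records' fixed columns are never modified.
#'
#' @param store A `variant_store`.
#' @param source An `annotation_source`.
#' @return List with `store` (annotated) and `count` (number of records
#'   that gained at least one annotation).
#' @export
annotate_store <- function(store, source) {
  new_ids <- if (source$mode == "list") source$name
             else paste0(source$name, "_", source$selected_keys)
  for (id in new_ids) {
    existing <- store$header$info_defs[[id]]
    if (!is.null(existing) &&
        !grepl(paste0("^transferred from source '", source$name, "'"),
               existing$description) &&
        !(source$mode == "list" && existing$type == "Flag" &&
          grepl("^membership flag", existing$description))) {
      stop("collision error: INFO field '", id,
           "' already exists in the target header", call. = FALSE)
    }
  }
  if (source$mode == "list") {
    store$header$info_defs[[source$name]] <-
      field_def(source$name, "INFO", 0, "Flag",
                paste0("membership flag for list '", source$name, "'"))
  } else {
    for (key in source$selected_keys) {
      def <- transferred_def(source, key)
      store$header$info_defs[[def$id]] <- def
    }
  }
  count <- 0L
  for (i in seq_len(store$n)) {
    rec <- store$records[[i]]
    keys <- record_allele_keys(rec)
    hits <- vapply(keys, exists, logical(1), envir = source$lookup,
                   inherits = FALSE)
    if (!any(hits)) next
    count <- count + 1L
    if (source$mode == "list") {
      rec$info[[source$name]] <- TRUE
    } else {
      n_alt <- length(rec$alt)
      for (key in source$selected_keys) {
        src_def <- source$defs[[key]]
        vals <- rep(NA, n_alt)
        vals <- if (src_def$type == "Integer") rep(NA_integer_, n_alt)
                else if (src_def$type == "Float") rep(NA_real_, n_alt)
                else rep(NA_character_, n_alt)
        for (j in which(hits)) {
          v <- get(keys[[j]], envir = source$lookup)[[key]]
          if (!is.null(v) && !all(is.na(v))) vals[[j]] <- v
        }
        if (!all(is.na(vals))) {
          rec$info[[paste0(source$name, "_", key)]] <- vals
        }
      }
    }
    store$records[[i]] <- rec
  }
  list(store = store, count = count)
}

#' Flag records overlapping BED intervals
#'
#' BED coordinates are 0-based half-open; a record is flagged iff
#' `POS - 1` lies in `[start, end)` on the normalization-matched
#' chromosome. Adds a Flag INFO field named `flag_name`.
#'
#' @param store A `variant_store`.
#' @param bed Path to a BED3+ file.
#' @param flag_name Name of the Flag to set.
#' @return List with `store` and `count` of records flagged.
#' @export
annotate_intervals <- function(store, bed, flag_name) {
  lines <- readLines(bed, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  ivs <- list()
  for (i in seq_along(lines)) {
    cols <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(cols) < 3) {
      stop("input error: BED line ", i, " has fewer than 3 columns",
           call. = FALSE)
    }
    s <- suppressWarnings(as.integer(cols[[2]]))
    e <- suppressWarnings(as.integer(cols[[3]]))
    if (is.na(s) || is.na(e) || s < 0 || e < s) {
      stop("input error: BED line ", i, " has invalid coordinates",
           call. = FALSE)
    }
    ch <- normalize_chrom(cols[[1]])
    ivs[[ch]] <- rbind(ivs[[ch]], c(s, e))
  }
  store$header$info_defs[[flag_name]] <-
    field_def(flag_name, "INFO", 0, "Flag",
              paste0("membership flag for intervals of ", basename(bed)))
  count <- 0L
  for (i in seq_len(store$n)) {
    rec <- store$records[[i]]
    tab <- ivs[[normalize_chrom(rec$chrom)]]
    if (is.null(tab)) next
    p0 <- rec$pos - 1L
    if (any(tab[, 1] <= p0 & p0 < tab[, 2])) {
      rec$info[[flag_name]] <- TRUE
      store$records[[i]] <- rec
      count <- count + 1L
    }
  }
  list(store = store, count = count)
}
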