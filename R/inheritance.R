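#' Assign trio roles to sample names
#'
#' @param father,mother,child Distinct sample names present in the header.
#' @param header The `vcf_header` to validate against.
#' @return A `trio_spec`.
#' @export
trio_spec <- function(father, mother, child, header) {
  roles <- c(father, mother, child)
  if (anyDuplicated(roles)) {
    stop("trio-spec error: father, mother and child must be distinct",
         call. = FALSE)
  }
  missing <- setdiff(roles, header$sample_names)
  if (length(missing)) {
    stop("trio-spec error: sample(s) not in header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(father = father, mother = mother, child = child),
            class = "trio_spec")
}

trio_genotypes <- function(rec, trio) {
  lapply(c(f = trio$father, m = trio$mother, c = trio$child), function(s) {
    v <- rec$samples[[s]][["GT"]]
    parse_genotype(if (value_is_missing(v)) NA_character_ else v)
  })
}

resolve_ids <- function(store_or_ids, store) {
  if (is.null(store)) {
    if (!inherits(store_or_ids, "variant_store")) {
      stop("pass a variant_store, or ids plus store=", call. = FALSE)
    }
    list(ids = seq_len(store_or_ids$n), store = store_or_ids)
  } else {
    list(ids = store_or_ids, store = store)
  }
}

trio_scan <- function(store_or_ids, trio, store, keep_missing, predicate) {
  x <- resolve_ids(store_or_ids, store)
  kept <- vapply(x$ids, function(i) {
    g <- trio_genotypes(x$store$records[[i]], trio)
    cls <- vapply(g, gt_class, character(1))
    if (any(cls == "missing")) return(keep_missing)
    predicate(x$store$records[[i]], g, cls)
  }, logical(1))
  x$ids[kept]
}

#' Autosomal-recessive trio filter
#'
#' Keeps records where both parents are heterozygous and the affected child
#' is homozygous for the alternate allele, with all three members sharing
#' the same alternate allele index ("parents het, child hom" on different
#' alleles is not a recessive transmission). Records with any missing trio
#' genotype are excluded unless `keep_missing = TRUE`.
#'
#' @param store_or_ids A `variant_store` (parsed at L2), or a vector of
#'   record ids (e.g. the survivors of a filter stack) with `store` given.
#' @param trio A [trio_spec()].
#' @param store Backing store when ids are passed.
#' @param keep_missing Keep records with missing trio genotypes? Default
#'   `FALSE`.
#' @return Integer vector of record ids.
#' @export
recessive_filter <- function(store_or_ids, trio, store = NULL,
                             keep_missing = FALSE) {
  trio_scan(store_or_ids, trio, store, keep_missing, function(rec, g, cls) {
    if (!(cls[["f"]] == "het" && cls[["m"]] == "het" &&
          cls[["c"]] == "hom_alt")) return(FALSE)
    a <- alt_indices(g$c)[[1]]
    a %in% alt_indices(g$f) && a %in% alt_indices(g$m)
  })
}

#' De novo trio filter
#'
#' Keeps records where both parents are homozygous reference and the child
#' carries at least one alternate allele. Records with missing trio
#' genotypes are excluded unless `keep_missing = TRUE`.
#'
#' @inheritParams recessive_filter
#' @return Integer vector of record ids.
#' @export
denovo_filter <- function(store_or_ids, trio, store = NULL,
                          keep_missing = FALSE) {
  trio_scan(store_or_ids, trio, store, keep_missing, function(rec, g, cls) {
    cls[["f"]] == "hom_ref" && cls[["m"]] == "hom_ref" && has_alt_allele(g$c)
  })
}

#' X-linked recessive trio filter
#'
#' Keeps records on the X chromosome (after normalization) where the mother
#' is heterozygous, the child is hemizygous-alt or homozygous-alt, and the
#' father carries no alternate allele. The father criterion can be relaxed
#' with `father_no_alt = FALSE` (then only mother and child are
#' constrained).
#'
#' @inheritParams recessive_filter
#' @param father_no_alt Require the father to carry no alternate allele
#'   (hemizygous- or homozygous-reference)? Default `TRUE`.
#' @return Integer vector of record ids.
#' @export
xlinked_recessive_filter <- function(store_or_ids, trio, store = NULL,
                                     keep_missing = FALSE,
                                     father_no_alt = TRUE) {
  trio_scan(store_or_ids, trio, store, keep_missing, function(rec, g, cls) {
    if (normalize_chrom(rec$chrom) != "X") return(FALSE)
    if (cls[["m"]] != "het") return(FALSE)
    if (!cls[["c"]] %in% c("hemi_alt", "hom_alt")) return(FALSE)
    !father_no_alt || cls[["f"]] %in% c("hemi_ref", "hom_ref")
  })
}

comphet_side <- function(g, cls) {
  # Which parent could have transmitted this child-het variant in trans?
  if (cls[["c"]] != "het") return(NA_character_)
  paternal <- has_alt_allele(g$f) && cls[["m"]] == "hom_ref"
  maternal <- has_alt_allele(g$m) && cls[["f"]] == "hom_ref"
  if (paternal && !maternal) return("paternal")
  if (maternal && !paternal) return("maternal")
  NA_character_
}

#' Compound-heterozygous trio filter
#'
#' Within each gene (as given by a string-typed INFO key), finds pairs of
#' variants where the child is heterozygous at both and the observed
#' parental genotypes force a trans configuration: at one variant the father
#' carries the alternate and the mother is homozygous reference, at the
#' other the roles are reversed. Records lacking the gene field are
#' skipped; missing trio genotypes exclude a record.
#'
#' @inheritParams recessive_filter
#' @param gene_field Declared string-typed INFO key holding the gene symbol.
#' @return Named list mapping gene -> list of id pairs `c(v1, v2)` with
#'   `v1 < v2`.
#' @export
compound_het <- function(store_or_ids, trio, gene_field, store = NULL,
                         keep_missing = FALSE) {
  x <- resolve_ids(store_or_ids, store)
  def <- x$store$header$info_defs[[gene_field]]
  if (is.null(def)) {
    stop("unknown INFO field '", gene_field, "'", call. = FALSE)
  }
  if (!def$type %in% c("String", "Character")) {
    stop("wrong-type error: gene_field ", gene_field,
         " must be string-typed, is ", def$type, call. = FALSE)
  }
  sides <- list()   # gene -> data.frame(id, side)
  for (i in x$ids) {
    rec <- x$store$records[[i]]
    gene <- rec$info[[gene_field]]
    if (value_is_missing(gene)) next
    g <- trio_genotypes(rec, trio)
    cls <- vapply(g, gt_class, character(1))
    if (any(cls == "missing") && !keep_missing) next
    side <- comphet_side(g, cls)
    if (is.na(side)) next
    for (gv in unique(as.character(gene))) {
      sides[[gv]] <- rbind(sides[[gv]],
                           data.frame(id = i, side = side,
                                      stringsAsFactors = FALSE))
    }
  }
  out <- list()
  for (gv in names(sides)) {
    tab <- sides[[gv]]
    pat <- tab$id[tab$side == "paternal"]
    mat <- tab$id[tab$side == "maternal"]
    if (length(pat) == 0 || length(mat) == 0) next
    pairs <- list()
    for (p in pat) for (m in mat) {
      pairs[[length(pairs) + 1]] <- sort(c(p, m))
    }
    out[[gv]] <- pairs
  }
  out[order(names(out))]
}
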