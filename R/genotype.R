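#' Parse a GT string into a genotype
#'
#' Splits on `/` (unphased) or `|` (phased); `.` denotes a missing allele;
#' a single index denotes hemizygosity (ploidy 1).
#'
#' @param gt GT string such as `"0/1"`, `"1|0"`, `"1"`, `"./."`.
#' @return A `genotype`: list with `alleles` (integer vector, `NA` for
#'   missing), `phased`, `ploidy`.
#' @export
parse_genotype <- function(gt) {
  if (is.null(gt) || length(gt) == 0 || is.na(gt) || gt == "" || gt == ".") {
    return(structure(list(alleles = NA_integer_, phased = FALSE, ploidy = 1L),
                     class = "genotype"))
  }
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")[[1]]
  alleles <- suppressWarnings(as.integer(parts))
  structure(list(alleles = alleles, phased = phased,
                 ploidy = length(alleles)),
            class = "genotype")
}

#' Classify a genotype
#'
#' @param g A `genotype` from [parse_genotype()].
#' @return One of `"hom_ref"`, `"het"`, `"hom_alt"`, `"hemi_ref"`,
#'   `"hemi_alt"`, `"missing"`, `"multi_alt_het"`. Any missing allele yields
#'   `"missing"`; ploidy 1 yields the hemizygous classes; two distinct
#'   nonzero alleles (e.g. `1/2`) yield `"multi_alt_het"`, which is excluded
#'   from `het` for inheritance-pattern purposes because its transmission is
#'   ambiguous.
#' @export
gt_class <- function(g) {
  a <- g$alleles
  if (any(is.na(a))) return("missing")
  if (g$ploidy == 1) return(if (a == 0) "hemi_ref" else "hemi_alt")
  if (all(a == 0)) return("hom_ref")
  if (all(a > 0)) {
    return(if (length(unique(a)) == 1) "hom_alt" else "multi_alt_het")
  }
  "het"
}

# Alternate-allele indices carried by a genotype (empty for hom_ref/missing).
alt_indices <- function(g) {
  a <- g$alleles
  unique(a[!is.na(a) & a > 0])
}

has_alt_allele <- function(g) length(alt_indices(g)) > 0
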