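#' Specification for a synthetic trio VCF with planted truth
#'
#' Describes the generator recipe: size, sample roles, seed, the exact
#' fraction of PASS records, planted inheritance-pattern counts, the number
#' of allele keys shared with the companion whitelist, and gene layout. The
#' same spec with the same seed always produces byte-identical output
#' files.
#'
#' @param n_variants Number of records.
#' @param samples Ordered roles; defaults to FATHER, MOTHER, CHILD.
#' @param seed RNG seed; default 42.
#' @param pass_fraction Exact fraction of records with `FILTER=PASS`
#'   (enforced by count, not sampled).
#' @param planted Named integer vector: `recessive`, `denovo`,
#'   `comphet_genes` (genes, two variants each), `xlinked`.
#' @param whitelist_overlap Exact number of allele keys shared between the
#'   trio VCF and the companion whitelist VCF.
#' @param gene_block Mean number of consecutive variants per gene.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_variants = 10000,
                         samples = c("FATHER", "MOTHER", "CHILD"),
                         seed = 42,
                         pass_fraction = 0.7,
                         planted = c(recessive = 12, denovo = 5,
                                     comphet_genes = 3, xlinked = 0),
                         whitelist_overlap = 37,
                         gene_block = 8) {
  full <- c(recessive = 0, denovo = 0, comphet_genes = 0, xlinked = 0)
  full[names(planted)] <- planted
  need <- full[["recessive"]] + full[["denovo"]] +
    2 * full[["comphet_genes"]] + full[["xlinked"]]
  if (need > n_variants) {
    stop("spec error: planted counts (", need, " records) exceed n_variants (",
         n_variants, ")", call. = FALSE)
  }
  if (length(samples) != 3) {
    stop("spec error: exactly three samples (father, mother, child) expected",
         call. = FALSE)
  }
  structure(
    list(n_variants = as.integer(n_variants), samples = samples,
         seed = as.integer(seed), pass_fraction = pass_fraction,
         planted = full, whitelist_overlap = as.integer(whitelist_overlap),
         gene_block = gene_block),
    class = "fixture_spec"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fixture_header <- function(samples) {
  h <- list(
    fileformat = "VCFv4.2",
    info_defs = list(),
    format_defs = list(),
    sample_names = samples,
    other_lines = c("##contig=<ID=1>", "##contig=<ID=X>",
                    "##FILTER=<ID=q10,Description=\"Quality below 10\">",
                    "##FILTER=<ID=s50,Description=\"Less than 50% of samples have data\">")
  )
  class(h) <- "vcf_header"
  for (d in list(
    field_def("KG_AF", "INFO", "A", "Float", "Population allele frequency, panel 1"),
    field_def("EXAC_AF", "INFO", "A", "Float", "Population allele frequency, panel 2"),
    field_def("ESP_AF", "INFO", "A", "Float", "Population allele frequency, panel 3"),
    field_def("FUNC", "INFO", "1", "String", "Functional class of the variant"),
    field_def("GENE", "INFO", "1", "String", "Gene symbol"),
    field_def("DP", "INFO", "1", "Integer", "Total depth"),
    field_def("DB", "INFO", "0", "Flag", "Known-variant membership")
  )) h$info_defs[[d$id]] <- d
  for (d in list(
    field_def("GT", "FORMAT", "1", "String", "Genotype"),
    field_def("DP", "FORMAT", "1", "Integer", "Read depth"),
    field_def("GQ", "FORMAT", "1", "Integer", "Genotype quality")
  )) h$format_defs[[d$id]] <- d
  h
}

BASES <- c("A", "C", "G", "T")

# Background trio genotype configurations (father, mother, child) chosen so
# that no background record can satisfy any planted inheritance pattern,
# even when sharing a gene with a planted compound-het pair: none of them
# is a child-het variant with one parent carrying the alternate and the
# other homozygous reference.
SAFE_CONFIGS <- list(
  c("0/0", "0/0", "0/0"),
  c("0/1", "0/1", "0/1"),
  c("0/1", "0/0", "0/0"),
  c("1/1", "0/1", "0/1")
)

maybe_phase <- function(gt, phase) {
  if (phase && gt == "0/1") "0|1" else gt
}

#' Generate a synthetic trio VCF with planted truth
#'
#' Writes four files to `outdir`:
#' \describe{
#'   \item{trio.vcf.gz}{the trio VCF: `n_variants` records over chromosomes
#'     1..22 and X with strictly increasing positions per chromosome, typed
#'     INFO fields (three allele-frequency-like Float fields, a
#'     function-class String field, a gene String field, an Integer depth
#'     and a Flag), exact PASS count, and per-sample GT/DP/GQ.}
#'   \item{truth.tsv}{every planted record id with its pattern and gene.}
#'   \item{whitelist.vcf}{shares exactly `whitelist_overlap` normalized
#'     allele keys with the trio (about a third written in padded,
#'     non-normal form and with a `chr` prefix to exercise matching), plus
#'     non-matching decoys.}
#'   \item{ann_source.vcf}{an annotation VCF over a subset of the trio
#'     sites carrying `SIFT_score` (Float, Number=1) and `GP_AF` (Float,
#'     Number=A) for keyed-transfer tests.}
#' }
#' Planted pattern sites are forced rare (< 0.01) on all three frequency
#' fields; background frequencies are uniform on (0, 0.5). Background
#' genotypes are drawn from configurations that cannot satisfy any planted
#' pattern, so each inheritance filter recovers exactly its planted set.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `paths`, `truth` (data.frame id/pattern/
#'   chrom/pos/gene), and `spec`.
#' @export
generate_fixture <- function(spec, outdir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, {
    n <- spec$n_variants
    chroms <- c(as.character(1:22), "X")
    w <- c(22:1, 8) / sum(c(22:1, 8))
    counts <- pmax(1L, as.integer(round(n * w)))
    # adjust to sum exactly n, keeping X big enough for planted X patterns
    counts[1] <- counts[1] + (n - sum(counts))
    x_need <- spec$planted[["xlinked"]] + 2L
    if (counts[23] < x_need) {
      counts[1] <- counts[1] - (x_need - counts[23])
      counts[23] <- x_need
    }
    chrom <- rep(chroms, counts)
    pos <- unlist(lapply(counts, function(k) cumsum(sample(10:300, k, TRUE))))
    is_x <- chrom == "X"

    # genes: consecutive blocks per chromosome
    gene <- character(n)
    offset <- 0
    for (ci in seq_along(chroms)) {
      k <- counts[ci]
      sizes <- integer(0)
      while (sum(sizes) < k) sizes <- c(sizes, sample(4:12, 1))
      blocks <- rep(seq_along(sizes), sizes)[seq_len(k)]
      gene[offset + seq_len(k)] <- sprintf("GENE_%s_%03d", chroms[ci], blocks)
      offset <- offset + k
    }

    # alleles: mostly SNVs, some indels, ~5% multi-allelic (background only)
    ref <- sample(BASES, n, TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
    alt <- as.list(alt)
    indel <- runif(n) < 0.04
    for (i in which(indel)) {
      if (runif(1) < 0.5) {
        ref[i] <- paste0(ref[i], sample(BASES, 1))   # deletion: AT > A
        alt[[i]] <- substr(ref[i], 1, 1)
      } else {
        alt[[i]] <- paste0(ref[i], sample(BASES, 1)) # insertion: A > AT
      }
    }
    multi <- runif(n) < 0.05 & !indel
    for (i in which(multi)) {
      alt[[i]] <- sample(setdiff(BASES, ref[i]), 2)
    }

    # planted pattern assignment (disjoint, autosomal except xlinked)
    planted_pattern <- character(n)
    auto_pool <- which(!is_x & !multi)
    take <- function(pool, k) {
      ids <- sample(pool, k)
      ids
    }
    rec_ids <- take(auto_pool, spec$planted[["recessive"]])
    auto_pool <- setdiff(auto_pool, rec_ids)
    dn_ids <- take(auto_pool, spec$planted[["denovo"]])
    auto_pool <- setdiff(auto_pool, dn_ids)
    planted_pattern[rec_ids] <- "recessive"
    planted_pattern[dn_ids] <- "denovo"
    ch_ids <- integer(0)
    if (spec$planted[["comphet_genes"]] > 0) {
      cand_genes <- unique(gene[auto_pool])
      picked <- character(0)
      for (g in sample(cand_genes)) {
        members <- intersect(which(gene == g), auto_pool)
        if (length(members) >= 2) {
          pair <- sort(members)[1:2]
          planted_pattern[pair[1]] <- "comphet_paternal"
          planted_pattern[pair[2]] <- "comphet_maternal"
          ch_ids <- c(ch_ids, pair)
          auto_pool <- setdiff(auto_pool, members)  # whole gene reserved
          picked <- c(picked, g)
          if (length(picked) == spec$planted[["comphet_genes"]]) break
        }
      }
      if (length(picked) < spec$planted[["comphet_genes"]]) {
        stop("spec error: not enough multi-variant genes to plant ",
             "compound-het pairs", call. = FALSE)
      }
    }
    xl_ids <- integer(0)
    if (spec$planted[["xlinked"]] > 0) {
      x_pool <- which(is_x & !multi)
      xl_ids <- take(x_pool, spec$planted[["xlinked"]])
      planted_pattern[xl_ids] <- "xlinked"
    }
    planted_idx <- which(planted_pattern != "")

    # FILTER: exact PASS count
    n_pass <- as.integer(round(spec$pass_fraction * n))
    filt <- sample(c("q10", "s50", "q10;s50"), n, TRUE)
    filt[sample.int(n, n_pass)] <- "PASS"

    # INFO values; planted sites forced rare on all three frequency fields
    n_alt <- vapply(alt, length, integer(1))
    af_field <- function() {
      lapply(seq_len(n), function(i) {
        if (planted_pattern[i] != "") round(runif(n_alt[i], 1e-4, 0.009), 4)
        else round(runif(n_alt[i], 0, 0.5), 4)
      })
    }
    kg <- af_field(); exac <- af_field(); esp <- af_field()
    drop_exac <- runif(n) < 0.03 & planted_pattern == ""
    func <- sample(c("nonsense", "missense", "synonymous", "intronic",
                     "intergenic"), n, TRUE,
                   prob = c(0.05, 0.25, 0.2, 0.3, 0.2))
    dp <- stats::rpois(n, 30) + 1L
    db <- runif(n) < 0.3
    qual <- round(runif(n, 10, 1000), 2)
    qual_missing <- runif(n) < 0.02 & planted_pattern == ""
    has_id <- runif(n) < 0.3
    rs <- cumsum(has_id)

    # genotypes
    phase <- runif(n) < 0.15
    child_missing <- runif(n) < 0.02 & planted_pattern == "" & !is_x
    gts <- vector("list", n)
    xl_background_hemi <- spec$planted[["xlinked"]] > 0
    for (i in seq_len(n)) {
      g <- switch(planted_pattern[i],
        recessive        = c("0/1", "0/1", "1/1"),
        denovo           = c("0/0", "0/0", "0/1"),
        comphet_paternal = c("0/1", "0/0", "0/1"),
        comphet_maternal = c("0/0", "0/1", "0/1"),
        xlinked          = c("0", "0/1", "1"),
        SAFE_CONFIGS[[sample.int(4, 1)]]
      )
      if (planted_pattern[i] == "" && is_x[i] && xl_background_hemi) {
        g[1] <- "0"   # hemizygous father on X
        g[3] <- "0"   # hemizygous-reference child: never an X-linked hit
      }
      if (child_missing[i]) g[3] <- "./."
      gts[[i]] <- vapply(g, maybe_phase, character(1), phase = phase[i],
                         USE.NAMES = FALSE)
    }

    header <- fixture_header(spec$samples)
    records <- vector("list", n)
    for (i in seq_len(n)) {
      info <- list(KG_AF = kg[[i]], EXAC_AF = exac[[i]], ESP_AF = esp[[i]],
                   FUNC = func[i], GENE = gene[i], DP = dp[i])
      if (drop_exac[i]) info$EXAC_AF <- NULL
      if (db[i]) info$DB <- TRUE
      samples <- list()
      for (s in seq_along(spec$samples)) {
        samples[[spec$samples[s]]] <-
          list(GT = gts[[i]][s],
               DP = as.integer(stats::rpois(1, 28) + 1L),
               GQ = as.integer(sample(20:99, 1)))
      }
      records[[i]] <- structure(
        list(chrom = chrom[i], pos = as.integer(pos[i]),
             id = if (has_id[i]) paste0("rs", 100000 + rs[i]) else NA_character_,
             ref = ref[i], alt = alt[[i]],
             qual = if (qual_missing[i]) NA_real_ else qual[i],
             filter = strsplit(filt[i], ";", fixed = TRUE)[[1]],
             info = info, format_keys = c("GT", "DP", "GQ"),
             samples = samples),
        class = "vcf_record")
    }

    trio_path <- file.path(outdir, "trio.vcf.gz")
    write_vcf(header, records, trio_path)

    # truth table
    pat_out <- sub("comphet_(paternal|maternal)", "comphet",
                   planted_pattern[planted_idx])
    truth <- data.frame(id = planted_idx, pattern = pat_out,
                        chrom = chrom[planted_idx], pos = pos[planted_idx],
                        gene = gene[planted_idx], stringsAsFactors = FALSE)
    truth <- truth[order(truth$id), ]
    truth_path <- file.path(outdir, "truth.tsv")
    truth_con <- file(truth_path, "wb")
    truth_rows <- if (nrow(truth)) {
      vapply(seq_len(nrow(truth)), function(k)
        paste(truth$id[k], truth$pattern[k], truth$chrom[k], truth$pos[k],
              truth$gene[k], sep = "\t"), character(1))
    } else character(0)
    writeLines(c(paste0("# fixture truth, seed=", spec$seed),
                 paste(colnames(truth), collapse = "\t"),
                 truth_rows),
               truth_con, sep = "\n")
    close(truth_con)

    # whitelist: exact overlap, some entries denormalized/chr-prefixed
    bi <- which(n_alt == 1)
    wl_idx <- sort(sample(bi, spec$whitelist_overlap))
    decoy_idx <- sort(sample(setdiff(bi, wl_idx), 15))
    wl_header <- structure(
      list(fileformat = "VCFv4.2", info_defs = list(), format_defs = list(),
           sample_names = character(0), other_lines = character(0)),
      class = "vcf_header")
    wl_rec <- function(i, denorm, decoy) {
      r <- ref[i]; a <- alt[[i]][1]; p <- pos[i]; ch <- chrom[i]
      if (decoy) a <- setdiff(BASES, c(substr(r, 1, 1), a))[1]
      if (denorm) {
        r <- paste0("A", r); a <- paste0("A", a); p <- p - 1L
        ch <- paste0("chr", ch)
      }
      structure(list(chrom = ch, pos = as.integer(p), id = NA_character_,
                     ref = r, alt = a, qual = NA_real_, filter = NULL,
                     info = list(), format_keys = character(0),
                     samples = list()),
                class = "vcf_record")
    }
    wl_records <- c(
      lapply(seq_along(wl_idx), function(k)
        wl_rec(wl_idx[k], denorm = k %% 3 == 0, decoy = FALSE)),
      lapply(decoy_idx, wl_rec, denorm = FALSE, decoy = TRUE))
    wl_path <- file.path(outdir, "whitelist.vcf")
    write_vcf(wl_header, wl_records, wl_path)

    # keyed annotation source over a subset of trio sites
    src_idx <- which(seq_len(n) %% 7 == 0 | multi)
    src_header <- wl_header
    src_header$info_defs <- list(
      SIFT_score = field_def("SIFT_score", "INFO", "1", "Float",
                             "Deleteriousness score"),
      GP_AF = field_def("GP_AF", "INFO", "A", "Float",
                        "Population allele frequency"))
    src_records <- lapply(src_idx, function(i) {
      structure(list(chrom = chrom[i], pos = as.integer(pos[i]),
                     id = NA_character_, ref = ref[i], alt = alt[[i]],
                     qual = NA_real_, filter = NULL,
                     info = list(SIFT_score = round(runif(1), 3),
                                 GP_AF = round(runif(n_alt[i], 0, 0.2), 4)),
                     format_keys = character(0), samples = list()),
                class = "vcf_record")
    })
    src_path <- file.path(outdir, "ann_source.vcf")
    write_vcf(src_header, src_records, src_path)

    invisible(list(
      paths = list(trio = trio_path, truth = truth_path,
                   whitelist = wl_path, ann_source = src_path),
      truth = truth, spec = spec))
  })
}

#' Read a fixture truth table
#' @param path Path to `truth.tsv`.
#' @return data.frame with columns id, pattern, chrom, pos, gene.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Run the trio filtering cascade on a store
#'
#' Reproduces the standard diagnostic cascade shape on a loaded trio store:
#' three frequency filters (`< threshold` on each frequency-like field),
#' one function-class set filter, then the autosomal-recessive trio
#' filter applied to the survivors. Counts after each step are returned;
#' they are non-increasing by construction of the stack.
#'
#' @param store An L2 `variant_store`.
#' @param trio A [trio_spec()].
#' @param freq_fields INFO keys of the frequency-like fields.
#' @param threshold Frequency cutoff (default 0.01).
#' @param func_field INFO key of the function-class field.
#' @param func_classes Retained classes (default nonsense, missense).
#' @return List with `counts` (named, one per step), `final_ids` (record
#'   ids after the inheritance step) and `stack`.
#' @export
trio_cascade <- function(store, trio,
                         freq_fields = c("KG_AF", "EXAC_AF", "ESP_AF"),
                         threshold = 0.01,
                         func_field = "FUNC",
                         func_classes = c("nonsense", "missense")) {
  stk <- filter_stack(store)
  counts <- c(loaded = store$n)
  for (f in freq_fields) {
    stk <- push_filter(stk, vcf_filter("info", f, "<", threshold,
                                       header = store$header), store)
    counts[[paste0(f, "<", threshold)]] <- survivor_count(stk)
  }
  stk <- push_filter(stk, vcf_filter("info", func_field, "in_set",
                                     func_classes, header = store$header),
                     store)
  counts[[paste0(func_field, " in_set ",
                 paste(func_classes, collapse = ","))]] <- survivor_count(stk)
  final <- recessive_filter(survivor_ids(stk), trio, store = store)
  counts[["trio recessive"]] <- length(final)
  list(counts = counts, final_ids = final, stack = stk)
}
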