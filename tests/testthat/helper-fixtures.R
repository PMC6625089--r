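# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# Small generated trio fixture used across module tests.
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    dir <- file.path(tempdir(), "vcfstack-small-fixture")
    spec <- fixture_spec(n_variants = 600, seed = 7, pass_fraction = 0.7,
                         planted = c(recessive = 12, denovo = 5,
                                     comphet_genes = 3, xlinked = 2),
                         whitelist_overlap = 37)
    res <- generate_fixture(spec, dir)
    store <- suppressMessages(load_vcf(res$paths$trio, "L2"))
    .fixture_cache$small <- list(res = res, store = store,
                                 trio = trio_spec("FATHER", "MOTHER", "CHILD",
                                                  store$header))
  }
  .fixture_cache$small
}

# Full-size fixture matching the default generator conditions; used by the
# acceptance tests.
full_fixture <- function() {
  if (is.null(.fixture_cache$full)) {
    dir <- file.path(tempdir(), "vcfstack-full-fixture")
    res <- generate_fixture(fixture_spec(), dir)
    store <- suppressMessages(load_vcf(res$paths$trio, "L2"))
    .fixture_cache$full <- list(res = res, store = store,
                                trio = trio_spec("FATHER", "MOTHER", "CHILD",
                                                 store$header))
  }
  .fixture_cache$full
}

# A tiny handcrafted VCF, exercising flags, multi-allelics, missing values
# and per-sample fields.
mini_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP\">",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Function\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "FATHER", "MOTHER", "CHILD", sep = "\t"),
    paste("1", "101", "rs1", "A", "G", "50", "PASS", "AF=0.01;DB;FUNC=missense",
          "GT:DP", "0/1:30", "0/1:25", "1/1:28", sep = "\t"),
    paste("1", "205", ".", "C", "G,T", ".", "q10;s50", "AF=0.10,0.005",
          "GT:DP", "0/1:10", "0/2:12", "1/2:9", sep = "\t"),
    paste("chr2", "77", ".", "CA", "CT", "12.5", "PASS", "FUNC=nonsense",
          "GT:DP", "0|1:7", "0/0:.", "./.:5", sep = "\t"))
}

mini_vcf_file <- function(lines = mini_vcf_lines(), ext = ".vcf") {
  path <- tempfile(fileext = ext)
  con <- if (grepl("\\.gz$", ext)) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  path
}

mini_store <- function() {
  suppressMessages(load_vcf(mini_vcf_file(), "L2"))
}

# In-memory randomized store for property tests: typed INFO (multi-valued
# Float, String, Flag), QUAL/FILTER with missingness. No files involved.
random_store <- function(n) {
  h <- parse_header(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"freq\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"class\">",
    "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"known\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t")))
  gts <- c("0/0", "0/1", "1/1", "0|1", "./.", "1", "1/2")
  records <- lapply(seq_len(n), function(i) {
    n_alt <- sample(1:2, 1, prob = c(0.85, 0.15))
    info <- list(AF = round(runif(n_alt), 3),
                 DP = sample(1:100, 1),
                 FUNC = sample(c("missense", "nonsense", "synonymous"), 1))
    if (runif(1) < 0.3) info$DB <- TRUE
    if (runif(1) < 0.1) info$AF <- NULL
    structure(list(
      chrom = sample(c("1", "chr1", "2", "X"), 1),
      pos = i * 10L,
      id = if (runif(1) < 0.5) paste0("rs", i) else NA_character_,
      ref = sample(c("A", "C", "G", "T"), 1),
      alt = sample(c("A", "C", "G", "T"), n_alt),
      qual = if (runif(1) < 0.1) NA_real_ else round(runif(1, 1, 100), 1),
      filter = if (runif(1) < 0.1) NULL else
        sample(list("PASS", "q10", c("q10", "s50")), 1)[[1]],
      info = info,
      format_keys = "GT",
      samples = list(S1 = list(GT = sample(gts, 1)),
                     S2 = list(GT = sample(gts, 1)))),
      class = "vcf_record")
  })
  variant_store(h, records)
}

# Random valid filter over the random_store schema.
random_filter <- function(header) {
  pick <- sample(6, 1)
  switch(pick,
    vcf_filter("info", "AF", sample(c("<", ">", "<=", ">="), 1), runif(1),
               header = header),
    vcf_filter("info", "DP", sample(c("<", ">"), 1), sample(1:100, 1),
               header = header),
    vcf_filter("info", "FUNC", "in_set",
               sample(c("missense", "nonsense", "synonymous"),
                      sample(1:2, 1)),
               header = header),
    vcf_filter("info", "DB", sample(c("present", "absent"), 1),
               header = header),
    vcf_filter("basic", sample(c("QUAL", "POS"), 1),
               sample(c("<", ">"), 1), runif(1, 1, 100), header = header),
    vcf_filter("format", "GT",
               sample(c("is_het", "has_alt", "is_hom_ref"), 1),
               sample_scope = sample(c("S1", "S2"), sample(1:2, 1)),
               header = header)
  )
}

# Independent brute-force oracle: records satisfying every filter,
# evaluated one by one with no stack involved.
brute_force_ids <- function(store, filters) {
  Filter(function(i) {
    all(vapply(filters, function(f)
      record_passes(store$records[[i]], f, store$header), logical(1)))
  }, seq_len(store$n))
}

push_all <- function(store, filters) {
  stk <- filter_stack(store)
  for (f in filters) stk <- push_filter(stk, f, store)
  stk
}
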