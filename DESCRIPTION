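Package: vcfstack
Title: Metadata-Driven VCF Parsing, Indexed Variant Stores, and LIFO Filter Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for interactive-style variant mining on VCF
    files. Parses VCF 4.x headers into typed field metadata and reads records
    at selectable depth (site-only, site+FORMAT keys, or full per-sample
    values), holds them in an indexed in-memory store, and filters them with a
    typed last-in-first-out filter stack whose operators are derived from the
    declared field types, including sample-scoped genotype filters. Supports
    variant-keyed annotation transfer from annotation VCFs with allele
    normalization, whitelist/blacklist flag screening, interval flags from BED,
    trio inheritance-pattern filters (autosomal recessive, de novo, X-linked
    recessive, compound heterozygous), export to VCF/CSV/TSV, and a
    deterministic synthetic trio-VCF generator with planted truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, tools, utils
Suggests: testthat (>= 3.0.0), vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
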