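# vcfstack

Headless variant mining for VCF files: metadata-driven parsing at selectable
depth, an indexed in-memory variant store, a typed LIFO filter-stack engine
with sample-scoped genotype filters, allele-keyed annotation transfer
(including whitelist/blacklist screening), trio inheritance-pattern filters,
and exporters — all scriptable from R or a thin command-line wrapper.

## The problem

Clinical and research genetics workflows routinely start from a multi-sample
VCF (often a parent–parent–child trio) and narrow hundreds of thousands of
variant calls down to a handful of candidates by stacking filters: population
allele frequency below a cutoff, damaging functional class, a Mendelian
inheritance pattern consistent with the phenotype, membership in a curated
whitelist. Interactive viewers implement this as a filter panel; `vcfstack`
implements the same semantics as a library, so the identical screening logic
is testable, reproducible and automatable:

- **Typed fields drive typed filters.** `##INFO`/`##FORMAT` header metadata
  is parsed into field definitions (`Number=`, `Type=`), and each field only
  admits the operators its type supports: relational operators (`<`, `>`,
  `>=`, `<=`, `==`, `!=`) for Integer/Float, `present`/`absent` for flags,
  equality and `in_set` for strings, and genotype-class operators
  (`is_het`, `is_hom_alt`, `has_alt`, ...) for `GT`.
- **LIFO filter stack.** Each pushed filter applies only to the survivors of
  all previous filters and reports its survivor count; removal is
  last-in-first-out. The final survivor set equals the conjunction of all
  filters evaluated independently, so it is invariant to push order even
  though the intermediate counts are not.
- **Three filter categories.** `basic` (CHROM, POS, ID, QUAL, FILTER — REF
  and ALT are deliberately excluded), `info` (INFO keys), and `format`
  (per-sample keys, restricted to an explicit sample scope; all scoped
  samples must pass).
- **Selectable parse depth.** `L0` parses the fixed columns plus typed INFO,
  `L1` adds the FORMAT key list, `L2` adds all typed per-sample values.
  FILTER is retained at every level so pass-status queries always work.
- **Allele-keyed annotation.** Annotation sources are themselves VCFs; keys
  are matched on normalized `(chrom, pos, ref, alt)` per alternate allele
  (shared suffix then prefix trimming), so padded representations of the
  same variant compare equal. Selected keys are copied under a namespaced
  id (`dbnsfp_SIFT_score`); whitelists/blacklists inject a presence Flag
  that screens via an ordinary flag filter.
- **Trio inheritance filters.** Autosomal recessive (parents het, child
  hom-alt on a shared allele), de novo (parents hom-ref, child carries an
  alt), X-linked recessive, and compound heterozygous (two child-het
  variants in one gene with observed trans parental configuration).

A deterministic synthetic trio-VCF generator with planted truth
(`fixture_spec()` / `generate_fixture()`) makes every component testable
without any external data.

## Worked example

```r
library(vcfstack)

dir  <- tempfile()
fx   <- generate_fixture(fixture_spec(n_variants = 1000, seed = 42), dir)
store <- load_vcf(fx$paths$trio, "L2")
store
#> Variant store: 1000 records, 3 samples, 0 indexes

trio <- trio_spec("FATHER", "MOTHER", "CHILD", store$header)

stk <- filter_stack(store)
stk <- push_filter(stk, vcf_filter("basic", "FILTER", "==", "PASS",
                                   header = store$header), store)
stk <- push_filter(stk, vcf_filter("info", "KG_AF", "<", 0.01,
                                   header = store$header), store)
stk
#> Filter stack: 2 filter(s), base 1000 records
#>    basic:FILTER == PASS -> 700 survivors
#>    info:KG_AF < 0.01 -> 25 survivors
```

The generator plants exactly 700 PASS records (`pass_fraction = 0.7`); the
frequency filter then keeps the 25 PASS records whose allele frequency is
below 1%. The standard diagnostic cascade — three frequency panels, a
functional-class cut, then the recessive trio pattern — runs in one call:

```r
cc <- trio_cascade(store, trio)
cc$counts
#>                        loaded                    KG_AF<0.01
#>                          1000                            45
#>                  EXAC_AF<0.01                   ESP_AF<0.01
#>                            24                            23
#> FUNC in_set nonsense,missense                trio recessive
#>                             7                             2
cc$final_ids
#> [1] 677 726
```

Counts shrink monotonically; the two final ids are exactly the planted
recessive sites that are rare in all three panels and nonsense/missense.
Whitelist screening works the same way through a flag filter:

```r
src <- build_annotation_source(fx$paths$whitelist, mode = "list", name = "WL")
ann <- annotate_store(store, src)
ann$count
#> [1] 37   # exactly the planted whitelist overlap
```

The same operations are available from a shell via the wrapper installed at
`system.file("cli", "vcfstack", package = "vcfstack")`:

```sh
vcfstack load trio.vcf.gz --level L2 --out trio.store
vcfstack filter --store trio.store --filter "info:KG_AF < 0.01" \
         --filter "format:GT is_het @FATHER,MOTHER" --export rare.vcf
vcfstack trio --store trio.store --father FATHER --mother MOTHER \
         --child CHILD --pattern recessive
```

Exported VCFs carry each applied filter as a `##vcfstack_filter=` provenance
line.

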