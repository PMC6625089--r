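---
title: "Variant mining with typed filter stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant mining with typed filter stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcfstack)
```

# Scope and model

`vcfstack` implements the screening semantics of an interactive variant
filter panel as a composable library. Its data model has three layers:

1. **Header metadata** (`parse_header()`): every `##INFO` and `##FORMAT`
   line becomes a typed field definition (identifier, `Number=` cardinality,
   `Type=`, description). All downstream behaviour — value coercion,
   operator generation, multi-valued semantics — is driven by these
   definitions, never by inspecting values.
2. **Records** (`parse_record()`): one object per body line, with typed
   INFO values and, at full depth, typed per-sample values.
3. **Store and stack** (`variant_store()`, `filter_stack()`): records under
   dense stable ids with optional per-field indexes, filtered by an ordered
   conjunction with last-in-first-out removal.

The engine assumes a structurally valid VCF 4.x file but deliberately
tolerates the common real-world defects: undeclared keys, missing values,
mixed chromosome naming, CRLF line endings, and values that contradict their
declared type.

# Parse depth

Records parse at one of three nested depths. `L0` retains the fixed columns
and typed INFO; `L1` adds the FORMAT key list; `L2` adds all per-sample
values. Site-level triage (frequency and consequence filtering) only needs
`L0`; genotype-dependent work (format filters, trio patterns) needs `L2`.
One deliberate deviation from a strict "first eight columns" reading of
`L0`: the FILTER column is retained at every depth, because pass-status
queries (`FILTER == PASS`) are the single most common operation and must
work regardless of how the file was loaded.

# Typing and coercion

`coerce_value()` applies the declared type: Integer/Float parse numerically,
`Number=` other than 0/1 splits on commas into vectors, `"."` maps to `NA`,
and a Flag key maps to a presence marker. Two rules keep a miner from
silently losing data:

- **Degradation, not rejection.** A value that fails numeric coercion (e.g.
  `AF=abc` under `Type=Float`) is kept as a string, tagged `degraded`, and
  reported as a warning. The record survives; under numeric operators the
  degraded value simply never passes (it behaves like missing).
- **Auto-registration.** An INFO or FORMAT key used in the body but absent
  from the header is registered as `Type=String, Number=.` and reported once
  per key. Real VCFs are chronically under-declared; rejecting them would
  make the tool useless in practice.

# Filter semantics

Operators are derived from the field type (`operators_for()`): relational
operators for numeric fields, `present`/`absent` for flags, equality /
`in_set` for strings, and genotype-class operators for `GT`. `GT` is
special-cased because a genotype class like "heterozygous" is not a string
predicate: `0/1`, `1|0` and `0|1` must all satisfy it.

Three evaluation rules deserve justification:

- **ANY over multi-valued fields.** A record with `AF=0.10,0.005` passes
  `AF < 0.01` because one allele does. This keeps multi-allelic records
  discoverable by the allele that matters; the conservative alternative is
  exposed as the `elementwise = "all"` modifier (serialized as an `all:`
  operator prefix) rather than as a global switch.
- **Missing fails everything except `is_missing`.** A missing QUAL fails
  both `QUAL > 30` and `QUAL <= 30`. This makes survivor counts predictable
  and arithmetic: the `is_missing` survivors plus the `not_missing`
  survivors always partition the present/absent records. "Keep missing"
  workflows are expressed explicitly, never implicitly.
- **FILTER is member-wise.** `FILTER == q10` matches `q10;s50`; `PASS`
  matches only the literal `PASS`.

Basic and info filters apply to the site; format filters apply to an
explicit sample scope, with AND over the scoped samples within one filter
(an empty scope means all samples). A scope of `{FATHER, MOTHER}` with
`is_het` is therefore exactly equivalent to two stacked single-sample
filters — a property the test suite checks.

The stack itself is a pure conjunction: push restricts the previous
survivor set, pop restores it exactly, counts are non-increasing, and the
final set is invariant to push order (verified against a brute-force oracle
that evaluates every filter independently on every record). Indexes, when
present, only change the access path; an indexed query must — and is tested
to — return the same ids as a full scan.

Chromosome names are normalized (leading `chr` stripped, uppercased) for
every comparison and preserved verbatim on output. Survivors are returned
in (normalized chromosome, position, REF, ALT) order with chromosomes
compared lexicographically; a contig dictionary would give karyotype order
but is not required by any downstream contract, and lexicographic order is
reproducible with no extra input.

# Annotation transfer and screening

Annotation sources are VCFs; matching is exact on the normalized
`(chrom, pos, ref, alt)` of each alternate allele. Normalization trims the
longest shared suffix, then the shared prefix while both alleles stay
non-empty, advancing the position per trimmed prefix base; it is idempotent.
Full left-alignment against a reference genome is deliberately out of
scope — it would require a FASTA — so two representations that differ by a
shift through a repeat tract will not match; this is the scheme's known
limitation, shared with any FASTA-free matcher.

Design choices: matching is allele-level, never position-only or rsID-based
(a whitelist hit must mean *this* allele); transferred keys are namespaced
`sourcename_key` to avoid clobbering in-house annotations, stored per
alternate allele (`Number=A`) aligned with the target's ALT order;
`Number=G` (genotype-shaped) fields are never copied because they are
sample-dependent; and a collision with an unrelated existing INFO id aborts
before any mutation. List mode (whitelists/blacklists) records presence
only and injects a single Flag, so screening reduces to an ordinary
`present`/`absent` filter — and `present` plus `absent` partitions the
store. BED interval flags use 0-based half-open coordinates: a variant at
1-based POS is covered iff `POS - 1` lies in `[start, end)`.

# Trio inheritance patterns

Genotypes classify as hom-ref / het / hom-alt / hemi-ref / hemi-alt /
missing / multi-alt-het. Four patterns are implemented, with the following
resolutions of genuinely open definitional points:

- **Recessive**: both parents het, child hom-alt, *sharing one alternate
  allele index*. "Child homozygous" is read as homozygous-alternate: a
  hom-ref child cannot carry a recessive condition, and without the shared
  allele requirement two different alt alleles would satisfy the genotype
  classes without any plausible transmission.
- **De novo**: both parents hom-ref, child carries at least one alternate
  allele (a `1/2` child still counts — it carries alt).
- **X-linked recessive**: chromosome X after normalization, mother het,
  child hemizygous- or homozygous-alt, and the father carries no alternate
  allele. The father criterion is the strictest defensible reading and is
  overridable (`father_no_alt = FALSE`).
- **Compound heterozygous**: within one gene (a string INFO key), one
  child-het variant whose observed parental genotypes force paternal origin
  (father carries alt, mother hom-ref) paired with one forcing maternal
  origin. Only genotype-observable trans configurations count; read-backed
  phasing is not available in a plain VCF.

Missing genotypes exclude a record from every pattern (conservative
screening; an include-missing flag exists). `multi_alt_het` (`1/2`) is
excluded from `het` for pattern purposes — its transmission is ambiguous —
but satisfies `has_alt`. On fully called trios the recessive and de novo
sets are provably disjoint, which the suite asserts.

Inheritance filters accept either a store or an id vector, so they compose
with filter-stack survivors: the standard cascade (frequency → functional
class → inheritance) is `trio_cascade()`.

# The synthetic-data generator

No suitable public trio dataset ships with typed truth for every planted
pattern, so the generator *is* the study condition. `fixture_spec()`
defaults describe a realistic small exome-like screen:

| parameter | default | rationale |
|---|---|---|
| `n_variants` | 10,000 | large enough for index/scan paths and sub-percent planted fractions; small enough to parse in seconds |
| `pass_fraction` | 0.7 | an exact count (7,000), enforced by construction — typical of a joint-called trio after standard soft filters |
| planted patterns | 12 recessive, 5 de novo, 3 compound-het genes | a plausible handful of true candidates against a 10⁴ background |
| `whitelist_overlap` | 37 | exact planted overlap, with a third of the whitelist written in padded non-normal form and `chr`-prefixed spelling to force the matcher through normalization |
| background allele frequency | uniform (0, 0.5) | planted sites forced `< 0.01` on all three frequency-like fields so the frequency cascade is discriminative |
| `seed` | 42 | recorded in the truth file; identical spec + seed gives byte-identical outputs |

Background trio genotypes are drawn from four configurations chosen so that
*no* background record can satisfy any planted pattern — including the
subtle case of a stray maternal-origin child-het landing in a planted
compound-het gene. Planted counts are therefore recovered exactly, not
statistically. Functional classes are drawn independently for all sites
(planted included), so the cascade's functional cut genuinely discriminates
and the expected final set is computed from the truth table, not assumed.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: linkage structure and realistic site spacing,
sequencing-error and genotype-error models, strand or allele-balance
artifacts, population structure in the frequency fields, multi-sample
cohorts beyond a trio, and structural/symbolic alleles. The engine's
correctness claims are about filtering semantics, not about variant-calling
noise robustness.

# Numerical and format choices

- Numbers render with `as.character()` (up to 15 significant digits), so a
  parse→write→parse cycle is the identity on every retained field — the
  round-trip contract is field equality after re-parse, not byte equality
  of the file.
- Gzip is detected by the two magic bytes, never the extension; output
  compression follows the requested file name. LF and CRLF inputs parse
  identically; output is LF.
- CSV export quotes RFC-4180-style (quotes doubled, fields containing
  delimiter/quote/newline quoted); TSV forbids tabs in values and replaces
  them with a space under a warning. Missing renders as `"."`; list values
  join with `","`.
- The store file written by the CLI is a versioned serialized payload;
  version mismatches are refused rather than guessed at.
- Record ids are dense 1-based insertion order, stable for the store's
  lifetime; all query results return ascending ids.

# Problem sizes used by the checks

The bundled suite exercises a 600-variant trio for module tests, a
10,000-variant trio for the end-to-end pattern-recovery and cascade checks,
100 randomized stores of 80–400 records for the conjunction-oracle
property, and 1,000 random push/pop steps for the LIFO contract. These
sizes were chosen to cover all code paths (multi-allelics, indels, phased
and missing genotypes, all 23 chromosomes) while keeping a full run fast
enough to be part of routine development.

# Known limitations

- No OR/NOT filter trees; the panel model is conjunctive by design (two
  stacks express a union manually).
- Allele matching is normalization-exact, not reference-aware
  (no left-alignment through repeats; no rsID fallback).
- Joint multi-allelic records are never split; ANY semantics plus
  per-allele annotation alignment are the mitigation.
- Pedigrees beyond a trio, PED parsing, and probabilistic inheritance
  models are out of scope.
- BCF and tabix-indexed access are out of scope; files are read whole into
  memory, which is the intended regime (interactive-scale VCFs, not
  population biobanks).
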