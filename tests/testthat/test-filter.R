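test_that("operators are generated from the declared data type", {
  num <- operators_for(field_def("AF", "INFO", "A", "Float"))
  expect_true(all(c(">", "<", ">=", "<=", "==", "!=", "is_missing",
                    "not_missing") %in% num))
  expect_setequal(operators_for(field_def("DB", "INFO", 0, "Flag")),
                  c("present", "absent"))
  expect_setequal(operators_for(field_def("FUNC", "INFO", 1, "String")),
                  c("==", "!=", "in_set", "is_missing", "not_missing"))
  expect_setequal(operators_for(field_def("GT", "FORMAT", 1, "String")),
                  c("is_hom_ref", "is_het", "is_hom_alt", "is_hemi",
                    "is_missing", "has_alt"))
})

test_that("string value domains split multi-member entries and normalize CHROM", {
  st <- mini_store()
  expect_equal(value_domain(st, "FILTER"), c("PASS", "q10", "s50"))
  expect_equal(value_domain(st, "CHROM"), c("1", "2"))
  expect_equal(value_domain(st, "FUNC", "info"), c("missense", "nonsense"))
  expect_error(value_domain(st, "QUAL"), "string fields")
})

test_that("operand type errors are raised at filter construction", {
  h <- mini_store()$header
  expect_error(vcf_filter("info", "AF", "<", "low", header = h), "numeric")
  expect_error(vcf_filter("info", "AF", "present", header = h),
               "not applicable")
  expect_error(vcf_filter("info", "FUNC", "<", 3, header = h),
               "not applicable")
  expect_error(vcf_filter("info", "DB", "present", operand = 1, header = h),
               "no operand")
  expect_error(vcf_filter("basic", "REF", "==", "A", header = h),
               "REF/ALT are excluded")
  expect_error(vcf_filter("format", "GT", "is_het",
                          sample_scope = "NOBODY", header = h),
               "unknown sample")
  expect_error(vcf_filter("info", "NOPE", "==", "x", header = h),
               "unknown info field")
})

test_that("multi-valued fields use ANY semantics, ALL under the modifier", {
  st <- mini_store()
  rec <- st$records[[2]]                     # AF = 0.10, 0.005
  any_f <- vcf_filter("info", "AF", "<", 0.01, header = st$header)
  all_f <- vcf_filter("info", "AF", "<", 0.01, elementwise = "all",
                      header = st$header)
  expect_true(record_passes(rec, any_f, st$header))
  expect_false(record_passes(rec, all_f, st$header))
  all_pass <- vcf_filter("info", "AF", "<", 0.5, elementwise = "all",
                         header = st$header)
  expect_true(record_passes(rec, all_pass, st$header))
})

test_that("missing values fail every operator except is_missing", {
  st <- mini_store()
  rec <- st$records[[2]]                     # QUAL missing, no FUNC
  h <- st$header
  expect_false(record_passes(rec, vcf_filter("basic", "QUAL", ">", 30,
                                             header = h), h))
  expect_false(record_passes(rec, vcf_filter("basic", "QUAL", "<", 1e9,
                                             header = h), h))
  expect_false(record_passes(rec, vcf_filter("basic", "QUAL", "not_missing",
                                             header = h), h))
  expect_true(record_passes(rec, vcf_filter("basic", "QUAL", "is_missing",
                                            header = h), h))
  expect_false(record_passes(rec, vcf_filter("info", "FUNC", "==", "missense",
                                             header = h), h))
  expect_true(record_passes(rec, vcf_filter("info", "FUNC", "is_missing",
                                            header = h), h))
})

test_that("FILTER equality matches any semicolon member; PASS is literal", {
  st <- mini_store()
  h <- st$header
  q10 <- vcf_filter("basic", "FILTER", "==", "q10", header = h)
  pass <- vcf_filter("basic", "FILTER", "==", "PASS", header = h)
  expect_true(record_passes(st$records[[2]], q10, h))   # FILTER=q10;s50
  expect_false(record_passes(st$records[[2]], pass, h))
  expect_true(record_passes(st$records[[1]], pass, h))
})

test_that("CHROM filters match across chr-prefix conventions", {
  st <- mini_store()
  h <- st$header
  f <- vcf_filter("basic", "CHROM", "==", "2", header = h)
  expect_true(record_passes(st$records[[3]], f, h))     # file spells chr2
  f2 <- vcf_filter("basic", "CHROM", "==", "chr2", header = h)
  expect_true(record_passes(st$records[[3]], f2, h))
  expect_false(record_passes(st$records[[1]], f2, h))
})

test_that("flag presence mirrors the key being set", {
  st <- mini_store()
  h <- st$header
  pres <- vcf_filter("info", "DB", "present", header = h)
  abs <- vcf_filter("info", "DB", "absent", header = h)
  expect_true(record_passes(st$records[[1]], pres, h))
  expect_false(record_passes(st$records[[1]], abs, h))
  expect_false(record_passes(st$records[[2]], pres, h))
  expect_true(record_passes(st$records[[2]], abs, h))
})

test_that("genotype-class filters evaluate per scoped sample with AND", {
  st <- mini_store()
  h <- st$header
  het_parents <- vcf_filter("format", "GT", "is_het",
                            sample_scope = c("FATHER", "MOTHER"), header = h)
  expect_true(record_passes(st$records[[1]], het_parents, h))  # 0/1 and 0/1
  hom_child <- vcf_filter("format", "GT", "is_hom_alt",
                          sample_scope = "CHILD", header = h)
  expect_true(record_passes(st$records[[1]], hom_child, h))
  # record 3: FATHER 0|1 (phased het), MOTHER 0/0, CHILD ./.
  expect_false(record_passes(st$records[[3]], het_parents, h))
  scoped_father <- vcf_filter("format", "GT", "is_het",
                              sample_scope = "FATHER", header = h)
  expect_true(record_passes(st$records[[3]], scoped_father, h))
  missing_child <- vcf_filter("format", "GT", "is_missing",
                              sample_scope = "CHILD", header = h)
  expect_true(record_passes(st$records[[3]], missing_child, h))
  # empty scope means all samples
  all_has_alt <- vcf_filter("format", "GT", "has_alt", header = h)
  expect_true(record_passes(st$records[[2]], all_has_alt, h))
  expect_false(record_passes(st$records[[3]], all_has_alt, h))
})

test_that("a format filter over a joint scope equals the two single-sample filters", {
  fx <- small_fixture()
  st <- fx$store
  h <- st$header
  joint <- vcf_filter("format", "GT", "is_het",
                      sample_scope = c("FATHER", "MOTHER"), header = h)
  f1 <- vcf_filter("format", "GT", "is_het", sample_scope = "FATHER",
                   header = h)
  f2 <- vcf_filter("format", "GT", "is_het", sample_scope = "MOTHER",
                   header = h)
  a <- survivor_ids(push_all(st, list(joint)))
  b <- survivor_ids(push_all(st, list(f1, f2)))
  expect_equal(a, b)
})

test_that("pushing a filter keeps exactly the passing survivors", {
  fx <- small_fixture()
  st <- fx$store
  stk <- push_filter(filter_stack(st),
                     vcf_filter("basic", "FILTER", "==", "PASS",
                                header = st$header), st)
  expect_equal(survivor_count(stk), 420)     # exact 70% of 600 by construction
  # a tautology leaves the count unchanged
  stk2 <- push_filter(stk, vcf_filter("info", "DP", ">=", 0,
                                      header = st$header), st)
  expect_equal(survivor_count(stk2), 420)
  # pushing onto an empty survivor set stays empty
  none <- push_filter(stk, vcf_filter("basic", "QUAL", ">", 1e9,
                                      header = st$header), st)
  expect_equal(survivor_count(none), 0)
  still_none <- push_filter(none, vcf_filter("info", "DP", ">=", 0,
                                             header = st$header), st)
  expect_equal(survivor_count(still_none), 0)
})

test_that("pop restores the previous survivor set exactly", {
  st <- small_fixture()$store
  h <- st$header
  a <- vcf_filter("basic", "QUAL", ">", 300, header = h)
  b <- vcf_filter("info", "FUNC", "==", "missense", header = h)
  s0 <- filter_stack(st)
  s1 <- push_filter(s0, a, st)
  s2 <- push_filter(s1, b, st)
  expect_equal(pop_filter(s2), s1)
  expect_equal(pop_filter(s1), s0)
  expect_error(pop_filter(s0), "stack-empty")
})

test_that("survivor counts never increase down the stack", {
  set.seed(11)
  st <- random_store(250)
  for (rep in 1:5) {
    filters <- lapply(1:4, function(i) random_filter(st$header))
    stk <- push_all(st, filters)
    counts <- vapply(stk$levels, function(l) l$count, integer(1))
    expect_true(all(diff(c(st$n, counts)) <= 0))
  }
})

test_that("the final survivor set equals brute-force conjunction and is order-invariant", {
  set.seed(23)
  for (rep in 1:8) {
    st <- random_store(120)
    filters <- lapply(seq_len(sample(2:4, 1)), function(i)
      random_filter(st$header))
    expected <- brute_force_ids(st, filters)
    expect_equal(survivor_ids(push_all(st, filters)), expected)
    expect_equal(survivor_ids(push_all(st, rev(filters))), expected)
    expect_equal(survivor_ids(push_all(st, sample(filters))), expected)
  }
})

test_that("survivors come back in genomic order", {
  st <- small_fixture()$store
  recs <- survivors(filter_stack(st), st)
  expect_length(recs, st$n)
  ch <- vapply(recs, function(r) normalize_chrom(r$chrom), character(1))
  pos <- vapply(recs, function(r) r$pos, integer(1))
  # already in (chrom, pos) order: a stable sort leaves it unchanged
  expect_identical(order(ch, pos), seq_along(ch))
})

test_that("filter serialization round-trips bit-exactly", {
  h <- mini_store()$header
  filters <- list(
    vcf_filter("info", "AF", "<", 0.01, header = h),
    vcf_filter("info", "AF", ">=", 0.25, elementwise = "all", header = h),
    vcf_filter("info", "DB", "present", header = h),
    vcf_filter("info", "FUNC", "in_set", c("nonsense", "missense"),
               header = h),
    vcf_filter("basic", "FILTER", "==", "PASS", header = h),
    vcf_filter("basic", "QUAL", ">", 30, header = h),
    vcf_filter("format", "GT", "is_het",
               sample_scope = c("FATHER", "MOTHER"), header = h),
    vcf_filter("format", "DP", ">", 10, sample_scope = "CHILD", header = h),
    vcf_filter("basic", "ID", "is_missing", header = h)
  )
  for (f in filters) {
    text <- render_filter(f)
    expect_equal(parse_filter(text, h), f, info = text)
    expect_equal(render_filter(parse_filter(text, h)), text)
  }
  expect_equal(render_filter(filters[[7]]),
               "format:GT is_het @FATHER,MOTHER")
  expect_error(parse_filter("nonsense text", h), "category:field")
  expect_error(parse_filter("info:AF <", h), "operand")
})
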