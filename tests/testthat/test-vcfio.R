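test_that("header metadata lines parse into typed field definitions", {
  h <- parse_header(mini_vcf_lines()[1:8])
  expect_equal(h$fileformat, "VCFv4.2")
  af <- h$info_defs$AF
  expect_equal(af$number, "A")
  expect_equal(af$type, "Float")
  expect_equal(af$description, "Allele Frequency")
  db <- h$info_defs$DB
  expect_equal(db$type, "Flag")
  expect_equal(db$number, "0")
  expect_equal(h$sample_names, c("FATHER", "MOTHER", "CHILD"))
  expect_equal(h$other_lines, "##contig=<ID=1>")
  expect_equal(names(h$format_defs), c("GT", "DP"))
})

test_that("defective headers are rejected with a named defect", {
  lines <- mini_vcf_lines()[1:7]             # no #CHROM line
  expect_error(parse_header(lines), "#CHROM")
  dup <- c(mini_vcf_lines()[1:8][1:3], mini_vcf_lines()[3], mini_vcf_lines()[8])
  expect_error(parse_header(dup), "duplicate INFO")
  expect_error(parse_header(c("##notfileformat", "#CHROM")), "fileformat")
})

test_that("rendering then re-parsing a header is the identity", {
  h <- parse_header(mini_vcf_lines()[1:8])
  h2 <- parse_header(render_header(h))
  expect_equal(h2$info_defs, h$info_defs)
  expect_equal(h2$format_defs, h$format_defs)
  expect_equal(h2$sample_names, h$sample_names)
  expect_equal(h2$other_lines, h$other_lines)
})

test_that("values coerce according to declared type and cardinality", {
  float1 <- field_def("AF", "INFO", 1, "Float")
  floatA <- field_def("AF", "INFO", "A", "Float")
  intA <- field_def("AC", "INFO", "A", "Integer")
  flag <- field_def("DB", "INFO", 0, "Flag")
  expect_identical(coerce_value("0.0134", float1), 0.0134)
  expect_identical(coerce_value("12,3", intA), c(12L, 3L))
  expect_identical(coerce_value(".", float1), NA)
  expect_identical(coerce_value(".", intA), NA)
  expect_true(coerce_value(NA, flag))
  expect_equal(coerce_value("0.1,.", floatA), c(0.1, NA))
})

test_that("failed numeric coercion degrades the value but keeps the record", {
  float1 <- field_def("AF", "INFO", 1, "Float")
  expect_warning(v <- coerce_value("abc", float1), "degraded")
  expect_identical(as.character(v), "abc")
  expect_true(attr(v, "degraded"))
})

test_that("records parse at each level with the documented retention", {
  h <- parse_header(mini_vcf_lines()[1:8])
  line <- mini_vcf_lines()[9]
  r0 <- parse_record(line, h, "L0")
  expect_equal(r0$chrom, "1")
  expect_equal(r0$pos, 101L)
  expect_equal(r0$info$AF, 0.01)
  expect_true(r0$info$DB)
  expect_equal(r0$filter, "PASS")           # FILTER kept at every level
  expect_length(r0$format_keys, 0)
  expect_length(r0$samples, 0)
  r1 <- parse_record(line, h, "L1")
  expect_equal(r1$format_keys, c("GT", "DP"))
  expect_length(r1$samples, 0)
  r2 <- parse_record(line, h, "L2")
  expect_equal(r2$samples$CHILD$GT, "1/1")
  expect_equal(r2$samples$FATHER$DP, 30L)
})

test_that("multi-allelic ALT and semicolon FILTER are split; missing maps to NA", {
  h <- parse_header(mini_vcf_lines()[1:8])
  r <- parse_record(mini_vcf_lines()[10], h, "L2")
  expect_equal(r$alt, c("G", "T"))
  expect_equal(r$filter, c("q10", "s50"))
  expect_true(is.na(r$qual))
  expect_true(is.na(r$id))
  expect_equal(r$info$AF, c(0.10, 0.005))
  expect_equal(r$samples$MOTHER$DP, 12L)
  r3 <- parse_record(mini_vcf_lines()[11], h, "L2")
  expect_identical(r3$samples$MOTHER$DP, NA)   # per-key "." is missing
})

test_that("malformed records raise errors naming the line", {
  h <- parse_header(mini_vcf_lines()[1:8])
  expect_error(parse_record("1\t101\trs1\tA", h, "L0", line_num = 12),
               "line 12.*columns|columns.*line 12")
  expect_error(parse_record("1\t-5\t.\tA\tG\t.\t.\t.", h, "L0"),
               "positive integer")
  expect_error(parse_record("1\tzzz\t.\tA\tG\t.\t.\t.", h, "L0"),
               "positive integer")
})

test_that("gzip is detected by magic bytes, not extension", {
  plain <- mini_vcf_file()
  gz_mislabeled <- tempfile(fileext = ".vcf")   # gzipped despite .vcf name
  con <- gzfile(gz_mislabeled, "wb")
  writeLines(mini_vcf_lines(), con)
  close(con)
  a <- read_vcf(plain, "L2")
  b <- read_vcf(gz_mislabeled, "L2")
  expect_equal(b$records, a$records)
  expect_equal(b$header, a$header)
})

test_that("CRLF line endings parse identically to LF", {
  crlf <- tempfile(fileext = ".vcf")
  con <- file(crlf, "wb")
  writeLines(mini_vcf_lines(), con, sep = "\r\n")
  close(con)
  a <- read_vcf(mini_vcf_file(), "L2")
  b <- read_vcf(crlf, "L2")
  expect_equal(b$records, a$records)
})

test_that("undeclared INFO keys auto-register as String and records survive", {
  lines <- mini_vcf_lines()
  lines[9] <- sub("AF=0.01", "AF=0.01;FOO=bar", lines[9])
  expect_message(parsed <- read_vcf(mini_vcf_file(lines), "L0"), "FOO")
  expect_equal(parsed$records[[1]]$info$FOO, "bar")
  def <- parsed$header$info_defs$FOO
  expect_equal(def$type, "String")
  expect_equal(def$number, ".")
})

test_that("unreadable and empty inputs raise input errors", {
  expect_error(read_vcf(tempfile()), "no such file")
  empty <- tempfile()
  file.create(empty)
  expect_error(read_vcf(empty), "empty file")
})

test_that("parse-write-parse is the identity on all retained fields", {
  fx <- small_fixture()
  a <- read_vcf(fx$res$paths$trio, "L2")
  out <- tempfile(fileext = ".vcf")
  n <- write_vcf(a$header, a$records, out,
                 provenance = "##vcfstack_filter=basic:QUAL > 30")
  expect_equal(n, length(a$records))
  expect_true(any(grepl("^##vcfstack_filter=basic:QUAL > 30$",
                        readLines(out))))
  b <- read_vcf(out, "L2")
  expect_equal(b$records, a$records)
  expect_equal(b$header$info_defs, a$header$info_defs)
})

test_that("L0 projection of an L2 parse equals the direct L0 parse", {
  fx <- small_fixture()
  l2 <- read_vcf(fx$res$paths$trio, "L2")
  l0 <- read_vcf(fx$res$paths$trio, "L0")
  projected <- lapply(l2$records, function(r) {
    r$format_keys <- character(0)
    r$samples <- list()
    r
  })
  expect_equal(projected, l0$records)
})

test_that("an empty survivor set still writes a valid header-only VCF", {
  fx <- small_fixture()
  out <- tempfile(fileext = ".vcf")
  expect_equal(write_vcf(fx$store$header, list(), out), 0)
  reread <- read_vcf(out, "L2")
  expect_length(reread$records, 0)
  expect_equal(reread$header$sample_names, fx$store$header$sample_names)
})

test_that("writing a record with an undeclared sample is a consistency error", {
  st <- mini_store()
  rec <- st$records[[1]]
  rec$samples$GHOST <- rec$samples$FATHER
  expect_error(write_vcf(st$header, list(rec), tempfile()),
               "consistency error.*GHOST")
})

test_that("table export flattens fixed, INFO and per-sample columns", {
  st <- mini_store()
  out <- tempfile(fileext = ".csv")
  n <- write_table(st$header, st$records,
                   c("CHROM", "POS", "REF", "ALT", "AF", "CHILD.GT"), out,
                   "CSV")
  lines <- readLines(out)
  expect_equal(n, 3)
  expect_length(lines, 4)                    # header + 3 records
  expect_equal(lines[1], "CHROM,POS,REF,ALT,AF,CHILD.GT")
  # multi-allelic AF list joined with "," and therefore quoted in CSV
  expect_match(lines[3], "\"0.1,0.005\"", fixed = TRUE)
  expect_match(lines[3], "\"G,T\"", fixed = TRUE)
  expect_match(lines[2], "1/1", fixed = TRUE)
  expect_match(lines[4], "\\./\\.")          # missing genotype rendered
})

test_that("unknown table columns are rejected with the valid names listed", {
  st <- mini_store()
  expect_error(write_table(st$header, st$records, c("CHROM", "XYZ"),
                           tempfile(), "CSV"),
               "unknown column 'XYZ'.*CHROM")
})

test_that("TSV export replaces embedded tabs with a space, with warning", {
  st <- mini_store()
  st$records[[1]]$info$FUNC <- "a\tb"
  out <- tempfile(fileext = ".tsv")
  expect_warning(write_table(st$header, st$records, c("POS", "FUNC"), out,
                             "TSV"),
                 "tab")
  expect_match(readLines(out)[2], "a b", fixed = TRUE)
})

test_that("parser agrees with an independent VCF reader on a fixture", {
  fx <- small_fixture()
  ours <- fx$store
  theirs <- vcfR::read.vcfR(fx$res$paths$trio, verbose = FALSE)
  expect_equal(ours$n, nrow(theirs@fix))
  expect_equal(vapply(ours$records, function(r) r$chrom, character(1)),
               unname(theirs@fix[, "CHROM"]))
  expect_equal(vapply(ours$records, function(r) r$pos, integer(1)),
               as.integer(theirs@fix[, "POS"]))
  expect_equal(vapply(ours$records, function(r) paste(r$alt, collapse = ","),
                      character(1)),
               unname(theirs@fix[, "ALT"]))
})
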