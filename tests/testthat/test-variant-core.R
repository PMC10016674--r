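test_that("classify_variant follows the prefix rules and partitions all pairs", {
  expect_identical(classify_variant("A", "G"), "snv")
  expect_identical(classify_variant("A", "ATT"), "insertion")
  expect_identical(classify_variant("ATTT", "A"), "deletion")
  expect_identical(classify_variant("AT", "GC"), "complex")
  expect_identical(classify_variant("AT", "AGC"), "complex")  # non-prefix growth
  expect_identical(classify_variant("a", "g"), "snv")         # case-insensitive

  # property: every random ACGTN pair falls in exactly one class
  withr::with_seed(11, {
    bases <- c("A", "C", "G", "T", "N")
    for (i in 1:200) {
      ref <- paste(sample(bases, sample(1:5, 1), replace = TRUE), collapse = "")
      alt <- paste(sample(bases, sample(1:5, 1), replace = TRUE), collapse = "")
      cls <- classify_variant(ref, alt)
      expect_true(cls %in% c("snv", "insertion", "deletion", "complex"))
      manual <- if (nchar(ref) == 1 && nchar(alt) == 1) "snv"
        else if (nchar(alt) > nchar(ref) && startsWith(alt, ref)) "insertion"
        else if (nchar(ref) > nchar(alt) && startsWith(ref, alt)) "deletion"
        else "complex"
      expect_identical(cls, manual)
    }
  })
})

test_that("classify_variant rejects symbolic and empty alleles", {
  expect_error(classify_variant("A", "<DEL>"), class = "cosegscan_format_error")
  expect_error(classify_variant("", "A"), class = "cosegscan_format_error")
  expect_error(classify_variant("A", "A*"), class = "cosegscan_format_error")
})

test_that("censored frequencies parse, format and compare correctly", {
  p <- parse_censored(c("<0.001", "0.005", ".", "0"))
  expect_equal(p$value, c(0.001, 0.005, NA, 0))
  expect_equal(p$censored, c(TRUE, FALSE, NA, FALSE))
  expect_identical(format_censored(p$value, p$censored),
                   c("<0.001", "0.005", ".", "0"))
  expect_error(parse_censored("abc"), class = "cosegscan_format_error")
  expect_error(parse_censored("1.5"), class = "cosegscan_format_error")

  # decidable censored comparison: bound at or below the threshold
  expect_true(censored_lt(0.001, TRUE, 0.01))
  expect_true(censored_lt(0.01, TRUE, 0.01))    # bound equal: true value < bound <= t
  expect_false(censored_lt(0.01, FALSE, 0.01))  # uncensored boundary
  expect_true(is.na(censored_lt(NA, NA, 0.01)))
  expect_error(censored_lt(0.05, TRUE, 0.01, label = "v1"),
               class = "cosegscan_censored_error")
})

test_that("indeterminate censored comparisons always raise, never guess", {
  withr::with_seed(21, {
    for (i in 1:100) {
      bound <- runif(1)
      t <- runif(1)
      if (bound <= t) {
        expect_true(censored_lt(bound, TRUE, t))
      } else {
        expect_error(censored_lt(bound, TRUE, t),
                     class = "cosegscan_censored_error")
      }
    }
  })
})

test_that("VCF round-trip preserves identity, genotype and annotations", {
  cs <- mk_callset(dplyr::bind_rows(
    mk_variant(pos = 100L, ref = "A", alt = "G",
               gnomad_popmax_af = 0.001, gnomad_popmax_censored = TRUE,
               topmed_af = 0.004, rsid = "rs1", phastcons7 = 0.5),
    mk_variant(pos = 200L, ref = "ATTT", alt = "A", consequence = "stop_gained",
               sift_label = NA_character_, polyphen_label = NA_character_),
    mk_variant(chrom = "chr2", pos = 300L, ref = "C", alt = "CGG")
  ), sample_id = "sampleX", caller_tag = "callerB")
  cs$genotype <- c("het", "hom_alt", "het")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_callset_vcf(cs, path)
  back <- read_callset(path, caller_tag = "callerB")
  expect_identical(back$sample_id, rep("sampleX", 3))
  cols <- c("chrom", "pos", "ref", "alt", "vclass", "qual", "gene", "rsid",
            "gnomad_popmax_af", "gnomad_popmax_censored", "topmed_af",
            "topmed_censored", "phastcons7", "consequence", "sift_label",
            "polyphen_label", "genotype", "depth")
  ord <- order(cs$chrom, cs$pos)
  expect_equal(as.data.frame(back[cols]), as.data.frame(cs[ord, cols]))
})

test_that("multi-allelic records decompose into one variant per ALT allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="dp">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\t.\tA\tG\t50\tPASS\tGENE=G1\tGT:DP\t0/1:30",
    "chr1\t200\t.\tA\tG,T\t60\tPASS\tGENE=G2,G2\tGT:DP\t1/2:25"
  ), path)
  cs <- read_callset(path, caller_tag = "callerA")
  expect_equal(nrow(cs), 3L)
  expect_setequal(variant_key(cs$chrom, cs$pos, cs$ref, cs$alt),
                  c("chr1:100:A:G", "chr1:200:A:G", "chr1:200:A:T"))
  expect_true(all(cs$genotype[cs$pos == 200] == "het"))
})

test_that("empty VCF body yields an empty callset", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1"
  ), path)
  cs <- read_callset(path, sample_id = "s1", caller_tag = "callerA")
  expect_equal(nrow(cs), 0L)
})

test_that("family table reading validates the pedigree invariants", {
  part <- participants_fixture()
  expect_equal(nrow(part), 21L)
  expect_equal(dplyr::n_distinct(part$family_id), 10L)

  # round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_family_table(part, path)
  expect_equal(as.data.frame(read_family_table(path)), as.data.frame(part))

  # one-member family rejected
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tsample_id\tage\tbilateral\tsex",
               "1\t1a\t10\tY\tfemale"), path2)
  expect_error(read_family_table(path2), class = "cosegscan_format_error")

  # duplicate sample rejected
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tsample_id\tage\tbilateral\tsex",
               "1\t1a\t10\tY\tfemale", "1\t1a\t12\tN\tmale"), path3)
  expect_error(read_family_table(path3), class = "cosegscan_format_error")
})

test_that("variant tables round-trip with censored frequencies intact", {
  v <- dplyr::bind_rows(
    mk_variant(pos = 10L, gnomad_popmax_af = 0.001, gnomad_popmax_censored = TRUE),
    mk_variant(pos = 20L, ref = "AT", alt = "A", gnomad_popmax_af = 0.005)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  back <- read_variant_table(path)
  expect_equal(as.data.frame(back[names(v)]), as.data.frame(v))
})
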