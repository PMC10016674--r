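test_that("hard filter retains by quality and depth, absent values fail", {
  cs <- mk_callset(dplyr::bind_rows(
    mk_variant(pos = 1L, qual = 100), mk_variant(pos = 2L, qual = 10),
    mk_variant(pos = 3L, qual = 50), mk_variant(pos = 4L, qual = NA_real_)
  ))
  cs$depth <- c(40L, 40L, 5L, 40L)
  expect_message(out <- hard_filter(cs), "absent qual/depth")
  expect_equal(out$pos, 1L)
  # vacuous thresholds are the identity on fully annotated callsets
  expect_equal(nrow(hard_filter(cs[1:3, ], 0, 0)), 3L)
})

test_that("snv identity is exact on (chrom, pos, ref, alt)", {
  a <- mk_variant(pos = 100L, ref = "A", alt = "G")
  expect_true(snv_identical(a, mk_variant(pos = 100L, ref = "A", alt = "G")))
  expect_false(snv_identical(a, mk_variant(pos = 100L, ref = "A", alt = "T")))
  expect_false(snv_identical(a, mk_variant(chrom = "chr2", pos = 100L)))
  expect_error(snv_identical(a, mk_variant(pos = 100L, ref = "AT", alt = "A")),
               class = "cosegscan_contract_error")
})

test_that("indel intervals map 1-based VCF coordinates to half-open intervals", {
  del <- mk_variant(pos = 101L, ref = "ATTT", alt = "A")
  expect_equal(indel_interval(del), tibble::tibble(start = 100L, end = 104L))
  ins <- mk_variant(pos = 50L, ref = "A", alt = "ATG")
  expect_equal(indel_interval(ins), tibble::tibble(start = 49L, end = 50L))
  cpx <- mk_variant(pos = 10L, ref = "ACG", alt = "TT")
  expect_equal(indel_interval(cpx), tibble::tibble(start = 9L, end = 12L))
  expect_error(indel_interval(mk_variant(pos = 5L)),
               class = "cosegscan_contract_error")
})

test_that("indel identity requires strictly more than the reciprocal fraction", {
  del10 <- function(pos) mk_variant(pos = pos, ref = paste0("A", strrep("T", 9)),
                                    alt = "A")
  # identical intervals: fraction 1
  expect_true(indel_identical(del10(101L), del10(101L)))
  # [100,110) vs [109,120): fractions 0.1 and 1/11 -- strict '>' fails
  b11 <- mk_variant(pos = 110L, ref = paste0("A", strrep("T", 10)), alt = "A")
  expect_false(indel_identical(del10(101L), b11))
  # [100,110) vs [109,119): both exactly 0.1 -- boundary does not match
  expect_false(indel_identical(del10(101L), del10(110L)))
  # both length 9: 1/9 > 0.1 on both sides
  del9 <- function(pos) mk_variant(pos = pos, ref = paste0("A", strrep("T", 8)),
                                   alt = "A")
  expect_true(indel_identical(del9(101L), del9(109L)))
  # disjoint
  expect_false(indel_identical(del10(101L), del10(300L)))
  expect_error(indel_identical(del10(101L), del10(101L), min_frac = 0),
               class = "cosegscan_config_error")
})

test_that("indel identity agrees with direct interval arithmetic exhaustively", {
  # every pair of small deletions: start 1..15, ref length 2..7
  for (s1 in seq(1L, 15L, by = 2L)) for (l1 in 2:7) {
    for (s2 in seq(1L, 15L, by = 2L)) for (l2 in 2:7) {
      a <- mk_variant(pos = s1, ref = paste0("A", strrep("T", l1 - 1)), alt = "A")
      b <- mk_variant(pos = s2, ref = paste0("A", strrep("T", l2 - 1)), alt = "A")
      ov <- max(0, min(s1 - 1 + l1, s2 - 1 + l2) - max(s1 - 1, s2 - 1))
      manual <- ov / l1 > 0.1 && ov / l2 > 0.1
      expect_identical(indel_identical(a, b), manual)
    }
  }
})

test_that("consensus intersection is idempotent, shrinks to empty on disjoint sets", {
  withr::with_seed(31, {
    a <- random_callset(60)
    self <- intersect_callsets(a, a)
    expect_setequal(variant_key(self$chrom, self$pos, self$ref, self$alt),
                    variant_key(a$chrom, a$pos, a$ref, a$alt))
    b <- random_callset(40, chroms = "chr9")
    expect_equal(nrow(intersect_callsets(a, b)), 0L)
  })
})

test_that("consensus retains exactly the caller-shared variants by construction", {
  withr::with_seed(32, {
    shared <- random_callset(100)
    a_only <- random_callset(40, chroms = "chr5")[1:20, ]
    b_only <- random_callset(40, chroms = "chr6")[1:15, ]
    a <- dplyr::bind_rows(shared, a_only)
    b <- dplyr::bind_rows(shared, b_only)
    b$caller_tag <- "callerB"
    cons <- intersect_callsets(a, b)
    expect_equal(nrow(cons), nrow(shared))
    # monotonicity: adding variants to b never shrinks the consensus
    b_more <- dplyr::bind_rows(b, random_callset(30, chroms = "chr7"))
    expect_gte(nrow(intersect_callsets(a, b_more)), nrow(cons))
    # SNV content symmetry
    ka <- with(subset(cons, vclass == "snv"), variant_key(chrom, pos, ref, alt))
    cons_ba <- intersect_callsets(b, a)
    kb <- with(subset(cons_ba, vclass == "snv"), variant_key(chrom, pos, ref, alt))
    expect_setequal(ka, kb)
  })
})

test_that("consensus agrees with the brute-force all-pairs oracle", {
  withr::with_seed(33, {
    for (rep in 1:8) {
      a <- random_callset(sample(20:80, 1))
      b <- random_callset(sample(20:80, 1))
      # overlap some of a into b so matches exist
      b <- dplyr::bind_rows(b, a[sample(nrow(a), nrow(a) %/% 2), ])
      b <- b[!duplicated(variant_key(b$chrom, b$pos, b$ref, b$alt)), ]
      got <- intersect_callsets(a, b)
      expect_identical(
        sort(variant_key(got$chrom, got$pos, got$ref, got$alt)),
        oracle_consensus_keys(a, b)
      )
    }
  })
})

test_that("consensus refuses mismatched samples", {
  a <- mk_callset(mk_variant(), sample_id = "s1")
  b <- mk_callset(mk_variant(), sample_id = "s2")
  expect_error(intersect_callsets(a, b), class = "cosegscan_input_error")
})
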