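test_that("case carrier counting follows the collapsing allele rules", {
  # hand-enumerated toy cohort: s1 het at one site (dominant only);
  # s2 hom_alt at one site (dominant + recessive);
  # s3 het at two sites in the gene (putative compound het: both models)
  v <- dplyr::bind_rows(
    mk_callset(mk_variant(pos = 10L, gene = "G1"), sample_id = "s1"),
    mk_callset(mk_variant(pos = 20L, gene = "G1"), sample_id = "s2", genotype = "hom_alt"),
    mk_callset(mk_variant(pos = 10L, gene = "G1"), sample_id = "s3"),
    mk_callset(mk_variant(pos = 30L, gene = "G1"), sample_id = "s3")
  )
  out <- case_carrier_counts(v)
  expect_equal(out$n_case_carriers_dom, 3L)
  expect_equal(out$n_case_carriers_rec, 2L)
  expect_equal(out$variant_count, 4L)
  # input order never matters
  out2 <- case_carrier_counts(v[rev(seq_len(nrow(v))), ])
  expect_equal(out, out2)
})

test_that("expected control carriers follow the collapsed closed forms", {
  ctl <- tibble::tibble(gene = "G1", control_ac = 1L, control_an = 1000L)
  out <- control_carrier_counts(ctl, n_controls = 500L)
  expect_equal(out$n_control_carriers_dom, 1L)  # 500 * (1 - 0.999) = 0.5 -> 1

  ctl2 <- tibble::tibble(gene = c("G2", "G2"), control_ac = c(1L, 1L),
                         control_an = c(2L, 2L))
  out2 <- control_carrier_counts(ctl2, n_controls = 4L)
  expect_equal(out2$n_control_carriers_dom, 3L)  # 4 * (1 - 0.25) = 3
  expect_equal(out2$n_control_carriers_rec, 4L)  # 4 * (0.5+0.5)^2 capped at 4

  expect_message(
    out3 <- control_carrier_counts(
      tibble::tibble(gene = "G3", control_ac = 0L, control_an = 0L), 100L),
    "AN = 0")
  expect_equal(nrow(out3), 0L)
})

test_that("expected dominant control carriers match a Monte-Carlo genotype draw", {
  withr::with_seed(61, {
    afs <- c(0.01, 0.003, 0.02)
    n_controls <- 2000L
    ctl <- tibble::tibble(gene = "G1", control_ac = as.integer(afs * 1e4),
                          control_an = 10000L)
    expected <- control_carrier_counts(ctl, n_controls)$n_control_carriers_dom
    # simulate: each control draws one allele per site at frequency af
    sims <- replicate(200, {
      carrier <- rep(FALSE, n_controls)
      for (af in afs) carrier <- carrier | (runif(n_controls) < af)
      sum(carrier)
    })
    expect_lt(abs(mean(sims) - expected), 3 * stats::sd(sims) / sqrt(200) + 1)
  })
})

test_that("two-sided exact test reproduces hand-enumerated tables", {
  expect_equal(fisher_two_sided(1, 1, 1, 1), 1.0)
  expect_equal(fisher_two_sided(2, 0, 0, 2), 1 / 3)
  expect_equal(fisher_two_sided(0, 5, 0, 5), 1.0)
  expect_equal(fisher_two_sided(0, 0, 0, 0), 1.0)
  expect_error(fisher_two_sided(-1, 1, 1, 1), class = "cosegscan_input_error")
})

test_that("two-sided exact test agrees with stats::fisher.test", {
  withr::with_seed(62, {
    tabs <- matrix(sample(0:40, 4 * 150, replace = TRUE), ncol = 4)
    got <- fisher_two_sided(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
    ref <- apply(tabs, 1, function(r) {
      stats::fisher.test(matrix(r, nrow = 2, byrow = TRUE))$p.value
    })
    expect_lt(max(abs(got - ref)), 1e-9)
  })
})

test_that("enrichment direction: more case carriers never raises the p-value", {
  n_cases <- 21L; n_controls <- 500L; ctl_car <- 5L
  expected_rate <- ctl_car / n_controls
  a_from <- ceiling(expected_rate * n_cases)
  p <- fisher_two_sided(a_from:n_cases, n_cases - (a_from:n_cases),
                        ctl_car, n_controls - ctl_car)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("burden table ranks a planted high-excess gene first", {
  withr::with_seed(63, {
    samples <- sprintf("s%02d", 1:21)
    planted <- dplyr::bind_rows(lapply(samples, function(s) {
      mk_callset(mk_variant(pos = 100L, gene = "EXCESS"), sample_id = s)
    }))
    null_gene <- dplyr::bind_rows(lapply(samples[1:2], function(s) {
      mk_callset(mk_variant(pos = 900L, gene = "NULLG"), sample_id = s)
    }))
    cases <- dplyr::bind_rows(planted, null_gene)
    controls <- tibble::tibble(
      chrom = "chr1", pos = c(100L, 900L), ref = "A", alt = "G",
      gene = c("EXCESS", "NULLG"),
      control_ac = c(1L, 1000L), control_an = 10000L,
      depth_pass_fraction = c(0.95, 0.95)
    )
    bt <- burden_table(cases, n_cases = 21L, controls, n_controls = 5000L)
    expect_equal(bt$gene[1], "EXCESS")
    expect_lt(bt$p_dom[1], 1e-10)
    # ~10% control carrier frequency vs 2/21 cases: consistent with the null
    expect_gt(bt$p_dom[bt$gene == "NULLG"], 0.05)
    expect_s3_class(bt, "coseg_burden")
    expect_equal(glance(bt)$n_genes, 2L)
  })
})

test_that("control sites failing depth QC are excluded from the burden test", {
  expect_equal(site_qc(tibble::tibble(depth_pass_fraction = c(0.95, 0.9, 0.5))),
               c(TRUE, TRUE, FALSE))
  cases <- mk_callset(mk_variant(pos = 1L, gene = "G1"))
  controls <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                             gene = "G1", control_ac = 4000L, control_an = 10000L,
                             depth_pass_fraction = 0.5)
  bt <- burden_table(cases, 21L, controls, 5000L)
  expect_equal(bt$n_control_carriers_dom, 0L)  # the only site failed QC
})

test_that("empty cohort gives an empty burden table", {
  bt <- burden_table(mk_callset(mk_variant())[0, ], 21L,
                     tibble::tibble(gene = character(), control_ac = integer(),
                                    control_an = integer(),
                                    depth_pass_fraction = numeric()), 5000L)
  expect_equal(nrow(bt), 0L)
})
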