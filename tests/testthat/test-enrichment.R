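mk_terms <- function(...) {
  sets <- list(...)
  tibble::tibble(
    term_id = names(sets),
    term_name = names(sets),
    source_tag = sub(":.*$", "", names(sets)),
    genes = unname(sets)
  )
}

test_that("GMT files round-trip and tag their source databases", {
  terms <- mk_terms(`GO_MF:T1` = c("A", "B", "C"), `REAC:T2` = c("B", "D"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(terms, path)
  back <- read_gmt(path)
  expect_equal(as.data.frame(back), as.data.frame(terms))
  writeLines("ID\tname_only", path)
  expect_error(read_gmt(path), class = "cosegscan_format_error")
})

test_that("hypergeometric enrichment matches exhaustive enumeration on small universes", {
  withr::with_seed(71, {
    for (rep in 1:25) {
      N <- sample(5:50, 1)
      universe <- sprintf("g%02d", seq_len(N))
      term_genes <- sample(universe, sample(1:N, 1))
      query <- sample(universe, sample(1:N, 1))
      terms <- mk_terms(`KEGG:T` = term_genes)
      rows <- hypergeometric_enrichment(query, terms, universe)
      k <- length(intersect(query, term_genes))
      expect_equal(rows$overlap_size, k)
      expect_equal(rows$p_raw,
                   oracle_hyper_tail(N, length(term_genes), length(query), k),
                   tolerance = 1e-12)
    }
  })
})

test_that("enrichment handles the degenerate configurations", {
  universe <- sprintf("g%03d", 1:100)
  # disjoint query and term
  rows <- hypergeometric_enrichment(universe[1:5],
                                    mk_terms(`REAC:T` = universe[50:60]), universe)
  expect_equal(rows$p_raw, 1)
  # term covering the whole universe: overlap is forced
  rows2 <- hypergeometric_enrichment(universe[1:5],
                                     mk_terms(`REAC:ALL` = universe), universe)
  expect_equal(rows2$p_raw, 1)
  # full containment of a sizeable query is astronomically unlikely by chance
  big_universe <- sprintf("g%05d", 1:20000)
  rows3 <- hypergeometric_enrichment(big_universe[1:10],
                                     mk_terms(`GO_MF:HIT` = big_universe[1:10]),
                                     big_universe)
  expect_lt(rows3$p_raw, 1e-30)
  expect_error(hypergeometric_enrichment("A", mk_terms(`REAC:T` = "B"), character()),
               class = "cosegscan_input_error")
  expect_message(
    hypergeometric_enrichment(c("A", "ZZZ"), mk_terms(`REAC:T` = c("A", "B")),
                              c("A", "B")),
    "not in the universe")
})

test_that("p-value adjustment reproduces hand-computed BH and Bonferroni values", {
  rows <- tibble::tibble(term_id = c("a", "b", "c"), term_name = c("a", "b", "c"),
                         source_tag = "REAC", overlap_size = 1L,
                         p_raw = c(0.01, 0.04, 0.9))
  bh <- adjust_pvalues(rows, "bh")
  expect_equal(bh$p_adj, c(0.03, 0.06, 0.9))
  bf <- adjust_pvalues(rows, "bonferroni")
  expect_equal(bf$p_adj, c(0.03, 0.12, 1))
  one <- adjust_pvalues(rows[1, ], "bonferroni")
  expect_equal(one$p_adj, 0.01)
  # adjusted p-values never fall below raw, and are rank-monotone
  withr::with_seed(72, {
    rnd <- tibble::tibble(term_id = sprintf("t%d", 1:30),
                          term_name = "t", source_tag = "GO_MF",
                          p_raw = runif(30))
    for (m in c("bh", "bonferroni")) {
      adj <- adjust_pvalues(rnd, m)
      expect_true(all(adj$p_adj >= adj$p_raw - 1e-12))
      ord <- order(adj$p_raw)
      expect_true(all(diff(adj$p_adj[ord]) >= -1e-12))
    }
  })
})

test_that("adjustment is applied within each source database separately", {
  rows <- tibble::tibble(term_id = c("a", "b"), term_name = c("a", "b"),
                         source_tag = c("REAC", "GO_MF"), p_raw = c(0.02, 0.02))
  bf <- adjust_pvalues(rows, "bonferroni")
  expect_equal(bf$p_adj, c(0.02, 0.02))  # each source has m = 1
})

test_that("common significant terms are intersected with per-analysis gene counts", {
  rows_a <- tibble::tibble(term_id = c("t1", "t2", "t3"), term_name = c("t1", "t2", "t3"),
                           source_tag = "REAC", overlap_size = c(3L, 2L, 5L),
                           p_raw = c(0.001, 0.5, 0.005))
  # identical analyses share all significant terms with equal counts
  self <- common_terms(rows_a, rows_a)
  expect_equal(self$term_id, c("t1", "t3"))
  expect_equal(self$count_a, self$count_b)
  # disjoint significant sets share nothing
  rows_b <- rows_a
  rows_b$p_raw <- c(0.5, 0.001, 0.8)
  expect_equal(nrow(common_terms(rows_a, rows_b)), 0L)
  # constructed pair with exactly six shared significant terms
  mk_rows <- function(ids, ps, ks) {
    tibble::tibble(term_id = ids, term_name = ids, source_tag = "GO_MF",
                   overlap_size = ks, p_raw = ps)
  }
  shared_ids <- sprintf("s%d", 1:6)
  ra <- mk_rows(c(shared_ids, "xa"), c(rep(0.001, 6), 0.002), c(1:6, 9L))
  rb <- mk_rows(c(shared_ids, "xb"), c(rep(0.003, 6), 0.004), c(11:16, 9L))
  both <- common_terms(ra, rb)
  expect_equal(both$term_id, shared_ids)
  expect_equal(both$count_a, 1:6)
  expect_equal(both$count_b, 11:16)
})

test_that("one-sided proportion test follows the continuity-corrected z formula", {
  expect_gte(proportion_increase_test(5, 50, 5, 50), 0.5)
  expect_lt(proportion_increase_test(1, 100, 30, 100), 1e-6)
  expect_equal(proportion_increase_test(0, 10, 0, 10), 1.0)
  expect_equal(proportion_increase_test(10, 10, 10, 10), 1.0)
  expect_error(proportion_increase_test(5, 0, 1, 10),
               class = "cosegscan_input_error")
  # agreement with the standard one-sided two-sample proportion test
  withr::with_seed(73, {
    for (i in 1:20) {
      n_a <- sample(20:200, 1); n_b <- sample(20:200, 1)
      k_a <- rbinom(1, n_a, 0.2); k_b <- rbinom(1, n_b, 0.4)
      if (k_a + k_b == 0 || k_a + k_b == n_a + n_b) next
      ref <- suppressWarnings(
        stats::prop.test(c(k_b, k_a), c(n_b, n_a), alternative = "greater",
                         correct = TRUE)$p.value
      )
      got <- proportion_increase_test(k_a, n_a, k_b, n_b)
      # prop.test caps the continuity correction at |p_b - p_a|; away from
      # that edge the two formulations coincide
      if (abs(k_b / n_b - k_a / n_a) > 0.5 * (1 / n_a + 1 / n_b)) {
        expect_equal(got, ref, tolerance = 1e-10)
      }
    }
  })
  # antisymmetry of direction
  p_fwd <- proportion_increase_test(2, 100, 30, 100)
  p_rev <- proportion_increase_test(30, 100, 2, 100)
  expect_lt(p_fwd, 0.05)
  expect_gt(p_rev, 0.95)
})
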