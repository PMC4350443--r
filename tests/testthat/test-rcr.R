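test_that("state-change thresholds are inclusive for FC/expression, strict for FDR", {
  rows <- tibble::tibble(
    gene_ns = "EGID", gene_id = as.character(1:6),
    fold_change = c(1.3, 5.0, -1.3, 1.29, 2.0, 2.0),
    fdr_p = c(0.049, 0.04, 0.01, 0.01, 0.05, 0.01),
    mean_expression = c(100, 99, 100, 500, 500, 500))
  sc <- select_state_changes(rows)
  # row 1: all three exactly at the passing boundary
  expect_true("EGID:1" %in% sc$gene)
  expect_equal(sc$direction[sc$gene == "EGID:1"], "up")
  # row 2 fails expr_min, row 4 fails fc_min, row 5 fails fdr (0.05 not < 0.05)
  expect_false(any(c("EGID:2", "EGID:4", "EGID:5") %in% sc$gene))
  expect_equal(sc$direction[sc$gene == "EGID:3"], "down")
  expect_equal(sc$gene, c("EGID:1", "EGID:3", "EGID:6"))  # input order
})

test_that("state-change selection rejects malformed tables and log2 input converts", {
  rows <- tibble::tibble(gene_ns = "EGID", gene_id = c("1", "1"),
                         fold_change = c(2, 2), fdr_p = c(0.01, 0.01),
                         mean_expression = c(200, 200))
  expect_error(select_state_changes(rows), "duplicate gene")
  rows2 <- tibble::tibble(gene_ns = "EGID", gene_id = "1", fold_change = NA,
                          fdr_p = 0.01, mean_expression = 200)
  expect_error(select_state_changes(rows2), "non-finite")

  # log2 fold change 0.5 = linear 1.41 passes; 0.3 = 1.23 fails
  rows3 <- tibble::tibble(gene_ns = "EGID", gene_id = c("1", "2"),
                          fold_change = c(-0.5, 0.3), fdr_p = 0.01,
                          mean_expression = 200)
  sc <- select_state_changes(rows3, sc_thresholds(log2_fc = TRUE))
  expect_equal(sc$gene, "EGID:1")
  expect_equal(sc$direction, "down")
})

test_that("selection agrees with independent row-by-row predicate evaluation", {
  set.seed(99)
  n <- 1000
  rows <- tibble::tibble(
    gene_ns = "EGID", gene_id = as.character(seq_len(n)),
    fold_change = round(stats::runif(n, -4, 4), 3),
    fdr_p = round(stats::runif(n), 4),
    mean_expression = round(stats::runif(n, 0, 1000), 1))
  rows <- rows[rows$fold_change != 0, ]
  sc <- select_state_changes(rows)
  expected <- character(0)
  for (i in seq_len(nrow(rows))) {
    if (rows$fdr_p[i] < 0.05 && abs(rows$fold_change[i]) >= 1.3 &&
        rows$mean_expression[i] >= 100) {
      expected <- c(expected, paste0("EGID:", rows$gene_id[i]))
    }
  }
  expect_identical(sc$gene, expected)
  # pure filter: output is a subset of input genes; idempotent re-selection
  expect_true(all(sc$gene %in% paste0(rows$gene_ns, ":", rows$gene_id)))
})

test_that("richness tail matches closed forms and literal draw enumeration", {
  expect_equal(richness_p(0, 6, 5, 20), 1.0)
  expect_equal(richness_p(5, 5, 5, 5), 1.0)
  # [C(5,4)C(15,2) + C(5,5)C(15,1)] / C(20,6)
  expect_equal(richness_p(4, 6, 5, 20),
               (choose(5, 4) * choose(15, 2) + choose(5, 5) * choose(15, 1)) /
                 choose(20, 6))
  # literal enumeration of all C(20,6) draws
  expect_equal(richness_p(4, 6, 5, 20), oracle_hyper_enum(4, 6, 5, 20),
               tolerance = 1e-12)
  for (case in list(c(2, 4, 3, 10), c(1, 5, 5, 12), c(3, 3, 6, 9))) {
    expect_equal(richness_p(case[1], case[2], case[3], case[4]),
                 oracle_hyper_enum(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
  expect_error(richness_p(7, 6, 5, 20), "bounds")
})

test_that("richness tail is monotone non-increasing in k", {
  for (n in c(5, 10)) {
    for (m in c(4, 8)) {
      p <- richness_p(0:min(n, m), n, m, 20)
      expect_true(all(diff(p) <= 1e-15))
    }
  }
})

test_that("concordance tail matches direct summation and the complement identity", {
  expect_equal(concordance_p(4, 4), 0.0625)
  expect_equal(concordance_p(0, 3), 1.0)
  expect_equal(concordance_p(0, 0), 1.0)
  expect_equal(concordance_p(7, 10), sum(choose(10, 7:10)) / 2^10)
  for (k in 0:15) {
    for (c in 0:k) {
      expect_equal(concordance_p(c, k), oracle_binom_sum(c, k),
                   tolerance = 1e-12)
      if (c >= 1) {
        expect_equal(concordance_p(c, k) +
                       stats::pbinom(c - 1, k, 0.5), 1, tolerance = 1e-12)
      }
    }
  }
  expect_error(concordance_p(5, 4), "bounds")
})

test_that("evaluate_hyps recovers a planted mechanism and applies both cutoffs", {
  fx <- sim_rcr_fixture(fixture_config(seed = 101))
  scs <- select_state_changes(fx$expression)
  scores <- evaluate_hyps(fx$kb, scs, fx$expression)
  planted <- fx$truth$upstream[fx$truth$planted]
  expect_true(planted %in% scores$upstream)
  expect_true(all(scores$richness_p < 0.1))
  expect_true(all(scores$concordance_p < 0.1))
  # scores agree with the generator's independent combinatorial truth record
  truth_row <- fx$truth[fx$truth$upstream == planted, ]
  score_row <- scores[scores$upstream == planted, ]
  expect_equal(score_row$overlap_k, truth_row$overlap_k)
  expect_equal(score_row$richness_p, truth_row$richness_p, tolerance = 1e-10)
  expect_equal(score_row$concordance_p, truth_row$concordance_p,
               tolerance = 1e-10)
})

test_that("disjoint downstream sets and empty universes are handled", {
  kb <- tibble::tibble(upstream = "kin(p(EGID:9001))", gene_ns = "EGID",
                       gene_id = c("1", "2"), sign = "+")
  scs <- tibble::tibble(gene = c("EGID:5", "EGID:6"),
                        direction = c("up", "down"))
  out <- evaluate_hyps(kb, scs, paste0("EGID:", 1:10))
  expect_equal(nrow(out), 0L)
  expect_error(evaluate_hyps(kb, scs, character()), "empty gene universe")
})

test_that("tied scores order deterministically by upstream key", {
  kb <- tibble::tibble(
    upstream = rep(c("kin(p(EGID:902))", "kin(p(EGID:901))"), each = 4),
    gene_ns = "EGID", gene_id = as.character(c(1:4, 1:4)), sign = "+")
  scs <- tibble::tibble(gene = paste0("EGID:", 1:4), direction = "up")
  out <- evaluate_hyps(kb, scs, paste0("EGID:", 1:40))
  expect_equal(out$upstream, c("kin(p(EGID:901))", "kin(p(EGID:902))"))
})

test_that("contradictory knowledgebase entries are dropped with a warning", {
  kb <- tibble::tibble(upstream = "kin(p(EGID:900))", gene_ns = "EGID",
                       gene_id = c("1", "1", "2"), sign = c("+", "-", "+"))
  scs <- tibble::tibble(gene = "EGID:2", direction = "up")
  expect_warning(out <- evaluate_hyps(kb, scs, paste0("EGID:", 1:10),
                                      significant_only = FALSE),
                 "contradictory")
  expect_equal(out$overlap_k, 1L)  # gene 1 no longer counted
})

test_that("planted mechanisms recover and random mechanisms rarely pass", {
  recovered <- logical(0)
  false_pass <- integer(0)
  false_total <- integer(0)
  for (seed in 1:30) {
    fx <- sim_rcr_fixture(fixture_config(seed = seed))
    scs <- select_state_changes(fx$expression)
    scores <- evaluate_hyps(fx$kb, scs, fx$expression)
    planted <- fx$truth$upstream[fx$truth$planted]
    recovered <- c(recovered, planted %in% scores$upstream)
    false_hyps <- fx$truth$upstream[!fx$truth$planted]
    false_pass <- c(false_pass, sum(false_hyps %in% scores$upstream))
    false_total <- c(false_total, length(false_hyps))
  }
  expect_gte(mean(recovered), 0.95)
  expect_lte(sum(false_pass) / sum(false_total), 0.10)
})

test_that("propose_enhancements proposes only novel upstream mechanisms", {
  net <- bel_network("Macrophage Signaling")
  net <- add_edge(net, 'p(HGNC:CSF1) increases bp(GO:"macrophage activation")',
                  ev(), prov1())
  anchor <- 'bp(GO:"macrophage activation")'
  scores <- tibble::tibble(
    upstream = c("p(HGNC:IL3)", "p(HGNC:CSF1)"),
    overlap_k = c(10L, 10L), concordant_c = c(9L, 9L),
    discordant_d = c(1L, 1L), richness_p = c(0.001, 0.001),
    concordance_p = c(0.01, 0.01), net_direction = c("up", "down"))
  cand <- propose_enhancements(net, scores, anchor)
  expect_equal(nrow(cand), 1L)  # CSF1 already in the network
  expect_equal(cand$upstream, "p(HGNC:IL3)")
  expect_equal(cand$relation, "increases")
  expect_equal(cand$edge[[1]]$provenance$phase, "phase1_rcr")
  expect_equal(cand$edge[[1]]$evidences[[1]]$status, "open")

  expect_equal(nrow(propose_enhancements(net, scores[0, ], anchor)), 0L)
  expect_error(propose_enhancements(net, scores, "bp(GO:nowhere)"),
               "anchor node not present")
})

test_that("expression and knowledgebase TSV round trips preserve content", {
  fx <- sim_rcr_fixture(fixture_config(seed = 5, n_genes = 50L, n_hyps = 3L,
                                       targets_per_hyp = 5L,
                                       signal_hyps = list()))
  dir <- withr::local_tempdir()
  write_fixtures(dir, fixture_config(seed = 5, n_genes = 50L, n_hyps = 3L,
                                     targets_per_hyp = 5L,
                                     signal_hyps = list()))
  expr <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(nrow(expr), 50L)
  expect_equal(expr$gene_id, fx$expression$gene_id)
  kb <- read_kb_tsv(file.path(dir, "kb.tsv"))
  expect_equal(kb$upstream, fx$kb$upstream)
  expect_equal(kb$gene_id, fx$kb$gene_id)
})
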