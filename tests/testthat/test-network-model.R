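test_that("add_edge creates endpoints, deduplicates statements, accumulates evidence", {
  net <- bel_network("Macrophage Signaling")
  net <- add_edge(net, "p(HGNC:EGR2) increases act(p(HGNC:CBLB))",
                  ev(), prov1("phase2_crowd"))
  expect_equal(glance(net)$n_nodes, 2L)
  expect_equal(glance(net)$n_edges, 1L)

  # identical canonical statement: evidence appended, no new edge
  net2 <- add_edge(net, "p( HGNC:EGR2 )  increases  act(p(HGNC:CBLB))",
                   ev(), prov1("phase2_crowd"))
  expect_equal(glance(net2)$n_nodes, 2L)
  expect_equal(glance(net2)$n_edges, 1L)
  expect_equal(glance(net2)$n_evidence, 2L)

  expect_error(add_edge(net, "p(HGNC:A) increases p(HGNC:B)", list(),
                        prov1()), "at least one evidence")
  e <- ev()
  expect_error(add_edge(net2, "p(HGNC:EGR2) increases act(p(HGNC:CBLB))",
                        list(e, e), prov1()), "duplicate evidence id")
})

test_that("every mutation increments revision by one and appends one history row", {
  net <- bel_network("x")
  for (i in 1:10) {
    before <- net
    net <- add_edge(net, sprintf("p(EGID:%d) increases p(EGID:%d)", i, i + 100),
                    ev(), prov1())
    expect_equal(net$revision, before$revision + 1L)
    expect_equal(nrow(net$history), nrow(before$history) + 1L)
  }
  net <- mark_evidence(net, net$edges[[1]]$evidences[[1]]$id, "approved",
                       prov1("phase2_crowd"))
  expect_equal(net$revision, 11L)
  expect_equal(nrow(net$history), 11L)
})

test_that("evidence status moves only open -> approved/rejected and is retained", {
  net <- add_edge(bel_network("x"), "p(HGNC:A) increases p(HGNC:B)",
                  ev(), prov1())
  id <- net$edges[[1]]$evidences[[1]]$id
  net <- mark_evidence(net, id, "rejected", prov1("phase2_crowd"))
  expect_equal(net$edges[[1]]$evidences[[1]]$status, "rejected")
  # rejected evidence stays in the network (full revision history)
  expect_equal(glance(net)$n_evidence, 1L)
  expect_error(mark_evidence(net, id, "approved", prov1("phase2_crowd")),
               "already rejected")
  expect_error(mark_evidence(net, "nope", "approved", prov1()), "not found")
})

test_that("boundary filter applies exclusions in fixed order with reasons", {
  cfg <- boundary_config(
    excluded_diseases = c("lung cancer", "asthma", "acute exacerbation"),
    excluded_cell_systems = c("tumor-derived cell line",
                              "immortalized cell line", "neuronal cells"),
    excluded_exposures = c("titanium dioxide", "quartz", "asbestos",
                           "carbon black"))

  ok <- apply_boundary_filter(
    evidence("1", "x", context = c(species = "human",
                                   cell_type = "alveolar macrophage")), cfg)
  expect_equal(ok$decision, "accept")
  expect_true(is.na(ok$reason))

  r1 <- apply_boundary_filter(
    evidence("1", "x", context = c(cell_type = "tumor-derived cell line")), cfg)
  expect_equal(r1$decision, "reject")
  expect_equal(r1$reason, "excluded_cell_system")

  r2 <- apply_boundary_filter(
    evidence("1", "x", context = c(exposure = "titanium dioxide")), cfg)
  expect_equal(r2$reason, "excluded_exposure")

  # rodent evidence admitted only via homologization, with annotation
  m <- apply_boundary_filter(evidence("1", "x", context = c(species = "mouse")),
                             cfg)
  expect_equal(m$decision, "accept")
  expect_equal(m$annotation, "homologized")
  no_hom <- boundary_config(homologization = FALSE)
  m2 <- apply_boundary_filter(evidence("1", "x", context = c(species = "mouse")),
                              no_hom)
  expect_equal(m2$decision, "reject")
  expect_equal(m2$reason, "excluded_species")

  # first matched rule in fixed order: disease precedes cell system
  both <- apply_boundary_filter(
    evidence("1", "x", context = c(disease = "lung cancer",
                                   cell_type = "neuronal cells")), cfg)
  expect_equal(both$reason, "excluded_disease")

  # empty context is unconstrained
  expect_equal(apply_boundary_filter(evidence("1", "x"), cfg)$decision,
               "accept")
})

test_that("boundary filter is idempotent and partitions an evidence set", {
  cfg <- boundary_config(excluded_diseases = "asthma",
                         excluded_exposures = "quartz")
  set.seed(11)
  net <- bel_network("x")
  ctx_pool <- list(c(species = "human"), c(disease = "asthma"),
                   c(exposure = "quartz"), c(species = "rat"),
                   character())
  for (i in 1:20) {
    net <- add_edge(net, sprintf("p(EGID:%d) increases p(EGID:%d)", i, i + 50),
                    evidence(paste0("c", i), "q",
                             context = ctx_pool[[sample(5, 1)]]),
                    prov1())
  }
  one <- filter_network_evidence(net, cfg)
  two <- filter_network_evidence(net, cfg)
  expect_identical(one, two)
  expect_true(all(one$decision %in% c("accept", "reject")))
  expect_equal(sum(one$decision == "accept") + sum(one$decision == "reject"),
               nrow(one))
})

test_that("diff_versions counts additions by canonical identity", {
  base <- chain_network("Th1-Th2 Signaling", 1:5)
  expect_equal(unlist(glance(diff_versions(base, base))[1, 1:3],
                      use.names = FALSE), c(0L, 0L, 0L))

  pair <- sim_version_pair(tibble::tibble(network = "Th1-Th2 Signaling",
                                          nodes_add = 12L, edges_add = 28L),
                           phase = "phase3_jamboree")
  d <- diff_versions(pair$old, pair$new)
  expect_equal(glance(d)$nodes_added, 12L)
  expect_equal(glance(d)$edges_added, 28L)

  pair2 <- sim_version_pair(tibble::tibble(network = "Neutrophil Signaling",
                                           nodes_add = 116L, edges_add = 160L,
                                           evidences_add = 181L))
  d2 <- diff_versions(pair2$old, pair2$new)
  expect_equal(glance(d2)$nodes_added, 116L)
  expect_equal(glance(d2)$edges_added, 160L)
  expect_equal(glance(d2)$evidences_added, 181L)
})

test_that("diff additivity holds along an edit path without deletions", {
  v1 <- chain_network("net", 1:4)
  v2 <- add_edge(v1, "p(EGID:10) increases p(EGID:11)", ev(), prov1())
  v3 <- add_edge(add_edge(v2, "p(EGID:12) increases p(EGID:13)", ev(), prov1()),
                 "p(EGID:10) increases p(EGID:13)", ev(), prov1())
  d13 <- glance(diff_versions(v1, v3))
  d12 <- glance(diff_versions(v1, v2))
  d23 <- glance(diff_versions(v2, v3))
  for (col in c("nodes_added", "edges_added", "evidences_added")) {
    expect_equal(d13[[col]], d12[[col]] + d23[[col]])
  }
})

test_that("share_report reproduces integer percent bookkeeping", {
  # evidences 266/885 -> 30%, edges 208/451 -> 46%
  adds <- tibble::tibble(
    network = c("Neutrophil Signaling", "Macrophage Signaling",
                "Th1-Th2 Signaling", "Other A", "Other B"),
    nodes_add = c(50L, 40L, 30L, 20L, 11L),
    edges_add = c(90L, 70L, 48L, 150L, 93L),
    evidences_add = c(120L, 80L, 66L, 400L, 219L))
  stopifnot(sum(adds$evidences_add) == 885L, sum(adds$edges_add) == 451L)
  pair <- sim_version_pair(adds)
  d <- diff_versions(pair$old, pair$new)
  rep <- share_report(d, c("Neutrophil Signaling", "Macrophage Signaling",
                           "Th1-Th2 Signaling"))
  expect_equal(rep$focus_count[rep$measure == "evidences"], 266)
  expect_equal(rep$share_pct[rep$measure == "evidences"], 30)
  expect_equal(rep$focus_count[rep$measure == "edges"], 208)
  expect_equal(rep$share_pct[rep$measure == "edges"], 46)
  # focus = all networks -> 100%
  all_rep <- share_report(d, adds$network)
  expect_true(all(all_rep$share_pct == 100))
  # unique citation count across added evidences is reported
  expect_true(attr(rep, "unique_citations") > 0)
  expect_error(share_report(d, "missing net"), "not in diff")
})

test_that("zero totals give undefined shares, not zero", {
  net <- chain_network("a", 1:3)
  d <- diff_versions(net, net)
  rep <- share_report(d, "a")
  expect_true(all(is.na(rep$share_pct)))
})

test_that("provenance ledger: literature plus RCR edges total correctly", {
  net <- bel_network("copd")
  n_lit <- 41L
  n_rcr <- 7L
  for (i in seq_len(n_lit)) {
    net <- add_edge(net, sprintf("p(EGID:%d) increases p(EGID:%d)", i, i + 500),
                    ev(), prov1("phase1_literature"))
  }
  for (i in seq_len(n_rcr)) {
    net <- add_edge(net, sprintf("p(EGID:%d) decreases p(EGID:%d)", i, i + 900),
                    ev(), prov1("phase1_rcr"))
  }
  ps <- provenance_summary(net)
  expect_equal(ps$n_edges[ps$phase == "phase1_literature"], n_lit)
  expect_equal(ps$n_edges[ps$phase == "phase1_rcr"], n_rcr)
  expect_equal(sum(ps$n_edges), n_lit + n_rcr)
})
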