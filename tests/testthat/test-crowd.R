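test_that("four up-votes lock approval at the fourth vote", {
  led <- vote_ledger()
  st <- lock_state()
  for (i in 1:4) {
    res <- cast_vote(led, i, paste0("u", i), "e1", "up", st)
    led <- res$ledger; st <- res$state
  }
  expect_equal(st$status, "approved")
  expect_equal(st$locked_at_seq, 4L)
  expect_error(cast_vote(led, 5, "u5", "e1", "up", st), "locked",
               class = "belnet_locked_error")
})

test_that("neither threshold reached leaves the evidence open", {
  led <- vote_ledger(1:6, paste0("u", 1:6), "e1",
                     rep(c("up", "down"), 3))
  rep <- replay_ledger(led)
  expect_equal(rep$status, "open")
  expect_equal(rep$effective_up, 3L)
  expect_equal(rep$effective_down, 3L)
})

test_that("first threshold crossed wins: 3 up then 4 down rejects at seq 7", {
  led <- vote_ledger(1:7, paste0("u", 1:7), "e1",
                     c("up", "up", "up", "down", "down", "down", "down"))
  rep <- replay_ledger(led)
  expect_equal(rep$status, "rejected")
  expect_equal(rep$locked_at_seq, 7L)
})

test_that("a user's later vote supersedes the earlier one", {
  led <- vote_ledger(1:2, c("ana", "ana"), "e1", c("up", "down"))
  rep <- replay_ledger(led)
  expect_equal(rep$effective_up, 0L)
  expect_equal(rep$effective_down, 1L)
  # raw counts still report both cast votes
  expect_equal(rep$n_up + rep$n_down, 2L)
  expect_error(vote_ledger(c(1, 1), c("a", "b"), "e1", c("up", "up")),
               "duplicate vote seq")
})

test_that("replay agrees with the brute-force prefix-scan oracle", {
  set.seed(123)
  for (i in 1:300) {
    led <- random_ledger()
    got <- replay_ledger(led)
    want <- oracle_replay_one(led$user, led$direction, led$seq)
    expect_equal(got$status, want$status)
    expect_equal(got$locked_at_seq, want$locked_at_seq)
    expect_equal(got$effective_up, want$effective_up)
    expect_equal(got$effective_down, want$effective_down)
    expect_equal(got$n_refused, want$n_refused)
    # determinism: replaying twice yields identical state
    expect_identical(got, replay_ledger(led))
  }
})

test_that("lock summary counts raw votes and network shares", {
  res <- sim_vote_totals(18, 7, per_network = tibble::tibble(
    network = "Neutrophil Signaling", n_votes = 5L))
  sm <- lock_summary(res$ledger, res$evidence_networks)
  expect_equal(glance(sm)$total_votes, 25L)
  expect_equal(glance(sm)$up_votes, 18L)
  expect_equal(glance(sm)$down_votes, 7L)
  per <- tidy(sm)
  expect_equal(sum(per$total_votes), 25L)
  expect_equal(per$share_pct[per$network == "Neutrophil Signaling"],
               20)  # round(100 * 5/25)
  # empty ledger: all zeros
  sm0 <- lock_summary(vote_ledger())
  expect_equal(glance(sm0)$total_votes, 0L)
  expect_equal(glance(sm0)$approved, 0L)
})

test_that("lock summary is invariant to ledger row order", {
  res <- sim_vote_totals(30, 10)
  shuffled <- res$ledger[sample(nrow(res$ledger)), ]
  expect_equal(glance(lock_summary(res$ledger)),
               glance(lock_summary(shuffled)))
})

test_that("leaderboard points follow the scheme with deterministic ties", {
  log <- action_log(1:5, "ana",
                    c("new_evidence", "new_evidence", "new_evidence",
                      "vote", "vote"), paste0("t", 1:5))
  board <- leaderboard(log)
  expect_equal(board$points, 17)  # 3*5 + 2*1
  expect_equal(board$evidences_created, 3L)

  # linearity: doubling a user's log doubles their points
  log2 <- dplyr::bind_rows(log, dplyr::mutate(log, seq = seq + 5L))
  expect_equal(leaderboard(log2)$points, 34)

  # ties broken by evidences_created then user id
  log3 <- action_log(1:4, c("bob", "bob", "amy", "amy"),
                     c("new_evidence", "vote", "new_edge", "vote"),
                     paste0("t", 1:4))
  board3 <- leaderboard(log3)
  expect_equal(board3$user, c("bob", "amy"))
  expect_equal(nrow(leaderboard(action_log())), 0L)
  # custom scheme is recorded
  sch <- point_scheme(new_evidence = 10)
  expect_identical(attr(leaderboard(log, sch), "scheme"), sch)
  expect_error(point_scheme(new_evidence = 1, vote = 5), "new_evidence")
})

test_that("invitee filter: top 20 evidence creators among users with >= 20 votes", {
  set.seed(42)
  entries <- list()
  s <- 0L
  for (u in 1:30) {
    n_votes <- if (u <= 25) 20L + u else 5L
    n_ev <- sample(1:50, 1L)
    user <- sprintf("u%02d", u)
    entries[[u]] <- tibble::tibble(
      seq = s + seq_len(n_votes + n_ev), user = user,
      action = c(rep("vote", n_votes), rep("new_evidence", n_ev)),
      target = paste0("t", s + seq_len(n_votes + n_ev)))
    s <- s + n_votes + n_ev
  }
  log <- dplyr::bind_rows(entries)
  inv <- jamboree_invitees(log)
  expect_equal(nrow(inv), 20L)
  expect_true(all(inv$votes_cast >= 20L))
  expect_true(all(diff(inv$evidences_created) <= 0))
})

test_that("crowd edits delegate to the network model with provenance and logging", {
  net <- add_edge(bel_network("x"), "p(HGNC:A) increases p(HGNC:B)",
                  ev(), prov1())
  res <- apply_edit(net, "new_evidence",
                    statement = "p(HGNC:A) increases p(HGNC:B)",
                    evidences = ev(), actor = "ana")
  expect_equal(glance(res$network)$n_edges, 1L)
  expect_equal(glance(res$network)$n_evidence, 2L)
  expect_equal(res$log$action, "new_evidence")
  expect_equal(res$log$user, "ana")

  res2 <- apply_edit(res$network, "new_edge",
                     statement = "p(HGNC:C) increases p(HGNC:D)",
                     evidences = ev(), actor = "bob", log = res$log)
  expect_equal(glance(res2$network)$n_nodes, 4L)
  expect_equal(glance(res2$network)$n_edges, 2L)
  expect_equal(res2$network$edges[[2]]$provenance$phase, "phase2_crowd")
  expect_equal(res2$network$edges[[2]]$provenance$actor, "bob")

  # duplicate new_edge becomes new_evidence in the log
  res3 <- apply_edit(res2$network, "new_edge",
                     statement = "p(HGNC:A) increases p(HGNC:B)",
                     evidences = ev(), actor = "cyd", log = res2$log)
  expect_equal(glance(res3$network)$n_edges, 2L)
  expect_equal(dplyr::last(res3$log$action), "new_evidence")

  res4 <- apply_edit(res3$network, "new_node", term = "p(HGNC:PF4)",
                     actor = "dee", log = res3$log)
  expect_equal(glance(res4$network)$n_nodes, 5L)
  expect_equal(dplyr::last(res4$log$action), "new_node")
})

test_that("vote ledger CSV round trips", {
  res <- sim_vote_totals(10, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_vote_ledger(res$ledger, path)
  back <- read_vote_ledger(path)
  expect_equal(back, res$ledger)
})
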