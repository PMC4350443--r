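# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: tails are computed by explicit combinatorial
# summation or literal enumeration of draws, and vote locking is replayed
# by recomputing tallies from scratch at every prefix.

# Hypergeometric upper tail by explicit summation with choose().
oracle_hyper_sum <- function(k, n, m, N) {
  if (k <= 0) return(1)
  hi <- min(n, m)
  if (k > hi) return(0)
  j <- k:hi
  sum(choose(m, j) * choose(N - m, n - j)) / choose(N, n)
}

# Hypergeometric upper tail by literal enumeration of all C(N, n) draws.
oracle_hyper_enum <- function(k, n, m, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= m)  # the first m elements are the "marked" set
  mean(hits >= k)
}

# Binomial(k, 1/2) upper tail by direct summation.
oracle_binom_sum <- function(c, k) {
  if (k == 0 || c <= 0) return(1)
  sum(choose(k, c:k)) / 2^k
}

# Brute-force lock replay: at each prefix, recompute effective tallies
# from scratch (last vote per user wins) and lock at the first prefix
# where a tally reaches the threshold. Returns the same fields as
# replay_ledger() for one evidence.
oracle_replay_one <- function(users, dirs, seqs, threshold = 4L) {
  status <- "open"; locked_at <- NA_integer_
  n_counted <- 0L
  for (i in seq_along(dirs)) {
    if (status != "open") break
    n_counted <- i
    eff_dirs <- tapply(dirs[1:i], users[1:i],
                       function(d) d[length(d)])
    up <- sum(eff_dirs == "up"); down <- sum(eff_dirs == "down")
    if (up >= threshold) { status <- "approved"; locked_at <- seqs[i] }
    else if (down >= threshold) { status <- "rejected"; locked_at <- seqs[i] }
  }
  counted <- seq_len(n_counted)
  eff_dirs <- if (n_counted)
    tapply(dirs[counted], users[counted], function(d) d[length(d)])
  else character(0)
  list(status = status, locked_at_seq = locked_at,
       effective_up = sum(eff_dirs == "up"),
       effective_down = sum(eff_dirs == "down"),
       n_up = sum(dirs[counted] == "up"),
       n_down = sum(dirs[counted] == "down"),
       n_refused = length(dirs) - n_counted)
}

# Random ledger generator for locking property tests: few users, repeats
# allowed so supersession is exercised.
random_ledger <- function(n_votes = NULL, n_users = NULL) {
  n_votes <- n_votes %||% sample(4:10, 1L)
  n_users <- n_users %||% sample(3:6, 1L)
  tibble::tibble(seq = seq_len(n_votes),
                 user = sample(paste0("u", seq_len(n_users)), n_votes,
                               replace = TRUE),
                 evidence_id = "e1",
                 direction = sample(c("up", "down"), n_votes, replace = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small evidence factory with unique ids.
ev <- local({
  counter <- 0L
  function(citation = NULL, quote = "synthetic", ...) {
    counter <<- counter + 1L
    evidence(citation %||% paste0("PMID", counter), quote,
             id = paste0("ev", counter), ...)
  }
})

prov1 <- function(phase = "phase1_literature") provenance(phase, "test")

# Quick n-node chain network builder.
chain_network <- function(name, genes, phase = "phase0_nondiseased") {
  net <- bel_network(name)
  for (i in seq_along(genes)[-1]) {
    net <- add_edge(net,
                    sprintf("p(EGID:%s) increases p(EGID:%s)",
                            genes[i - 1], genes[i]),
                    ev(), prov1(phase))
  }
  net
}

# Graph signature for isomorphism-with-equal-labels comparison.
graph_signature <- function(net) {
  edges <- tidy(net)
  list(nodes = sort(names(net$nodes)),
       edges = sort(paste(edges$subject, edges$relation, edges$object)))
}
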