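# Deterministic synthetic-data generators. Every stage of the toolkit is
# testable without any external download: toy knowledgebases and
# expression tables with planted upstream-mechanism signals, vote ledgers
# realizing configured tallies, and network version pairs whose expected
# diffs are known by construction. Truth records are always computed by
# direct independent arithmetic (combinatorial sums), never by calling the
# scoring engine.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Independent tail oracles used only for truth records: explicit
# combinatorial summation via lchoose, no distribution functions.
direct_hyper_tail <- function(k, n, m, N) {
  if (k <= 0) return(1)
  j <- seq(k, min(n, m))
  sum(exp(lchoose(m, j) + lchoose(N - m, n - j) - lchoose(N, n)))
}

direct_binom_tail <- function(c, k) {
  if (k == 0 || c <= 0) return(1)
  j <- seq(c, k)
  sum(exp(lchoose(k, j) - k * log(2)))
}

#' Configuration for the RCR fixture generator
#'
#' Defaults emulate the study conditions of a disease transcriptomics
#' comparison on a mid-size array: a universe of 1000 measured genes, a
#' 20-hypothesis knowledgebase with 20 signed targets each, one planted
#' mechanism whose 18 concordantly-flipped targets sit among roughly 50
#' total state changes (background state-change rate 0.033). At that
#' signal strength the planted mechanism passes the 0.1/0.1 cutoffs with
#' wide margin.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @param n_genes Universe size (genes synthesized as EGID:1..n).
#' @param n_hyps Number of hypotheses in the knowledgebase.
#' @param targets_per_hyp Downstream targets per hypothesis.
#' @param signal_hyps List of `list(index =, n_concordant =)` planting a
#'   signal into the indexed hypothesis.
#' @param background_sc_rate Probability that any gene is a background
#'   state change (random direction).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_genes = 1000L, n_hyps = 20L,
                           targets_per_hyp = 20L,
                           signal_hyps = list(list(index = 1L,
                                                   n_concordant = 18L)),
                           background_sc_rate = 0.033) {
  stopifnot(n_genes >= 1L, n_hyps >= 1L, targets_per_hyp >= 1L,
            targets_per_hyp <= n_genes,
            background_sc_rate >= 0, background_sc_rate <= 1)
  for (s in signal_hyps) {
    if (s$index < 1L || s$index > n_hyps ||
        s$n_concordant > targets_per_hyp) {
      abort("infeasible signal configuration")
    }
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_hyps = as.integer(n_hyps),
                 targets_per_hyp = as.integer(targets_per_hyp),
                 signal_hyps = signal_hyps,
                 background_sc_rate = background_sc_rate),
            class = "fixture_config")
}

#' Generate a knowledgebase and expression table with planted signals
#'
#' Synthesizes `n_hyps` hypotheses with random signed EGID targets, plants
#' the configured concordant state changes for signal hypotheses, adds
#' background state changes at the configured rate, and builds an
#' expression table in which exactly the state-change genes pass the
#' selection thresholds (non-state-change rows each fail one predicate:
#' FDR, fold change, or minimum expression). The truth record lists each
#' hypothesis's overlap and tail p-values computed by direct combinatorial
#' summation.
#'
#' @param config A [fixture_config()].
#' @param thresholds The [sc_thresholds()] the table is built against.
#' @return A list: `kb` (tibble `upstream`, `gene_ns`, `gene_id`, `sign`),
#'   `expression` (tibble in expression-TSV layout), `state_changes`
#'   (tibble `gene`, `direction`), and `truth` (tibble `upstream`,
#'   `planted`, `overlap_k`, `concordant_c`, `richness_p`,
#'   `concordance_p`, `expect_significant`).
#' @export
sim_rcr_fixture <- function(config = fixture_config(),
                            thresholds = sc_thresholds()) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    genes <- paste0("EGID:", seq_len(config$n_genes))
    hyp_ids <- paste0("kin(p(EGID:", config$n_genes + seq_len(config$n_hyps),
                      "))")
    kb <- purrr::map_dfr(seq_len(config$n_hyps), function(i) {
      targets <- sample(genes, config$targets_per_hyp)
      tibble::tibble(upstream = hyp_ids[i], gene = targets,
                     sign = sample(c("+", "-"), config$targets_per_hyp,
                                   replace = TRUE))
    })
    # background state changes, random direction
    is_sc <- stats::runif(config$n_genes) < config$background_sc_rate
    direction <- ifelse(stats::runif(config$n_genes) < 0.5, "up", "down")
    # planted concordant flips override background
    planted_idx <- vapply(config$signal_hyps, function(s) s$index, integer(1))
    for (s in config$signal_hyps) {
      rows <- which(kb$upstream == hyp_ids[s$index])
      pick <- rows[seq_len(s$n_concordant)]
      gi <- match(kb$gene[pick], genes)
      is_sc[gi] <- TRUE
      direction[gi] <- ifelse(kb$sign[pick] == "+", "up", "down")
    }
    expression <- build_expression_table(genes, is_sc, direction, thresholds)
    scs <- tibble::tibble(gene = genes[is_sc], direction = direction[is_sc])
    sc_dir <- stats::setNames(scs$direction, scs$gene)
    truth <- kb |>
      dplyr::group_by(.data$upstream) |>
      dplyr::summarise(
        m = dplyr::n(),
        overlap_k = sum(.data$gene %in% names(sc_dir)),
        concordant_c = sum((.data$sign == "+" &
                              sc_dir[.data$gene] == "up") |
                             (.data$sign == "-" &
                                sc_dir[.data$gene] == "down"),
                           na.rm = TRUE),
        .groups = "drop") |>
      dplyr::mutate(
        planted = .data$upstream %in% hyp_ids[planted_idx],
        richness_p = purrr::map2_dbl(.data$overlap_k, .data$m,
                                     ~direct_hyper_tail(.x, nrow(scs), .y,
                                                        config$n_genes)),
        concordance_p = purrr::map2_dbl(.data$concordant_c, .data$overlap_k,
                                        ~direct_binom_tail(.x, .y)),
        expect_significant = .data$richness_p < 0.1 &
          .data$concordance_p < 0.1)
    parts <- strsplit(kb$gene, ":", fixed = TRUE)
    list(kb = tibble::tibble(upstream = kb$upstream,
                             gene_ns = vapply(parts, `[`, character(1), 1L),
                             gene_id = vapply(parts, `[`, character(1), 2L),
                             sign = kb$sign),
         expression = expression, state_changes = scs, truth = truth)
  })
}

build_expression_table <- function(genes, is_sc, direction, thresholds) {
  n <- length(genes)
  fdr <- stats::runif(n, 0, thresholds$fdr_max * 0.98)
  fc_mag <- stats::runif(n, thresholds$fc_min, thresholds$fc_min + 3)
  expr <- stats::runif(n, thresholds$expr_min, thresholds$expr_min + 900)
  sign <- ifelse(direction == "up", 1, -1)
  # each non-state-change row fails exactly one predicate, chosen at random
  fail_mode <- sample(c("fdr", "fc", "expr"), n, replace = TRUE)
  miss <- !is_sc
  f <- miss & fail_mode == "fdr"
  fdr[f] <- stats::runif(sum(f), thresholds$fdr_max, 1)
  f <- miss & fail_mode == "fc"
  fc_mag[f] <- stats::runif(sum(f), max(1, thresholds$fc_min - 0.29),
                            thresholds$fc_min - 0.01)
  f <- miss & fail_mode == "expr"
  expr[f] <- stats::runif(sum(f), 0, thresholds$expr_min - 0.5)
  parts <- strsplit(genes, ":", fixed = TRUE)
  tibble::tibble(gene_ns = vapply(parts, `[`, character(1), 1L),
                 gene_id = vapply(parts, `[`, character(1), 2L),
                 fold_change = round(sign * fc_mag, 4),
                 fdr_p = round(fdr, 6),
                 mean_expression = round(expr, 2))
}

#' Generate vote ledgers realizing configured tallies
#'
#' Each profile row gives an evidence id, its up/down counts and an
#' interleaving pattern (`up_first`, `down_first` or `alternate`). Every
#' vote comes from a distinct user, so supersession never triggers; the
#' expected lock state per evidence is computed by an independent
#' prefix-scan of the interleaved sequence (first tally to reach the
#' threshold locks; later votes would be refused and are reported in
#' `expect_refused`).
#'
#' @param profiles Tibble with columns `evidence_id`, `n_up`, `n_down`,
#'   `pattern`.
#' @param lock_threshold Locking threshold (default 4).
#' @param seed Seed controlling user-id synthesis.
#' @return A list: `ledger` (vote tibble) and `expected` (tibble
#'   `evidence_id`, `expect_status`, `expect_locked_at_seq`,
#'   `expect_refused`).
#' @export
sim_vote_ledger <- function(profiles, lock_threshold = 4L, seed = 1L) {
  stopifnot(all(c("evidence_id", "n_up", "n_down", "pattern") %in%
                  names(profiles)))
  with_seed(seed, {
    seq_counter <- 0L
    user_counter <- 0L
    rows <- list()
    expected <- list()
    for (i in seq_len(nrow(profiles))) {
      nu <- profiles$n_up[i]
      nd <- profiles$n_down[i]
      dirs <- switch(profiles$pattern[i],
                     up_first = c(rep("up", nu), rep("down", nd)),
                     down_first = c(rep("down", nd), rep("up", nu)),
                     alternate = interleave_votes(nu, nd),
                     abort(paste0("unknown pattern: ", profiles$pattern[i])))
      seqs <- seq_counter + seq_along(dirs)
      seq_counter <- seq_counter + length(dirs)
      users <- paste0("u", user_counter + seq_along(dirs))
      user_counter <- user_counter + length(dirs)
      rows[[i]] <- tibble::tibble(seq = seqs, user = users,
                                  evidence_id = profiles$evidence_id[i],
                                  direction = dirs)
      # independent prefix-scan oracle
      up <- 0L; down <- 0L; status <- "open"; lock_at <- NA_integer_
      refused <- 0L
      for (j in seq_along(dirs)) {
        if (status != "open") { refused <- refused + 1L; next }
        if (dirs[j] == "up") up <- up + 1L else down <- down + 1L
        if (up >= lock_threshold) { status <- "approved"; lock_at <- seqs[j] }
        else if (down >= lock_threshold) { status <- "rejected"; lock_at <- seqs[j] }
      }
      expected[[i]] <- tibble::tibble(evidence_id = profiles$evidence_id[i],
                                      expect_status = status,
                                      expect_locked_at_seq = lock_at,
                                      expect_refused = refused)
    }
    list(ledger = dplyr::bind_rows(rows),
         expected = dplyr::bind_rows(expected))
  })
}

interleave_votes <- function(nu, nd) {
  dirs <- character(nu + nd)
  u <- nu; d <- nd
  for (i in seq_along(dirs)) {
    if (u >= d && u > 0L) { dirs[i] <- "up"; u <- u - 1L }
    else if (d > 0L) { dirs[i] <- "down"; d <- d - 1L }
    else { dirs[i] <- "up"; u <- u - 1L }
  }
  dirs
}

#' Build an aggregate voting profile with known totals
#'
#' Convenience generator for summary fixtures: spreads a target number of
#' raw up and down votes over evidences (optionally assigned to networks
#' with fixed per-network vote counts) such that no evidence ever locks
#' before its last vote, so every configured vote is counted.
#'
#' @param n_up,n_down Total raw up/down votes to realize.
#' @param per_network Optional tibble `network`, `n_votes` assigning the
#'   first `sum(n_votes)` votes to networks; remaining evidence falls in
#'   `"(other)"`.
#' @param seed Seed.
#' @return A list: `ledger`, `expected`, and `evidence_networks` (mapping
#'   tibble, `NULL` when `per_network` is not given).
#' @export
sim_vote_totals <- function(n_up, n_down, per_network = NULL, seed = 1L) {
  # 3 up + 3 down per evidence never locks at threshold 4
  profiles <- list()
  eid <- 0L
  nets <- list()
  alloc <- function(target_up, target_down, network) {
    out <- list()
    while (target_up > 0L || target_down > 0L) {
      u <- min(3L, target_up); d <- min(3L, target_down)
      if (u == 0L && d == 0L) break
      eid <<- eid + 1L
      id <- paste0("ev", eid)
      out[[length(out) + 1L]] <-
        tibble::tibble(evidence_id = id, n_up = u, n_down = d,
                       pattern = "alternate")
      if (!is.null(network)) {
        nets[[length(nets) + 1L]] <<- tibble::tibble(evidence_id = id,
                                                     network = network)
      }
      target_up <- target_up - u; target_down <- target_down - d
    }
    dplyr::bind_rows(out)
  }
  if (!is.null(per_network)) {
    remaining_up <- n_up; remaining_down <- n_down
    for (i in seq_len(nrow(per_network))) {
      nv <- per_network$n_votes[i]
      # split this network's votes proportionally to the global up/down mix
      u <- min(remaining_up, round_half_up(nv * n_up / (n_up + n_down)))
      d <- nv - u
      if (d > remaining_down) { d <- remaining_down; u <- nv - d }
      profiles[[length(profiles) + 1L]] <-
        alloc(u, d, per_network$network[i])
      remaining_up <- remaining_up - u
      remaining_down <- remaining_down - d
    }
    profiles[[length(profiles) + 1L]] <-
      alloc(remaining_up, remaining_down, "(other)")
  } else {
    profiles[[length(profiles) + 1L]] <- alloc(n_up, n_down, NULL)
  }
  res <- sim_vote_ledger(dplyr::bind_rows(profiles), seed = seed)
  res$evidence_networks <- if (length(nets)) dplyr::bind_rows(nets) else NULL
  res
}

#' Generate a network version pair with a known diff
#'
#' Builds a small base version of each named network, then applies the
#' scripted number of node, edge and evidence additions; the expected
#' diff equals the script by construction. New edges connect new or
#' existing nodes without ever creating endpoints beyond the scripted
#' node additions, and extra evidences are appended to added edges.
#'
#' @param additions Tibble with columns `network`, `nodes_add`,
#'   `edges_add`, and optionally `evidences_add` (defaults to
#'   `edges_add`; must be `>= edges_add` since every new edge carries one
#'   evidence).
#' @param base_nodes,base_edges Size of each base version.
#' @param phase Provenance phase recorded on the additions.
#' @param seed Seed (controls nothing random at present; kept for
#'   interface stability).
#' @return A list: `old` and `new` (named lists of networks) and
#'   `expected` (the additions tibble normalized).
#' @export
sim_version_pair <- function(additions, base_nodes = 6L, base_edges = 4L,
                             phase = "phase2_crowd", seed = 1L) {
  stopifnot(all(c("network", "nodes_add", "edges_add") %in% names(additions)))
  if (!"evidences_add" %in% names(additions)) {
    additions$evidences_add <- additions$edges_add
  }
  if (any(additions$evidences_add < additions$edges_add)) {
    abort("evidences_add must be >= edges_add (each new edge carries one evidence)")
  }
  old <- list()
  new <- list()
  gene_base <- 0L
  for (i in seq_len(nrow(additions))) {
    nm <- additions$network[i]
    base <- base_network(nm, base_nodes, base_edges, gene_base)
    gene_base <- gene_base + base_nodes + additions$nodes_add[i] + 1L
    v_new <- grow_network(base$network, additions$nodes_add[i],
                          additions$edges_add[i],
                          additions$evidences_add[i],
                          base$gene_ids, phase)
    old[[nm]] <- base$network
    new[[nm]] <- v_new
  }
  list(old = old, new = new, expected = additions)
}

base_network <- function(name, n_nodes, n_edges, gene_base) {
  stopifnot(n_edges <= n_nodes * (n_nodes - 1))
  net <- bel_network(name, "synthetic base version")
  ids <- gene_base + seq_len(n_nodes)
  terms <- paste0("p(EGID:", ids, ")")
  prov <- provenance("phase0_nondiseased", actor = "fixture")
  made <- 0L
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      if (i == j || made >= n_edges) next
      made <- made + 1L
      net <- add_edge(net, paste(terms[i], "increases", terms[j]),
                      evidence(paste0("PMID", name, "-base-", made),
                               "base evidence"),
                      prov)
    }
  }
  # isolated base nodes not yet used as endpoints
  for (t in terms) {
    key <- canonical_key(parse_term(t))
    if (is.null(net$nodes[[key]])) {
      net$nodes[[key]] <- canonicalize_term(parse_term(t))
      net <- bump_revision(net, paste0("add node ", key), prov)
    }
  }
  list(network = net, gene_ids = ids)
}

grow_network <- function(net, nodes_add, edges_add, evidences_add,
                         base_gene_ids, phase) {
  prov <- provenance(phase, actor = "fixture")
  new_ids <- max(base_gene_ids) + seq_len(nodes_add)
  all_ids <- c(base_gene_ids, new_ids)
  term_of <- function(id) paste0("p(EGID:", id, ")")
  # create the new nodes first (as isolated nodes), so edge additions can
  # reuse them without minting endpoints beyond the scripted count
  for (id in new_ids) {
    key <- term_of(id)
    net$nodes[[key]] <- canonicalize_term(parse_term(key))
    net <- bump_revision(net, paste0("add node ", key), prov)
  }
  made <- 0L
  added_keys <- character()
  ev_counter <- 0L
  for (i in seq_along(all_ids)) {
    for (j in seq_along(all_ids)) {
      if (i == j || made >= edges_add) next
      skey <- paste(term_of(all_ids[i]), "increases", term_of(all_ids[j]))
      if (!is.null(net$edges[[skey]])) next
      ev_counter <- ev_counter + 1L
      net <- add_edge(net, skey,
                      evidence(paste0("PMID-", net$name, "-add-", ev_counter),
                               "added evidence"),
                      prov)
      added_keys <- c(added_keys, skey)
      made <- made + 1L
    }
  }
  if (made < edges_add) abort("infeasible edge addition script")
  extra <- evidences_add - edges_add
  k <- 0L
  while (k < extra) {
    skey <- added_keys[(k %% length(added_keys)) + 1L]
    ev_counter <- ev_counter + 1L
    net <- add_edge(net, skey,
                    evidence(paste0("PMID-", net$name, "-add-", ev_counter),
                             "supplementary evidence"),
                    prov)
    k <- k + 1L
  }
  net
}

#' Generate a random valid BEL term
#'
#' Random-term generator for property tests: draws a function prefix,
#' builds 1-3 arguments (entities, nested terms up to the given depth, or
#' plain qualifier tokens where legal), and occasionally uses quoted names
#' containing spaces or colons.
#'
#' @param depth Maximum remaining nesting depth.
#' @param functions,namespaces Registries to draw from.
#' @return A `bel_term`.
#' @export
random_term <- function(depth = 3L, functions = NULL, namespaces = NULL) {
  reg <- default_registries(functions, namespaces)
  fun <- sample(reg$functions$prefix, 1L)
  n_args <- if (fun %in% c("complex", "composite")) sample(2:3, 1L) else
    sample(1:2, 1L)
  args <- lapply(seq_len(n_args), function(i) {
    r <- stats::runif(1)
    if (depth > 1L && r < 0.3) {
      random_term(depth - 1L, reg$functions, reg$namespaces)
    } else if (fun %in% QUALIFIER_FUNCTIONS && r < 0.5) {
      paste0("Q", sample(99L, 1L))
    } else {
      ns <- sample(reg$namespaces$prefix, 1L)
      name <- if (stats::runif(1) < 0.15) {
        paste0("name with space:", sample(999L, 1L))
      } else {
        paste0("G", sample(9999L, 1L))
      }
      bel_entity(ns, name)
    }
  })
  bel_term(fun, args)
}

#' Generate a random small network
#'
#' Builds a network of random parseable protein/process nodes and random
#' causal edges; used by round-trip property tests.
#'
#' @param n_nodes,n_edges Size of the network.
#' @return A `bel_network`.
#' @export
random_network <- function(n_nodes = 6L, n_edges = 8L) {
  funs <- c("p", "r", "g", "a", "bp", "act")
  terms <- vapply(seq_len(n_nodes), function(i) {
    f <- sample(funs, 1L)
    inner <- paste0("EGID:", sample(99999L, 1L))
    if (f == "act") paste0("act(p(", inner, "))") else
      paste0(f, "(", inner, ")")
  }, character(1))
  terms <- unique(terms)
  net <- bel_network(paste0("random-", sample(1e6L, 1L)))
  prov <- provenance("phase0_nondiseased", actor = "fixture")
  made <- 0L
  guard <- 0L
  while (made < n_edges && guard < n_edges * 20L) {
    guard <- guard + 1L
    ij <- sample(length(terms), 2L)
    rel <- sample(CAUSAL_RELATIONS, 1L)
    skey <- paste(terms[ij[1]], rel, terms[ij[2]])
    if (!is.null(net$edges[[skey]])) next
    net <- add_edge(net, skey,
                    evidence(paste0("PMID", made), "synthetic"),
                    prov)
    made <- made + 1L
  }
  net
}

#' Write a full fixture set to a directory
#'
#' Emits the RCR knowledgebase/expression/truth files, a vote ledger with
#' expected lock states, and a manifest recording the seed and
#' configuration, for use from the command line.
#'
#' @param dir Output directory (created if needed).
#' @param config A [fixture_config()].
#' @return Invisibly, the manifest as a data frame.
#' @export
write_fixtures <- function(dir, config = fixture_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- sim_rcr_fixture(config)
  kb_path <- file.path(dir, "kb.tsv")
  kb_out <- tibble::tibble(upstream = fx$kb$upstream,
                           gene = paste0(fx$kb$gene_ns, ":", fx$kb$gene_id),
                           sign = fx$kb$sign)
  utils::write.table(kb_out, kb_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expr_path <- file.path(dir, "expression.tsv")
  utils::write.table(fx$expression, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(fx$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  votes <- sim_vote_ledger(tibble::tibble(
    evidence_id = paste0("ev", 1:6),
    n_up = c(4L, 3L, 0L, 3L, 5L, 2L),
    n_down = c(0L, 3L, 4L, 1L, 2L, 2L),
    pattern = c("up_first", "alternate", "down_first", "alternate",
                "alternate", "up_first")), seed = config$seed)
  ledger_path <- file.path(dir, "votes.csv")
  write_vote_ledger(votes$ledger, ledger_path)
  utils::write.table(votes$expected, file.path(dir, "votes_expected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(kb_path, expr_path, truth_path, ledger_path)
  manifest <- data.frame(
    file = basename(paths),
    md5 = vapply(paths, function(p) unname(tools::md5sum(p)), character(1)),
    row.names = NULL)
  manifest_path <- file.path(dir, "manifest.tsv")
  header <- sprintf("# seed=%d n_genes=%d n_hyps=%d targets_per_hyp=%d background_sc_rate=%g",
                    config$seed, config$n_genes, config$n_hyps,
                    config$targets_per_hyp, config$background_sc_rate)
  writeLines(header, manifest_path)
  suppressWarnings(utils::write.table(manifest, manifest_path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(manifest)
}
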