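#' Vote ledgers and the four-vote locking rule
#'
#' During the open crowd-verification phase every evidence accumulates a
#' chronological ledger of up/down votes. Each user holds at most one
#' effective vote per evidence — a later vote by the same user supersedes
#' the earlier one. Tallies are re-evaluated after every vote: the first
#' time the effective up-votes reach 4 the evidence is locked `approved`;
#' the first time the effective down-votes reach 4 it is locked
#' `rejected`. Once locked, further votes are refused.
#'
#' `vote_ledger()` builds/validates a ledger tibble, `cast_vote()` appends
#' one vote functionally, and `replay_ledger()` processes a complete
#' multi-evidence ledger chronologically.
#'
#' @param seq Strictly increasing integer ordinals, unique in a ledger.
#' @param user User ids.
#' @param evidence_id Evidence ids voted on.
#' @param direction `"up"` or `"down"`.
#' @return `vote_ledger()`: a validated tibble with those four columns.
#' @export
vote_ledger <- function(seq = integer(), user = character(),
                        evidence_id = character(), direction = character()) {
  led <- tibble::tibble(seq = as.integer(seq), user = as.character(user),
                        evidence_id = as.character(evidence_id),
                        direction = as.character(direction))
  validate_ledger(led)
  led
}

validate_ledger <- function(led) {
  stopifnot(all(c("seq", "user", "evidence_id", "direction") %in% names(led)))
  if (anyDuplicated(led$seq)) {
    abort(paste0("duplicate vote seq: ", led$seq[duplicated(led$seq)][1]))
  }
  if (nrow(led) && !all(led$direction %in% c("up", "down"))) {
    abort("vote direction must be 'up' or 'down'")
  }
  invisible(led)
}

#' @rdname vote_ledger
#' @param status,locked_at_seq Current lock status and (if locked) the seq
#'   of the locking vote.
#' @export
lock_state <- function(status = "open", locked_at_seq = NA_integer_) {
  status <- match.arg(status, EVIDENCE_STATUSES)
  structure(list(status = status, locked_at_seq = as.integer(locked_at_seq)),
            class = "lock_state")
}

#' @rdname vote_ledger
#' @param ledger An existing ledger tibble (votes for one evidence).
#' @param state The evidence's current [lock_state()].
#' @param lock_threshold Effective votes required to lock (default 4).
#' @return `cast_vote()`: a list with the appended `ledger` and the new
#'   `state`. Voting on locked evidence is an error that reports the
#'   status.
#' @export
cast_vote <- function(ledger, seq, user, evidence_id, direction,
                      state = lock_state(), lock_threshold = 4L) {
  validate_ledger(ledger)
  if (state$status != "open") {
    abort(sprintf("evidence '%s' is locked (%s); vote refused",
                  evidence_id, state$status),
          class = "belnet_locked_error")
  }
  if (seq %in% ledger$seq) abort(paste0("duplicate vote seq: ", seq))
  if (!direction %in% c("up", "down")) abort("direction must be 'up' or 'down'")
  ledger <- dplyr::bind_rows(ledger,
                             tibble::tibble(seq = as.integer(seq),
                                            user = as.character(user),
                                            evidence_id = as.character(evidence_id),
                                            direction = as.character(direction)))
  eff <- effective_tally(ledger[ledger$evidence_id == evidence_id, ])
  if (eff["up"] >= lock_threshold) {
    state <- lock_state("approved", seq)
  } else if (eff["down"] >= lock_threshold) {
    state <- lock_state("rejected", seq)
  }
  list(ledger = ledger, state = state)
}

# Effective tallies under supersession: each user's latest vote counts.
effective_tally <- function(votes) {
  if (!nrow(votes)) return(c(up = 0L, down = 0L))
  latest <- votes |>
    dplyr::arrange(.data$seq) |>
    dplyr::group_by(.data$user) |>
    dplyr::slice_tail(n = 1L) |>
    dplyr::ungroup()
  c(up = sum(latest$direction == "up"),
    down = sum(latest$direction == "down"))
}

#' @rdname vote_ledger
#' @param votes A ledger tibble covering any number of evidences.
#' @return `replay_ledger()`: one row per evidence with `status`,
#'   `locked_at_seq`, effective tallies, raw counted votes (`n_up`,
#'   `n_down`) and `n_refused` (votes arriving after a lock, which are
#'   refused and excluded from all tallies).
#' @export
replay_ledger <- function(votes, lock_threshold = 4L) {
  validate_ledger(votes)
  if (!nrow(votes)) {
    return(tibble::tibble(evidence_id = character(), status = character(),
                          locked_at_seq = integer(),
                          effective_up = integer(),
                          effective_down = integer(), n_up = integer(),
                          n_down = integer(), n_refused = integer()))
  }
  votes <- votes[order(votes$seq), , drop = FALSE]
  eids <- unique(votes$evidence_id)
  idx <- split(seq_len(nrow(votes)), factor(votes$evidence_id, levels = eids))
  out <- vector("list", length(eids))
  for (e in seq_along(eids)) {
    rows <- idx[[e]]
    users <- votes$user[rows]
    dirs <- votes$direction[rows]
    seqs <- votes$seq[rows]
    # incremental effective tallies under supersession
    user_dir <- character(0)
    up <- 0L; down <- 0L
    n_up <- 0L; n_down <- 0L; refused <- 0L
    status <- "open"; locked_at <- NA_integer_
    for (i in seq_along(rows)) {
      if (status != "open") { refused <- refused + 1L; next }
      u <- users[i]; d <- dirs[i]
      if (d == "up") n_up <- n_up + 1L else n_down <- n_down + 1L
      prev <- user_dir[u]
      if (!is.na(prev)) {
        if (prev == "up") up <- up - 1L else down <- down - 1L
      }
      if (d == "up") up <- up + 1L else down <- down + 1L
      user_dir[u] <- d
      if (up >= lock_threshold) {
        status <- "approved"; locked_at <- seqs[i]
      } else if (down >= lock_threshold) {
        status <- "rejected"; locked_at <- seqs[i]
      }
    }
    out[[e]] <- tibble::tibble(evidence_id = eids[e], status = status,
                               locked_at_seq = locked_at,
                               effective_up = up, effective_down = down,
                               n_up = n_up, n_down = n_down,
                               n_refused = refused)
  }
  dplyr::bind_rows(out)
}

#' Summarize voting activity
#'
#' Totals count raw cast votes (not effective votes after supersession),
#' matching how aggregate voting activity is reported; per-network totals
#' sum to the grand total and carry an integer percent share (rounded
#' half up).
#'
#' @param votes A ledger tibble; refused (post-lock) votes are excluded.
#' @param evidence_networks Optional tibble mapping `evidence_id` to
#'   `network`; unmapped evidence falls under `"(unassigned)"`.
#' @param lock_threshold Effective votes required to lock.
#' @return A `lock_summary` object: `totals` (one row: `total_votes`,
#'   `up_votes`, `down_votes`, `approved`, `rejected`, `open`) and
#'   `per_network`. `glance()` returns the totals, `tidy()` the
#'   per-network table.
#' @export
lock_summary <- function(votes, evidence_networks = NULL, lock_threshold = 4L) {
  rep <- replay_ledger(votes, lock_threshold)
  if (!is.null(evidence_networks)) {
    rep <- dplyr::left_join(rep, evidence_networks, by = "evidence_id") |>
      tidyr::replace_na(list(network = "(unassigned)"))
  } else {
    rep$network <- "(all)"
  }
  totals <- tibble::tibble(
    total_votes = sum(rep$n_up) + sum(rep$n_down),
    up_votes = sum(rep$n_up), down_votes = sum(rep$n_down),
    approved = sum(rep$status == "approved"),
    rejected = sum(rep$status == "rejected"),
    open = sum(rep$status == "open"))
  per_network <- rep |>
    dplyr::group_by(.data$network) |>
    dplyr::summarise(total_votes = sum(.data$n_up) + sum(.data$n_down),
                     up_votes = sum(.data$n_up),
                     down_votes = sum(.data$n_down),
                     approved = sum(.data$status == "approved"),
                     rejected = sum(.data$status == "rejected"),
                     .groups = "drop") |>
    dplyr::mutate(share_pct = if (totals$total_votes == 0) NA_real_ else
      round_half_up(100 * .data$total_votes / totals$total_votes))
  structure(list(totals = totals, per_network = per_network),
            class = "lock_summary")
}

#' @export
print.lock_summary <- function(x, ...) {
  cat("<lock_summary>\n")
  print(x$totals)
  invisible(x)
}

#' @export
tidy.lock_summary <- function(x, ...) x$per_network

#' @export
glance.lock_summary <- function(x, ...) x$totals

#' @rdname lock_summary
#' @param object A `lock_summary`.
#' @param ... Unused.
#' @export
autoplot.lock_summary <- function(object, ...) {
  df <- object$per_network |>
    dplyr::select("network", "up_votes", "down_votes") |>
    tidyr::pivot_longer(-"network", names_to = "direction", values_to = "votes")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network, y = .data$votes,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "raw votes")
}

# ---- points & leaderboard ---------------------------------------------------

#' Credit point scheme
#'
#' The platform rewarded contributing new evidence most, then new edges,
#' new nodes, and votes; exact published values are not available, so the
#' defaults here are declared package constants, overridable, and every
#' leaderboard records the scheme used.
#'
#' @param new_evidence,new_edge,new_node,vote Points per action.
#' @return A named numeric vector of class `point_scheme`;
#'   `new_evidence` must exceed `vote`.
#' @export
point_scheme <- function(new_evidence = 5, new_edge = 5, new_node = 2,
                         vote = 1) {
  stopifnot(new_evidence > vote)
  structure(c(new_evidence = new_evidence, new_edge = new_edge,
              new_node = new_node, vote = vote),
            class = "point_scheme")
}

ACTION_TYPES <- c("vote", "new_evidence", "new_edge", "new_node")

#' @rdname leaderboard
#' @export
action_log <- function(seq = integer(), user = character(),
                       action = character(), target = character()) {
  log <- tibble::tibble(seq = as.integer(seq), user = as.character(user),
                        action = as.character(action),
                        target = as.character(target))
  if (nrow(log) && !all(log$action %in% ACTION_TYPES)) {
    abort(paste0("unknown action type(s): ",
                 paste(setdiff(log$action, ACTION_TYPES), collapse = ", ")))
  }
  log
}

#' Leaderboard ranking and jamboree invitee selection
#'
#' `leaderboard()` scores each user's actions under a [point_scheme()] and
#' ranks descending by points, breaking ties by evidences created and then
#' user id. `jamboree_invitees()` implements the invitation rule for the
#' in-person phase: among users who cast at least `min_votes` votes, rank
#' by evidences created and take the top `top_n`.
#'
#' @param log An [action_log()] tibble.
#' @param scheme A [point_scheme()].
#' @return A tibble `user`, `points`, `evidences_created`, `edges_created`,
#'   `nodes_created`, `votes_cast`, in rank order; the scheme used is kept
#'   in attribute `scheme`.
#' @examples
#' log <- action_log(1:5, "ana", c("new_evidence", "new_evidence",
#'                                 "new_evidence", "vote", "vote"),
#'                   paste0("e", 1:5))
#' leaderboard(log)  # 3 * 5 + 2 * 1 = 17 points
#' @export
leaderboard <- function(log, scheme = point_scheme()) {
  stopifnot(inherits(scheme, "point_scheme"))
  log <- action_log(log$seq, log$user, log$action, log$target)
  if (!nrow(log)) {
    out <- tibble::tibble(user = character(), points = double(),
                          evidences_created = integer(),
                          edges_created = integer(),
                          nodes_created = integer(), votes_cast = integer())
    attr(out, "scheme") <- scheme
    return(out)
  }
  out <- log |>
    dplyr::group_by(.data$user) |>
    dplyr::summarise(
      evidences_created = sum(.data$action == "new_evidence"),
      edges_created = sum(.data$action == "new_edge"),
      nodes_created = sum(.data$action == "new_node"),
      votes_cast = sum(.data$action == "vote"),
      .groups = "drop") |>
    dplyr::mutate(points = .data$evidences_created * scheme[["new_evidence"]] +
                    .data$edges_created * scheme[["new_edge"]] +
                    .data$nodes_created * scheme[["new_node"]] +
                    .data$votes_cast * scheme[["vote"]]) |>
    dplyr::arrange(dplyr::desc(.data$points),
                   dplyr::desc(.data$evidences_created), .data$user) |>
    dplyr::select("user", "points", "evidences_created", "edges_created",
                  "nodes_created", "votes_cast")
  attr(out, "scheme") <- scheme
  out
}

#' @rdname leaderboard
#' @param min_votes Minimum votes cast to qualify (default 20).
#' @param top_n Number of invitees (default 20).
#' @export
jamboree_invitees <- function(log, min_votes = 20L, top_n = 20L,
                              scheme = point_scheme()) {
  board <- leaderboard(log, scheme)
  board |>
    dplyr::filter(.data$votes_cast >= min_votes) |>
    dplyr::arrange(dplyr::desc(.data$evidences_created), .data$user) |>
    dplyr::slice_head(n = top_n)
}

# ---- crowd edits ------------------------------------------------------------

#' Apply a crowd edit to a network
#'
#' Applies one open-phase contribution — new evidence for an existing
#' edge, a new edge (which degrades gracefully to new evidence when the
#' canonical statement already exists), or a new isolated node — recording
#' the actor in the edit's provenance and appending to the action log.
#'
#' @param network A `bel_network`.
#' @param action One of `"new_evidence"`, `"new_edge"`, `"new_node"`.
#' @param statement Statement text or `bel_statement` (for evidence/edge
#'   actions).
#' @param evidences Evidence(s) supporting the contribution.
#' @param term Term text or `bel_term` (for `new_node`).
#' @param actor Crowd user id.
#' @param log The running [action_log()].
#' @return A list with the updated `network` and `log`. The log records
#'   the effective action (a duplicate new_edge is logged as
#'   new_evidence).
#' @export
apply_edit <- function(network, action = c("new_evidence", "new_edge", "new_node"),
                       statement = NULL, evidences = NULL, term = NULL,
                       actor = "crowd", log = action_log()) {
  action <- match.arg(action)
  prov <- provenance("phase2_crowd", actor = actor,
                     timestamp = nrow(log) + 1L)
  if (action %in% c("new_evidence", "new_edge")) {
    if (is.null(statement)) abort("statement is required for this action")
    statement <- as_statement(statement)
    skey <- statement_key(statement)
    effective <- if (action == "new_edge" && !is.null(network$edges[[skey]])) {
      "new_evidence"
    } else if (action == "new_evidence" && is.null(network$edges[[skey]])) {
      "new_edge"
    } else {
      action
    }
    network <- add_edge(network, statement, evidences, prov)
    target <- skey
  } else {
    if (is.null(term)) abort("term is required for new_node")
    if (!inherits(term, "bel_term")) term <- parse_term(term)
    key <- canonical_key(term)
    if (!is.null(network$nodes[[key]])) {
      abort(paste0("node already present: ", key))
    }
    network$nodes[[key]] <- canonicalize_term(term)
    network <- bump_revision(network, paste0("add node ", key), prov)
    effective <- "new_node"
    target <- key
  }
  log <- dplyr::bind_rows(log, tibble::tibble(seq = nrow(log) + 1L,
                                              user = actor,
                                              action = effective,
                                              target = target))
  list(network = network, log = log)
}

# ---- CSV formats ------------------------------------------------------------

#' Read/write vote ledgers and action logs as CSV
#'
#' Ledger CSV columns: `seq,user,evidence_id,direction`; action log CSV
#' columns: `seq,user,action,target`.
#'
#' @param path File path.
#' @return A validated tibble (readers) or the path invisibly (writers).
#' @export
read_vote_ledger <- function(path) {
  df <- utils::read.csv(path, colClasses = c(seq = "integer",
                                             user = "character",
                                             evidence_id = "character",
                                             direction = "character"))
  vote_ledger(df$seq, df$user, df$evidence_id, df$direction)
}

#' @rdname read_vote_ledger
#' @param ledger A ledger tibble.
#' @export
write_vote_ledger <- function(ledger, path) {
  validate_ledger(ledger)
  utils::write.csv(ledger, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_vote_ledger
#' @export
read_action_log <- function(path) {
  df <- utils::read.csv(path, colClasses = c(seq = "integer",
                                             user = "character",
                                             action = "character",
                                             target = "character"))
  action_log(df$seq, df$user, df$action, df$target)
}

#' @rdname read_vote_ledger
#' @param log An action log tibble.
#' @export
write_action_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
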