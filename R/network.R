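#' Construction phases
#'
#' Every edit to a network carries provenance naming the construction phase
#' it came from: the non-diseased starting scaffolds, phase-1 literature
#' curation, phase-1 data-driven (RCR) enhancement, the phase-2 open
#' crowd-verification phase, or the phase-3 in-person jamboree.
#'
#' @format Character vector of the five phase codes.
#' @export
NETWORK_PHASES <- c("phase0_nondiseased", "phase1_literature", "phase1_rcr",
                    "phase2_crowd", "phase3_jamboree")

EVIDENCE_STATUSES <- c("open", "approved", "rejected")
CONTEXT_FIELDS <- c("species", "tissue", "cell_type", "disease", "exposure")

#' Evidence supporting an edge
#'
#' An evidence record pairs a literature citation (PMID) with the quoted
#' supporting text and the experimental context it was observed in. Its
#' status starts `open` and may move once to `approved` or `rejected`
#' (by crowd locking or curator decision); records are never deleted, so
#' the revision history stays complete.
#'
#' @param citation PMID (or other citation token); must be non-empty.
#' @param quote Supporting text quoted from the publication.
#' @param context Named character vector with any of `species`, `tissue`,
#'   `cell_type`, `disease`, `exposure`; missing fields mean unconstrained.
#' @param id Evidence identity; defaults to a hash of citation and quote.
#' @param status One of `open`, `approved`, `rejected`.
#' @return An object of class `bel_evidence`.
#' @examples
#' evidence("12345678", "X increases Y in alveolar macrophages",
#'          context = c(species = "human", cell_type = "alveolar macrophage"))
#' @export
evidence <- function(citation, quote = "", context = character(), id = NULL,
                     status = "open") {
  stopifnot(is.character(citation), length(citation) == 1L, nchar(citation) > 0L)
  status <- match.arg(status, EVIDENCE_STATUSES)
  if (length(context)) {
    stopifnot(is.character(context), !is.null(names(context)))
    bad <- setdiff(names(context), CONTEXT_FIELDS)
    if (length(bad)) {
      abort(paste0("unknown evidence context field(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  id <- id %||% rlang::hash(paste0(citation, "\x1f", quote))
  structure(list(id = id, citation = citation, quote = quote,
                 context = context, status = status),
            class = "bel_evidence")
}

#' Edit provenance
#'
#' @param phase One of [NETWORK_PHASES].
#' @param actor Who made the edit (curator or crowd user id).
#' @param timestamp Ordinal timestamp (any non-decreasing integer scheme).
#' @return An object of class `bel_provenance`.
#' @export
provenance <- function(phase, actor = "curator", timestamp = 0L) {
  phase <- match.arg(phase, NETWORK_PHASES)
  structure(list(phase = phase, actor = actor,
                 timestamp = as.integer(timestamp)),
            class = "bel_provenance")
}

#' Create an empty network model
#'
#' A network holds BEL-term nodes keyed by canonical key, edges (one per
#' canonical statement, each with one or more evidences and provenance), a
#' revision counter and an append-only history. All mutating operations
#' return a new network with the revision incremented by one and one
#' history entry appended.
#'
#' @param name Network name.
#' @param description Free-text description.
#' @return An object of class `bel_network`.
#' @examples
#' net <- bel_network("Apoptosis")
#' net <- add_edge(net, "p(HGNC:XRCC6) decreases act(p(HGNC:BAX))",
#'                 evidence("15782130", "XRCC6 inhibits BAX activity"),
#'                 provenance("phase3_jamboree", "curator"))
#' glance(net)
#' @export
bel_network <- function(name, description = "") {
  structure(list(name = name, description = description,
                 nodes = list(), edges = list(), revision = 0L,
                 history = tibble::tibble(revision = integer(),
                                          description = character(),
                                          phase = character(),
                                          actor = character(),
                                          timestamp = integer())),
            class = "bel_network")
}

bump_revision <- function(network, description, prov) {
  network$revision <- network$revision + 1L
  network$history <- dplyr::bind_rows(
    network$history,
    tibble::tibble(revision = network$revision, description = description,
                   phase = prov$phase, actor = prov$actor,
                   timestamp = prov$timestamp))
  network
}

as_statement <- function(statement, functions = NULL, namespaces = NULL) {
  if (inherits(statement, "bel_statement")) return(statement)
  parse_statement(statement, functions, namespaces)
}

as_evidence_list <- function(evidences) {
  if (inherits(evidences, "bel_evidence")) evidences <- list(evidences)
  stopifnot(is.list(evidences))
  if (length(evidences) == 0L) abort("at least one evidence is required")
  ok <- vapply(evidences, inherits, logical(1), "bel_evidence")
  if (!all(ok)) abort("evidences must be bel_evidence objects")
  evidences
}

#' Add an edge (or more evidence for an existing edge)
#'
#' Endpoints absent from the node set are created automatically by
#' canonical key. If an edge with the identical canonical statement already
#' exists, the new evidences are appended to it rather than duplicating the
#' edge — edge identity is the canonical statement string, and evidence
#' accumulates under it.
#'
#' @param network A `bel_network`.
#' @param statement A `bel_statement` or statement text.
#' @param evidences A `bel_evidence` or list of them (at least one).
#' @param prov A [provenance()] record.
#' @return The updated network (revision + 1).
#' @export
add_edge <- function(network, statement, evidences, prov) {
  stopifnot(inherits(network, "bel_network"), inherits(prov, "bel_provenance"))
  statement <- as_statement(statement)
  evidences <- as_evidence_list(evidences)
  ids <- vapply(evidences, function(e) e$id, character(1))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate evidence id: ", ids[duplicated(ids)][1]))
  }
  skey <- statement_key(statement)
  subj_key <- canonical_key(statement$subject)
  obj_key <- canonical_key(statement$object)
  if (is.null(network$nodes[[subj_key]])) {
    network$nodes[[subj_key]] <- canonicalize_term(statement$subject)
  }
  if (is.null(network$nodes[[obj_key]])) {
    network$nodes[[obj_key]] <- canonicalize_term(statement$object)
  }
  existing <- network$edges[[skey]]
  if (is.null(existing)) {
    network$edges[[skey]] <- list(statement = statement, evidences = evidences,
                                  provenance = prov, family_forms = character())
    desc <- paste0("add edge ", skey)
  } else {
    old_ids <- vapply(existing$evidences, function(e) e$id, character(1))
    clash <- intersect(ids, old_ids)
    if (length(clash)) {
      abort(paste0("duplicate evidence id: ", clash[1]))
    }
    existing$evidences <- c(existing$evidences, evidences)
    network$edges[[skey]] <- existing
    desc <- paste0("add evidence to ", skey)
  }
  bump_revision(network, desc, prov)
}

#' Change the status of an evidence record
#'
#' Statuses move only `open -> approved` or `open -> rejected`; rejected
#' evidence is retained (never physically removed) so the full revision
#' history is preserved.
#'
#' @inheritParams add_edge
#' @param evidence_id The evidence id to update.
#' @param status `"approved"` or `"rejected"`.
#' @return The updated network (revision + 1).
#' @export
mark_evidence <- function(network, evidence_id, status, prov) {
  stopifnot(inherits(network, "bel_network"))
  status <- match.arg(status, c("approved", "rejected"))
  found <- FALSE
  for (skey in names(network$edges)) {
    evs <- network$edges[[skey]]$evidences
    for (j in seq_along(evs)) {
      if (evs[[j]]$id == evidence_id) {
        if (evs[[j]]$status != "open") {
          abort(sprintf("evidence '%s' is already %s", evidence_id,
                        evs[[j]]$status))
        }
        evs[[j]]$status <- status
        network$edges[[skey]]$evidences <- evs
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  if (!found) abort(sprintf("evidence '%s' not found", evidence_id))
  bump_revision(network, paste0("mark evidence ", evidence_id, " ", status), prov)
}

#' @export
print.bel_network <- function(x, ...) {
  cat(sprintf("<bel_network> %s: %d nodes, %d edges, %d evidences (rev %d)\n",
              x$name, length(x$nodes), length(x$edges),
              n_evidences(x), x$revision))
  invisible(x)
}

n_evidences <- function(network) {
  if (!length(network$edges)) return(0L)
  sum(vapply(network$edges, function(e) length(e$evidences), integer(1)))
}

#' Tabular views of a network
#'
#' `tidy()` returns one row per edge; `glance()` a one-row summary;
#' `evidence_table()` one row per evidence with its context fields spread
#' into columns.
#'
#' @param x A `bel_network`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bel_network <- function(x, ...) {
  if (!length(x$edges)) {
    return(tibble::tibble(statement = character(), subject = character(),
                          relation = character(), object = character(),
                          n_evidence = integer(), phase = character()))
  }
  tibble::tibble(
    statement = names(x$edges),
    subject = vapply(x$edges, function(e) canonical_key(e$statement$subject),
                     character(1), USE.NAMES = FALSE),
    relation = vapply(x$edges, function(e) e$statement$relation, character(1),
                      USE.NAMES = FALSE),
    object = vapply(x$edges, function(e) canonical_key(e$statement$object),
                    character(1), USE.NAMES = FALSE),
    n_evidence = vapply(x$edges, function(e) length(e$evidences), integer(1),
                        USE.NAMES = FALSE),
    phase = vapply(x$edges, function(e) e$provenance$phase, character(1),
                   USE.NAMES = FALSE))
}

#' @rdname tidy.bel_network
#' @export
glance.bel_network <- function(x, ...) {
  tibble::tibble(name = x$name, revision = x$revision,
                 n_nodes = length(x$nodes), n_edges = length(x$edges),
                 n_evidence = n_evidences(x))
}

#' @rdname tidy.bel_network
#' @param network A `bel_network`.
#' @export
evidence_table <- function(network) {
  stopifnot(inherits(network, "bel_network"))
  rows <- purrr::map_dfr(names(network$edges), function(skey) {
    purrr::map_dfr(network$edges[[skey]]$evidences, function(e) {
      ctx <- stats::setNames(rep(NA_character_, length(CONTEXT_FIELDS)),
                             CONTEXT_FIELDS)
      ctx[names(e$context)] <- e$context
      dplyr::bind_cols(
        tibble::tibble(statement = skey, evidence_id = e$id,
                       citation = e$citation, quote = e$quote,
                       status = e$status),
        tibble::as_tibble(as.list(ctx)))
    })
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(statement = character(), evidence_id = character(),
                           citation = character(), quote = character(),
                           status = character(), species = character(),
                           tissue = character(), cell_type = character(),
                           disease = character(), exposure = character())
  }
  rows
}

#' Edge counts by construction phase
#'
#' Summarizes a network's edges by the phase recorded in their provenance;
#' useful as the bookkeeping ledger of what each phase contributed.
#'
#' @param networks A `bel_network` or list of them.
#' @return A tibble with columns `phase` and `n_edges`.
#' @export
provenance_summary <- function(networks) {
  if (inherits(networks, "bel_network")) networks <- list(networks)
  phases <- unlist(lapply(networks, function(n) {
    vapply(n$edges, function(e) e$provenance$phase, character(1))
  }))
  tibble::tibble(phase = NETWORK_PHASES) |>
    dplyr::left_join(
      tibble::tibble(phase = as.character(phases)) |> dplyr::count(phase, name = "n_edges"),
      by = "phase") |>
    tidyr::replace_na(list(n_edges = 0L))
}
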