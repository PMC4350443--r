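#' Difference between two versions of a network set
#'
#' Counts nodes, edges and evidences present in the new version but not
#' the old, per network and in total. Networks are matched by name; a
#' network present only in the new set counts wholly as added, one present
#' only in the old set wholly as removed. Node identity is the canonical
#' key, edge identity the canonical statement, and evidence identity the
#' (statement, evidence id) pair.
#'
#' @param old,new A `bel_network` or list of networks.
#' @return A `phase_diff` object: `breakdown` (per-network tibble with
#'   `*_added` and `*_removed` counts plus the citations of added
#'   evidences) and `totals`. `tidy()` returns the breakdown, `glance()`
#'   the totals.
#' @examples
#' v0 <- bel_network("Th1-Th2 Signaling")
#' v1 <- add_edge(v0, "p(HGNC:EGR2) increases act(p(HGNC:CBLB))",
#'                evidence("19494265", "EGR2 induces CBL-B"),
#'                provenance("phase3_jamboree"))
#' glance(diff_versions(v0, v1))
#' @export
diff_versions <- function(old, new) {
  old <- as_network_list(old)
  new <- as_network_list(new)
  nms <- union(names(new), names(old))
  breakdown <- purrr::map_dfr(nms, function(nm) {
    o <- old[[nm]]
    n <- new[[nm]]
    o_nodes <- if (is.null(o)) character() else names(o$nodes)
    n_nodes <- if (is.null(n)) character() else names(n$nodes)
    o_edges <- if (is.null(o)) character() else names(o$edges)
    n_edges <- if (is.null(n)) character() else names(n$edges)
    o_ev <- evidence_ids(o)
    n_ev <- evidence_ids(n)
    added_ev <- n_ev[!n_ev$key %in% o_ev$key, , drop = FALSE]
    tibble::tibble(
      network = nm,
      nodes_added = length(setdiff(n_nodes, o_nodes)),
      edges_added = length(setdiff(n_edges, o_edges)),
      evidences_added = nrow(added_ev),
      nodes_removed = length(setdiff(o_nodes, n_nodes)),
      edges_removed = length(setdiff(o_edges, n_edges)),
      evidences_removed = sum(!o_ev$key %in% n_ev$key),
      added_citations = list(added_ev$citation))
  })
  structure(list(breakdown = breakdown,
                 totals = tibble::tibble(
                   nodes_added = sum(breakdown$nodes_added),
                   edges_added = sum(breakdown$edges_added),
                   evidences_added = sum(breakdown$evidences_added),
                   nodes_removed = sum(breakdown$nodes_removed),
                   edges_removed = sum(breakdown$edges_removed),
                   evidences_removed = sum(breakdown$evidences_removed))),
            class = "phase_diff")
}

as_network_list <- function(x) {
  if (inherits(x, "bel_network")) x <- list(x)
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "bel_network")))
  stats::setNames(x, vapply(x, function(n) n$name, character(1)))
}

evidence_ids <- function(network) {
  if (is.null(network) || !length(network$edges)) {
    return(tibble::tibble(key = character(), citation = character()))
  }
  purrr::map_dfr(names(network$edges), function(skey) {
    evs <- network$edges[[skey]]$evidences
    tibble::tibble(
      key = paste0(skey, "\x1f", vapply(evs, function(e) e$id, character(1))),
      citation = vapply(evs, function(e) e$citation, character(1)))
  })
}

#' @export
print.phase_diff <- function(x, ...) {
  cat("<phase_diff>\n")
  print(x$totals)
  invisible(x)
}

#' @export
tidy.phase_diff <- function(x, ...) x$breakdown

#' @export
glance.phase_diff <- function(x, ...) x$totals

#' Share of additions falling in focus networks
#'
#' Reports, for nodes, edges and evidences added, the count within a set
#' of focus networks, the grand total, and the integer percentage share
#' (rounded half up, matching curation bookkeeping style such as
#' "266 of 885 new evidences, 30%"). Also reports the number of unique
#' citations across all added evidences. A zero total yields an undefined
#' (`NA`) share, never 0.
#'
#' @param diff A [diff_versions()] result.
#' @param focus Character vector of network names; must exist in the
#'   breakdown.
#' @return A tibble with columns `measure`, `focus_count`, `total`,
#'   `share_pct`, with the unique added-citation count in attribute
#'   `unique_citations`.
#' @export
share_report <- function(diff, focus) {
  stopifnot(inherits(diff, "phase_diff"))
  b <- diff$breakdown
  missing <- setdiff(focus, b$network)
  if (length(missing)) {
    abort(paste0("focus network(s) not in diff: ", paste(missing, collapse = ", ")))
  }
  in_focus <- b$network %in% focus
  measures <- c(nodes = "nodes_added", edges = "edges_added",
                evidences = "evidences_added")
  out <- purrr::map_dfr(names(measures), function(m) {
    col <- measures[[m]]
    total <- sum(b[[col]])
    fc <- sum(b[[col]][in_focus])
    tibble::tibble(measure = m, focus_count = fc, total = total,
                   share_pct = if (total == 0) NA_real_ else
                     round_half_up(100 * fc / total))
  })
  attr(out, "unique_citations") <-
    length(unique(unlist(b$added_citations)))
  out
}

#' Plot a phase diff
#'
#' Bar chart of per-network added counts, one facet per measure.
#'
#' @param object A `phase_diff`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_diff <- function(object, ...) {
  df <- object$breakdown |>
    dplyr::select("network", "nodes_added", "edges_added", "evidences_added") |>
    tidyr::pivot_longer(-"network", names_to = "measure", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$network, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "added")
}
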