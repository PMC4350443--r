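#' Merge specification
#'
#' Network agglomeration consolidates networks covering related biological
#' processes: each group of two or more source networks is merged into one
#' target network, and the remaining sources pass through standalone.
#' When applied, every input network name must appear exactly once across
#' groups and standalone.
#'
#' @param groups Named list: target network name -> character vector of
#'   at least two source names.
#' @param standalone Character vector of source names passed through
#'   unchanged.
#' @return A `merge_spec` object.
#' @examples
#' merge_spec(groups = list("Th1 Signaling" = c("Th1 Differentiation",
#'                                              "Th1 Response",
#'                                              "T-cell Recruitment/Activation")),
#'            standalone = "Apoptosis")
#' @export
merge_spec <- function(groups = list(), standalone = character()) {
  stopifnot(is.list(groups), is.character(standalone))
  if (length(groups) && is.null(names(groups))) {
    abort("groups must be a named list (target name -> sources)")
  }
  small <- vapply(groups, length, integer(1)) < 2L
  if (any(small)) {
    abort(paste0("merge group(s) with fewer than 2 sources: ",
                 paste(names(groups)[small], collapse = ", ")))
  }
  sources <- c(unlist(groups, use.names = FALSE), standalone)
  if (anyDuplicated(sources)) {
    abort(paste0("source network covered more than once: ",
                 sources[duplicated(sources)][1]))
  }
  structure(list(groups = groups, standalone = standalone),
            class = "merge_spec")
}

#' Read a merge specification from a YAML file
#'
#' Expected structure: a `groups` mapping (target -> list of sources) and
#' a `standalone` list.
#'
#' @param path File path.
#' @return A validated `merge_spec`.
#' @export
read_merge_spec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading merge specs from YAML requires the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  merge_spec(groups = lapply(y$groups %||% list(), unlist),
             standalone = as.character(y$standalone %||% character()))
}

#' Merge networks per a specification
#'
#' Each group yields one network: the node set is the union (by canonical
#' key) of the sources' nodes, and the edges are the deduplicated union —
#' on a canonical-statement collision the evidence lists are concatenated
#' (evidence is never lost). Standalone networks pass through unchanged.
#' The output count is `|groups| + |standalone|`.
#'
#' @param networks List of `bel_network`s; their names must match the spec
#'   exactly (no uncovered or doubly-covered source).
#' @param spec A [merge_spec()].
#' @param prov Provenance recorded on merged networks' history.
#' @return A named list of networks.
#' @export
merge_networks <- function(networks, spec,
                           prov = provenance("phase1_literature",
                                             actor = "agglomeration")) {
  stopifnot(inherits(spec, "merge_spec"))
  networks <- as_network_list(networks)
  covered <- c(unlist(spec$groups, use.names = FALSE), spec$standalone)
  missing <- setdiff(covered, names(networks))
  if (length(missing)) {
    abort(paste0("merge spec names unknown network(s): ",
                 paste(missing, collapse = ", ")))
  }
  uncovered <- setdiff(names(networks), covered)
  if (length(uncovered)) {
    abort(paste0("merge spec leaves network(s) uncovered: ",
                 paste(uncovered, collapse = ", ")))
  }
  merged <- lapply(names(spec$groups), function(target) {
    sources <- networks[spec$groups[[target]]]
    out <- bel_network(target, paste0("merged from: ",
                                      paste(names(sources), collapse = ", ")))
    for (src in sources) {
      for (key in names(src$nodes)) {
        if (is.null(out$nodes[[key]])) out$nodes[[key]] <- src$nodes[[key]]
      }
      for (skey in names(src$edges)) {
        e <- src$edges[[skey]]
        if (is.null(out$edges[[skey]])) {
          out$edges[[skey]] <- e
        } else {
          existing <- out$edges[[skey]]
          old_ids <- vapply(existing$evidences, function(x) x$id, character(1))
          new <- e$evidences[!vapply(e$evidences, function(x) x$id,
                                     character(1)) %in% old_ids]
          existing$evidences <- c(existing$evidences, new)
          existing$family_forms <- union(existing$family_forms, e$family_forms)
          out$edges[[skey]] <- existing
        }
      }
    }
    bump_revision(out, paste0("merge of ", length(sources), " networks: ",
                              paste(names(sources), collapse = ", ")), prov)
  })
  names(merged) <- names(spec$groups)
  c(merged, networks[spec$standalone])
}

# An edge is family-eligible when its relation is causal and its object is
# a bare p/r/g/sec over a single entity (nested objects such as act(p(X))
# never agglomerate).
FAMILY_FUNCTIONS <- c("p", "r", "g", "sec")

family_object_info <- function(edge) {
  obj <- edge$statement$object
  if (!edge$statement$relation %in% CAUSAL_RELATIONS) return(NULL)
  if (!obj$fun %in% FAMILY_FUNCTIONS) return(NULL)
  if (length(obj$args) != 1L || !inherits(obj$args[[1]], "bel_entity")) {
    return(NULL)
  }
  list(fun = obj$fun, gene = paste0(obj$args[[1]]$ns, ":", obj$args[[1]]$name))
}

#' Collapse protein/RNA/gene/secretion edge variants
#'
#' Edges sharing a subject, a downstream gene and a causal sign but
#' differing only in the object's molecular form — protein `p(X)`, RNA
#' `r(X)`, gene `g(X)` or secretion `sec(X)` — describe the same
#' verifiable relationship; collapsing them reduces the number of edges a
#' reviewer must verify. Each such family of two or more members is
#' replaced by a single representative edge (form preference
#' p > r > g > sec) carrying the union of the members' evidences and a
#' family annotation listing the collapsed object forms. Edge count never
#' increases and evidence count is conserved; the operation is idempotent.
#'
#' @param network A `bel_network`.
#' @param prov Provenance for the history entry.
#' @return The agglomerated network (revision + 1 if anything collapsed).
#' @export
agglomerate_edges <- function(network,
                              prov = provenance("phase1_literature",
                                                actor = "agglomeration")) {
  stopifnot(inherits(network, "bel_network"))
  skeys <- names(network$edges)
  infos <- lapply(network$edges, family_object_info)
  fam_key <- rep(NA_character_, length(skeys))
  fam_fun <- rep(NA_character_, length(skeys))
  for (i in seq_along(skeys)) {
    if (is.null(infos[[i]])) next
    e <- network$edges[[i]]
    fam_key[i] <- paste0(canonical_key(e$statement$subject), "\x1f",
                         infos[[i]]$gene, "\x1f", e$statement$relation)
    fam_fun[i] <- infos[[i]]$fun
  }
  drop_keys <- character()
  collapsed <- 0L
  for (fk in unique(fam_key[!is.na(fam_key)])) {
    members <- which(!is.na(fam_key) & fam_key == fk)
    if (length(members) < 2L) next
    pref <- match(fam_fun[members], FAMILY_FUNCTIONS)
    rep_i <- members[which.min(pref)]
    rep_edge <- network$edges[[rep_i]]
    forms <- character()
    for (i in members) {
      forms <- union(forms,
                     c(serialize_term(network$edges[[i]]$statement$object),
                       network$edges[[i]]$family_forms))
      if (i == rep_i) next
      ids <- vapply(rep_edge$evidences, function(x) x$id, character(1))
      extra <- network$edges[[i]]$evidences
      extra <- extra[!vapply(extra, function(x) x$id, character(1)) %in% ids]
      rep_edge$evidences <- c(rep_edge$evidences, extra)
    }
    rep_edge$family_forms <- sort(forms, method = "radix")
    network$edges[[rep_i]] <- rep_edge
    drop_keys <- c(drop_keys, skeys[setdiff(members, rep_i)])
    collapsed <- collapsed + length(members) - 1L
  }
  if (collapsed == 0L) return(network)
  network$edges[drop_keys] <- NULL
  bump_revision(network,
                sprintf("agglomerate edges: collapsed %d variant edge(s)",
                        collapsed), prov)
}
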