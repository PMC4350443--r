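# BEL-script dialect and XGMML import/export.

SET_CONTEXT_KEYS <- c(Species = "species", Tissue = "tissue",
                      CellType = "cell_type", Disease = "disease",
                      Exposure = "exposure")

escape_quotes <- function(x) gsub('(["\\\\])', "\\\\\\1", x)

strip_quotes <- function(x) {
  x <- trimws(x)
  if (startsWith(x, '"') && endsWith(x, '"') && nchar(x) >= 2L) {
    unquote_name(x)
  } else {
    x
  }
}

#' Read a network from BEL-script text
#'
#' The dialect is line oriented: a header block of
#' `SET Document Name = "..."` / `SET Document Description = "..."`, then
#' per evidence a `SET Citation = "PMID"` (which starts a fresh evidence
#' block, clearing the previous quote and context), an optional
#' `SET Evidence = "quoted supporting text"`, optional context annotations
#' (`SET Species/Tissue/CellType/Disease/Exposure = "..."`), and one or
#' more BEL statement lines that each become an edge carrying the current
#' evidence. Evidence identity is the hash of citation, quote and
#' statement, so two statements under one block get distinct ids. Blank
#' lines and `#` comments are ignored. Errors report the line number.
#'
#' @param text BEL script as a single string or character vector of lines.
#' @param name Fallback network name if the script has no header.
#' @param prov Provenance attached to the edges read.
#' @param functions,namespaces Registries for statement parsing.
#' @return A `bel_network`.
#' @export
read_bel_script <- function(text, name = "network",
                            prov = provenance("phase0_nondiseased",
                                              actor = "import"),
                            functions = NULL, namespaces = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  net_name <- name
  net_desc <- ""
  citation <- NULL
  quote <- ""
  context <- character()
  edges <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    if (grepl("^SET\\s", raw)) {
      body <- sub("^SET\\s+", "", raw)
      if (!grepl("=", body, fixed = TRUE)) {
        abort(sprintf("line %d: SET without '='", ln),
              class = "belnet_script_error")
      }
      key <- trimws(sub("=.*$", "", body))
      val <- strip_quotes(sub("^[^=]*=", "", body))
      if (key == "Document Name") {
        net_name <- val
      } else if (key == "Document Description") {
        net_desc <- val
      } else if (key == "Citation") {
        citation <- val
        quote <- ""
        context <- character()
      } else if (key == "Evidence") {
        quote <- val
      } else if (key %in% names(SET_CONTEXT_KEYS)) {
        context[[SET_CONTEXT_KEYS[[key]]]] <- val
      } else {
        abort(sprintf("line %d: unknown SET key '%s'", ln, key),
              class = "belnet_script_error")
      }
      next
    }
    # a statement line
    if (is.null(citation)) {
      abort(sprintf("line %d: statement before any SET Citation", ln),
            class = "belnet_script_error")
    }
    stmt <- tryCatch(parse_statement(raw, functions, namespaces),
                     error = function(e) {
                       abort(sprintf("line %d: %s", ln, conditionMessage(e)),
                             class = "belnet_script_error")
                     })
    ev <- evidence(citation, quote, context = context,
                   id = rlang::hash(paste0(citation, "\x1f", quote, "\x1f",
                                           statement_key(stmt))))
    edges[[length(edges) + 1L]] <- list(statement = stmt, evidence = ev)
  }
  net <- bel_network(net_name, net_desc)
  for (e in edges) {
    net <- add_edge(net, e$statement, e$evidence, prov)
  }
  net
}

#' @rdname read_bel_script
#' @param network A `bel_network`.
#' @return For `write_bel_script()`: the script as a single string. Edges
#'   are emitted sorted by canonical statement (deterministic output);
#'   read/write round trips preserve edge and evidence counts.
#' @export
write_bel_script <- function(network) {
  stopifnot(inherits(network, "bel_network"))
  out <- c(sprintf('SET Document Name = "%s"', escape_quotes(network$name)),
           sprintf('SET Document Description = "%s"',
                   escape_quotes(network$description)))
  for (skey in sort(names(network$edges) %||% character(), method = "radix")) {
    e <- network$edges[[skey]]
    for (ev in e$evidences) {
      out <- c(out, "",
               sprintf('SET Citation = "%s"', escape_quotes(ev$citation)),
               sprintf('SET Evidence = "%s"', escape_quotes(ev$quote)))
      for (k in names(SET_CONTEXT_KEYS)) {
        field <- SET_CONTEXT_KEYS[[k]]
        if (field %in% names(ev$context)) {
          out <- c(out, sprintf('SET %s = "%s"',
                                k, escape_quotes(ev$context[[field]])))
        }
      }
      out <- c(out, skey)
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

# ---- XGMML ------------------------------------------------------------------

XGMML_NS <- "http://www.cs.rpi.edu/XGMML"

# Node shapes by function class, following the network figure conventions:
# activities are triangles, biological processes and pathologies diamonds,
# translocations rounded squares, protein abundances squares, and other
# abundances circles.
ACTIVITY_FUNCTIONS <- c("act", "cat", "kin", "phos", "pep", "gtp", "chap",
                        "ribo", "tscript", "tport")
ABUNDANCE_FUNCTIONS <- c("a", "g", "r", "m", "complex", "composite", "sec",
                         "surf")

node_shape <- function(fun) {
  if (fun %in% ACTIVITY_FUNCTIONS) return("triangle")
  if (fun %in% c("bp", "path")) return("diamond")
  if (fun == "tloc") return("rounded-square")
  if (fun == "p") return("square")
  if (fun %in% ABUNDANCE_FUNCTIONS) return("circle")
  "square"
}

#' Export a network as XGMML
#'
#' Writes one `node` element per network node (label = canonical key,
#' with a `shape` attribute by function class) and one `edge` element per
#' edge (`interaction` = relation code, `evidences` = evidence count).
#' Element order is deterministic: nodes sorted by canonical key, edges by
#' canonical statement — exporting twice yields byte-identical text.
#'
#' @param network A `bel_network`.
#' @return XGMML document text (UTF-8, standalone).
#' @export
export_xgmml <- function(network) {
  stopifnot(inherits(network, "bel_network"))
  doc <- xml2::xml_new_root("graph", label = network$name,
                            xmlns = XGMML_NS, directed = "1")
  keys <- sort(names(network$nodes) %||% character(), method = "radix")
  ids <- stats::setNames(as.character(seq_along(keys)), keys)
  for (key in keys) {
    node <- xml2::xml_add_child(doc, "node", id = ids[[key]], label = key)
    xml2::xml_add_child(node, "att", name = "shape",
                        value = node_shape(network$nodes[[key]]$fun))
  }
  for (skey in sort(names(network$edges) %||% character(), method = "radix")) {
    e <- network$edges[[skey]]
    subj <- canonical_key(e$statement$subject)
    obj <- canonical_key(e$statement$object)
    edge <- xml2::xml_add_child(doc, "edge", label = skey,
                                source = ids[[subj]], target = ids[[obj]])
    xml2::xml_add_child(edge, "att", name = "interaction",
                        value = e$statement$relation)
    xml2::xml_add_child(edge, "att", name = "evidences",
                        value = as.character(length(e$evidences)))
  }
  as.character(doc)
}

#' Import a network from XGMML (structure only)
#'
#' Reconstructs nodes and edges from an XGMML document. Node labels are
#' re-parsed as BEL terms where possible; unparseable labels are retained
#' as opaque nodes and listed in the returned network's `unparsed_nodes`
#' field (edges touching them go to `opaque_edges`). Evidence metadata is
#' not carried by XGMML, so each edge receives placeholder evidence
#' records matching its exported evidence count.
#' `import_xgmml(export_xgmml(n))` is graph-isomorphic to `n` with equal
#' labels.
#'
#' @param text XGMML document text.
#' @param functions,namespaces Registries for label parsing.
#' @return A `bel_network` with extra fields `unparsed_nodes` (character)
#'   and `opaque_edges` (tibble `source`, `relation`, `target`).
#' @export
import_xgmml <- function(text, functions = NULL, namespaces = NULL) {
  doc <- xml2::read_xml(text)
  xml2::xml_ns_strip(doc)
  net <- bel_network(xml2::xml_attr(doc, "label") %||% "network")
  net$unparsed_nodes <- character()
  net$opaque_edges <- tibble::tibble(source = character(),
                                     relation = character(),
                                     target = character())
  labels <- list()
  terms <- list()
  for (node in xml2::xml_find_all(doc, "./node")) {
    id <- xml2::xml_attr(node, "id")
    label <- xml2::xml_attr(node, "label")
    if (is.na(id) || is.na(label)) abort("node without id or label")
    if (!is.null(labels[[id]])) abort(paste0("duplicate node id: ", id))
    labels[[id]] <- label
    term <- tryCatch(parse_term(label, functions, namespaces),
                     error = function(e) NULL)
    if (is.null(term)) {
      net$unparsed_nodes <- c(net$unparsed_nodes, label)
    } else {
      terms[[id]] <- term
      net$nodes[[canonical_key(term)]] <- canonicalize_term(term)
    }
  }
  prov <- provenance("phase0_nondiseased", actor = "import")
  for (edge in xml2::xml_find_all(doc, "./edge")) {
    src <- xml2::xml_attr(edge, "source")
    tgt <- xml2::xml_attr(edge, "target")
    for (endpoint in c(src, tgt)) {
      if (is.null(labels[[endpoint]])) {
        abort(paste0("edge endpoint refers to missing node id: ", endpoint))
      }
    }
    rel <- xml2::xml_attr(
      xml2::xml_find_first(edge, "./att[@name='interaction']"), "value")
    if (is.na(rel)) rel <- "increases"
    n_ev <- xml2::xml_attr(
      xml2::xml_find_first(edge, "./att[@name='evidences']"), "value")
    n_ev <- max(1L, suppressWarnings(as.integer(n_ev)), na.rm = TRUE)
    if (is.null(terms[[src]]) || is.null(terms[[tgt]]) ||
        !rel %in% RELATION_CODES) {
      net$opaque_edges <- dplyr::bind_rows(
        net$opaque_edges,
        tibble::tibble(source = labels[[src]], relation = rel,
                       target = labels[[tgt]]))
      next
    }
    stmt <- bel_statement(terms[[src]], rel, terms[[tgt]])
    evs <- lapply(seq_len(n_ev), function(i) {
      evidence("import", "", id = paste0("import:", statement_key(stmt),
                                         ":", i))
    })
    net <- add_edge(net, stmt, evs, prov)
  }
  net
}
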