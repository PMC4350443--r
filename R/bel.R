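#' @importFrom rlang %||% abort warn .data
NULL

# Functions whose arguments may be plain (namespace-free) qualifier tokens,
# e.g. pmod(P,S,273) or tloc compartment shorthands. Everywhere else a bare
# token is a missing-namespace error: the dialect requires every biological
# entity to carry the database it is defined in.
QUALIFIER_FUNCTIONS <- c("pmod", "tloc", "sub", "trunc", "fus")

MAX_NESTING_DEPTH <- 4L

RELATION_CODES <- c("increases", "decreases", "nonCausal")
CAUSAL_RELATIONS <- c("increases", "decreases")

# ---- tokenizer --------------------------------------------------------------

# One-pass regex tokenizer. Token types: quoted string, identifier,
# punctuation ( ) , :  — whitespace is skipped, anything else is an error
# reported with its 1-based character position.
tokenize_bel <- function(text) {
  pattern <- '"(?:[^"\\\\]|\\\\.)*"|[A-Za-z0-9_.\\-]+|[(),:]|\\s+'
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    abort(sprintf("syntax error at position 1: unexpected character '%s'",
                  substr(text, 1, 1)), class = "belnet_parse_error")
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  # every character must be covered by some token
  cursor <- 1L
  for (i in seq_along(starts)) {
    if (starts[i] > cursor) {
      abort(sprintf("syntax error at position %d: unexpected character '%s'",
                    cursor, substr(text, cursor, cursor)),
            class = "belnet_parse_error")
    }
    cursor <- starts[i] + lens[i]
  }
  if (cursor <= nchar(text)) {
    abort(sprintf("syntax error at position %d: unexpected character '%s'",
                  cursor, substr(text, cursor, cursor)),
          class = "belnet_parse_error")
  }
  values <- regmatches(text, list(m))[[1]]
  keep <- !grepl("^\\s", values)
  values <- values[keep]
  starts <- starts[keep]
  type <- ifelse(startsWith(values, '"'), "quoted",
                 ifelse(values %in% c("(", ")", ",", ":"), "punct", "ident"))
  list(value = values, type = type, pos = starts, n = length(values))
}

unquote_name <- function(x) {
  inner <- substr(x, 2L, nchar(x) - 1L)
  gsub('\\\\(["\\\\])', "\\1", inner)
}

quote_name <- function(x) {
  if (nchar(x) == 0L || grepl('[\\s():,"\\\\]', x, perl = TRUE)) {
    paste0('"', gsub('(["\\\\])', "\\\\\\1", x), '"')
  } else {
    x
  }
}

# ---- constructors -----------------------------------------------------------

#' Construct BEL term components programmatically
#'
#' `bel_entity()` makes a namespaced entity reference and `bel_term()` a
#' function application over entities, nested terms or plain qualifier
#' tokens. Most users will get these from [parse_term()] instead.
#'
#' @param ns Namespace prefix (must be present in the namespace registry
#'   when the term is validated or serialized via parsing).
#' @param name Entity identifier, verbatim (unquoted form).
#' @return An object of class `bel_entity` or `bel_term`.
#' @examples
#' bel_term("p", list(bel_entity("HGNC", "CCL3")))
#' @export
bel_entity <- function(ns, name) {
  stopifnot(is.character(ns), length(ns) == 1L, is.character(name),
            length(name) == 1L, nchar(name) > 0L)
  structure(list(ns = ns, name = name), class = "bel_entity")
}

#' @rdname bel_entity
#' @param fun Function prefix, e.g. `"p"` or `"act"`.
#' @param args List of `bel_entity`, `bel_term`, or single character strings
#'   (plain qualifier tokens, only legal under pmod/tloc/sub/trunc/fus).
#' @export
bel_term <- function(fun, args) {
  stopifnot(is.character(fun), length(fun) == 1L, is.list(args),
            length(args) >= 1L)
  structure(list(fun = fun, args = args), class = "bel_term")
}

#' @export
print.bel_term <- function(x, ...) {
  cat("<bel_term> ", serialize_term(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.bel_entity <- function(x, ...) {
  cat("<bel_entity> ", x$ns, ":", quote_name(x$name), "\n", sep = "")
  invisible(x)
}

# ---- parser -----------------------------------------------------------------

#' Parse a BEL term
#'
#' Parses text such as `"act(p(HGNC:SIRT1))"` into a structured term.
#' Whitespace between tokens is ignored; quoted entity names are preserved
#' verbatim with the quotes stripped. The function prefix must appear in
#' the function registry and every entity must carry a namespace prefix
#' present in the namespace registry. Nesting is limited to depth 4.
#'
#' @param text A single BEL term as a string.
#' @param functions,namespaces Registries from [bel_functions()] /
#'   [bel_namespaces()]; defaults to the packaged tables.
#' @return A `bel_term`.
#' @examples
#' parse_term("p(HGNC:CCL3)")
#' parse_term("act( p( HGNC:SIRT1 ) )")
#' @export
parse_term <- function(text, functions = NULL, namespaces = NULL) {
  stopifnot(is.character(text), length(text) == 1L, nchar(text) > 0L)
  reg <- default_registries(functions, namespaces)
  toks <- tokenize_bel(text)
  st <- parse_term_at(toks, 1L, reg, depth = 1L)
  if (st$i <= toks$n) {
    abort(sprintf("syntax error at position %d: unexpected token '%s' after term",
                  toks$pos[st$i], toks$value[st$i]),
          class = "belnet_parse_error")
  }
  st$term
}

tok_at <- function(toks, i) {
  if (i > toks$n) NULL else list(value = toks$value[i], type = toks$type[i],
                                 pos = toks$pos[i])
}

abort_eoi <- function() {
  abort("syntax error at end-of-input: unexpected end of term",
        class = "belnet_parse_error")
}

parse_term_at <- function(toks, i, reg, depth) {
  if (depth > MAX_NESTING_DEPTH) {
    abort(sprintf("term nesting exceeds maximum depth %d", MAX_NESTING_DEPTH),
          class = "belnet_parse_error")
  }
  t1 <- tok_at(toks, i)
  if (is.null(t1)) abort_eoi()
  if (t1$type != "ident") {
    abort(sprintf("syntax error at position %d: expected function prefix, got '%s'",
                  t1$pos, t1$value), class = "belnet_parse_error")
  }
  if (!has_prefix(reg$functions, t1$value)) {
    abort(sprintf("unknown function prefix '%s' at position %d",
                  t1$value, t1$pos), class = "belnet_parse_error")
  }
  fun <- t1$value
  t2 <- tok_at(toks, i + 1L)
  if (is.null(t2)) abort_eoi()
  if (t2$value != "(") {
    abort(sprintf("syntax error at position %d: expected '(' after '%s'",
                  t2$pos, fun), class = "belnet_parse_error")
  }
  i <- i + 2L
  args <- list()
  repeat {
    t <- tok_at(toks, i)
    if (is.null(t)) abort_eoi()
    if (t$value == ")" && length(args) == 0L) {
      abort(sprintf("syntax error at position %d: empty argument list for '%s'",
                    t$pos, fun), class = "belnet_parse_error")
    }
    st <- parse_arg_at(toks, i, reg, fun, depth)
    args[[length(args) + 1L]] <- st$arg
    i <- st$i
    t <- tok_at(toks, i)
    if (is.null(t)) abort_eoi()
    if (t$value == ",") { i <- i + 1L; next }
    if (t$value == ")") { i <- i + 1L; break }
    abort(sprintf("syntax error at position %d: expected ',' or ')', got '%s'",
                  t$pos, t$value), class = "belnet_parse_error")
  }
  list(term = bel_term(fun, args), i = i)
}

parse_arg_at <- function(toks, i, reg, fun, depth) {
  t <- tok_at(toks, i)
  if (is.null(t)) abort_eoi()
  nxt <- tok_at(toks, i + 1L)
  # nested term: ident followed by '('
  if (t$type == "ident" && !is.null(nxt) && nxt$value == "(") {
    st <- parse_term_at(toks, i, reg, depth + 1L)
    return(list(arg = st$term, i = st$i))
  }
  if (t$type %in% c("ident", "quoted")) {
    if (!is.null(nxt) && nxt$value == ":") {
      ns_tok <- t
      name_tok <- tok_at(toks, i + 2L)
      if (is.null(name_tok)) abort_eoi()
      if (!name_tok$type %in% c("ident", "quoted")) {
        abort(sprintf("syntax error at position %d: expected entity name after ':'",
                      name_tok$pos), class = "belnet_parse_error")
      }
      if (ns_tok$type != "ident") {
        abort(sprintf("syntax error at position %d: namespace prefix may not be quoted",
                      ns_tok$pos), class = "belnet_parse_error")
      }
      if (!has_prefix(reg$namespaces, ns_tok$value)) {
        abort(sprintf("unknown namespace prefix '%s' at position %d",
                      ns_tok$value, ns_tok$pos), class = "belnet_parse_error")
      }
      name <- if (name_tok$type == "quoted") unquote_name(name_tok$value) else name_tok$value
      if (nchar(name) == 0L) {
        abort(sprintf("empty entity name at position %d", name_tok$pos),
              class = "belnet_parse_error")
      }
      return(list(arg = bel_entity(ns_tok$value, name), i = i + 3L))
    }
    # bare token without a namespace
    if (fun %in% QUALIFIER_FUNCTIONS) {
      val <- if (t$type == "quoted") unquote_name(t$value) else t$value
      return(list(arg = val, i = i + 1L))
    }
    abort(sprintf(
      "missing namespace for '%s' at position %d: every entity must be namespaced",
      t$value, t$pos), class = "belnet_parse_error")
  }
  abort(sprintf("syntax error at position %d: unexpected token '%s'",
                t$pos, t$value), class = "belnet_parse_error")
}

# ---- serialization & canonicalization --------------------------------------

#' Serialize a BEL term to canonical text
#'
#' Produces the deterministic canonical form: no whitespace, entity names
#' quoted only when they contain spaces, colons or other special
#' characters, and `complex`/`composite` arguments sorted lexicographically
#' (byte order) so that argument order never distinguishes two terms
#' denoting the same complex. All other functions keep their argument order
#' (pmod/tloc arguments are positional).
#'
#' @param term A `bel_term`.
#' @return A single string; `parse_term(serialize_term(t))` is structurally
#'   equal to the canonical form of `t`.
#' @examples
#' serialize_term(parse_term("act( p( HGNC:SIRT1 ) )"))
#' @export
serialize_term <- function(term) {
  stopifnot(inherits(term, "bel_term"))
  args <- vapply(term$args, serialize_arg, character(1))
  if (term$fun %in% c("complex", "composite")) {
    args <- sort(args, method = "radix")
  }
  paste0(term$fun, "(", paste(args, collapse = ","), ")")
}

serialize_arg <- function(a) {
  if (inherits(a, "bel_term")) return(serialize_term(a))
  if (inherits(a, "bel_entity")) return(paste0(a$ns, ":", quote_name(a$name)))
  if (is.character(a) && length(a) == 1L) return(quote_name(a))
  abort("invalid term argument")
}

#' Canonicalize a BEL term in place
#'
#' Reorders `complex`/`composite` arguments into canonical (lexicographic)
#' order recursively, returning a structurally canonical term. Serializing
#' and reparsing a term yields its canonical form automatically.
#'
#' @param term A `bel_term`.
#' @return The canonical `bel_term`.
#' @export
canonicalize_term <- function(term) {
  stopifnot(inherits(term, "bel_term"))
  args <- lapply(term$args, function(a) {
    if (inherits(a, "bel_term")) canonicalize_term(a) else a
  })
  if (term$fun %in% c("complex", "composite")) {
    keys <- vapply(args, serialize_arg, character(1))
    args <- args[order(keys, method = "radix")]
  }
  bel_term(term$fun, args)
}

#' Canonical node identity key
#'
#' The canonical key is the serialized canonical form of a term. Two terms
#' share a key exactly when they are structurally equal after
#' canonicalization; it is the identity used for node deduplication,
#' network merging and diffs.
#'
#' @param term A `bel_term`.
#' @return A single string.
#' @examples
#' canonical_key(parse_term('complex(p(HGNC:STAB2),p(HGNC:STAB1))'))
#' @export
canonical_key <- function(term) serialize_term(term)

# ---- statements -------------------------------------------------------------

#' Parse and serialize BEL statements
#'
#' A statement is `subject relation object` where the relation is one of
#' `increases`, `decreases` (causal) or `nonCausal` (e.g. a protein linked
#' to its own activity). Exactly one relation keyword must occur at the top
#' level; subject and object are full BEL terms. A causal statement may not
#' relate a term to itself.
#'
#' @param text Statement text.
#' @inheritParams parse_term
#' @return A `bel_statement` with fields `subject`, `relation`, `object`.
#' @examples
#' parse_statement("p(HGNC:XRCC6) decreases act(p(HGNC:BAX))")
#' @export
parse_statement <- function(text, functions = NULL, namespaces = NULL) {
  stopifnot(is.character(text), length(text) == 1L, nchar(text) > 0L)
  reg <- default_registries(functions, namespaces)
  toks <- tokenize_bel(text)
  depth <- 0L
  rel_idx <- integer(0)
  for (i in seq_len(toks$n)) {
    v <- toks$value[i]
    if (v == "(") depth <- depth + 1L
    else if (v == ")") depth <- depth - 1L
    else if (depth == 0L && toks$type[i] == "ident" && v %in% RELATION_CODES) {
      rel_idx <- c(rel_idx, i)
    }
  }
  if (length(rel_idx) == 0L) {
    abort("statement error: no relation keyword (increases/decreases/nonCausal) found",
          class = "belnet_parse_error")
  }
  if (length(rel_idx) > 1L) {
    abort(sprintf("statement error: %d relation keywords found, expected exactly one",
                  length(rel_idx)), class = "belnet_parse_error")
  }
  ri <- rel_idx[1]
  if (ri == 1L) {
    abort("statement error: missing subject term", class = "belnet_parse_error")
  }
  if (ri == toks$n) {
    abort("statement error: missing object term", class = "belnet_parse_error")
  }
  subj_toks <- lapply(toks[c("value", "type", "pos")], `[`, seq_len(ri - 1L))
  subj_toks$n <- ri - 1L
  obj_toks <- lapply(toks[c("value", "type", "pos")], `[`, seq(ri + 1L, toks$n))
  obj_toks$n <- toks$n - ri
  subject <- parse_whole_term(subj_toks, reg)
  object <- parse_whole_term(obj_toks, reg)
  bel_statement(subject, toks$value[ri], object)
}

parse_whole_term <- function(toks, reg) {
  st <- parse_term_at(toks, 1L, reg, depth = 1L)
  if (st$i <= toks$n) {
    abort(sprintf("syntax error at position %d: unexpected token '%s' after term",
                  toks$pos[st$i], toks$value[st$i]),
          class = "belnet_parse_error")
  }
  st$term
}

#' @rdname parse_statement
#' @param subject,object `bel_term`s.
#' @param relation One of `"increases"`, `"decreases"`, `"nonCausal"`.
#' @export
bel_statement <- function(subject, relation, object) {
  stopifnot(inherits(subject, "bel_term"), inherits(object, "bel_term"))
  if (!relation %in% RELATION_CODES) {
    abort(sprintf("unknown relation '%s'", relation), class = "belnet_parse_error")
  }
  if (relation %in% CAUSAL_RELATIONS &&
      identical(canonical_key(subject), canonical_key(object))) {
    abort("a causal statement may not relate a term to itself",
          class = "belnet_parse_error")
  }
  structure(list(subject = subject, relation = relation, object = object),
            class = "bel_statement")
}

#' @rdname parse_statement
#' @param statement A `bel_statement`.
#' @export
serialize_statement <- function(statement) {
  stopifnot(inherits(statement, "bel_statement"))
  paste(serialize_term(statement$subject), statement$relation,
        serialize_term(statement$object))
}

#' @export
print.bel_statement <- function(x, ...) {
  cat("<bel_statement> ", serialize_statement(x), "\n", sep = "")
  invisible(x)
}

statement_key <- function(statement) serialize_statement(statement)
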