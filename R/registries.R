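#' BEL function and namespace registries
#'
#' The dialect understood by this package restricts BEL terms to a closed
#' set of function prefixes (protein abundance `p`, molecular activity
#' `act`, biological process `bp`, ...) and a closed set of namespace
#' prefixes (HGNC, EGID, CHEBI, GO, ...). Both registries ship as packaged
#' two-column tables and can be extended or replaced from a user-supplied
#' TSV, so a new namespace can be adopted without a code change.
#'
#' @param file Optional path to a two-column TSV (`prefix`, `description`)
#'   replacing the packaged table.
#' @return A tibble with columns `prefix` and `description`, of class
#'   `bel_registry`. Prefixes are unique and case-sensitive.
#' @examples
#' bel_functions()
#' bel_namespaces()
#' @export
bel_functions <- function(file = NULL) {
  read_registry(file %||% system.file("extdata", "bel_functions.tsv",
                                      package = "belnet"))
}

#' @rdname bel_functions
#' @export
bel_namespaces <- function(file = NULL) {
  read_registry(file %||% system.file("extdata", "bel_namespaces.tsv",
                                      package = "belnet"))
}

read_registry <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  if (!identical(names(df), c("prefix", "description"))) {
    rlang::abort("registry file must have columns 'prefix' and 'description'")
  }
  if (anyDuplicated(df$prefix)) {
    rlang::abort(paste0("duplicate registry prefix: ",
                        df$prefix[duplicated(df$prefix)][1]))
  }
  structure(tibble::as_tibble(df), class = c("bel_registry", class(tibble::tibble())))
}

#' Extend a registry with additional prefixes
#'
#' @param registry A registry from [bel_functions()] or [bel_namespaces()].
#' @param prefix,description Character vectors of equal length.
#' @return The extended registry; duplicate prefixes are rejected.
#' @export
registry_extend <- function(registry, prefix, description) {
  stopifnot(inherits(registry, "bel_registry"), length(prefix) == length(description))
  out <- dplyr::bind_rows(registry,
                          tibble::tibble(prefix = as.character(prefix),
                                         description = as.character(description)))
  if (anyDuplicated(out$prefix)) {
    rlang::abort(paste0("duplicate registry prefix: ",
                        out$prefix[duplicated(out$prefix)][1]))
  }
  structure(out, class = class(registry))
}

has_prefix <- function(registry, prefix) prefix %in% registry$prefix

# Packaged default registries are cached for the session; a user-extended
# registry can always be passed through explicitly.
.registry_cache <- new.env(parent = emptyenv())

default_registries <- function(functions = NULL, namespaces = NULL) {
  if (is.null(functions)) {
    if (is.null(.registry_cache$functions)) {
      .registry_cache$functions <- bel_functions()
    }
    functions <- .registry_cache$functions
  }
  if (is.null(namespaces)) {
    if (is.null(.registry_cache$namespaces)) {
      .registry_cache$namespaces <- bel_namespaces()
    }
    namespaces <- .registry_cache$namespaces
  }
  list(functions = functions, namespaces = namespaces)
}
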