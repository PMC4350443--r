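#' Boundary conditions for evidence inclusion
#'
#' Curation of an early-disease network restricts which experimental
#' contexts may support an edge: evidence from diseases with a different
#' pathogenesis, from excluded in-vitro cell systems (tumor-derived or
#' immortalized lines, neuronal cells), or from solid-particle inhalation
#' exposures is rejected; human evidence is prioritized, and rodent
#' evidence is admissible only when homologization is enabled, in which
#' case it is accepted with a `homologized` annotation.
#'
#' @param allowed_species Species accepted outright; `"human"` is always
#'   included.
#' @param homologized_species Species accepted only with homologization.
#' @param homologization Whether homologized species are admissible.
#' @param excluded_diseases,excluded_cell_systems,excluded_exposures
#'   Exclusion lists matched case-insensitively against the evidence
#'   context (exact string match; no ontology expansion).
#' @return A `boundary_config` object.
#' @examples
#' cfg <- boundary_config(
#'   excluded_diseases = c("lung cancer", "asthma"),
#'   excluded_cell_systems = c("tumor-derived cell line", "neuronal cells"),
#'   excluded_exposures = c("titanium dioxide", "asbestos"))
#' apply_boundary_filter(
#'   evidence("1", "x", context = c(cell_type = "tumor-derived cell line")), cfg)
#' @export
boundary_config <- function(allowed_species = "human",
                            homologized_species = c("mouse", "rat"),
                            homologization = TRUE,
                            excluded_diseases = character(),
                            excluded_cell_systems = character(),
                            excluded_exposures = character()) {
  allowed_species <- union("human", tolower(allowed_species))
  structure(list(allowed_species = allowed_species,
                 homologized_species = tolower(homologized_species),
                 homologization = isTRUE(homologization),
                 excluded_diseases = tolower(excluded_diseases),
                 excluded_cell_systems = tolower(excluded_cell_systems),
                 excluded_exposures = tolower(excluded_exposures)),
            class = "boundary_config")
}

#' Read a boundary configuration from a key/list file
#'
#' The file format is `key: value, value, ...` per line with the keys of
#' [boundary_config()]; `homologization` takes `true`/`false`. Blank lines
#' and `#` comments are ignored.
#'
#' @param path File path.
#' @return A `boundary_config`.
#' @export
read_boundary_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      abort(paste0("boundary config line without ':': ", ln))
    }
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(strsplit(sub("^[^:]*:", "", ln), ",")[[1]])
    val <- val[nzchar(val)]
    if (key == "homologization") {
      args[[key]] <- tolower(val[1]) %in% c("true", "yes", "1")
    } else {
      args[[key]] <- val
    }
  }
  bad <- setdiff(names(args), names(formals(boundary_config)))
  if (length(bad)) abort(paste0("unknown boundary config key(s): ",
                                paste(bad, collapse = ", ")))
  do.call(boundary_config, args)
}

#' Apply the boundary filter to evidence
#'
#' Exclusion rules are checked in a fixed order — disease, cell system,
#' exposure, species — and the decision reports the first rule matched.
#' Context fields absent from the evidence are unconstrained and pass.
#' The filter is deterministic and idempotent: accept and reject partition
#' any evidence set.
#'
#' @param ev A [evidence()] record (or a bare named context vector).
#' @param config A [boundary_config()].
#' @return A one-row tibble with columns `decision` (`"accept"`/`"reject"`),
#'   `reason` (the matched exclusion rule or `NA`), and `annotation`
#'   (`"homologized"` when rodent evidence is admitted by homologization).
#' @export
apply_boundary_filter <- function(ev, config) {
  stopifnot(inherits(config, "boundary_config"))
  ctx <- if (inherits(ev, "bel_evidence")) ev$context else ev
  ctx <- if (length(ctx)) stats::setNames(tolower(ctx), names(ctx)) else character()
  get <- function(field) if (field %in% names(ctx)) ctx[[field]] else NA_character_
  reject <- function(reason) {
    tibble::tibble(decision = "reject", reason = reason,
                   annotation = NA_character_)
  }
  disease <- get("disease")
  if (!is.na(disease) && disease %in% config$excluded_diseases) {
    return(reject("excluded_disease"))
  }
  cell <- get("cell_type")
  if (!is.na(cell) && cell %in% config$excluded_cell_systems) {
    return(reject("excluded_cell_system"))
  }
  exposure <- get("exposure")
  if (!is.na(exposure) && exposure %in% config$excluded_exposures) {
    return(reject("excluded_exposure"))
  }
  species <- get("species")
  if (!is.na(species) && !species %in% config$allowed_species) {
    if (config$homologization && species %in% config$homologized_species) {
      return(tibble::tibble(decision = "accept", reason = NA_character_,
                            annotation = "homologized"))
    }
    return(reject("excluded_species"))
  }
  tibble::tibble(decision = "accept", reason = NA_character_,
                 annotation = NA_character_)
}

#' @rdname apply_boundary_filter
#' @param network A `bel_network`; every evidence is filtered and the
#'   result joined onto [evidence_table()] rows.
#' @return For `filter_network_evidence()`: the evidence table with
#'   `decision`, `reason` and `annotation` columns appended.
#' @export
filter_network_evidence <- function(network, config) {
  tab <- evidence_table(network)
  if (!nrow(tab)) {
    return(dplyr::mutate(tab, decision = character(), reason = character(),
                         annotation = character()))
  }
  dec <- purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    ctx <- unlist(tab[i, CONTEXT_FIELDS])
    ctx <- ctx[!is.na(ctx)]
    names(ctx) <- sub("^.*\\.", "", names(ctx))
    apply_boundary_filter(ctx, config)
  })
  dplyr::bind_cols(tab, dec)
}
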