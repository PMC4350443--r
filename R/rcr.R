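#' State-change selection thresholds
#'
#' Defaults follow the enhancement protocol for the disease data sets:
#' a gene is a state change when its FDR-adjusted p-value is below 0.05,
#' its absolute linear fold change is at least 1.3, and its mean
#' expression is at least 100 (intensity units of the array platform).
#' The FDR cutoff is strict (`<`); fold change and expression are
#' inclusive (`>=`).
#'
#' @param fdr_max Maximum FDR-adjusted p-value (exclusive), in (0, 1].
#' @param fc_min Minimum absolute linear fold change (inclusive), >= 1.
#' @param expr_min Minimum mean expression (inclusive), >= 0.
#' @param log2_fc If `TRUE`, input fold changes are log2-scale and are
#'   converted to signed linear ratios before thresholding.
#' @return An `sc_thresholds` object.
#' @export
sc_thresholds <- function(fdr_max = 0.05, fc_min = 1.3, expr_min = 100,
                          log2_fc = FALSE) {
  stopifnot(fdr_max > 0, fdr_max <= 1, fc_min >= 1, expr_min >= 0)
  structure(list(fdr_max = fdr_max, fc_min = fc_min, expr_min = expr_min,
                 log2_fc = isTRUE(log2_fc)),
            class = "sc_thresholds")
}

#' Reverse-causal-reasoning configuration
#'
#' @param thresholds An [sc_thresholds()].
#' @param richness_max Richness p-value cutoff (exclusive), default 0.1.
#' @param concordance_max Concordance p-value cutoff (exclusive), default
#'   0.1. No multiple-testing correction is applied across hypotheses;
#'   the cutoffs are raw.
#' @param universe_policy `"measured_genes"` (all genes in the expression
#'   table; the default, since state-change rates are platform-dependent)
#'   or `"kb_covered_genes"` (only genes downstream of some hypothesis;
#'   offered for sensitivity analysis).
#' @return An `rcr_config` object.
#' @export
rcr_config <- function(thresholds = sc_thresholds(), richness_max = 0.1,
                       concordance_max = 0.1,
                       universe_policy = c("measured_genes", "kb_covered_genes")) {
  stopifnot(inherits(thresholds, "sc_thresholds"),
            richness_max > 0, richness_max <= 1,
            concordance_max > 0, concordance_max <= 1)
  structure(list(thresholds = thresholds, richness_max = richness_max,
                 concordance_max = concordance_max,
                 universe_policy = match.arg(universe_policy)),
            class = "rcr_config")
}

#' Select state changes from a differential-expression table
#'
#' A pure filter over the expression rows: a gene passes when
#' `fdr_p < fdr_max`, `|fold_change| >= fc_min` and
#' `mean_expression >= expr_min`; its direction is the sign of the fold
#' change. Output order follows input order.
#'
#' @param rows Tibble/data frame with columns `gene_ns`, `gene_id`,
#'   `fold_change`, `fdr_p`, `mean_expression`; one row per gene.
#' @param thresholds An [sc_thresholds()].
#' @return A tibble with columns `gene_ns`, `gene_id`, `gene`
#'   (namespace:id key) and `direction` (`"up"`/`"down"`).
#' @examples
#' rows <- tibble::tibble(gene_ns = "HGNC", gene_id = c("CCL3", "IL3"),
#'                        fold_change = c(1.3, -5), fdr_p = c(0.049, 0.2),
#'                        mean_expression = c(100, 500))
#' select_state_changes(rows, sc_thresholds())
#' @export
select_state_changes <- function(rows, thresholds = sc_thresholds()) {
  stopifnot(inherits(thresholds, "sc_thresholds"))
  required <- c("gene_ns", "gene_id", "fold_change", "fdr_p", "mean_expression")
  missing <- setdiff(required, names(rows))
  if (length(missing)) {
    abort(paste0("expression table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  key <- paste0(rows$gene_ns, ":", rows$gene_id)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate gene in expression table: ",
                 key[duplicated(key)][1]))
  }
  num <- c(rows$fold_change, rows$fdr_p, rows$mean_expression)
  if (any(!is.finite(num))) abort("non-finite value in expression table")
  if (any(rows$fdr_p < 0 | rows$fdr_p > 1)) abort("fdr_p outside [0, 1]")
  fc <- rows$fold_change
  if (thresholds$log2_fc) {
    fc <- sign(fc) * 2^abs(fc)
  }
  if (any(fc == 0)) abort("fold_change of 0 is not a valid ratio")
  pass <- rows$fdr_p < thresholds$fdr_max &
    abs(fc) >= thresholds$fc_min &
    rows$mean_expression >= thresholds$expr_min
  tibble::tibble(gene_ns = rows$gene_ns[pass], gene_id = rows$gene_id[pass],
                 gene = key[pass],
                 direction = ifelse(fc[pass] > 0, "up", "down"))
}

#' Richness p-value (hypergeometric upper tail)
#'
#' Probability that a hypothesis with `m` downstream genes in a universe
#' of `N` measured genes overlaps at least `k` of the `n` observed state
#' changes by chance: `P(X >= k)` for `X ~ Hypergeometric(N, m, n)`.
#' Returns 1 when `k = 0`.
#'
#' @param k Observed overlap count.
#' @param n Number of state changes.
#' @param m Hypothesis downstream-set size.
#' @param N Universe size. Requires `0 <= k <= min(n, m) <= N`.
#' @return The upper-tail p-value; vectorized over its arguments.
#' @examples
#' richness_p(4, 6, 5, 20)
#' @export
richness_p <- function(k, n, m, N) {
  if (any(k < 0 | n < 0 | m < 0 | N < 0 | k > pmin(n, m) | n > N | m > N)) {
    abort("richness_p bounds violated: need 0 <= k <= min(n, m) <= N")
  }
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Concordance p-value (binomial upper tail, fair-coin null)
#'
#' Probability of observing at least `c` direction-concordant genes among
#' `k` overlapping genes when each agrees with probability 1/2:
#' `P(X >= c)` for `X ~ Binomial(k, 0.5)`. Returns 1 when `k = 0`.
#'
#' @param c Concordant count.
#' @param k Overlap count. Requires `0 <= c <= k`.
#' @return The upper-tail p-value; vectorized.
#' @examples
#' concordance_p(4, 4)  # 0.0625
#' @export
concordance_p <- function(c, k) {
  if (any(c < 0 | k < 0 | c > k)) {
    abort("concordance_p bounds violated: need 0 <= c <= k")
  }
  stats::pbinom(c - 1, k, 0.5, lower.tail = FALSE)
}

#' Score candidate upstream mechanisms against state changes
#'
#' Every hypothesis (HYP) in the knowledgebase is scored: its downstream
#' genes are intersected with the universe, the overlap with the state
#' changes gives the richness (hypergeometric) tail, and the number of
#' overlapping genes whose observed direction matches the predicted sign
#' gives the concordance (binomial) tail. Hypotheses pass when
#' `richness_p < richness_max` and `concordance_p < concordance_max`.
#' Downstream genes listed with both signs under one hypothesis are
#' contradictory and dropped from that hypothesis (with a warning giving
#' the count).
#'
#' @param kb Knowledgebase tibble with columns `upstream` (BEL term text),
#'   `gene_ns`, `gene_id`, `sign` (`"+"`/`"-"`).
#' @param scs State changes from [select_state_changes()].
#' @param universe Character vector of `ns:id` gene keys, or an expression
#'   table (its genes are used). Under policy `kb_covered_genes` the
#'   universe is restricted to genes downstream of some hypothesis.
#' @param config An [rcr_config()].
#' @param significant_only If `FALSE`, return all scored hypotheses with a
#'   `significant` column instead of filtering.
#' @return A tibble with columns `upstream` (canonical key), `overlap_k`,
#'   `concordant_c`, `discordant_d`, `richness_p`, `concordance_p`,
#'   `net_direction`, sorted by richness then concordance then upstream
#'   key (deterministic tie order).
#' @export
evaluate_hyps <- function(kb, scs, universe, config = rcr_config(),
                          significant_only = TRUE) {
  stopifnot(inherits(config, "rcr_config"))
  required <- c("upstream", "gene_ns", "gene_id", "sign")
  missing <- setdiff(required, names(kb))
  if (length(missing)) {
    abort(paste0("knowledgebase lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(kb$sign %in% c("+", "-"))) abort("kb sign must be '+' or '-'")
  if (is.data.frame(universe)) {
    universe <- paste0(universe$gene_ns, ":", universe$gene_id)
  }
  universe <- unique(as.character(universe))
  kb <- tibble::tibble(upstream = kb$upstream,
                       gene = paste0(kb$gene_ns, ":", kb$gene_id),
                       sign = kb$sign) |>
    dplyr::distinct()
  # canonicalize upstream terms once per distinct text
  ups <- unique(kb$upstream)
  canon <- vapply(ups, function(u) canonical_key(parse_term(u)), character(1))
  kb$upstream <- unname(canon[kb$upstream])
  # drop contradictory (both-sign) downstream entries
  contradictory <- kb |>
    dplyr::count(.data$upstream, .data$gene) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(contradictory)) {
    warn(sprintf("dropped %d contradictory downstream entr%s (gene with both signs under one hypothesis)",
                 nrow(contradictory), if (nrow(contradictory) == 1L) "y" else "ies"))
    kb <- dplyr::anti_join(kb, contradictory, by = c("upstream", "gene"))
  }
  if (config$universe_policy == "kb_covered_genes") {
    universe <- intersect(universe, unique(kb$gene))
  }
  if (length(universe) == 0L) abort("empty gene universe")
  kb <- kb[kb$gene %in% universe, , drop = FALSE]
  sc_dir <- stats::setNames(scs$direction, scs$gene)
  sc_dir <- sc_dir[names(sc_dir) %in% universe]
  n <- length(sc_dir)
  N <- length(universe)
  scores <- kb |>
    dplyr::group_by(.data$upstream) |>
    dplyr::summarise(
      m = dplyr::n(),
      overlap_k = sum(.data$gene %in% names(sc_dir)),
      concordant_c = sum((.data$sign == "+" &
                            sc_dir[.data$gene] == "up") |
                           (.data$sign == "-" &
                              sc_dir[.data$gene] == "down"), na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      discordant_d = .data$overlap_k - .data$concordant_c,
      richness_p = richness_p(.data$overlap_k, n, .data$m, N),
      concordance_p = concordance_p(.data$concordant_c, .data$overlap_k),
      net_direction = ifelse(.data$concordant_c >= .data$discordant_d,
                             "up", "down"),
      significant = .data$richness_p < config$richness_max &
        .data$concordance_p < config$concordance_max) |>
    dplyr::arrange(.data$richness_p, .data$concordance_p,
                   .data$upstream) |>
    dplyr::select("upstream", "overlap_k", "concordant_c", "discordant_d",
                  "richness_p", "concordance_p", "net_direction",
                  "significant")
  if (significant_only) {
    scores <- dplyr::filter(scores, .data$significant) |>
      dplyr::select(-"significant")
  }
  scores
}

#' Propose candidate edges from significant mechanisms
#'
#' For each significant hypothesis whose upstream term is not already a
#' node of the network, a candidate edge is proposed connecting the
#' upstream term to a caller-designated anchor process node, with relation
#' `increases` when the mechanism's net predicted direction is up and
#' `decreases` otherwise. Candidates carry phase-1 RCR provenance and an
#' open synthesized evidence record; they are flagged for human curation
#' and never merged automatically.
#'
#' @param network A `bel_network`.
#' @param scores Significant scores from [evaluate_hyps()].
#' @param anchor Canonical key (or `bel_term`) of the anchor process node;
#'   must already exist in the network.
#' @return A tibble of candidates: `upstream`, `relation`, `anchor`,
#'   `statement`, `richness_p`, `concordance_p`, and a list-column `edge`
#'   holding the ready-to-curate edge record.
#' @export
propose_enhancements <- function(network, scores, anchor) {
  stopifnot(inherits(network, "bel_network"))
  if (inherits(anchor, "bel_term")) anchor <- canonical_key(anchor)
  if (!anchor %in% names(network$nodes)) {
    abort(paste0("anchor node not present in network: ", anchor))
  }
  if (!nrow(scores)) {
    return(tibble::tibble(upstream = character(), relation = character(),
                          anchor = character(), statement = character(),
                          richness_p = double(), concordance_p = double(),
                          edge = list()))
  }
  novel <- !scores$upstream %in% names(network$nodes)
  scores <- scores[novel, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(scores)), function(i) {
    rel <- if (scores$net_direction[i] == "up") "increases" else "decreases"
    stmt_text <- paste(scores$upstream[i], rel, anchor)
    stmt <- parse_statement(stmt_text)
    ev <- evidence(
      citation = "RCR",
      quote = sprintf("mechanism %s predicted (richness p=%.3g, concordance p=%.3g)",
                      scores$upstream[i], scores$richness_p[i],
                      scores$concordance_p[i]),
      id = paste0("rcr:", scores$upstream[i]),
      status = "open")
    tibble::tibble(upstream = scores$upstream[i], relation = rel,
                   anchor = anchor, statement = stmt_text,
                   richness_p = scores$richness_p[i],
                   concordance_p = scores$concordance_p[i],
                   edge = list(list(statement = stmt, evidences = list(ev),
                                    provenance = provenance("phase1_rcr",
                                                            actor = "rcr"))))
  })
}

#' Read/write the RCR file formats
#'
#' Expression tables are TSV with columns `gene_ns`, `gene_id`,
#' `fold_change`, `fdr_p`, `mean_expression`; knowledgebase files are TSV
#' with `upstream` (BEL term text), `gene` (`namespace:id`) and `sign`
#' (`+`/`-`); hypothesis scores are written as TSV.
#'
#' @param path File path.
#' @return A tibble (readers) or the path invisibly (writer).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(gene_ns = "character",
                                         gene_id = "character"))
  tibble::as_tibble(df)
}

#' @rdname read_expression_tsv
#' @export
read_kb_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  stopifnot(all(c("upstream", "gene", "sign") %in% names(df)))
  parts <- strsplit(df$gene, ":", fixed = TRUE)
  tibble::tibble(upstream = df$upstream,
                 gene_ns = vapply(parts, `[`, character(1), 1L),
                 gene_id = vapply(parts, function(p)
                   paste(p[-1], collapse = ":"), character(1)),
                 sign = df$sign)
}

#' @rdname read_expression_tsv
#' @param scores A score tibble from [evaluate_hyps()].
#' @export
write_hyp_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot hypothesis scores
#'
#' Scatter of -log10 richness vs -log10 concordance p-values with the
#' cutoff lines; significant mechanisms fall in the upper-right region.
#'
#' @param scores Scores from [evaluate_hyps()] (with
#'   `significant_only = FALSE` to see the full field).
#' @param config The [rcr_config()] whose cutoffs to draw.
#' @return A ggplot object.
#' @export
plot_hyp_scores <- function(scores, config = rcr_config()) {
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = -log10(.data$richness_p),
                               y = -log10(.data$concordance_p))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = -log10(config$richness_max),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(config$concordance_max),
                        linetype = "dashed") +
    ggplot2::labs(x = "-log10 richness p", y = "-log10 concordance p")
}
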