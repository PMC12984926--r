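#' Read annotation edge, expression label and gene-set tables
#'
#' Annotation edges link partner proteins to the anchor kinase:
#' `edge_type` is one of `kinase_of`, `substrate_of`, `binary_interactor`,
#' `complex_interactor`, with a free-text `evidence` provenance tag and an
#' optional site-specific `site` column (e.g. `"S241"`). Expression labels
#' carry a per-protein `direction` (`up`/`down`) in some disease `context`
#' plus optional semicolon-separated `activity_sites`. Gene sets use the GMT
#' dialect: one set per line, `set_id <TAB> description <TAB> member...`.
#'
#' @param path Path to the file.
#' @return `read_annotation_edges()` and `read_expression_labels()` return
#'   tibbles; `read_gmt()` returns a named list of character vectors.
#' @export
read_annotation_edges <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  req <- c("source", "target", "edge_type", "evidence")
  if (!all(req %in% names(tbl))) {
    abort(paste0("Annotation edge table needs columns: ", paste(req, collapse = ", ")))
  }
  ok <- tbl$edge_type %in% c("kinase_of", "substrate_of",
                             "binary_interactor", "complex_interactor")
  if (!all(ok)) {
    abort(paste0("Unknown edge_type value(s): ",
                 paste(unique(tbl$edge_type[!ok]), collapse = ", ")))
  }
  if (any(is.na(tbl$evidence) | tbl$evidence == "")) {
    abort("Every annotation edge must carry a non-empty evidence tag.")
  }
  if (!"site" %in% names(tbl)) tbl$site <- NA_character_
  tbl
}

#' @rdname read_annotation_edges
#' @export
read_expression_labels <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  req <- c("protein", "direction", "context")
  if (!all(req %in% names(tbl))) {
    abort(paste0("Expression label table needs columns: ", paste(req, collapse = ", ")))
  }
  if (!all(tbl$direction %in% c("up", "down"))) {
    abort("Expression label direction must be 'up' or 'down'.")
  }
  if (!"activity_sites" %in% names(tbl)) tbl$activity_sites <- NA_character_
  tbl
}

#' @rdname read_annotation_edges
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nchar(trimws(lines)) > 0]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort("GMT lines need set_id, description and >= 1 member.")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Overlay annotation edges onto co-regulation calls
#'
#' Attaches, to every screened partner, the types of annotation edges linking
#' its protein to the anchor protein (in either orientation). No call is
#' dropped; partners with no edge get an empty annotation.
#'
#' @param calls A [coregulation_screen()] result (or its [tidy()] tibble).
#' @param edges An annotation edge tibble (see [read_annotation_edges()]).
#' @param anchor_protein The anchor's protein symbol; defaults to the
#'   screen's anchor.
#' @return `calls` with `edge_types` (semicolon-joined, `""` when none) and
#'   `edge_evidence` columns added; row count unchanged.
#' @export
overlay_annotations <- function(calls, edges,
                                anchor_protein = NULL) {
  if (is.null(anchor_protein)) {
    anchor <- attr(calls, "anchor")
    if (is.null(anchor)) abort("anchor_protein not given and calls carry no anchor.")
    anchor_protein <- parse_site_id(anchor)$protein
  }
  if (is.null(edges) || nrow(edges) == 0) {
    calls$edge_types <- ""
    calls$edge_evidence <- ""
    return(calls)
  }
  rel <- edges[edges$source == anchor_protein | edges$target == anchor_protein, ,
               drop = FALSE]
  rel$partner_protein <- ifelse(rel$source == anchor_protein, rel$target, rel$source)
  agg <- rel |>
    dplyr::group_by(.data$partner_protein) |>
    dplyr::summarise(
      edge_types = paste(sort(unique(.data$edge_type)), collapse = ";"),
      edge_evidence = paste(sort(unique(.data$evidence)), collapse = ";"),
      .groups = "drop"
    )
  i <- match(calls$protein, agg$partner_protein)
  calls$edge_types <- ifelse(is.na(i), "", agg$edge_types[i])
  calls$edge_evidence <- ifelse(is.na(i), "", agg$edge_evidence[i])
  calls
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query proteins overlap it more than
#' expected under sampling without replacement from the universe:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' universe size, `K` the in-universe set size, `n` the query size and `k`
#' the observed overlap. Gene sets are intersected with the universe first;
#' the query must be a subset of the universe.
#'
#' @param query Character vector of query proteins.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector, the background protein universe.
#' @param adjust Add a BH-adjusted `p_adj` column.
#' @return A tibble sorted by `p`: `gene_set_id`, `universe_size`,
#'   `set_size`, `query_size`, `overlap`, `p` (and `p_adj`).
#' @export
hypergeometric_ora <- function(query, gene_sets, universe, adjust = TRUE) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("Empty universe.")
  query <- unique(query)
  if (!all(query %in% universe)) {
    abort("Query proteins must all be members of the universe.")
  }
  res <- purrr::imap_dfr(gene_sets, function(set, id) {
    set <- intersect(unique(set), universe)
    k <- length(intersect(query, set))
    tibble(
      gene_set_id = id,
      universe_size = length(universe),
      set_size = length(set),
      query_size = length(query),
      overlap = k,
      p = hyper_upper_tail(k, length(set), length(query), length(universe))
    )
  })
  if (adjust && nrow(res) > 0) res$p_adj <- p.adjust(res$p, method = "BH")
  dplyr::arrange(res, .data$p, .data$gene_set_id)
}
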