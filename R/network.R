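#' Build the annotated co-regulation network
#'
#' Nodes are the anchor phosphosite plus every partner site passing the
#' confidence filters; node attributes carry the protein, residue, position,
#' disease expression direction and the activity-associated flag (from the
#' label table). Edges are the signed co-regulation links (`pos_coreg` /
#' `neg_coreg`, with the FET p and supporting count as attributes) plus any
#' typed annotation edges between the partner's protein and the anchor
#' protein. Node order is deterministic: anchor first, partners sorted by
#' site id.
#'
#' @param calls A [coregulation_screen()] result.
#' @param edges Optional annotation edge tibble ([read_annotation_edges()]).
#' @param labels Optional expression label tibble
#'   ([read_expression_labels()]).
#' @param anchor Anchor site id; defaults to the screen's anchor attribute.
#' @param passing_only Keep only filter-passing calls (default `TRUE`).
#' @return An [igraph::graph] object.
#' @export
build_network <- function(calls, edges = NULL, labels = NULL,
                          anchor = attr(calls, "anchor"),
                          passing_only = TRUE) {
  if (is.null(anchor)) abort("anchor not given and calls carry no anchor.")
  anchor_protein <- parse_site_id(anchor)$protein
  df <- as_tibble(tidy_if_screen(calls))
  if (passing_only && nrow(df) > 0) df <- df[df$passes_filters, , drop = FALSE]
  df <- df[order(df$partner), , drop = FALSE]

  ap <- parse_site_id(anchor)
  nodes <- tibble(
    name = c(anchor, df$partner),
    protein = c(ap$protein, df$protein),
    residue = c(ap$residue, df$residue),
    position = c(ap$position, df$position),
    is_anchor = c(TRUE, rep(FALSE, nrow(df)))
  )
  nodes$expression <- NA_character_
  nodes$activity_associated <- FALSE
  if (!is.null(labels) && nrow(labels) > 0) {
    i <- match(nodes$protein, labels$protein)
    nodes$expression <- labels$direction[i]
    acts <- strsplit(tidyr::replace_na(labels$activity_sites[i], ""), ";", fixed = TRUE)
    site_str <- paste0(nodes$residue, nodes$position)
    nodes$activity_associated <- purrr::map2_lgl(acts, site_str,
                                                 ~ .y %in% trimws(.x))
  }

  edge_df <- tibble(
    from = rep(anchor, nrow(df)),
    to = df$partner,
    type = ifelse(df$direction == "negative", "neg_coreg", "pos_coreg"),
    evidence = "coregulation_screen",
    fet_p = df$fet_p,
    supporting = as.numeric(df$supporting)
  )
  if (!is.null(edges) && nrow(edges) > 0) {
    rel <- edges[edges$source == anchor_protein | edges$target == anchor_protein, ,
                 drop = FALSE]
    rel$partner_protein <- ifelse(rel$source == anchor_protein, rel$target, rel$source)
    hit <- dplyr::inner_join(
      tibble(partner = df$partner, partner_protein = df$protein),
      rel, by = "partner_protein", relationship = "many-to-many"
    )
    if (nrow(hit) > 0) {
      ann <- tibble(
        from = rep(anchor, nrow(hit)),
        to = hit$partner,
        type = hit$edge_type,
        evidence = hit$evidence,
        fet_p = NA_real_,
        supporting = NA_real_
      ) |> dplyr::distinct()
      edge_df <- dplyr::bind_rows(edge_df, ann)
    }
  }
  edge_df <- dplyr::arrange(edge_df, .data$from, .data$to, .data$type)
  igraph::graph_from_data_frame(edge_df, directed = FALSE, vertices = nodes)
}

tidy_if_screen <- function(x) {
  if (inherits(x, "coregulation_screen")) tidy(x) else x
}

#' Export and import co-regulation networks
#'
#' `export_network()` writes a built network as SIF (three-token interaction
#' lines), edge TSV (all edge attributes, canonically sorted) or GraphML
#' (via [igraph::write_graph()]). `import_edge_tsv()` rebuilds a graph from
#' an edge TSV so edge-table exports round-trip.
#'
#' @param network An igraph object from [build_network()].
#' @param path Output file path.
#' @param format One of `"sif"`, `"edge_tsv"`, `"graphml"`.
#' @return `path`, invisibly; `import_edge_tsv()` returns an igraph object.
#' @export
export_network <- function(network, path, format = c("sif", "edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    el <- igraph::as_data_frame(network, what = "edges")
    lines <- if (nrow(el) > 0) {
      el <- el[order(el$from, el$to, el$type), , drop = FALSE]
      paste(el$from, el$type, el$to, sep = "\t")
    } else character(0)
    writeLines(lines, path)
  } else if (format == "edge_tsv") {
    el <- as_tibble(igraph::as_data_frame(network, what = "edges"))
    el <- dplyr::arrange(el, .data$from, .data$to, .data$type)
    # fixed 15-significant-digit formatting so re-imported exports are
    # byte-identical (shortest-representation writers are not idempotent
    # under parse/write cycles)
    el <- dplyr::mutate(el, dplyr::across(
      dplyr::where(is.numeric), ~ ifelse(is.na(.x), NA, sprintf("%.15g", .x))))
    readr::write_tsv(el, path)
  } else {
    igraph::write_graph(network, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_edge_tsv <- function(path) {
  el <- readr::read_tsv(path, col_types = readr::cols(
    from = readr::col_character(), to = readr::col_character(),
    type = readr::col_character(), evidence = readr::col_character(),
    .default = readr::col_double()
  ))
  igraph::graph_from_data_frame(el, directed = FALSE)
}
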