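#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one structure:
#' the differential-record thresholds, the co-regulation confidence
#' criteria, the predominance selection parameters and the conservation
#' parameters. Unknown keys are rejected. A resolved configuration (defaults
#' merged with overrides) is echoed to the output directory by
#' [run_pipeline()] so any run can be reproduced from its own output.
#'
#' @param thresholds A [differential_thresholds()] object.
#' @param criteria A [confidence_criteria()] object.
#' @param min_fraction,top_k Predominance selection (see
#'   [select_predominant()]).
#' @param window_radius,mixing_weight,conservation_threshold Conservation
#'   scoring (see [conservation_score()]).
#' @param include_same_protein,adjust_p Screen options (see
#'   [coregulation_screen()]).
#' @param seed Seed recorded for provenance.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(thresholds = differential_thresholds(),
                            criteria = confidence_criteria(),
                            min_fraction = 0, top_k = 2,
                            window_radius = 5, mixing_weight = 0.5,
                            conservation_threshold = 0.75,
                            include_same_protein = FALSE,
                            adjust_p = FALSE,
                            seed = 1L) {
  structure(
    list(thresholds = thresholds, criteria = criteria,
         min_fraction = min_fraction, top_k = top_k,
         window_radius = window_radius, mixing_weight = mixing_weight,
         conservation_threshold = conservation_threshold,
         include_same_protein = include_same_protein,
         adjust_p = adjust_p, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `thresholds`, `criteria` and the scalar parameters of
#' [pipeline_config()] may each be given partially; unspecified values keep
#' their defaults. Unknown keys at either level raise an error.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("thresholds", "criteria", "min_fraction", "top_k",
                 "window_radius", "mixing_weight", "conservation_threshold",
                 "include_same_protein", "adjust_p", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  check_sub <- function(vals, fn, what) {
    allowed <- names(formals(fn))
    unknown <- setdiff(names(vals), allowed)
    if (length(unknown) > 0) {
      abort(paste0("Unknown ", what, " key(s): ", paste(unknown, collapse = ", ")))
    }
    do.call(fn, vals)
  }
  args <- raw
  args$thresholds <- check_sub(raw$thresholds %||% list(),
                               differential_thresholds, "thresholds")
  args$criteria <- check_sub(raw$criteria %||% list(),
                             confidence_criteria, "criteria")
  do.call(pipeline_config, args)
}

write_resolved_config <- function(config, path) {
  flat <- list(
    thresholds = unclass(config$thresholds),
    criteria = unclass(config$criteria),
    min_fraction = config$min_fraction, top_k = config$top_k,
    window_radius = config$window_radius,
    mixing_weight = config$mixing_weight,
    conservation_threshold = config$conservation_threshold,
    include_same_protein = config$include_same_protein,
    adjust_p = config$adjust_p, seed = config$seed
  )
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Run the full co-regulation pipeline
#'
#' Chains ingest, ranking, predominant-site selection, co-regulation
#' screening and (optionally) conservation scoring and annotation overlay,
#' logging the record funnel at each filtering step — how many records the
#' class-1 filter, the regulation caller and each confidence criterion
#' remove. When `out_dir` is given, every stage's table is written as TSV
#' together with the resolved configuration and the funnel.
#'
#' @param differential Differential record tibble ([read_differential()]) or
#'   a path to the TSV.
#' @param profiling Optional profiling record tibble ([read_profiling()]) or
#'   path.
#' @param anchor Anchor site id (`"PKN1:S562"`); `NULL` selects the rank-1
#'   predominant site automatically.
#' @param config A [pipeline_config()] object.
#' @param alignment Optional family alignment tibble or path, for
#'   conservation scoring of the anchor protein's ranked sites.
#' @param alignment_reference Sequence id of the anchor protein in the
#'   alignment (defaults to the anchor protein symbol).
#' @param annotation_edges,expression_labels,gene_sets Optional annotation
#'   inputs (tibbles / named list, or paths).
#' @param alias_table Optional alias table used when reading from paths.
#' @param out_dir Optional output directory for TSV exports.
#' @return A list with `frequencies`, `predominant`, `screen`, `funnel` and
#'   (when inputs were given) `conservation`, `enrichment`, `network`.
#' @export
run_pipeline <- function(differential, profiling = NULL, anchor = NULL,
                         config = pipeline_config(),
                         alignment = NULL, alignment_reference = NULL,
                         annotation_edges = NULL, expression_labels = NULL,
                         gene_sets = NULL, alias_table = NULL,
                         out_dir = NULL) {
  if (is.character(differential)) {
    differential <- read_differential(differential, alias_table)
  }
  if (is.character(profiling)) profiling <- read_profiling(profiling, alias_table)
  if (is.character(alignment)) alignment <- read_family_alignment(alignment)
  if (is.character(annotation_edges)) annotation_edges <- read_annotation_edges(annotation_edges)
  if (is.character(expression_labels)) expression_labels <- read_expression_labels(expression_labels)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)

  n0 <- nrow(differential)
  diff1 <- filter_class1(differential, config$thresholds)
  called <- call_regulation(diff1, config$thresholds)
  n_called <- sum(called$state != "N")
  matrix <- build_regulation_matrix(called)

  prof1 <- if (!is.null(profiling)) filter_class1(profiling, config$thresholds) else NULL
  freqs <- site_frequencies(matrix, prof1)

  if (is.null(anchor)) {
    pred <- select_predominant(freqs, config$min_fraction, config$top_k)
    if (nrow(pred) == 0) abort("No sites survive ingest; cannot pick an anchor.")
    anchor <- pred$site_id[1]
  } else {
    pred <- freqs[freqs$site_id == anchor, , drop = FALSE]
    if (nrow(pred) == 0) abort(sprintf("Anchor '%s' not present after ingest.", anchor))
  }

  screen <- coregulation_screen(matrix, anchor, config$criteria,
                                include_same_protein = config$include_same_protein,
                                adjust_p = config$adjust_p)

  funnel <- tibble(
    step = c("input_records", "class1", "called_U_or_D",
             "partners_screened", "pass_alpha", "pass_freq",
             "pass_pmids", "pass_conditions", "pass_all"),
    n = c(n0, nrow(diff1), n_called, nrow(screen), sum(screen$pass_alpha),
          sum(screen$pass_freq), sum(screen$pass_pmids),
          sum(screen$pass_conditions), sum(screen$passes_filters))
  )
  inform(paste0("funnel: ", paste(funnel$step, funnel$n, sep = "=", collapse = ", ")))

  out <- list(anchor = anchor, matrix = matrix, frequencies = freqs,
              predominant = pred, screen = screen, funnel = funnel)

  anchor_protein <- parse_site_id(anchor)$protein
  if (!is.null(alignment)) {
    ref <- alignment_reference %||% anchor_protein
    anchor_sites <- freqs[freqs$protein == anchor_protein, , drop = FALSE]
    out$conservation <- conservation_score(
      alignment, ref, anchor_sites,
      window_radius = config$window_radius,
      mixing_weight = config$mixing_weight,
      threshold = config$conservation_threshold
    )
  }
  if (!is.null(annotation_edges)) {
    out$screen <- overlay_annotations(out$screen, annotation_edges, anchor_protein)
  }
  if (!is.null(gene_sets)) {
    universe <- unique(freqs$protein)
    query <- unique(out$screen$protein[out$screen$passes_filters])
    if (length(query) > 0) {
      out$enrichment <- hypergeometric_ora(query, gene_sets, universe)
    }
  }
  out$network <- build_network(out$screen, annotation_edges, expression_labels,
                               anchor = anchor)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(as_tibble(freqs), file.path(out_dir, "site_ranking.tsv"))
    export_lollipop_table(freqs, path = file.path(out_dir, "lollipop.tsv"))
    readr::write_tsv(tidy(out$screen), file.path(out_dir, "coregulation.tsv"))
    readr::write_tsv(funnel, file.path(out_dir, "funnel.tsv"))
    if (!is.null(out$conservation)) {
      readr::write_tsv(out$conservation, file.path(out_dir, "conservation.tsv"))
    }
    if (!is.null(out$enrichment)) {
      readr::write_tsv(out$enrichment, file.path(out_dir, "enrichment.tsv"))
    }
    export_network(out$network, file.path(out_dir, "network.sif"), "sif")
    export_network(out$network, file.path(out_dir, "network_edges.tsv"), "edge_tsv")
    write_resolved_config(config, file.path(out_dir, "config_resolved.yaml"))
  }
  out
}
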