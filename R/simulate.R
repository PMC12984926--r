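#' Configuration for the synthetic phosphoproteomic corpus generator
#'
#' The generator emulates the structure of a curated corpus of many small
#' studies: each study (PMID) contributes a few treatment-vs-control
#' experimental conditions; detection is sparse; one anchor site is detected
#' far more often than the background; planted partner sites are positively
#' or negatively co-regulated with the anchor; the remaining sites are
#' independent nulls.
#'
#' Per condition: the anchor is detected with probability
#' `anchor_detection_prob` and, when detected, called up with probability
#' `up_prob` (down otherwise). A positive partner is detected with
#' probability `partner_detection_coupling` when the anchor is detected
#' (`null_detection_prob` otherwise) and, when both are detected, copies the
#' anchor's direction with probability `agreement_prob` (flips it
#' otherwise); a negative partner copies the opposite direction with
#' probability `agreement_prob`. Null sites are detected with probability
#' `null_detection_prob` with an independent direction. Fold changes
#' consistent with the direction are drawn from log-normal distributions
#' truncated to the calling regions (> `1.3` for up, < `0.76` for down), and
#' p-values for significant calls from Uniform(0, 0.05); a `near_miss_fraction`
#' of records instead receives a sub-threshold fold change or a
#' non-significant p-value, so the `N` branch of the caller is exercised.
#' Every record carries class-1 localization evidence.
#'
#' @param n_conditions Number of differential experimental conditions.
#' @param conditions_per_study Conditions per study; PMIDs partition the
#'   conditions contiguously.
#' @param n_null_sites Number of independent null sites.
#' @param n_pos_partners,n_neg_partners Planted partner counts.
#' @param anchor_detection_prob,null_detection_prob Per-condition detection
#'   probabilities for the anchor and for null sites / uncoupled partners.
#' @param agreement_prob Probability a detected partner copies the (opposite
#'   of the) anchor direction.
#' @param partner_detection_coupling Partner detection probability given the
#'   anchor is detected.
#' @param up_prob Probability an anchor call is up.
#' @param fc_up_meanlog,fc_up_sdlog,fc_down_meanlog,fc_down_sdlog Log-normal
#'   parameters of the fold-change draws before truncation.
#' @param near_miss_fraction Fraction of detections rendered uncallable.
#' @param n_profiling_datasets Standalone profiling datasets to simulate.
#' @param seed Integer seed; a fixed seed gives a byte-identical corpus.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_conditions = 200,
                              conditions_per_study = 3,
                              n_null_sites = 50,
                              n_pos_partners = 1,
                              n_neg_partners = 1,
                              anchor_detection_prob = 0.5,
                              null_detection_prob = 0.15,
                              agreement_prob = 0.9,
                              partner_detection_coupling = 0.9,
                              up_prob = 0.5,
                              fc_up_meanlog = log(2), fc_up_sdlog = 0.35,
                              fc_down_meanlog = log(0.5), fc_down_sdlog = 0.35,
                              near_miss_fraction = 0.10,
                              n_profiling_datasets = 25,
                              seed = 1L) {
  probs <- c(anchor_detection_prob, null_detection_prob, agreement_prob,
             partner_detection_coupling, up_prob, near_miss_fraction)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  stopifnot(n_conditions >= 1, conditions_per_study >= 1, n_null_sites >= 0,
            n_pos_partners >= 0, n_neg_partners >= 0, n_profiling_datasets >= 0)
  structure(
    list(n_conditions = as.integer(n_conditions),
         conditions_per_study = as.integer(conditions_per_study),
         n_null_sites = as.integer(n_null_sites),
         n_pos_partners = as.integer(n_pos_partners),
         n_neg_partners = as.integer(n_neg_partners),
         anchor_detection_prob = anchor_detection_prob,
         null_detection_prob = null_detection_prob,
         agreement_prob = agreement_prob,
         partner_detection_coupling = partner_detection_coupling,
         up_prob = up_prob,
         fc_up_meanlog = fc_up_meanlog, fc_up_sdlog = fc_up_sdlog,
         fc_down_meanlog = fc_down_meanlog, fc_down_sdlog = fc_down_sdlog,
         near_miss_fraction = near_miss_fraction,
         n_profiling_datasets = as.integer(n_profiling_datasets),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a synthetic phosphoproteomic corpus
#'
#' Generates differential and profiling record tables in the ingest format,
#' plus a truth table recording each site's planted role, under the model
#' described in [simulation_config()]. All randomness comes from the config
#' seed through one stream, so identical configs yield identical corpora.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `"synthetic_corpus"`: `differential` and
#'   `profiling` record tibbles, `truth` (site_id, protein, residue,
#'   position, role) and the `config`.
#' @export
simulate_corpus <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_corpus_impl(config))
}

simulate_corpus_impl <- function(cfg) {
  nc <- cfg$n_conditions
  conditions <- sprintf("COND%04d", seq_len(nc))
  pmids <- sprintf("PMID%04d", ceiling(seq_len(nc) / cfg$conditions_per_study))

  mk_sites <- function(prefix, n, role) {
    if (n == 0) {
      return(tibble(protein = character(0), residue = character(0),
                    position = integer(0), role = character(0)))
    }
    tibble(protein = sprintf("%s%03d", prefix, seq_len(n)),
           residue = "S",
           position = as.integer(100 + seq_len(n)),
           role = role)
  }
  sites <- dplyr::bind_rows(
    tibble(protein = "KINA", residue = "S", position = 100L, role = "anchor"),
    mk_sites("POSP", cfg$n_pos_partners, "positive_partner"),
    mk_sites("NEGP", cfg$n_neg_partners, "negative_partner"),
    mk_sites("NULL", cfg$n_null_sites, "null")
  )
  sites$site_id <- paste0(sites$protein, ":", sites$residue, sites$position)

  anchor_det <- runif(nc) < cfg$anchor_detection_prob
  anchor_dir <- ifelse(runif(nc) < cfg$up_prob, "U", "D")

  sim_one <- function(role) {
    if (role == "anchor") {
      det <- anchor_det
      dir <- anchor_dir
    } else if (role %in% c("positive_partner", "negative_partner")) {
      p_det <- ifelse(anchor_det, cfg$partner_detection_coupling,
                      cfg$null_detection_prob)
      det <- runif(nc) < p_det
      agree <- runif(nc) < cfg$agreement_prob
      base <- if (role == "positive_partner") anchor_dir else flip(anchor_dir)
      dir <- ifelse(agree, base, flip(base))
      # when the anchor is undetected there is no direction to copy
      indep <- ifelse(runif(nc) < cfg$up_prob, "U", "D")
      dir[!anchor_det] <- indep[!anchor_det]
    } else {
      det <- runif(nc) < cfg$null_detection_prob
      dir <- ifelse(runif(nc) < cfg$up_prob, "U", "D")
    }
    list(det = det, dir = dir)
  }

  recs <- purrr::pmap_dfr(sites, function(protein, residue, position, role, site_id) {
    s <- sim_one(role)
    idx <- which(s$det)
    if (length(idx) == 0) return(tibble())
    dir <- s$dir[idx]
    k <- length(idx)
    fc <- numeric(k)
    up <- dir == "U"
    fc[up] <- draw_truncated_lnorm(sum(up), cfg$fc_up_meanlog, cfg$fc_up_sdlog,
                                   lower = 1.3)
    fc[!up] <- draw_truncated_lnorm(sum(!up), cfg$fc_down_meanlog,
                                    cfg$fc_down_sdlog, upper = 0.76)
    p <- runif(k, 0, 0.05)
    near <- runif(k) < cfg$near_miss_fraction
    if (any(near)) {
      # half get an in-between fold change, half a non-significant p
      via_fc <- near & (runif(k) < 0.5)
      via_p <- near & !via_fc
      fc[via_fc] <- runif(sum(via_fc), 0.76, 1.3)
      p[via_p] <- runif(sum(via_p), 0.05, 1)
    }
    tibble(
      protein = protein, residue = residue, position = position,
      site_id = site_id,
      condition_code = conditions[idx],
      pmid = pmids[idx],
      fold_change = fc,
      p_value = p,
      loc_prob = round(runif(k, 0.75, 1), 3),
      a_score = NA_real_
    )
  })

  prof <- if (cfg$n_profiling_datasets > 0) {
    purrr::pmap_dfr(sites, function(protein, residue, position, role, site_id) {
      p_det <- if (role == "anchor") cfg$anchor_detection_prob else cfg$null_detection_prob
      det <- which(runif(cfg$n_profiling_datasets) < p_det)
      if (length(det) == 0) return(tibble())
      tibble(
        protein = protein, residue = residue, position = position,
        site_id = site_id,
        dataset_id = sprintf("DS%03d", det),
        loc_prob = round(runif(length(det), 0.75, 1), 3),
        a_score = NA_real_
      )
    })
  } else {
    tibble(protein = character(0), residue = character(0),
           position = integer(0), site_id = character(0),
           dataset_id = character(0), loc_prob = numeric(0),
           a_score = numeric(0))
  }

  structure(
    list(
      differential = recs,
      profiling = prof,
      truth = dplyr::select(sites, dplyr::all_of(
        c("site_id", "protein", "residue", "position", "role"))),
      config = cfg
    ),
    class = "synthetic_corpus"
  )
}

flip <- function(dir) ifelse(dir == "U", "D", "U")

# rejection sampling from a log-normal restricted to (lower, Inf) or (0, upper)
draw_truncated_lnorm <- function(n, meanlog, sdlog, lower = NULL, upper = NULL) {
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    x <- rlnorm(2 * (n - length(out)) + 10, meanlog, sdlog)
    if (!is.null(lower)) x <- x[x > lower]
    if (!is.null(upper)) x <- x[x < upper]
    out <- c(out, x)
    guard <- guard + 1
    if (guard > 1000) abort("Fold-change distribution barely overlaps its calling region.")
  }
  out[seq_len(n)]
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_corpus> %d differential records over %d conditions (%d studies), %d sites, %d profiling records\n",
    nrow(x$differential), x$config$n_conditions,
    ceiling(x$config$n_conditions / x$config$conditions_per_study),
    nrow(x$truth), nrow(x$profiling)))
  print(table(x$truth$role))
  invisible(x)
}

#' Write a synthetic corpus to ingest-format fixture files
#'
#' Writes `differential.tsv` and `profiling.tsv` in the exact dialect
#' [read_differential()] and [read_profiling()] expect, plus `truth.tsv`
#' with the planted roles, so the corpus round-trips through the ingest
#' module losslessly.
#'
#' @param corpus A [simulate_corpus()] result.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_fixture_files <- function(corpus, out_dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  diff_path <- file.path(out_dir, "differential.tsv")
  prof_path <- file.path(out_dir, "profiling.tsv")
  truth_path <- file.path(out_dir, "truth.tsv")
  corpus$differential |>
    dplyr::mutate(site = paste0(.data$residue, .data$position)) |>
    dplyr::select(dplyr::all_of(.diff_cols)) |>
    readr::write_tsv(diff_path)
  corpus$profiling |>
    dplyr::mutate(site = paste0(.data$residue, .data$position)) |>
    dplyr::select(dplyr::all_of(.prof_cols)) |>
    readr::write_tsv(prof_path)
  readr::write_tsv(corpus$truth, truth_path)
  invisible(c(differential = diff_path, profiling = prof_path, truth = truth_path))
}
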