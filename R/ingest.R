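#' Thresholds for class-1 filtering and regulation calling
#'
#' Bundles the quantitative cutoffs applied to each differential record. The
#' defaults are the values used throughout large-scale phosphoproteomic
#' curation: a site is called up-regulated when its treatment/control fold
#' change exceeds 1.3 and down-regulated when it falls below 0.76, both at
#' study-level significance p < 0.05; class-1 localization confidence requires
#' a localization probability of at least 0.75 or an A-score above 13.
#'
#' Boundary semantics follow the wording the cutoffs come from: the
#' localization probability is inclusive (">= 0.75"), the A-score strict
#' ("> 13"), and both fold-change cuts strict, so fc = 1.3 or fc = 0.76 are
#' not called.
#'
#' @param fc_up Ratio-scale fold change above which a site is up-regulated.
#' @param fc_down Fold change below which a site is down-regulated.
#' @param p_cutoff Significance threshold on the study-reported p-value.
#' @param loc_prob_min Minimum localization probability (inclusive).
#' @param a_score_min A-score that must be exceeded (strict).
#' @param allow_missing_p If `TRUE`, records without a p-value are treated as
#'   significant (for corpora pre-filtered upstream); by default a missing
#'   p-value fails significance and the record is called `N`.
#'
#' @return A list of class `"differential_thresholds"`.
#' @export
differential_thresholds <- function(fc_up = 1.3, fc_down = 0.76, p_cutoff = 0.05,
                                    loc_prob_min = 0.75, a_score_min = 13,
                                    allow_missing_p = FALSE) {
  stopifnot(fc_down < 1, fc_up > 1, p_cutoff > 0, p_cutoff < 1,
            loc_prob_min >= 0, loc_prob_min <= 1, a_score_min >= 0)
  structure(
    list(fc_up = fc_up, fc_down = fc_down, p_cutoff = p_cutoff,
         loc_prob_min = loc_prob_min, a_score_min = a_score_min,
         allow_missing_p = isTRUE(allow_missing_p)),
    class = "differential_thresholds"
  )
}

.diff_cols <- c("protein", "site", "condition_code", "pmid", "fold_change",
                "p_value", "loc_prob", "a_score")
.prof_cols <- c("protein", "site", "dataset_id", "loc_prob", "a_score")

#' Read differential or profiling phosphosite observation tables
#'
#' Both readers expect tab-separated UTF-8 files with a header and '.' decimal
#' marks. Differential tables have columns `protein`, `site`,
#' `condition_code`, `pmid`, `fold_change`, `p_value`, `loc_prob`, `a_score`;
#' a `log2_fold_change` column may stand in for `fold_change` and is converted
#' via `2^x`. Profiling tables have `protein`, `site`, `dataset_id`,
#' `loc_prob`, `a_score`. Site identities are normalized on read (see
#' [normalize_site_keys()]).
#'
#' @param path Path to the TSV file.
#' @param alias_table Optional alias table (see [read_alias_table()]).
#' @return A tibble of validated records with normalized `protein`,
#'   `residue`, `position`, `site_id` columns.
#' @export
read_differential <- function(path, alias_table = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(),
    site = readr::col_character(),
    condition_code = readr::col_character(),
    pmid = readr::col_character(),
    .default = readr::col_double()
  ))
  if (!"fold_change" %in% names(raw) && "log2_fold_change" %in% names(raw)) {
    raw$fold_change <- 2^raw$log2_fold_change
    raw$log2_fold_change <- NULL
  }
  missing <- setdiff(.diff_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Differential table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(!is.na(raw$fold_change) & raw$fold_change <= 0)) {
    abort("fold_change must be positive (treatment/control ratio scale).")
  }
  keys <- normalize_site_keys(raw$protein, raw$site, alias_table)
  dplyr::bind_cols(
    keys,
    dplyr::select(raw, dplyr::all_of(c("condition_code", "pmid", "fold_change",
                                       "p_value", "loc_prob", "a_score")))
  )
}

#' @rdname read_differential
#' @export
read_profiling <- function(path, alias_table = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(),
    site = readr::col_character(),
    dataset_id = readr::col_character(),
    .default = readr::col_double()
  ))
  missing <- setdiff(.prof_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Profiling table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  keys <- normalize_site_keys(raw$protein, raw$site, alias_table)
  dplyr::bind_cols(
    keys,
    dplyr::select(raw, dplyr::all_of(c("dataset_id", "loc_prob", "a_score")))
  )
}

#' Filter records to high-confidence class-1 sites
#'
#' Keeps a record iff its localization probability is at least
#' `loc_prob_min` (inclusive) OR its A-score exceeds `a_score_min` (strict).
#' Records carrying neither field are dropped and counted in the message.
#' The filter is idempotent.
#'
#' @param records A tibble of differential or profiling records with
#'   `loc_prob` and `a_score` columns (either may be `NA`).
#' @param thresholds A [differential_thresholds()] object.
#' @param quiet Suppress the dropped-record message.
#' @return The filtered tibble, same columns.
#' @export
filter_class1 <- function(records, thresholds = differential_thresholds(),
                          quiet = FALSE) {
  lp <- records$loc_prob
  as_ <- records$a_score
  keep <- (!is.na(lp) & lp >= thresholds$loc_prob_min) |
    (!is.na(as_) & as_ > thresholds$a_score_min)
  n_blank <- sum(is.na(lp) & is.na(as_))
  if (!quiet) {
    inform(sprintf(
      "class-1 filter: kept %d / %d records (%d dropped, of which %d had neither loc_prob nor a_score)",
      sum(keep), length(keep), sum(!keep), n_blank
    ))
  }
  records[keep, , drop = FALSE]
}

#' Call per-condition regulation states
#'
#' Adds a `state` column with one of `"U"` (up), `"D"` (down) or `"N"` (not
#' called). A record is `U` iff `fold_change > fc_up` and `p_value <
#' p_cutoff`; `D` iff `fold_change < fc_down` and `p_value < p_cutoff`;
#' otherwise `N`. Both fold-change boundaries are strict, so fc = 1.3 and
#' fc = 0.76 are `N` regardless of significance. Missing p-values fail
#' significance unless `allow_missing_p` was set in the thresholds.
#'
#' @inheritParams filter_class1
#' @param records A tibble of differential records (`fold_change`, `p_value`).
#' @return `records` with a `state` factor-free character column appended.
#' @export
call_regulation <- function(records, thresholds = differential_thresholds()) {
  fc <- records$fold_change
  if (any(is.na(fc)) || any(fc <= 0)) {
    abort("call_regulation: fold_change must be present and positive.")
  }
  p <- records$p_value
  sig <- if (thresholds$allow_missing_p) {
    is.na(p) | p < thresholds$p_cutoff
  } else {
    !is.na(p) & p < thresholds$p_cutoff
  }
  state <- rep("N", length(fc))
  state[sig & fc > thresholds$fc_up] <- "U"
  state[sig & fc < thresholds$fc_down] <- "D"
  records$state <- state
  records
}

#' Assemble the site-by-condition regulation matrix
#'
#' Collects called differential records into a dense character matrix of
#' states over the union of sites (rows) and experimental conditions
#' (columns). A site absent from a condition's source data gets `"N"`: a site
#' that was quantified but unchanged and a site that was not detected are
#' deliberately not distinguished. Duplicate records for one (site,
#' condition) are collapsed when their states agree and raise an error when
#' they conflict.
#'
#' @param records A tibble of differential records with a `state` column
#'   (from [call_regulation()]).
#' @return An object of class `"regulation_matrix"`: a list with `state`
#'   (character matrix, rownames = site ids, colnames = condition codes),
#'   `sites` (tibble: site_id, protein, residue, position) and `conditions`
#'   (tibble: condition_code, pmid).
#' @export
build_regulation_matrix <- function(records) {
  if (nrow(records) == 0) {
    return(new_regulation_matrix(
      matrix(character(0), 0, 0),
      sites = tibble(site_id = character(0), protein = character(0),
                     residue = character(0), position = integer(0)),
      conditions = tibble(condition_code = character(0), pmid = character(0))
    ))
  }
  if (!"state" %in% names(records)) {
    abort("Records must carry a 'state' column; run call_regulation() first.")
  }

  dedup <- dplyr::distinct(records, .data$site_id, .data$condition_code,
                           .data$state)
  conflicts <- dedup |>
    dplyr::count(.data$site_id, .data$condition_code) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(paste0(
      "Conflicting regulation states for duplicated (site, condition) pairs: ",
      paste(utils::head(paste0(conflicts$site_id, " @ ", conflicts$condition_code), 5),
            collapse = "; ")
    ))
  }

  pmid_map <- dplyr::distinct(records, .data$condition_code, .data$pmid)
  multi_pmid <- dplyr::count(pmid_map, .data$condition_code) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi_pmid) > 0) {
    abort(paste0("Conditions mapped to multiple PMIDs: ",
                 paste(multi_pmid$condition_code, collapse = ", ")))
  }
  if (any(is.na(pmid_map$pmid) | pmid_map$pmid == "")) {
    abort("Every condition must carry a non-empty pmid.")
  }

  sites <- records |>
    dplyr::distinct(.data$site_id, .data$protein, .data$residue, .data$position) |>
    dplyr::arrange(.data$protein, .data$position, .data$residue)
  conditions <- dplyr::arrange(pmid_map, .data$condition_code)

  state <- matrix("N", nrow(sites), nrow(conditions),
                  dimnames = list(sites$site_id, conditions$condition_code))
  state[cbind(dedup$site_id, dedup$condition_code)] <- dedup$state
  new_regulation_matrix(state, sites, conditions)
}

new_regulation_matrix <- function(state, sites, conditions) {
  structure(list(state = state, sites = sites, conditions = conditions),
            class = "regulation_matrix")
}

#' @export
print.regulation_matrix <- function(x, ...) {
  cat(sprintf("<regulation_matrix> %d sites x %d conditions (%d studies)\n",
              nrow(x$state), ncol(x$state), dplyr::n_distinct(x$conditions$pmid)))
  tab <- table(factor(x$state, levels = c("U", "D", "N")))
  cat(sprintf("  states: U=%d D=%d N=%d\n", tab["U"], tab["D"], tab["N"]))
  invisible(x)
}

#' Tidy a regulation matrix into long form
#'
#' @param x A `regulation_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `site_id`, `condition_code`, `pmid`, `state`,
#'   one row per cell.
#' @export
tidy.regulation_matrix <- function(x, ...) {
  if (nrow(x$state) == 0 || ncol(x$state) == 0) {
    return(tibble(site_id = character(0), condition_code = character(0),
                  pmid = character(0), state = character(0)))
  }
  long <- tibble(
    site_id = rep(rownames(x$state), times = ncol(x$state)),
    condition_code = rep(colnames(x$state), each = nrow(x$state)),
    state = as.vector(x$state)
  )
  dplyr::left_join(long, x$conditions, by = "condition_code") |>
    dplyr::select(dplyr::all_of(c("site_id", "condition_code", "pmid", "state")))
}
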