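#' Confidence criteria for co-regulation calls
#'
#' The stringent evidence filters applied after the exact test. Defaults are
#' the published screen's settings: raw FET p below 0.05, a supporting-event
#' count of at least 10% of the anchor's differential detection frequency,
#' consistent evidence from at least three independent studies (PMIDs) and at
#' least three distinct experimental conditions. `dominance_ratio` governs the
#' direction call: the concordant count must exceed the discordant count by
#' at least this ratio (and strictly, so exact ties are direction `"none"`).
#'
#' @param alpha FET significance threshold.
#' @param freq_fraction Supporting events required as a fraction of the
#'   anchor's differential frequency.
#' @param min_pmids Minimum distinct supporting studies.
#' @param min_conditions Minimum distinct supporting conditions.
#' @param dominance_ratio Required ratio of concordant to discordant events
#'   (or vice versa for negative calls).
#' @return A list of class `"confidence_criteria"`.
#' @export
confidence_criteria <- function(alpha = 0.05, freq_fraction = 0.10,
                                min_pmids = 3, min_conditions = 3,
                                dominance_ratio = 1.0) {
  stopifnot(alpha > 0, alpha < 1, freq_fraction >= 0,
            min_pmids >= 1, min_conditions >= 1, dominance_ratio > 0)
  structure(
    list(alpha = alpha, freq_fraction = freq_fraction,
         min_pmids = as.integer(min_pmids),
         min_conditions = as.integer(min_conditions),
         dominance_ratio = dominance_ratio),
    class = "confidence_criteria"
  )
}

#' Code the joint regulation states of a site pair
#'
#' Walks every experimental condition of the matrix and tallies the joint
#' state of the anchor and partner: `uu`/`dd` concordant calls, `ud`/`du`
#' discordant calls (first letter = anchor), `a` conditions where neither was
#' called, `b` conditions where exactly one was called. The contingency cells
#' are then `a`, `b`, `c = ud + du`, `d = uu + dd`, with
#' `n = a + b + c + d` equal to the condition count. The PMIDs and condition
#' codes of the concordant (`d`) events support a positive call; those of the
#' discordant (`c`) events support a negative call.
#'
#' @param matrix A `regulation_matrix`.
#' @param anchor,partner Site ids (`"PKN1:S562"`), both present in the matrix.
#' @return A list with the eight tallies, `n`, and character vectors
#'   `pmids_pos`, `pmids_neg`, `conditions_pos`, `conditions_neg`.
#' @export
code_pair_states <- function(matrix, anchor, partner) {
  stopifnot(inherits(matrix, "regulation_matrix"))
  if (identical(anchor, partner)) {
    abort("Self-pairing is not allowed: anchor and partner are the same site.")
  }
  for (s in c(anchor, partner)) {
    if (!s %in% rownames(matrix$state)) {
      abort(sprintf("Site '%s' is not in the regulation matrix.", s))
    }
  }
  av <- matrix$state[anchor, ]
  pv <- matrix$state[partner, ]
  uu <- sum(av == "U" & pv == "U")
  dd <- sum(av == "D" & pv == "D")
  ud <- sum(av == "U" & pv == "D")
  du <- sum(av == "D" & pv == "U")
  a <- sum(av == "N" & pv == "N")
  b <- sum(xor(av == "N", pv == "N"))
  pos_mask <- (av == "U" & pv == "U") | (av == "D" & pv == "D")
  neg_mask <- (av == "U" & pv == "D") | (av == "D" & pv == "U")
  conds <- colnames(matrix$state)
  pmids <- setNames(matrix$conditions$pmid, matrix$conditions$condition_code)
  list(
    anchor = anchor, partner = partner,
    uu = uu, dd = dd, ud = ud, du = du,
    a = a, b = b, c = ud + du, d = uu + dd,
    n = length(av),
    pmids_pos = unique(unname(pmids[conds[pos_mask]])),
    pmids_neg = unique(unname(pmids[conds[neg_mask]])),
    conditions_pos = conds[pos_mask],
    conditions_neg = conds[neg_mask]
  )
}

#' Classify the direction of co-regulation
#'
#' Positive iff the concordant count `d` is non-zero, strictly exceeds the
#' discordant count `c`, and `d / max(c, 1)` reaches the dominance ratio;
#' negative symmetrically; `"none"` otherwise (ties included).
#'
#' @param d,c Concordant and discordant event counts (vectorized).
#' @param criteria A [confidence_criteria()] object.
#' @return Character vector in `c("positive", "negative", "none")`.
#' @export
classify_coregulation <- function(d, c, criteria = confidence_criteria()) {
  r <- criteria$dominance_ratio
  dplyr::case_when(
    d > 0 & d > c & d / pmax(c, 1) >= r ~ "positive",
    c > 0 & c > d & c / pmax(d, 1) >= r ~ "negative",
    .default = "none"
  )
}

#' Apply the high-confidence evidence filters
#'
#' Sets per-criterion pass flags and the overall `passes_filters` on a
#' screen table: FET p below `alpha`; supporting events (`d` for positive
#' calls, `c` for negative) at least `freq_fraction` of the anchor's
#' differential frequency; at least `min_pmids` distinct supporting studies;
#' at least `min_conditions` distinct supporting conditions. Calls with
#' direction `"none"` never pass.
#'
#' @param calls A tibble with `fet_p`, `direction`, `c`, `d`, `n_pmids`,
#'   `n_conditions_support` columns (as produced by [coregulation_screen()]).
#' @param anchor_diff_frequency The anchor site's differential detection
#'   frequency (count of U/D conditions).
#' @param criteria A [confidence_criteria()] object.
#' @return `calls` with `supporting`, `pass_alpha`, `pass_freq`,
#'   `pass_pmids`, `pass_conditions` and `passes_filters` columns.
#' @export
apply_confidence_filters <- function(calls, anchor_diff_frequency,
                                     criteria = confidence_criteria()) {
  supporting <- dplyr::case_when(
    calls$direction == "positive" ~ calls$d,
    calls$direction == "negative" ~ calls$c,
    .default = 0
  )
  calls$supporting <- as.integer(supporting)
  calls$pass_alpha <- calls$fet_p < criteria$alpha
  calls$pass_freq <- supporting >= criteria$freq_fraction * anchor_diff_frequency
  calls$pass_pmids <- calls$n_pmids >= criteria$min_pmids
  calls$pass_conditions <- calls$n_conditions_support >= criteria$min_conditions
  calls$passes_filters <- calls$direction != "none" &
    calls$pass_alpha & calls$pass_freq & calls$pass_pmids & calls$pass_conditions
  calls
}

#' Screen all partner phosphosites for co-regulation with an anchor
#'
#' Pairs the anchor (predominant) site with every other phosphosite in the
#' regulation matrix — by default only sites on other proteins, the "POp"
#' universe — codes the joint states over all conditions, computes the
#' two-sided Fisher's exact p-value on the `a/b/c/d` table, assigns a
#' direction and applies the confidence filters. Results are sorted by
#' ascending p, then descending supporting count, then site id, so the output
#' is a deterministic function of the matrix.
#'
#' @param matrix A `regulation_matrix`.
#' @param anchor Anchor site id (`"PKN1:S562"`); must be in the matrix.
#' @param criteria A [confidence_criteria()] object.
#' @param include_same_protein Also screen sites on the anchor's own protein.
#' @param adjust_p Add a Benjamini-Hochberg adjusted column `fet_p_adj`
#'   (not used in filtering; the screen filters on raw p).
#' @return A tibble of class `"coregulation_screen"`, one row per partner,
#'   with the joint tallies, contingency cells, `odds_ratio` (convenience,
#'   `a*d / (b*c)` on the co-detection table), `fet_p`, `direction`,
#'   supporting-evidence counts and filter flags. Attributes: `anchor`,
#'   `anchor_frequency`, `n_conditions`, `criteria`.
#' @export
coregulation_screen <- function(matrix, anchor,
                                criteria = confidence_criteria(),
                                include_same_protein = FALSE,
                                adjust_p = FALSE) {
  stopifnot(inherits(matrix, "regulation_matrix"))
  if (!anchor %in% rownames(matrix$state)) {
    abort(sprintf("Anchor site '%s' is not in the regulation matrix.", anchor))
  }
  anchor_protein <- matrix$sites$protein[matrix$sites$site_id == anchor]
  partners <- matrix$sites
  partners <- partners[partners$site_id != anchor, , drop = FALSE]
  if (!include_same_protein) {
    partners <- partners[partners$protein != anchor_protein, , drop = FALSE]
  }

  av <- matrix$state[anchor, ]
  anchor_freq <- sum(av != "N")
  n_cond <- length(av)

  if (nrow(partners) == 0) {
    out <- empty_screen()
  } else {
    P <- matrix$state[partners$site_id, , drop = FALSE]
    aU <- av == "U"; aD <- av == "D"; aN <- av == "N"
    PU <- P == "U"; PD <- P == "D"; PN <- P == "N"

    uu <- rowSums(PU[, aU, drop = FALSE])
    dd <- rowSums(PD[, aD, drop = FALSE])
    ud <- rowSums(PD[, aU, drop = FALSE])
    du <- rowSums(PU[, aD, drop = FALSE])
    a <- rowSums(PN[, aN, drop = FALSE])
    d <- uu + dd
    cc <- ud + du
    b <- n_cond - a - d - cc

    # concordant / discordant event masks, partners x conditions
    Mpos <- (PU & rep(aU, each = nrow(P))) | (PD & rep(aD, each = nrow(P)))
    Mneg <- (PD & rep(aU, each = nrow(P))) | (PU & rep(aD, each = nrow(P)))
    pmid_f <- factor(matrix$conditions$pmid[
      match(colnames(P), matrix$conditions$condition_code)])
    C <- stats::model.matrix(~ pmid_f - 1)  # conditions x pmids incidence
    n_pmids_pos <- rowSums((Mpos %*% C) > 0)
    n_pmids_neg <- rowSums((Mneg %*% C) > 0)

    direction <- classify_coregulation(d, cc, criteria)
    n_pmids <- ifelse(direction == "negative", n_pmids_neg, n_pmids_pos)
    n_support <- ifelse(direction == "negative", cc, d)

    out <- tibble(
      partner = partners$site_id,
      protein = partners$protein,
      residue = partners$residue,
      position = partners$position,
      uu = as.integer(uu), dd = as.integer(dd),
      ud = as.integer(ud), du = as.integer(du),
      a = as.integer(a), b = as.integer(b),
      c = as.integer(cc), d = as.integer(d),
      n = as.integer(n_cond),
      odds_ratio = (a * d) / (b * cc),
      fet_p = fisher_exact_2x2(a, b, cc, d),
      direction = direction,
      n_pmids = as.integer(n_pmids),
      n_conditions_support = as.integer(n_support)
    )
    out <- apply_confidence_filters(out, anchor_freq, criteria)
    if (adjust_p) out$fet_p_adj <- p.adjust(out$fet_p, method = "BH")
    out <- dplyr::arrange(out, .data$fet_p, dplyr::desc(.data$supporting),
                          .data$partner)
  }

  structure(out,
            class = c("coregulation_screen", class(tibble())),
            anchor = anchor,
            anchor_frequency = anchor_freq,
            n_conditions = n_cond,
            criteria = criteria)
}

empty_screen <- function() {
  tibble(
    partner = character(0), protein = character(0), residue = character(0),
    position = integer(0), uu = integer(0), dd = integer(0), ud = integer(0),
    du = integer(0), a = integer(0), b = integer(0), c = integer(0),
    d = integer(0), n = integer(0), odds_ratio = numeric(0),
    fet_p = numeric(0), direction = character(0), n_pmids = integer(0),
    n_conditions_support = integer(0), supporting = integer(0),
    pass_alpha = logical(0), pass_freq = logical(0), pass_pmids = logical(0),
    pass_conditions = logical(0), passes_filters = logical(0)
  )
}

#' @export
print.coregulation_screen <- function(x, ...) {
  cat(sprintf(
    "<coregulation_screen> anchor %s (differential frequency %d over %d conditions)\n",
    attr(x, "anchor"), attr(x, "anchor_frequency"), attr(x, "n_conditions")))
  cat(sprintf("  %d partners screened, %d pass all filters (%d positive, %d negative)\n",
              nrow(x), sum(x$passes_filters),
              sum(x$passes_filters & x$direction == "positive"),
              sum(x$passes_filters & x$direction == "negative")))
  NextMethod()
}

#' Tidy and summarize a co-regulation screen
#'
#' `tidy()` returns the per-partner table as a plain tibble; `glance()`
#' returns a one-row summary with the anchor, its frequency, partner counts
#' and the filter funnel.
#'
#' @param x A `coregulation_screen`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.coregulation_screen <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  attr(out, "anchor") <- NULL
  attr(out, "anchor_frequency") <- NULL
  attr(out, "n_conditions") <- NULL
  attr(out, "criteria") <- NULL
  out
}

#' @rdname tidy.coregulation_screen
#' @export
glance.coregulation_screen <- function(x, ...) {
  tibble(
    anchor = attr(x, "anchor"),
    anchor_frequency = attr(x, "anchor_frequency"),
    n_conditions = attr(x, "n_conditions"),
    n_partners = nrow(x),
    n_pass_alpha = sum(x$pass_alpha),
    n_pass_freq = sum(x$pass_freq),
    n_pass_pmids = sum(x$pass_pmids),
    n_pass_conditions = sum(x$pass_conditions),
    n_passing = sum(x$passes_filters),
    n_positive = sum(x$passes_filters & x$direction == "positive"),
    n_negative = sum(x$passes_filters & x$direction == "negative")
  )
}

#' Volcano-style overview of a co-regulation screen
#'
#' Supporting-event count against -log10 FET p, coloured by direction, with
#' filter-passing partners emphasized.
#'
#' @param object A `coregulation_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coregulation_screen <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$supporting,
                                   y = -log10(.data$fet_p),
                                   colour = .data$direction,
                                   alpha = .data$passes_filters)) +
    ggplot2::geom_point() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::labs(x = "supporting co-regulation events",
                  y = expression(-log[10] ~ "FET p"),
                  colour = "direction",
                  title = sprintf("Co-regulation screen: %s", attr(object, "anchor"))) +
    ggplot2::theme_minimal()
}
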