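#' Read a protein family multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal format, auto-detected from the first
#' non-blank line (`>` for FASTA, a `CLUSTAL`/`MUSCLE` header otherwise).
#' Parsing is delegated to [Biostrings::readAAMultipleAlignment()].
#'
#' @param path Path to the alignment file.
#' @return A tibble with columns `sequence_id` and `aligned` (gap `'-'`),
#'   all sequences the same length.
#' @export
read_family_alignment <- function(path) {
  first <- ""
  con <- file(path, "r")
  on.exit(close(con))
  while (nchar(trimws(first)) == 0) {
    first <- readLines(con, n = 1)
    if (length(first) == 0) abort("Alignment file is empty.")
  }
  fmt <- if (startsWith(trimws(first), ">")) "fasta" else "clustal"
  aln <- Biostrings::readAAMultipleAlignment(path, format = fmt)
  seqs <- as.character(Biostrings::unmasked(aln))
  tbl <- tibble(sequence_id = names(seqs), aligned = toupper(unname(seqs)))
  if (dplyr::n_distinct(nchar(tbl$aligned)) > 1) {
    abort("Aligned sequences have unequal lengths.")
  }
  tbl
}

#' Map a phosphosite position to its alignment column
#'
#' Locates the alignment column whose ungapped index in the reference
#' sequence equals the site position, and checks that the reference residue
#' there is the site's phospho-acceptor.
#'
#' @param family An alignment tibble from [read_family_alignment()] (columns
#'   `sequence_id`, `aligned`).
#' @param reference_id The sequence carrying the site.
#' @param position 1-based position in the ungapped reference.
#' @param residue Expected residue letter at that position (S, T or Y);
#'   `NULL` skips the check.
#' @return The 1-based alignment column (integer).
#' @export
map_site_to_column <- function(family, reference_id, position, residue = NULL) {
  ref <- family$aligned[family$sequence_id == reference_id]
  if (length(ref) != 1) {
    abort(sprintf("Reference sequence '%s' is not in the alignment.", reference_id))
  }
  chars <- strsplit(ref, "")[[1]]
  ungapped <- cumsum(chars != "-")
  col <- which(ungapped == position & chars != "-")
  if (length(col) == 0) {
    abort(sprintf(
      "Position %d is beyond the ungapped length (%d) of reference '%s'.",
      position, max(ungapped), reference_id))
  }
  col <- col[1]
  if (!is.null(residue) && chars[col] != residue) {
    abort(sprintf(
      "Residue mismatch at %s position %d: site says '%s' but the reference has '%s'.",
      reference_id, position, residue, chars[col]))
  }
  as.integer(col)
}

#' Window-based phosphosite conservation score
#'
#' Scores the conservation of a phosphosite within its protein family from a
#' supplied alignment, combining two ingredients computed over the
#' non-reference members:
#'
#' * **acceptor fraction** — the fraction of members carrying a
#'   phospho-acceptor in the site's alignment column. Serine and threonine
#'   are interchangeable acceptors (a site conserved as S in one paralog and
#'   T in another counts as conserved); tyrosine sites require Y.
#' * **window identity** — the mean, over the up to `2 * window_radius + 1`
#'   columns centred on the site (truncated at the alignment ends; columns
#'   where the reference is gapped are skipped), of the fraction of members
#'   whose residue matches the reference residue, a gap opposite a residue
#'   counting as a mismatch.
#'
#' The score is `mixing_weight * acceptor_fraction + (1 - mixing_weight) *
#' window_identity`, in \[0, 1\]. A single-member family scores 1 by
#' convention. This is a fully specified surrogate for database conservation
#' scores whose formulas are unpublished; it is not expected to reproduce any
#' particular resource's numbers, and classification against the threshold is
#' what downstream steps consume.
#'
#' @param family Alignment tibble (`sequence_id`, `aligned`).
#' @param reference_id Sequence id carrying the site(s).
#' @param sites A tibble with `residue` and `position` columns (e.g. rows of
#'   a [site_frequencies()] table), or a single site id string `"S916"`.
#' @param window_radius Half-width of the window in residues (default 5).
#' @param mixing_weight Weight of the acceptor fraction in \[0, 1\]
#'   (default 0.5).
#' @param threshold Classification threshold; scores at or above it are
#'   `conserved` (inclusive, default 0.75).
#' @return A tibble, one row per site: `site`, `alignment_column`,
#'   `acceptor_fraction`, `window_identity`, `score`, `conserved`.
#' @export
conservation_score <- function(family, reference_id, sites,
                               window_radius = 5, mixing_weight = 0.5,
                               threshold = 0.75) {
  stopifnot(window_radius >= 0, mixing_weight >= 0, mixing_weight <= 1)
  if (nrow(family) == 0) abort("Empty family alignment.")
  if (is.character(sites)) {
    m <- regmatches(sites, regexec("^([STY])([0-9]+)$", sites))
    bad <- vapply(m, length, integer(1)) != 3
    if (any(bad)) abort("Site strings must look like 'S916'.")
    sites <- tibble(residue = vapply(m, `[`, "", 2),
                    position = as.integer(vapply(m, `[`, "", 3)))
  }

  ref_row <- which(family$sequence_id == reference_id)
  if (length(ref_row) != 1) {
    abort(sprintf("Reference sequence '%s' is not in the alignment.", reference_id))
  }
  mat <- do.call(rbind, strsplit(family$aligned, ""))
  ref <- mat[ref_row, ]
  others <- mat[-ref_row, , drop = FALSE]
  n_other <- nrow(others)
  L <- ncol(mat)

  purrr::pmap_dfr(sites[, c("residue", "position")], function(residue, position) {
    col <- map_site_to_column(family, reference_id, position, residue)
    if (n_other == 0) {
      acc <- 1; ident <- 1  # single-member family: conserved by convention
    } else {
      acceptors <- if (residue == "Y") "Y" else c("S", "T")
      acc <- mean(others[, col] %in% acceptors)
      win <- max(1, col - window_radius):min(L, col + window_radius)
      win <- win[ref[win] != "-"]
      ident <- mean(vapply(win, function(j) mean(others[, j] == ref[j]), numeric(1)))
    }
    score <- mixing_weight * acc + (1 - mixing_weight) * ident
    tibble(
      site = paste0(residue, position),
      alignment_column = col,
      acceptor_fraction = acc,
      window_identity = ident,
      score = score,
      conserved = classify_conserved(score, threshold)
    )
  })
}

#' Classify a conservation score against the family threshold
#'
#' Inclusive comparison: a score exactly at the threshold classifies as
#' conserved (so a score printed as "0.75" is conserved at the default).
#'
#' @param score Numeric score(s) in \[0, 1\].
#' @param threshold Classification threshold (default 0.75).
#' @return Logical vector.
#' @export
classify_conserved <- function(score, threshold = 0.75) {
  score >= threshold
}
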