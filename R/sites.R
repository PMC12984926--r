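#' Parse and normalize phosphosite identities
#'
#' A phosphosite is identified by its protein (gene symbol), phospho-acceptor
#' residue (S, T or Y) and 1-based position in the canonical protein sequence,
#' written in the field's usual `"S562"` shorthand. `normalize_site_keys()`
#' upper-cases gene symbols, resolves aliases through a user-supplied alias
#' table (one canonical/alias pair per row, in lieu of a live HGNC lookup) and
#' validates the site string. Unknown symbols pass through unchanged with a
#' warning so that corpora with incomplete alias coverage still load.
#'
#' @param protein Character vector of raw protein/gene symbols.
#' @param site Character vector of site strings, residue letter followed by a
#'   1-based position (e.g. `"S562"`, `"T774"`).
#' @param alias_table Optional data frame with columns `canonical_symbol` and
#'   `alias` mapping alternative symbols to their canonical form, or `NULL`.
#' @param accession Optional character vector of protein accessions, carried
#'   through unchanged.
#' @param quiet Suppress the unknown-alias warning.
#'
#' @return A tibble with one row per input: `protein` (normalized symbol),
#'   `residue`, `position`, `accession` and `site_id` (`"PROTEIN:S562"`), the
#'   identity used everywhere downstream. Equality of sites is equality of
#'   `site_id`.
#'
#' @examples
#' normalize_site_keys(
#'   c("pkn1", "Prk1"), c("S562", "T774"),
#'   alias_table = data.frame(canonical_symbol = "PKN1", alias = c("PKN1", "PRK1"))
#' )
#' @export
normalize_site_keys <- function(protein, site, alias_table = NULL,
                                accession = NA_character_, quiet = FALSE) {
  stopifnot(length(protein) == length(site))
  protein <- toupper(trimws(as.character(protein)))
  site <- trimws(as.character(site))

  bad <- !grepl("^[A-Za-z][0-9]+$", site)
  residue <- toupper(substr(site, 1, 1))
  position <- suppressWarnings(as.integer(sub("^[A-Za-z]", "", site)))
  bad <- bad | !(residue %in% c("S", "T", "Y")) | is.na(position) | position < 1
  if (any(bad)) {
    abort(paste0(
      "Malformed site string(s): residue must be one of S/T/Y and position >= 1.\n",
      "Offending records: ",
      paste(utils::head(paste0(protein[bad], " ", site[bad]), 5), collapse = ", "),
      if (sum(bad) > 5) sprintf(" (and %d more)", sum(bad) - 5) else ""
    ))
  }

  if (!is.null(alias_table) && nrow(alias_table) > 0) {
    stopifnot(all(c("canonical_symbol", "alias") %in% names(alias_table)))
    lut <- setNames(
      toupper(alias_table$canonical_symbol),
      toupper(alias_table$alias)
    )
    hit <- protein %in% names(lut)
    unknown <- unique(protein[!hit])
    protein[hit] <- unname(lut[protein[hit]])
    if (length(unknown) > 0 && !quiet) {
      warn(paste0(
        "Symbols absent from the alias table pass through unchanged: ",
        paste(utils::head(unknown, 10), collapse = ", "),
        if (length(unknown) > 10) " ..." else ""
      ))
    }
  }

  tibble(
    protein = protein,
    residue = residue,
    position = position,
    accession = as.character(accession),
    site_id = paste0(protein, ":", residue, position)
  )
}

#' Read an alias table
#'
#' Tab-separated, header required, columns `canonical_symbol` and `alias`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the two columns.
#' @export
read_alias_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("canonical_symbol", "alias") %in% names(tbl))) {
    abort("Alias table must have columns 'canonical_symbol' and 'alias'.")
  }
  tbl
}

# "PKN1:S562" -> list(protein, residue, position); used by anchor selectors.
parse_site_id <- function(site_id) {
  m <- regmatches(site_id, regexec("^([^:]+):([STY])([0-9]+)$", site_id))[[1]]
  if (length(m) != 4) {
    abort(sprintf("Cannot parse site id '%s' (expected 'PROTEIN:S123').", site_id))
  }
  list(protein = m[2], residue = m[3], position = as.integer(m[4]))
}
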