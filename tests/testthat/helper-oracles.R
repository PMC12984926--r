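# Independent oracles and fixture builders shared across the test files.

# Brute-force two-sided Fisher p: enumerate every 2x2 table with the observed
# margins and sum the point probabilities (stats::dhyper route, independent of
# the package's log-factorial implementation) that do not exceed the observed
# table's.
oracle_fet <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  x <- max(0, c1 - (n - r1)):min(r1, c1)
  pts <- dhyper(x, c1, n - c1, r1)
  obs <- dhyper(a, c1, n - c1, r1)
  min(sum(pts[pts <= obs * (1 + 1e-7)]), 1)
}

# Direct log-factorial summation of the upper hypergeometric tail, independent
# of stats::phyper.
oracle_hyper_upper <- function(k, K, n, N) {
  if (k == 0) return(1)
  x <- k:min(K, n)
  lp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  sum(exp(lp))
}

# Build a regulation_matrix from named per-site state vectors, e.g.
# toy_matrix(list("PKN1:S562" = c("U","U","D","N","U","N"), ...)).
toy_matrix <- function(states, conditions_per_study = 3) {
  stopifnot(length(unique(lengths(states))) == 1)
  nc <- length(states[[1]])
  conds <- sprintf("C%03d", seq_len(nc))
  pmids <- sprintf("P%03d", ceiling(seq_len(nc) / conditions_per_study))
  recs <- purrr::imap_dfr(states, function(sv, sid) {
    m <- regmatches(sid, regexec("^([^:]+):([STY])([0-9]+)$", sid))[[1]]
    tibble::tibble(
      protein = m[2], residue = m[3], position = as.integer(m[4]),
      site_id = sid, condition_code = conds, pmid = pmids, state = sv
    )
  })
  build_regulation_matrix(recs)
}

# A small aligned family as a tibble, from equal-length gapped strings.
toy_alignment <- function(...) {
  seqs <- c(...)
  tibble::tibble(sequence_id = names(seqs), aligned = unname(seqs))
}
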