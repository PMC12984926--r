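test_that("site positions map through reference gaps to alignment columns", {
  fam <- toy_alignment(REF = "AS-TK", OTH = "ASSTK")
  expect_equal(map_site_to_column(fam, "REF", 2, "S"), 2L)
  # a gap before the site shifts its column
  fam2 <- toy_alignment(REF = "A-STK", OTH = "AASTK")
  expect_equal(map_site_to_column(fam2, "REF", 2, "S"), 3L)
  # downstream positions shift past the gap too
  expect_equal(map_site_to_column(fam2, "REF", 3, "T"), 4L)

  expect_error(map_site_to_column(fam, "REF", 9, "S"), "beyond")
  expect_error(map_site_to_column(fam, "REF", 2, "T"), "mismatch")
  expect_error(map_site_to_column(fam, "NOPE", 2, "S"), "not in")
})

test_that("identical families score 1 and fully diverged windows score 0", {
  fam <- toy_alignment(A = "ASTSKLM", B = "ASTSKLM", C = "ASTSKLM")
  res <- conservation_score(fam, "A", "S2", window_radius = 2)
  expect_equal(res$acceptor_fraction, 1)
  expect_equal(res$window_identity, 1)
  expect_equal(res$score, 1)
  expect_true(res$conserved)

  # no other member has an acceptor at the column, nothing matches anywhere
  div <- toy_alignment(A = "ASTSK", B = "GWFVR", C = "PLHEM")
  res0 <- conservation_score(div, "A", "S2", window_radius = 2)
  expect_equal(res0$score, 0)
  expect_false(res0$conserved)

  # single-member family: conserved by convention
  solo <- conservation_score(toy_alignment(A = "ASTSK"), "A", "S2")
  expect_equal(solo$score, 1)

  expect_error(conservation_score(toy_alignment(A = "ASTSK")[0, ], "A", "S2"),
               "Empty")
})

test_that("a hand-built three-member toy matches the spelled-out recomputation", {
  # reference ASTSK, site S2, window radius 2 -> columns 1..4.
  # MEM2 has a gap opposite the site; MEM3 diverges at columns 1 and 3.
  fam <- toy_alignment(REF = "ASTSK", MEM2 = "A-TAK", MEM3 = "GSASK")
  res <- conservation_score(fam, "REF", "S2", window_radius = 2,
                            mixing_weight = 0.5)
  # site column 2: MEM2 '-' (not an acceptor), MEM3 'S' -> 1 of 2
  expect_equal(res$acceptor_fraction, 1 / 2)
  # col1 A: A,G -> 1/2 ; col2 S: -,S -> 1/2 ; col3 T: T,A -> 1/2 ; col4 S: A,S -> 1/2
  expect_equal(res$window_identity, (1/2 + 1/2 + 1/2 + 1/2) / 4)
  expect_equal(res$score, 0.5 * (1/2) + 0.5 * (1/2))

  # S/T interchangeability: a T in another member counts as an acceptor
  fam2 <- toy_alignment(REF = "ASTSK", MEM2 = "ATTSK", MEM3 = "GSASK")
  res2 <- conservation_score(fam2, "REF", "S2", window_radius = 0)
  expect_equal(res2$acceptor_fraction, 1)
  # Y sites require Y
  famy <- toy_alignment(REF = "AYK", MEM2 = "ASK", MEM3 = "AYK")
  resy <- conservation_score(famy, "REF", "Y2", window_radius = 0)
  expect_equal(resy$acceptor_fraction, 1 / 2)
})

test_that("columns where the reference is gapped are skipped in the window", {
  fam <- toy_alignment(REF = "AS--TK", MEM2 = "ASGGTK", MEM3 = "ASGGAK")
  res <- conservation_score(fam, "REF", "S2", window_radius = 3)
  # raw window is columns 1..5; the reference is gapped at 3 and 4, so the
  # scored columns are 1, 2, 5 with identities 1, 1, 1/2
  expect_equal(res$window_identity, (1 + 1 + 1/2) / 3)
})

test_that("the score is permutation-invariant and never drops when adding a reference copy", {
  fam <- toy_alignment(REF = "ASTSK", MEM2 = "A-TAK", MEM3 = "GSASK")
  perm <- fam[c(2, 3, 1), ]
  expect_equal(conservation_score(perm, "REF", "S2", window_radius = 2)$score,
               conservation_score(fam, "REF", "S2", window_radius = 2)$score)

  withr::local_seed(5)
  aas <- c("A", "S", "T", "K", "L", "G", "P", "-")
  for (i in 1:20) {
    ref <- paste0("AS", paste(sample(aas[aas != "-"], 6, TRUE), collapse = ""))
    mk <- function() paste(sample(aas, 8, TRUE), collapse = "")
    fam <- toy_alignment(REF = ref, M1 = mk(), M2 = mk())
    base <- conservation_score(fam, "REF", "S2", window_radius = 3)$score
    expect_gte(base, 0); expect_lte(base, 1)
    grown <- dplyr::bind_rows(fam, tibble::tibble(sequence_id = "COPY", aligned = ref))
    expect_gte(conservation_score(grown, "REF", "S2", window_radius = 3)$score,
               base)
  }
})

test_that("classification against the family threshold is inclusive", {
  expect_true(classify_conserved(0.79))   # the conserved regime
  expect_false(classify_conserved(0.46))  # the non-conserved regime
  expect_true(classify_conserved(0.75))   # boundary is inclusive
  expect_false(classify_conserved(0.7499999))
  expect_equal(classify_conserved(c(0.8, 0.1), threshold = 0.5), c(TRUE, FALSE))
})

test_that("aligned FASTA and Clustal inputs parse to the same alignment", {
  fa <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">REF", "ASTSK", ">MEM2", "A-TAK", ">MEM3", "GSASK"), fa)
  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "REF     ASTSK", "MEM2    A-TAK", "MEM3    GSASK"), cl)
  from_fa <- read_family_alignment(fa)
  from_cl <- read_family_alignment(cl)
  expect_equal(from_fa, from_cl)
  expect_equal(nrow(from_fa), 3)
  expect_equal(from_fa$aligned[from_fa$sequence_id == "MEM2"], "A-TAK")
})
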