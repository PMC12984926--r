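test_that("pair coding reproduces the hand-enumerated six-condition toy", {
  m <- toy_matrix(list(
    "PKN1:S562" = c("U", "U", "D", "N", "U", "N"),
    "MAPT:T548" = c("U", "D", "D", "N", "N", "U")
  ))
  pc <- code_pair_states(m, "PKN1:S562", "MAPT:T548")
  # joint states: UU, UD, DD, NN, UN, NU -> uu=1 ud=1 dd=1 a=1 b=2
  expect_equal(pc$uu, 1); expect_equal(pc$ud, 1); expect_equal(pc$dd, 1)
  expect_equal(pc$du, 0)
  expect_equal(pc$a, 1); expect_equal(pc$b, 2)
  expect_equal(pc$c, 1); expect_equal(pc$d, 2)
  expect_equal(pc$n, 6)
  expect_equal(pc$a + pc$b + pc$c + pc$d, 6)
  # supporting evidence follows the events of each direction
  expect_setequal(pc$conditions_pos, c("C001", "C003"))
  expect_setequal(pc$conditions_neg, "C002")
  expect_setequal(pc$pmids_pos, "P001")
})

test_that("pair coding limit cases: identical partner and never-called partner", {
  states <- c("U", "U", "D", "N", "U", "N")
  m <- toy_matrix(list("PKN1:S562" = states,
                       "AAA1:S1" = states,
                       "BBB1:S2" = rep("N", 6)))
  ident <- code_pair_states(m, "PKN1:S562", "AAA1:S1")
  expect_equal(ident$c, 0); expect_equal(ident$b, 0)
  expect_equal(ident$d, sum(states != "N"))

  silent <- code_pair_states(m, "PKN1:S562", "BBB1:S2")
  expect_equal(silent$b, sum(states != "N"))
  expect_equal(silent$c, 0); expect_equal(silent$d, 0)

  expect_error(code_pair_states(m, "PKN1:S562", "PKN1:S562"), "Self-pairing")
  expect_error(code_pair_states(m, "PKN1:S562", "ZZZ:S9"), "not in")
})

test_that("direction classification follows dominance with ties to none", {
  expect_equal(classify_coregulation(12, 1), "positive")
  expect_equal(classify_coregulation(3, 3), "none")
  expect_equal(classify_coregulation(0, 5), "negative")
  expect_equal(classify_coregulation(0, 0), "none")
  # vectorized
  expect_equal(classify_coregulation(c(12, 3, 0), c(1, 3, 5)),
               c("positive", "none", "negative"))
  # a stricter dominance ratio demotes weak majorities
  strict <- confidence_criteria(dominance_ratio = 3)
  expect_equal(classify_coregulation(5, 4, strict), "none")
  expect_equal(classify_coregulation(12, 4, strict), "positive")
})

test_that("confidence filters require alpha, frequency, study and condition support", {
  calls <- tibble::tibble(
    fet_p = c(0.001, 0.001, 0.2),
    direction = c("positive", "positive", "positive"),
    c = c(1L, 0L, 0L),
    d = c(12L, 5L, 30L),
    n_pmids = c(3L, 2L, 8L),
    n_conditions_support = c(12L, 5L, 30L)
  )
  out <- apply_confidence_filters(calls, anchor_diff_frequency = 103)
  # 12 >= 10.3 with 3 pmids passes everything
  expect_true(out$passes_filters[1])
  # two studies only: fails min_pmids (and 5 < 10.3 fails the 10% rule)
  expect_false(out$pass_pmids[2])
  expect_false(out$pass_freq[2])
  expect_false(out$passes_filters[2])
  # p = 0.2 fails alpha regardless of counts
  expect_false(out$pass_alpha[3])
  expect_false(out$passes_filters[3])
  # direction "none" can never pass
  none <- apply_confidence_filters(
    dplyr::mutate(calls[1, ], direction = "none"), 103)
  expect_false(none$passes_filters)
})

test_that("the screen matches per-pair coding and conserves the condition count", {
  cfg <- simulation_config(n_conditions = 40, n_null_sites = 8, seed = 11)
  corpus <- simulate_corpus(cfg)
  m <- build_regulation_matrix(
    call_regulation(filter_class1(corpus$differential, quiet = TRUE)))
  sc <- coregulation_screen(m, "KINA:S100")

  expect_equal(sc$a + sc$b + sc$c + sc$d, sc$n)
  expect_true(all(sc$n == ncol(m$state)))

  for (p in sc$partner[1:min(5, nrow(sc))]) {
    pc <- code_pair_states(m, "KINA:S100", p)
    row <- sc[sc$partner == p, ]
    expect_equal(row$uu, pc$uu); expect_equal(row$dd, pc$dd)
    expect_equal(row$ud, pc$ud); expect_equal(row$du, pc$du)
    expect_equal(row$a, pc$a); expect_equal(row$b, pc$b)
    expect_equal(row$fet_p, fisher_exact_2x2(pc$a, pc$b, pc$c, pc$d))
    n_pm <- if (row$direction == "negative") length(pc$pmids_neg) else length(pc$pmids_pos)
    expect_equal(row$n_pmids, n_pm)
  }
})

test_that("screening is pure: anchor order does not matter and singletons screen empty", {
  m <- toy_matrix(list(
    "PKN1:S562" = c("U", "U", "D", "N"),
    "PKN1:S916" = c("U", "D", "D", "N"),
    "MAPT:T548" = c("U", "N", "D", "U")
  ))
  s1a <- coregulation_screen(m, "PKN1:S562")
  s2 <- coregulation_screen(m, "PKN1:S916")
  s1b <- coregulation_screen(m, "PKN1:S562")
  expect_identical(tidy(s1a), tidy(s1b))
  expect_false(identical(attr(s1a, "anchor"), attr(s2, "anchor")))

  # same-protein sites are excluded from the POp universe by default
  expect_false("PKN1:S916" %in% s1a$partner)
  expect_true("PKN1:S916" %in%
                coregulation_screen(m, "PKN1:S562", include_same_protein = TRUE)$partner)

  single <- toy_matrix(list("PKN1:S562" = c("U", "D", "N")))
  expect_equal(nrow(coregulation_screen(single, "PKN1:S562")), 0)
  expect_error(coregulation_screen(single, "XX:S1"), "not in")
})

test_that("glance summarizes the filter funnel and BH adjustment is optional", {
  m <- toy_matrix(list(
    "PKN1:S562" = c("U", "U", "D", "D", "U", "N"),
    "AAA1:S1" = c("U", "U", "D", "D", "N", "N"),
    "BBB1:S2" = c("D", "N", "U", "N", "D", "U")
  ))
  sc <- coregulation_screen(m, "PKN1:S562", adjust_p = TRUE)
  g <- glance(sc)
  expect_equal(g$n_partners, 2)
  expect_equal(g$anchor_frequency, 5)
  expect_true("fet_p_adj" %in% names(sc))
  expect_true(all(sc$fet_p_adj >= sc$fet_p))
  expect_s3_class(autoplot(sc), "ggplot")
})
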