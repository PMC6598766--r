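# Screen decision logic: well scoring, categorisation, hit selection,
# counter-screen and mechanism classes, duplicate reconciliation.

test_that("score_well sums live embryos and raises flags", {
  expect_equal(score_well(c(0, 1, 1))$sum, 2L)
  expect_equal(score_well(c(0, 1, 1))$flag, "ok")
  expect_equal(score_well(c(3, 3, 3))$sum, 9L)
  # all dead: toxic
  tox <- score_well(integer(0), n_embryos_found = 3, n_dead_or_abnormal = 3)
  expect_equal(tox$flag, "toxic")
  # one dead is toxic under the default "any" rule, not under "majority"
  expect_equal(score_well(c(1, 2), 3, 1)$flag, "toxic")
  expect_equal(score_well(c(1, 2), 3, 1, toxicity_rule = "majority")$flag, "ok")
  expect_equal(score_well(c(1, 2), 3, 1, toxicity_rule = "majority")$sum, 3L)
  # no embryos found: empty (potentially corrosive)
  expect_equal(score_well(integer(0), 0, 0)$flag, "empty")
  expect_error(score_well(c(0, 4, 1)), "0..3")
  expect_error(score_well(c(1, 1, 1), n_embryos_found = 2), "inconsistent")
})

test_that("categories bin the well sum with A <= 2 and flags mapping to F/G", {
  expect_equal(categorize_primary(0), "A")
  expect_equal(categorize_primary(2), "A")
  expect_equal(categorize_primary(3), "B")
  expect_equal(categorize_primary(4), "B")
  expect_equal(categorize_primary(5), "C")
  expect_equal(categorize_primary(6), "C")
  expect_equal(categorize_primary(7), "D")
  expect_equal(categorize_primary(8), "D")
  expect_equal(categorize_primary(9), "E")
  expect_equal(categorize_primary(score_well(integer(0), 3, 3)), "F")
  expect_equal(categorize_primary(score_well(integer(0), 0, 0)), "G")
  # bins are configurable but must partition 0-9
  alt <- list(A = c(0L, 1L), B = c(2L, 4L), C = c(5L, 6L), D = c(7L, 8L),
              E = c(9L, 9L))
  expect_equal(categorize_primary(2, alt), "B")
  expect_error(categorize_primary(2, list(A = c(0L, 2L))), "partition")
})

test_that("hit selection averages three tests and caps individual scores at 7", {
  sel <- select_hits(2, c(2, 2))
  expect_equal(sel$vcanb_average, 2.00)
  expect_true(sel$is_hit)
  # a single score above 7 disqualifies even a good average
  expect_false(select_hits(0, c(0, 8))$is_hit)
  # category boundary: average must land in A-C (<= 6)
  expect_true(select_hits(6, c(6, 6))$is_hit)
  expect_false(select_hits(7, c(7, 7))$is_hit)
  expect_false(select_hits(9, c(9, 9))$is_hit)
  # incomplete test sets are flagged and never hits
  inc <- select_hits(2, c(2, NA))
  expect_false(inc$is_hit)
  expect_false(inc$complete)
})

test_that("counter-screen bins have inclusive upper edges at 1.5 and 3.5", {
  expect_equal(classify_mbp(8.50), "rescue")
  expect_equal(classify_mbp(3.5 + 1e-9), "rescue")
  expect_equal(classify_mbp(3.5), "no_rescue")
  expect_equal(classify_mbp(1.5 + 1e-9), "no_rescue")
  expect_equal(classify_mbp(1.5), "downregulated")
  expect_equal(classify_mbp(0), "downregulated")
  expect_error(classify_mbp(9.5), "range")
  # the three bins partition [0, 9]
  grid <- seq(0, 9, by = 0.25)
  cls <- vapply(grid, classify_mbp, character(1))
  expect_true(all(cls %in% c("rescue", "no_rescue", "downregulated")))
  expect_equal(sum(table(cls)), length(grid))
})

test_that("mechanism rule maps strong-allele sums 7/8/9 and missing codes", {
  expect_equal(classify_fr24(0), "downstream")
  expect_equal(classify_fr24(7), "downstream")
  expect_equal(classify_fr24(8), "inconclusive")
  expect_equal(classify_fr24(9), "receptor_candidate")
  expect_equal(classify_fr24("ND"), "inconclusive")
  expect_equal(classify_fr24("DE"), "inconclusive")
  expect_equal(classify_fr24("0.00"), "downstream")
  expect_error(classify_fr24("??"), "fr24")
  expect_error(classify_fr24(10), "range")
})

test_that("duplicate reconciliation matches brute-force binning on a 0.5 grid", {
  expect_equal(reconcile_duplicates(4.0, 4.0), "0")
  expect_equal(reconcile_duplicates(5.0, 3.0), "1-2")
  expect_equal(reconcile_duplicates(9.0, 2.0), "7-9")
  grid <- seq(0, 9, by = 0.5)
  for (a in grid) {
    for (b in grid) {
      d <- abs(a - b)
      want <- if (d == 0) "0" else if (d <= 2) "1-2"
              else if (d <= 6) "3-6" else "7-9"
      expect_identical(reconcile_duplicates(a, b), want)
    }
  }
})

test_that("mechanism_report tallies classes overall and per library", {
  t1 <- screen_table1()
  t1$mechanism_class <- vapply(t1$fr24_score, classify_fr24, character(1))
  rep <- mechanism_report(t1)
  expect_equal(rep$n, 41L)
  expect_equal(sum(rep$counts), rep$n)  # classes partition the hit set
  expect_equal(rownames(rep$by_library), c("S", "T"))
  expect_equal(as.integer(rowSums(rep$by_library)), c(29L, 12L))

  empty <- mechanism_report(data.frame())
  expect_equal(sum(empty$counts), 0L)

  all_nd <- data.frame(mechanism_class = rep("inconclusive", 3),
                       plate = c("T01", "S01", "S02"))
  expect_equal(mechanism_report(all_nd)$counts[["inconclusive"]], 3L)
})

test_that("triage_screen composes the stages over a well table", {
  run <- fixture_zero_noise_run()
  tri <- run$triage
  expect_s3_class(tri, "zf_triage")
  expect_equal(nrow(tri), sum(run$cfg$n_compounds))
  # category invariants: F iff toxic flag, G iff empty flag
  expect_true(all((tri$primary_category == "F") ==
                    (tri$primary_flag == "toxic")))
  # hits satisfy both selection criteria
  hits <- tri[tri$is_hit, ]
  expect_true(all(hits$vcanb_average <= 6))
  sums <- lapply(strsplit(hits$retest_sums, ";"), as.numeric)
  expect_true(all(vapply(sums, max, numeric(1)) <= 7))
  # mechanism classes appear only for counter-screen rescuers
  expect_true(all(is.na(tri$mechanism_class) |
                    (!is.na(tri$mbp_class) & tri$mbp_class == "rescue")))
  # print and summary methods run
  expect_output(print(tri), "confirmed hits")
  expect_output(print(summary(tri)), "Mechanism classes")
})
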