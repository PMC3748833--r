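test_that("pair classification is exact set arithmetic", {
  a <- secondary_structure(rbind(c(1, 10), c(2, 9)), 10)
  b <- secondary_structure(rbind(c(1, 10), c(3, 8)), 10)
  cls <- classify_pairs(a, b)
  expect_equal(cls$TP, matrix(c(1L, 10L), 1, dimnames = list(NULL, c("i", "j"))))
  expect_equal(unname(cls$FP), matrix(c(2L, 9L), 1))
  expect_equal(unname(cls$FN), matrix(c(3L, 8L), 1))

  # identical structures: no FP/FN
  cls2 <- classify_pairs(a, a)
  expect_equal(nrow(cls2$FP), 0)
  expect_equal(nrow(cls2$FN), 0)
  expect_equal(nrow(cls2$TP), 2)

  # disjoint pair sets: no TP
  d <- secondary_structure(rbind(c(4, 8)), 10)
  expect_equal(nrow(classify_pairs(a, d)$TP), 0)

  expect_error(classify_pairs(a, secondary_structure(NULL, 9)), "length")
})

test_that("compatible pairs are exactly the insertable ones", {
  ref <- secondary_structure(rbind(c(1, 10), c(2, 9)), 12)
  # endpoints free, crosses nothing: compatible
  expect_equal(compatible_count(rbind(c(4, 8)), ref), 1L)
  # shares position 2 with a reference pair: not compatible
  expect_equal(compatible_count(rbind(c(2, 6)), ref), 0L)
  # crosses (2,9): not compatible
  expect_equal(compatible_count(rbind(c(5, 11)), ref), 0L)
  # violates the hairpin bound
  expect_equal(compatible_count(rbind(c(4, 6)), ref), 0L)
  expect_equal(compatible_count(matrix(integer(0), ncol = 2), ref), 0L)
})

test_that("compatible counts agree with the insertion-revalidation brute force", {
  toy <- toy_parameters()
  set.seed(19)
  cases <- 0
  for (s in random_sequences(30, 14, seed = 19)) {
    en <- enumerate_structures(s, toy)
    if (en$count < 2) next
    for (rep in 1:5) {
      ref <- en$structures[[sample.int(en$count, 1)]]
      prd <- en$structures[[sample.int(en$count, 1)]]
      fp <- classify_pairs(prd, ref)$FP
      expect_identical(compatible_count(fp, ref, h = toy$h),
                       wavefold:::brute_force_xi(fp, ref, h = toy$h))
      cases <- cases + 1
    }
  }
  expect_gte(cases, 100)
})

test_that("sensitivity and selectivity follow the published formulas", {
  # fixed fixture: TP = 8, FN = 2, FP = 5, xi = 1 -> 0.8 and 8/12
  # reference: an 8-pair helix (true-positive region) plus two pairs the
  # prediction misses; prediction: the helix, one compatible extra pair,
  # and four pairs reusing positions of the missed reference pairs
  n <- 80
  helix <- cbind(1:8, 31 - (1:8))
  ref <- secondary_structure(rbind(helix, c(40, 60), c(41, 59)), n)
  fp <- rbind(c(45, 50),                       # insertable into ref: compatible
              c(40, 56), c(41, 55),            # reuse FN positions 40, 41
              c(59, 70), c(60, 69))            # reuse FN positions 59, 60
  prd <- secondary_structure(rbind(helix, fp), n)
  rep <- accuracy_report(prd, ref)
  expect_equal(rep$tp, 8)
  expect_equal(rep$fn, 2)
  expect_equal(rep$fp, 5)
  expect_equal(rep$xi, 1)
  expect_equal(rep$sensitivity, 0.8)
  expect_equal(rep$selectivity, 8 / 12)

  td <- tidy(rep)
  expect_equal(td$sensitivity, 0.8)
  expect_equal(glance(rep), td)
})

test_that("degenerate accuracy cases are flagged undefined, not NaN", {
  ref <- secondary_structure(rbind(c(1, 10)), 10)
  none <- secondary_structure(NULL, 10)
  r <- accuracy_report(none, ref)
  expect_equal(r$sensitivity, 0)
  expect_false(r$selectivity_defined)
  expect_true(is.na(r$selectivity))
  # prediction == reference: both metrics 1
  r2 <- accuracy_report(ref, ref)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$selectivity, 1)
})

test_that("the xi correction never lowers selectivity", {
  toy <- toy_parameters()
  set.seed(23)
  for (s in random_sequences(20, 14, seed = 23)) {
    en <- enumerate_structures(s, toy)
    if (en$count < 2) next
    ref <- en$structures[[sample.int(en$count, 1)]]
    prd <- en$structures[[sample.int(en$count, 1)]]
    r <- accuracy_report(prd, ref)
    if (r$tp + r$fp > 0 && r$selectivity_defined) {
      expect_gte(r$selectivity, r$tp / (r$tp + r$fp))
    }
  }
})

test_that("batch accuracy emits per-sequence rows plus the mean summary point", {
  ref1 <- from_dotbracket("((((....))))")
  prd1 <- from_dotbracket("(((......)))")
  ref2 <- from_dotbracket("(((...)))...")
  prd2 <- ref2
  tbl <- accuracy_table(list(a = prd1, b = prd2), list(ref1, ref2))
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$name, c("a", "b"))
  expect_equal(attr(tbl, "mean_sensitivity"),
               mean(tbl$sensitivity))
  expect_equal(tbl$sensitivity[2], 1)
})
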