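test_that("candidate pairs match a brute-force double loop and honor constraints", {
  p <- toy_parameters()
  s <- rna_sequence("ACGCGU")
  # independent double-loop oracle over the six canonical pair types
  canonical <- c("AU", "UA", "CG", "GC", "GU", "UG")
  expected <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    if (j - i - 1 >= 3 && paste0(s$residues[i], s$residues[j]) %in% canonical) {
      expected[[length(expected) + 1]] <- c(i, j)
    }
  }
  cp <- candidate_pairs(s, p)
  expect_equal(nrow(cp), length(expected))
  expect_equal(unname(as.matrix(cp)), do.call(rbind, expected))

  # prohibiting a pair is exact set subtraction
  cons <- fold_constraints(prohibited = cbind(1, 6))
  cp2 <- candidate_pairs(s, p, constraints = cons)
  expect_false(any(cp2$i == 1 & cp2$j == 6))
  expect_equal(nrow(cp2), nrow(cp) - 1)

  # forced-single positions drop every pair touching them
  cp3 <- candidate_pairs(s, p, constraints = fold_constraints(single = 1))
  expect_false(any(cp3$i == 1 | cp3$j == 1))
})

test_that("the neighbor prefilter drops isolated pairs and only those", {
  p <- toy_parameters()
  # (1,6) is admissible but neither (2,5) nor an outer neighbor can pair
  s <- "GAAAAC"
  off <- candidate_pairs(s, p, prefilter = FALSE)
  on <- candidate_pairs(s, p, prefilter = TRUE)
  expect_true(any(off$i == 1 & off$j == 6))
  expect_false(any(on$i == 1 & on$j == 6))
  # prefilter output is always a subset of the unfiltered set
  for (s2 in random_sequences(10, 20, seed = 5)) {
    a <- candidate_pairs(s2, p, prefilter = TRUE)
    b <- candidate_pairs(s2, p, prefilter = FALSE)
    expect_true(all(paste(a$i, a$j) %in% paste(b$i, b$j)))
  }
})

test_that("internal-loop window matches brute force and the closed-form count", {
  w <- internal_loop_window(1, 6, 30)
  brute <- list()
  for (ip in 2:4) for (jp in (ip + 1):5) {
    l1 <- ip - 2; l2 <- 6 - jp - 1
    if (l1 + l2 >= 1 && l1 + l2 <= 30) brute[[length(brute) + 1]] <- c(ip, jp)
  }
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_equal(key(w), key(do.call(rbind, brute)))
  expect_equal(nrow(internal_loop_window(1, 6, 0)), 0)
  # (1,34), span 30: all (l1, l2) with 1 <= l1 + l2 <= 30 fit, giving
  # sum_{t=1}^{30} (t + 1) = 495 bounded compositions
  expect_equal(nrow(internal_loop_window(1, 34, 30)), 495)
})

test_that("short sequences cannot fold: V forbidden, W stays zero", {
  p <- toy_parameters()
  tb <- fill_tables("GGCC", p)
  expect_true(all(tb$V >= wavefold:::ENERGY_INF))
  expect_equal(tb$W, rep(0L, 5))
})

test_that("DP minimum equals the enumeration oracle on worked and random cases", {
  # GC-stack-only parameters on GGGAAAUCCC
  p <- params_gc_stack()
  s <- "GGGAAAUCCC"
  expect_equal(mfe(s, p), oracle_min(s, p))
  # random mini-panel across modes and parameter sets
  toy <- toy_parameters()
  for (s2 in random_sequences(12, 6 + (1:12 %% 9), seed = 21)) {
    for (pset in list(toy, zero_parameters())) for (dg in c("none", "dangles", "mismatch")) {
      expect_equal(mfe(s2, pset, dangle = dg),
                   oracle_min(s2, pset, dangle = dg),
                   info = paste(as.character(s2), dg))
    }
  }
})

test_that("constraints: hard satisfaction and never-better optima", {
  toy <- toy_parameters()
  set.seed(8)
  for (s in random_sequences(8, 30, seed = 8)) {
    f0 <- rna_fold(s, toy, dangle = "dangles")
    cons <- wavefold:::random_constraints(s, toy)
    fc <- rna_fold(s, toy, constraints = cons, dangle = "dangles")
    expect_true(constraints_satisfied(fc$structure, cons))
    expect_gte(fc$mfe, f0$mfe)
    # prohibiting any pair of the current optimum never improves the MFE
    if (nrow(f0$structure$pairs) > 0) {
      pr <- fold_constraints(prohibited = f0$structure$pairs[1, , drop = FALSE])
      expect_gte(mfe(s, toy, constraints = pr, dangle = "dangles"), f0$mfe)
    }
    # forcing a pair already in the optimum leaves the MFE unchanged
    if (nrow(f0$structure$pairs) > 0) {
      fr <- fold_constraints(forced = f0$structure$pairs[1, , drop = FALSE])
      expect_equal(mfe(s, toy, constraints = fr, dangle = "dangles"), f0$mfe)
    }
  }
  # malformed constraint sets are rejected before any fill
  expect_error(fold_constraints(forced = rbind(c(1, 10), c(5, 15))), "cross")
  expect_error(fold_constraints(forced = cbind(2, 9), single = 2), "forced-single")
  # forced pair that cannot form at sequence level
  expect_error(mfe("AAAAAAAAAA", toy_parameters(),
                   constraints = fold_constraints(forced = cbind(1, 10))),
               "forced pair \\(1,10\\)")
})

test_that("constrained optima match the oracle restricted to feasible structures", {
  toy <- toy_parameters()
  set.seed(31)
  for (s in random_sequences(8, 14, seed = 31)) {
    cons <- wavefold:::random_constraints(s, toy)
    en <- enumerate_structures(s, toy, constraints = cons, dangle = "dangles")
    if (en$count == 0) next
    expect_equal(mfe(s, toy, constraints = cons, dangle = "dangles"), en$min_energy)
  }
})

test_that("W is non-increasing in j on unconstrained folds", {
  toy <- toy_parameters()
  for (s in random_sequences(10, 40, seed = 13)) {
    W <- fill_tables(s, toy, dangle = "dangles")$W
    expect_true(all(diff(W) <= 0))
  }
})

test_that("wavefront worker count never changes any table or output", {
  toy <- toy_parameters()
  for (s in random_sequences(5, 80, seed = 17)) {
    t1 <- fill_tables(s, toy, dangle = "dangles", workers = 1)
    for (w in c(2, 3, 4, 7)) {
      tw <- fill_tables(s, toy, dangle = "dangles", workers = w)
      expect_identical(t1$V, tw$V)
      expect_identical(t1$WM, tw$WM)
      expect_identical(t1$WM1, tw$WM1)
      expect_identical(t1$W, tw$W)
    }
  }
})

test_that("SHAPE pseudo-energies steer the optimum and vanish when null", {
  toy <- toy_parameters()
  s <- "GGGCGCAAAAGCGCCC"
  f0 <- rna_fold(s, toy)
  # all reactivities missing: nothing changes
  sh_na <- shape_profile(rep(NA_real_, 16), slope = 3, intercept = 0)
  expect_equal(rna_fold(s, toy, shape = sh_na)$mfe, f0$mfe)
  # zero map: nothing changes
  sh0 <- shape_profile(rep(2, 16), slope = 0, intercept = 0)
  expect_equal(rna_fold(s, toy, shape = sh0)$mfe, f0$mfe)
  # high reactivity on the optimal helix flips the optimum away from it
  r <- rep(NA_real_, 16)
  r[c(f0$structure$pairs)] <- 5
  sh <- shape_profile(r, slope = 3, intercept = 0)
  f1 <- rna_fold(s, toy, shape = sh)
  hot <- c(f0$structure$pairs)
  expect_false(any(c(f1$structure$pairs) %in% hot))
  # and the SHAPE-aware engine still matches the SHAPE-aware oracle
  en <- enumerate_structures(s, toy, shape = sh)
  expect_equal(f1$mfe, en$min_energy)
  expect_error(shape_profile(c(-0.5, 1), 1, 0), "non-negative")
  expect_error(rna_fold("ACGUACGUA", toy, shape = shape_profile(rep(1, 5), 1, 0)),
               "length")
})
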