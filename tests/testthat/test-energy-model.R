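test_that("hairpin evaluation: lookup, hairpin bound, forbidden sentinel", {
  p <- params_hairpin5()
  expect_equal(eval_hairpin("GAAAC", 1, 5, p), 5.0)
  # loop of 2 unpaired violates h = 3
  expect_identical(eval_hairpin("GAAC", 1, 4, p), Inf)
  # inadmissible closing pair
  expect_identical(eval_hairpin("AAAAA", 1, 5, p), Inf)
})

test_that("long hairpin loops use the logarithmic extrapolation", {
  hp <- integer(30)
  hp[30] <- 200L
  p <- params_with(hairpin_init = hp, extrapolation = 108L)
  s <- paste0("G", strrep("A", 60), "C")   # loop length 60 = 2 * l_max
  expected <- (200L + floor(108 * log(60 / 30) + 0.5)) / 100
  expect_equal(eval_hairpin(s, 1, 62, p), expected)
})

test_that("stack evaluation: lookup and inadmissible inner pair", {
  pt <- c("AU", "UA", "CG", "GC", "GU", "UG")
  st <- matrix(0L, 6, 6, dimnames = list(pt, pt))
  st["CG", "CG"] <- -300L
  p <- params_with(stack = st)
  expect_equal(eval_stack("CCGG", 1, 4, p), -3.0)
  expect_identical(eval_stack("CAGG", 1, 4, p), Inf)   # inner A-G is not a pair
})

test_that("stacks obey strand-flip symmetry on a symmetric table", {
  # toy stack table satisfies stack[p, q] == stack[rev p, rev q]; brute
  # force over all ordered pair-type combinations
  p <- toy_parameters()
  pt <- rownames(p$stack)
  for (a in pt) for (b in pt) {
    outer <- strsplit(a, "")[[1]]
    inner <- strsplit(b, "")[[1]]
    s <- c(outer[1], inner[1], inner[2], outer[2])
    expect_equal(eval_stack(paste(s, collapse = ""), 1, 4, p),
                 eval_stack(paste(rev(s), collapse = ""), 1, 4, p),
                 info = paste(a, b))
  }
})

test_that("bulges: single-base bulge keeps the stacking bonus", {
  pt <- c("AU", "UA", "CG", "GC", "GU", "UG")
  st <- matrix(0L, 6, 6, dimnames = list(pt, pt))
  st["GC", "GC"] <- -200L
  bi <- integer(30); bi[1] <- 300L
  p <- params_with(stack = st, bulge_init = bi)
  # (1,6) G-C closing, one-base 5' bulge at 2, inner pair (3,5) G-C
  expect_equal(eval_internal("GAGACC", 1, 6, 3, 5, p), 3.0 - 2.0)
})

test_that("internal loops: initiation, asymmetry penalty, stack rejection", {
  ii <- integer(30); ii[2] <- 150L
  p <- params_with(internal_init = ii)
  # symmetric 1x1 loop, all mismatch terms zero
  expect_equal(eval_internal("CAGCAG", 1, 6, 3, 4, p), 1.5)
  # 3x1 loop with coefficient 0.5 adds 0.5 * |3 - 1| over the size-4 init
  ii4 <- integer(30); ii4[4] <- 100L
  p2 <- params_with(internal_init = ii4, asym_coeff = 50L, asym_max = 300L)
  # closing (1,8) C-G, inner (5,6) G-C: l1 = 3, l2 = 1
  expect_equal(eval_internal("CAAAGCAG", 1, 8, 5, 6, p2), 1.0 + 1.0)
  # asymmetry cap
  p3 <- params_with(internal_init = ii4, asym_coeff = 50L, asym_max = 30L)
  expect_equal(eval_internal("CAAAGCAG", 1, 8, 5, 6, p3), 1.0 + 0.3)
  # both sides zero is a stack, not an internal loop
  expect_error(eval_internal("CCGGGG", 1, 6, 2, 5, p), "eval_stack")
})

test_that("multiloop score is affine in branches and unpaired bases", {
  p <- params_with(ml_a = 460L, ml_b = 40L, ml_c = 10L)
  expect_equal(multiloop_terms(3, 5, p), 6.3)
  expect_equal(multiloop_terms(7, 0, zero_parameters()), 0)
  # increasing unpaired_count by one adds exactly c
  expect_equal(multiloop_terms(3, 6, p) - multiloop_terms(3, 5, p), 0.1)
})

test_that("end contributions: none, best dangle subset, sequence edges", {
  expect_equal(end_contribution("GGGAAACCC", c(2, 8), mode = "none",
                                params = toy_parameters()), 0)
  p <- params_with(dangle5 = matrix(-30L, 6, 4), dangle3 = matrix(-20L, 6, 4))
  # both flanks exist: minimum over subsets is d5 + d3
  expect_equal(end_contribution("AGGAAACCA", c(2, 8), mode = "dangles", params = p), -0.5)
  # pair at (1, n): no flanking bases, every term omitted
  expect_equal(end_contribution("GAAAAAAAC", c(1, 9), mode = "dangles", params = p), 0)
  # 3' flank only
  expect_equal(end_contribution("GAAAAAACA", c(1, 8), mode = "dangles", params = p), -0.2)
  # dangles are never allowed to worsen the branch: positive table gives 0
  pp <- params_with(dangle5 = matrix(30L, 6, 4), dangle3 = matrix(20L, 6, 4))
  expect_equal(end_contribution("AGGAAACCA", c(2, 8), mode = "dangles", params = pp), 0)
})

test_that("parameter files: fidelity, round trip, hard parse errors", {
  path <- system.file("extdata", "params_toy.txt", package = "wavefold")
  p <- read_parameters(path)
  expect_identical(p, toy_parameters())
  # the printed STACK CG CG value is what the object holds
  ln <- grep("^CG CG ", readLines(path), value = TRUE)[1]
  expect_equal(p$stack["CG", "CG"], as.integer(round(100 * as.numeric(strsplit(ln, " ")[[1]][3]))))

  tmp <- tempfile(fileext = ".txt")
  write_parameters(p, tmp)
  expect_identical(read_parameters(tmp), p)

  # truncated file: parse error, no partial object
  full <- readLines(tmp)
  writeLines(full[1:40], tmp)
  expect_error(read_parameters(tmp), "incomplete|missing")

  # a malformed numeric names file, line and field
  writeLines(sub("^CG CG .*$", "CG CG oops", full), tmp)
  err <- tryCatch(read_parameters(tmp), error = conditionMessage)
  expect_match(err, "not a number")
  expect_match(err, basename(tmp), fixed = TRUE)
})

test_that("all-zero parameters make every admissible loop score zero", {
  z <- zero_parameters()
  expect_equal(eval_hairpin("GAAAC", 1, 5, z), 0)
  expect_equal(eval_stack("CCGG", 1, 4, z), 0)
  expect_equal(eval_internal("CAGCAG", 1, 6, 3, 4, z), 0)
  for (s in random_sequences(5, 15, seed = 99)) {
    expect_equal(mfe(s, z), 0)
  }
})

test_that("the forbidden sentinel saturates and leaves no gap", {
  # evaluators return either a finite two-decimal energy or Inf; Inf
  # saturates under addition by construction of the scorer
  p <- toy_parameters()
  vals <- c(eval_hairpin("AAAAA", 1, 5, p),       # inadmissible
            eval_hairpin("GAAC", 1, 4, p),        # h violation
            eval_stack("CAGG", 1, 4, p))          # broken inner pair
  expect_true(all(is.infinite(vals)))
  st <- secondary_structure(cbind(1, 5), 5)
  dec <- score_structure("AAAAA", st, p)          # forbidden pair in a structure
  expect_identical(total_energy(dec), Inf)
})
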