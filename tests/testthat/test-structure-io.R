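test_that("FASTA reading validates and normalizes residues", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGU"), fa)
  s <- read_fasta(fa)[[1]]
  expect_equal(as.character(s), "ACGU")
  expect_equal(s$name, "x")

  writeLines(c(">x", "acgt"), fa)
  expect_equal(as.character(read_fasta(fa)[[1]]), "ACGU")

  writeLines(c(">x", "ACGN"), fa)
  err <- tryCatch(read_fasta(fa), error = conditionMessage)
  expect_match(err, "position 4")

  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "empty|readable")

  # multi-record files keep order and names
  writeLines(c(">a", "ACGU", ">b", "GGGAAACCC"), fa)
  seqs <- read_fasta(fa)
  expect_equal(names(seqs), c("a", "b"))
  unlink(fa)
})

test_that("CT writing produces the documented layout and reads back exactly", {
  ct <- tempfile(fileext = ".ct")
  # empty structure of length 4: four rows, partner 0
  write_ct(rna_sequence("ACGU", "t"), secondary_structure(NULL, 4), ct)
  lines <- readLines(ct)
  expect_length(lines, 5)
  expect_match(lines[1], "^4 t$")
  expect_equal(sapply(strsplit(lines[-1], " "), `[`, 5), rep("0", 4))

  # hairpin (1,5): rows 1 and 5 reference each other
  write_ct(rna_sequence("GAAAC", "hp"), secondary_structure(cbind(1, 5), 5), ct,
           energy = -1.25)
  lines <- readLines(ct)
  expect_match(lines[1], "ENERGY = -1.25")
  r1 <- strsplit(lines[2], " ")[[1]]
  r5 <- strsplit(lines[6], " ")[[1]]
  expect_equal(r1[5], "5")
  expect_equal(r5[5], "1")
  rt <- read_ct(ct)
  expect_equal(rt$energy, -1.25)
  expect_equal(as.character(rt$seq), "GAAAC")

  # symmetric-partner violation is a parse error with the row number
  lines[6] <- sub(" 1 ", " 2 ", lines[6])
  writeLines(lines, ct)
  err <- tryCatch(read_ct(ct), error = conditionMessage)
  expect_match(err, "symmetric")
  unlink(ct)
})

test_that("FASTA, CT and dot-bracket round trips are identities on random folds", {
  toy <- toy_parameters()
  for (s in random_sequences(15, 35, seed = 9)) {
    f <- rna_fold(s, toy, dangle = "dangles")
    fa <- tempfile(fileext = ".fa"); ct <- tempfile(fileext = ".ct")
    write_fasta(s, fa)
    expect_identical(read_fasta(fa)[[1]]$residues, s$residues)
    write_ct(s, f$structure, ct, energy = f$mfe)
    back <- read_ct(ct)
    expect_identical(as.character(back$seq), as.character(s))
    expect_true(wavefold:::same_pairs(back$structure, f$structure))
    expect_true(wavefold:::same_pairs(from_dotbracket(to_dotbracket(f$structure)),
                                      f$structure))
    unlink(c(fa, ct))
  }
})

test_that("dot-bracket parsing reports unbalanced brackets with positions", {
  expect_equal(to_dotbracket(secondary_structure(NULL, 5)), ".....")
  expect_equal(to_dotbracket(secondary_structure(cbind(1, 5), 5)), "(...)")
  expect_true(wavefold:::same_pairs(from_dotbracket("(...)"),
                                    secondary_structure(cbind(1, 5), 5)))
  err <- tryCatch(from_dotbracket("(()"), error = conditionMessage)
  expect_match(err, "position 1.*end of string|unclosed")
  err2 <- tryCatch(from_dotbracket("())"), error = conditionMessage)
  expect_match(err2, "position 3")
  expect_error(from_dotbracket("(.x.)"), "position 3")
})

test_that("the CLI folds, scores, compares and fails cleanly", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">demo", "GGGCGCAAAAGCGCCC"), fa)
  out <- tempfile(fileext = ".txt")
  status <- wavefold_cli(c("fold", fa, "--dangle", "dangles", "--out", out))
  expect_identical(status, 0L)
  lines <- readLines(out)
  expect_equal(lines[1], ">demo")
  expect_match(lines[4], "^MFE = -?[0-9.]+ kcal/mol$")

  # score the folded structure back through the CLI
  db <- tempfile(fileext = ".db")
  writeLines(lines[3], db)
  out2 <- tempfile()
  expect_identical(wavefold_cli(c("score", fa, db, "--dangle", "dangles", "--out", out2)), 0L)
  expect_match(readLines(out2)[1], "^energy = ")
  # engine MFE and CLI-scored energy agree
  expect_equal(readLines(out2)[1],
               sub("^MFE", "energy", lines[4]))

  # compare a prediction against itself: perfect accuracy
  out3 <- tempfile()
  expect_identical(wavefold_cli(c("compare", db, db, "--out", out3)), 0L)
  tsv <- read.delim(out3)
  expect_equal(tsv$sensitivity[1], 1)
  expect_equal(tsv$selectivity[1], 1)

  # errors: nonzero status, no partial output file
  bad <- tempfile(fileext = ".fa")
  writeLines(c(">bad", "ACGN"), bad)
  out4 <- tempfile()
  expect_identical(suppressMessages(wavefold_cli(c("fold", bad, "--out", out4))), 1L)
  expect_false(file.exists(out4))
  expect_identical(suppressMessages(wavefold_cli(c("nonsense"))), 1L)

  # config file supplies flag defaults
  cfg <- tempfile()
  writeLines("dangle = dangles", cfg)
  out5 <- tempfile()
  expect_identical(wavefold_cli(c("fold", fa, "--config", cfg, "--out", out5)), 0L)
  expect_identical(readLines(out5), lines)
  unlink(c(fa, db, bad, cfg, out, out2, out3, out5))
})
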