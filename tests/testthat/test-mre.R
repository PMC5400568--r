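mir133b <- mature_mirna("miR-133b", "UUUGGUCCCCUUCAACCAGCUA")

test_that("mature miRNA construction validates alphabet and length", {
  expect_identical(mature_mirna("m", "acgtacgu")$sequence, "ACGUACGU")
  expect_error(mature_mirna("m", "ACGUACG"), "8")
  expect_error(mature_mirna("m", "ACGUACGB"), "A/C/G/U")
})

test_that("a seed complement followed by A is called as 7mer-A1", {
  # seed positions 2-7 of miR-133b are UUGGUC; the target-site match is
  # its reverse complement GACCAA, here followed by an A
  sites <- seed_match_scan(mir133b, c(tx = "AAAGACCAAAAA"))
  a1 <- sites[sites$site_class == "7mer-A1", ]
  expect_identical(nrow(a1), 1L)
  expect_identical(a1$start, 3L)
  expect_identical(a1$end, 10L)
  # the nested 6mer is reported at consistent coordinates
  m6 <- sites[sites$site_class == "6mer", ]
  expect_identical(m6$start, 3L)
  expect_identical(m6$end, 9L)
  # no 7mer-m8/8mer: position 8 of the miRNA (C) is not paired here
  expect_false(any(sites$site_class %in% c("7mer-m8", "8mer")))
})

test_that("the exact reverse complement of positions 1-8 is an 8mer at 0", {
  # miR-133b positions 1-8 = UUUGGUCC; its reverse complement GGACCAAA
  # ends in the A opposite position 1, so it is a full 8mer site
  sites <- seed_match_scan(mir133b, c(tx = "GGACCAAA"))
  m8 <- sites[sites$site_class == "8mer", ]
  expect_identical(m8$start, 0L)
  expect_identical(m8$end, 8L)
  # nested classes coexist at consistent offsets
  expect_identical(sites$start[sites$site_class == "7mer-m8"], 0L)
  expect_identical(sites$start[sites$site_class == "7mer-A1"], 1L)
  expect_identical(sites$start[sites$site_class == "6mer"], 1L)
})

test_that("no complementary hexamer means no sites; short sequences too", {
  expect_identical(nrow(seed_match_scan(mir133b, c(tx = "UUUUUUUUUUUU"))), 0L)
  expect_identical(nrow(seed_match_scan(mir133b, c(tx = "GACCA"))), 0L)
})

test_that("scanner agrees with the per-offset pairing oracle", {
  set.seed(99)
  for (i in seq_len(1000)) {
    mir_seq <- random_rna(sample(8:23, 1))
    tx <- random_rna(sample(8:50, 1))
    got <- seed_match_scan(mature_mirna("m", mir_seq), c(t1 = tx))
    want <- seed_scan_brute(mir_seq, tx)
    got <- got[order(got$start, got$site_class), c("start", "end", "site_class")]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("planted 8mers always carry their nested site classes", {
  set.seed(4)
  pats <- ceRNAforge:::.seed_patterns(mir133b)
  for (i in 1:20) {
    bg <- random_rna(60)
    pos <- sample(1:(60 - 8), 1)
    tx <- paste0(substr(bg, 1, pos - 1), pats[["8mer"]],
                 substr(bg, pos + 8, 60))
    sites <- seed_match_scan(mir133b, c(t1 = tx))
    s0 <- pos - 1L
    expect_true(all(c("8mer", "7mer-m8") %in%
                      sites$site_class[sites$start == s0]))
    expect_true(all(c("7mer-A1", "6mer") %in%
                      sites$site_class[sites$start == s0 + 1L]))
  }
})

test_that("dual-predictor consensus is the intersection of support", {
  rec <- data.frame(
    transcript_id = c("t1", "t1", "t2", "t3"),
    mirna_name = "miR-133b",
    predictor = c("RNA22", "PITA", "RNA22", "PITA"))
  expect_identical(consensus_mre(rec), "t1")
  expect_identical(consensus_mre(rec, required_predictors = character()),
                   c("t1", "t2", "t3"))
  expect_error(consensus_mre(rec, required_predictors = "nonesuch"),
               "unknown predictor")
})

test_that("the bundled prediction records give 9 consensus lncRNAs", {
  ex <- mir133b_example()
  got <- consensus_mre(ex$predictions, c("RNA22", "PITA"), "miR-133b")
  expect_length(got, 9)
  expect_true(all(c("ENST00000520055", "ENST00000535511",
                    "ENST00000366185") %in% got))
  expect_false("ENST00000999999" %in% got)   # single-predictor decoy
})

test_that("prediction tables load with labels and set semantics", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "p.tsv")
  writeLines(c("transcript_id\tmirna_name", "t1\tmiR-1", "t2\tmiR-1",
               "t1\tmiR-1"), path)
  rec <- load_prediction_table(path, "RNA22")
  expect_identical(nrow(rec), 2L)             # duplicates collapsed
  expect_identical(unique(rec$predictor), "RNA22")

  writeLines("transcript_id\tmirna_name", path)
  expect_identical(nrow(load_prediction_table(path, "PITA")), 0L)

  writeLines(c("a\tb", "t1\tmiR-1"), path)
  expect_error(load_prediction_table(path, "PITA"), "columns")
})
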