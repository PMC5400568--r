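small_spec <- function(seed = 3, ...) {
  synthetic_spec(n_pairs = 12, n_lncRNA = 60, n_mRNA = 120, n_triplets = 3,
                 n_de_only = 6, seed = seed, ...)
}

test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(n_lncRNA = 2, n_mRNA = 5, n_triplets = 3),
               "n_triplets")
  expect_error(synthetic_spec(planted_r = 1), "planted_r")
  expect_error(synthetic_spec(planted_fc = 0.5), "planted_fc")
})

test_that("generated cohorts pass the readers' validation end to end", {
  co <- generate_cohort(small_spec())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  es <- read_expression(file.path(dir, "matrix.tsv"),
                        file.path(dir, "design.tsv"),
                        file.path(dir, "annotation.tsv"))
  expect_equal(es$expr, co$es$expr, tolerance = 1e-12)
  seqs <- read_fasta_rna(file.path(dir, "sequences.fasta"))
  expect_length(seqs, nrow(co$truth))
  expect_identical(nrow(read_response_table(file.path(dir, "perturbation.tsv"))),
                   sum(co$truth$biotype == "mRNA"))
  expect_true(nrow(read_ct_table(file.path(dir, "ct.tsv"))) > 0)
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(small_spec(seed = 5)), d1)
  write_cohort(generate_cohort(small_spec(seed = 5)), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  d3 <- withr::local_tempdir()
  write_cohort(generate_cohort(small_spec(seed = 6)), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "matrix.tsv"))),
                         unname(tools::md5sum(file.path(d3, "matrix.tsv")))))
})

test_that("planted pairs reach the target correlation and fold change", {
  reached <- 0L
  for (seed in 1:10) {
    co <- generate_cohort(small_spec(seed = seed))
    lv <- log2(co$es$expr)
    trip <- co$truth[co$truth$role == "triplet_lncRNA", ]
    rs <- mapply(function(l, m) cor(lv[l, ], lv[m, ]),
                 trip$probe_id, trip$partner)
    if (all(rs >= 0.995)) reached <- reached + 1L
    # fold change of planted probes is near the planted value
    tum <- co$es$design$sample_id[co$es$design$group == "tumor"]
    nor <- co$es$design$sample_id[co$es$design$group == "normal"]
    fc <- rowMeans(co$es$expr[trip$probe_id, tum, drop = FALSE]) /
      rowMeans(co$es$expr[trip$probe_id, nor, drop = FALSE])
    expect_true(all(fc > 2.5 & fc < 6.5))
  }
  expect_gte(reached, 9L)    # >= 90% of seeds hit |r| >= 0.995
})

test_that("perturbation table marks planted targets down, nulls near 1", {
  co <- generate_cohort(small_spec())
  pert <- generate_perturbation(co)
  targets <- co$truth$probe_id[co$truth$role == "triplet_mRNA"]
  is_t <- pert$gene_symbol %in% targets
  expect_true(all(pert$direction[is_t] == "down"))
  expect_true(all(pert$fc[is_t] >= 2 & pert$p[is_t] < 0.05))
  expect_true(mean(pert$fc[!is_t]) < 1.3)
  expect_true(all(pert$fc[!is_t] >= 1))
})

test_that("planted transcripts carry their recorded site; nulls carry none", {
  spec <- small_spec()
  co <- generate_cohort(spec)
  sq <- generate_sequences(co)
  mir <- mature_mirna(spec$mirna_name, spec$mirna_sequence)
  sites <- seed_match_scan(mir, sq$sequences)
  for (i in seq_len(nrow(sq$site_truth))) {
    row <- sq$site_truth[i, ]
    hit <- sites[sites$transcript_id == row$probe_id &
                   sites$start == row$start &
                   sites$site_class == row$site_class, ]
    expect_identical(nrow(hit), 1L)
  }
  planted <- sq$site_truth$probe_id
  null_ids <- setdiff(co$truth$probe_id, planted)
  expect_false(any(sites$transcript_id %in% null_ids))
  expect_true(all(sq$site_truth$site_class == "8mer"))
})

test_that("a structureless cohort yields an empty network downstream", {
  spec <- synthetic_spec(n_pairs = 10, n_lncRNA = 40, n_mRNA = 80,
                         n_triplets = 0, n_de_only = 0, seed = 8)
  co <- generate_cohort(spec)
  res <- run_pipeline(co$es, generate_perturbation(co),
                      generate_sequences(co)$sequences,
                      mature_mirna(spec$mirna_name, spec$mirna_sequence),
                      pipeline_config(seed = 8))
  expect_identical(summary(res$network)$n_lncRNA, 0L)
  expect_identical(summary(res$network)$n_mRNA, 0L)
})
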