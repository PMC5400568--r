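# A small expression set with a lncRNA whose profile is echoed, noisily,
# by a block of "pathway" genes.
make_gsea_es <- function(n_pairs = 10, n_genes = 60, n_hot = 8, seed = 51,
                         hot_sd = 0.3) {
  set.seed(seed)
  n_s <- 2 * n_pairs
  prof <- rnorm(n_s, 0, 1)
  genes <- matrix(rnorm(n_genes * n_s, 8, 1), n_genes)
  for (i in seq_len(n_hot)) genes[i, ] <- 8 + prof + rnorm(n_s, 0, hot_sd)
  vals <- rbind(8 + prof, genes)
  ids <- c("LNC1", sprintf("G%03d", seq_len(n_genes)))
  make_es(2^vals, n_pairs = n_pairs, probe_ids = ids,
          biotype = c("lncRNA", rep("mRNA", n_genes)))
}

test_that("ranking by correlation matches per-gene Pearson computation", {
  es <- make_gsea_es(n_genes = 5, n_hot = 0)
  lv <- log2(es$expr)
  # plant perfect echo and perfect anti-echo
  lv["G001", ] <- 2 * lv["LNC1", ] + 1
  lv["G002", ] <- -lv["LNC1", ]
  es$expr <- 2^lv
  ranked <- rank_by_correlation(es, "LNC1", sprintf("G%03d", 1:5))
  expect_identical(names(ranked)[1], "G001")
  expect_identical(names(ranked)[5], "G002")
  direct <- sapply(sprintf("G%03d", 1:5),
                   function(g) cor(lv["LNC1", ], lv[g, ]))
  expect_equal(unname(ranked), unname(sort(direct, decreasing = TRUE)))
})

test_that("unweighted ES of a top-block set is 1 and reverses with the list", {
  scores <- seq(10, 1)
  names(scores) <- LETTERS[1:10]
  es1 <- enrichment_score(scores, c("A", "B"), weight_p = 0)
  expect_equal(es1$es, 1)
  rev_scores <- rev(scores)
  es2 <- enrichment_score(rev_scores, c("A", "B"), weight_p = 0)
  expect_equal(es2$es, -es1$es)
  # a set at the bottom has negative ES
  es3 <- enrichment_score(scores, c("I", "J"), weight_p = 0)
  expect_true(es3$es < 0)
  # no overlap or full coverage -> degenerate
  expect_null(enrichment_score(scores, c("X", "Y")))
  expect_null(enrichment_score(scores, LETTERS[1:10]))
})

test_that("ES equals the exhaustive oracle over all set placements (N <= 12)", {
  set.seed(61)
  for (N in c(5, 8, 12)) {
    scores <- sort(rnorm(N, 0, 1.5), decreasing = TRUE)
    names(scores) <- sprintf("G%02d", seq_len(N))
    masks <- 1:(2^N - 2)
    got <- want <- numeric(length(masks))
    for (mask in masks) {
      hit <- as.logical(bitwAnd(mask, 2^(seq_len(N) - 1)))
      got[mask] <- enrichment_score(scores, names(scores)[hit])$es
      want[mask] <- es_brute(scores, hit, p = 1)
    }
    expect_equal(got, want)
  }
})

test_that("ES agrees with an established implementation on random instances", {
  set.seed(67)
  for (i in 1:200) {
    N <- sample(10:80, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    names(scores) <- sprintf("G%03d", seq_len(N))
    k <- sample(2:(N - 2), 1)
    hits <- sort(sample.int(N, k))
    got <- enrichment_score(scores, names(scores)[hits])$es
    want <- fgsea::calcGseaStat(scores, selectedStats = hits, gseaParam = 1)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("a planted co-expressed set is enriched; permutations are seeded", {
  es <- make_gsea_es()
  coding <- sprintf("G%03d", 1:60)
  sets <- list(HOT = sprintf("G%03d", 1:8),
               COLD1 = sprintf("G%03d", 21:30),
               COLD2 = sprintf("G%03d", 31:45))
  r1 <- permutation_gsea(es, "LNC1", coding, sets, n_perm = 200, seed = 7)
  r2 <- permutation_gsea(es, "LNC1", coding, sets, n_perm = 200, seed = 7)
  expect_identical(r1, r2)                       # bit-reproducible
  hot <- r1[r1$set_name == "HOT", ]
  expect_true(hot$nes > 1)
  expect_true(hot$fdr_q < 0.2)
  expect_true(sign(hot$nes) == sign(hot$es))
  # degenerate set covering every coding gene is skipped with a notice
  expect_message(
    r3 <- permutation_gsea(es, "LNC1", coding, c(sets, list(ALL = coding)),
                           n_perm = 50, seed = 1),
    "degenerate")
  expect_false("ALL" %in% r3$set_name)
})

test_that("identical sample reordering leaves every ES unchanged", {
  es <- make_gsea_es()
  coding <- sprintf("G%03d", 1:60)
  sets <- list(A = sprintf("G%03d", 1:8), B = sprintf("G%03d", 40:55))
  ranked1 <- rank_by_correlation(es, "LNC1", coding)
  perm <- sample(ncol(es$expr))
  es2 <- es
  es2$expr <- es$expr[, perm]
  es2$design <- es$design[perm, ]
  ranked2 <- rank_by_correlation(es2, "LNC1", coding)
  for (s in sets)
    expect_equal(enrichment_score(ranked1, s)$es,
                 enrichment_score(ranked2, s)$es)
})

test_that("significance filter applies the |NES| and FDR thresholds", {
  res <- data.frame(set_name = c("a", "b", "c", "d"),
                    size = 10, es = c(0.5, 0.4, -0.6, 0.3),
                    nes = c(1.2, 0.9, -1.4, 1.1),
                    p_nominal = 0.01,
                    fdr_q = c(0.1, 0.1, 0.05, 0.3))
  keep <- significant_sets(res)
  expect_setequal(keep$set_name, c("a", "c"))
  expect_identical(nrow(significant_sets(res[0, ])), 0L)
})

test_that("over-representation equals the hypergeometric tail oracle", {
  # 5 of 10 DE genes inside a 10-of-100 set
  uni <- sprintf("U%03d", 1:100)
  set10 <- uni[1:10]
  de <- c(uni[1:5], uni[50:54])
  got <- over_representation(de, uni, set10)
  expect_identical(got$overlap, 5L)
  expect_equal(got$p, hyper_brute(5, 10, 90, 10))
  # matches stats::fisher.test one-sided
  ft <- fisher.test(matrix(c(5, 5, 5, 85), 2), alternative = "greater")
  expect_equal(got$p, ft$p.value)

  expect_equal(over_representation(uni, uni, set10)$p, 1)
  expect_message(p0 <- over_representation(de, uni, c("Z1", "Z2")), "overlap")
  expect_equal(p0$p, 1)
  expect_error(over_representation(c(de, "NOTUNI"), uni, set10), "subset")

  set.seed(71)
  for (i in 1:100) {
    m <- sample(3:30, 1); nn <- sample(10:60, 1); K <- sample(3:(m + nn - 1), 1)
    uni_i <- sprintf("g%d", seq_len(m + nn))
    got <- over_representation(sample(uni_i, K), uni_i, uni_i[1:m])
    expect_equal(got$p, hyper_brute(got$overlap, m, nn, K))
  }
})
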