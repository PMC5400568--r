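test_that("Pearson coefficient handles the canonical cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(x, rep(2, 4)), "constant")
  expect_error(pearson_r(1:2, 1:2), "3")
})

test_that("Pearson matches the product-moment oracle and is invariant", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- pearson_r(x, y)
    expect_equal(r, pearson_brute(x, y))
    expect_equal(pearson_r(y, x), r)                       # symmetry
    expect_equal(pearson_r(2.5 * x + 7, y), r)             # affine invariance
  }
})

test_that("correlation p-values follow the t transform", {
  expect_equal(as.numeric(correlation_p(0, 10)), 1)
  # r = 0.8, n = 4 -> t = 1.8856 on 2 df
  t_expected <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(as.numeric(correlation_p(0.8, 4)),
               2 * pt(-abs(t_expected), 2))
  # cross-check against cor.test on random data
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    ct <- cor.test(x, y)
    expect_equal(as.numeric(correlation_p(unname(ct$estimate), n)),
                 ct$p.value)
  }
  # monotone decreasing in |r| at fixed n
  ps <- as.numeric(correlation_p(seq(0, 0.99, by = 0.01), 10))
  expect_true(all(diff(ps) < 0))
  # perfect correlation: p = 0 with a degeneracy flag
  p1 <- correlation_p(1, 5)
  expect_equal(as.numeric(p1), 0)
  expect_identical(attr(p1, "degenerate"), 1L)
})

test_that("co-expression screen keeps exact copies and drops r = 0.9 pairs", {
  set.seed(23)
  n <- 20
  base <- rnorm(2 * n, 8, 1)
  copy <- 3 + 1.5 * base                      # affine copy, r = 1
  noise <- matrix(rnorm(30 * 2 * n, 8, 1), 30)
  vals <- 2^rbind(base, copy, noise)     # linear scale; screen works on log2
  es <- make_es(vals, n_pairs = n,
                probe_ids = c("LNC_A", "M_A", sprintf("N%02d", 1:30)),
                biotype = c("lncRNA", rep("mRNA", 31)))
  edges <- build_cnc(es, mrna_ids = c("M_A", sprintf("N%02d", 1:30)),
                     lncrna_ids = "LNC_A")
  expect_identical(edges$mRNA_id, "M_A")
  expect_identical(edges$sign, "positive")

  # a pair at r ~ 0.9 fails the |PCC| >= 0.995 screen
  y <- base + rnorm(2 * n, 0, sqrt(var(base) * (1 / 0.81 - 1)))
  vals2 <- rbind(LNC_B = base, M_B = y)
  es2 <- make_es(2^vals2, n_pairs = n, probe_ids = c("LNC_B", "M_B"),
                 biotype = c("lncRNA", "mRNA"))
  edges2 <- build_cnc(es2, "M_B", "LNC_B")
  expect_identical(nrow(edges2), 0L)
})

test_that("BH over the tested-pair family matches the brute-force oracle", {
  set.seed(29)
  vals <- 2^matrix(rnorm(40 * 16, 8, 1), 40, 16)
  es <- make_es(vals, n_pairs = 8,
                probe_ids = c(sprintf("L%02d", 1:20), sprintf("M%02d", 1:20)),
                biotype = rep(c("lncRNA", "mRNA"), each = 20))
  edges <- build_cnc(es, sprintf("M%02d", 1:20), sprintf("L%02d", 1:20),
                     pcc_min = 0, fdr_max = 1.01)
  all_pairs <- attr(edges, "all_pairs")
  expect_identical(nrow(all_pairs), 400L)
  expect_equal(all_pairs$q, bh_brute(all_pairs$p))
})

test_that("edge set shrinks as thresholds tighten", {
  set.seed(37)
  vals <- 2^matrix(rnorm(20 * 12, 8, 1), 20, 12)
  es <- make_es(vals, n_pairs = 6,
                probe_ids = c(sprintf("L%d", 1:10), sprintf("M%d", 1:10)),
                biotype = rep(c("lncRNA", "mRNA"), each = 10))
  n_edges <- function(pcc, fdr)
    nrow(build_cnc(es, sprintf("M%d", 1:10), sprintf("L%d", 1:10),
                   pcc_min = pcc, fdr_max = fdr))
  expect_true(n_edges(0.2, 0.9) >= n_edges(0.5, 0.9))
  expect_true(n_edges(0.2, 0.9) >= n_edges(0.2, 0.5))
})

test_that("planted near-perfect pairs are recovered among null lncRNAs", {
  set.seed(41)
  n <- 20
  res_sd <- sqrt(1 * (1 / 0.999 - 1))
  lat <- replicate(3, rnorm(2 * n, 0, 1))
  planted_l <- 8 + lat + matrix(rnorm(3 * 2 * n, 0, res_sd), 2 * n)
  planted_m <- 9 + lat + matrix(rnorm(3 * 2 * n, 0, res_sd), 2 * n)
  nulls <- matrix(rnorm(200 * 2 * n, 8, 1), 200)
  vals <- 2^rbind(t(planted_l), t(planted_m), nulls)
  ids <- c(sprintf("PL%d", 1:3), sprintf("PM%d", 1:3), sprintf("NL%03d", 1:200))
  es <- make_es(vals, n_pairs = n, probe_ids = ids,
                biotype = c(rep("lncRNA", 3), rep("mRNA", 3),
                            rep("lncRNA", 200)))
  edges <- build_cnc(es, sprintf("PM%d", 1:3),
                     c(sprintf("PL%d", 1:3), sprintf("NL%03d", 1:200)))
  expect_setequal(paste(edges$lncRNA_id, edges$mRNA_id),
                  paste(sprintf("PL%d", 1:3), sprintf("PM%d", 1:3)))
})
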