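# Independent brute-force oracles. These deliberately re-derive each
# statistic from first principles, by enumeration or naive looping, and
# share no code with the package internals they check.

# Benjamini-Hochberg step-up: sort, take min over higher ranks, cap at 1.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    cands <- vapply(i:n, function(j) p[o][j] * n / j, numeric(1))
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Product-moment correlation straight from the defining sums.
pearson_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Upper-tail hypergeometric by explicit summation of choose() terms:
# P(X >= k) with m set members, n non-members, K draws.
hyper_brute <- function(k, m, n, K) {
  kk <- k:min(K, m)
  sum(choose(m, kk) * choose(n, K - kk)) / choose(m + n, K)
}

# Weighted KS enrichment score by an explicit position-by-position walk.
es_brute <- function(scores, hit, p = 1) {
  N <- length(scores)
  nh <- sum(hit)
  nr <- sum(abs(scores[hit])^p)
  run <- 0
  maxp <- -Inf; minn <- Inf
  for (i in seq_len(N)) {
    if (hit[i]) run <- run + if (nr > 0) abs(scores[i])^p / nr else 1 / nh
    else run <- run - 1 / (N - nh)
    if (run > maxp) maxp <- run
    if (run < minn) minn <- run
  }
  if (maxp + minn > 1e-12) maxp else minn
}

# Canonical seed-site scan by testing the class predicate at every
# offset with an explicit Watson-Crick pair table (no string matching).
seed_scan_brute <- function(mirna_seq, transcript) {
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  mir <- strsplit(mirna_seq, "")[[1]]
  tx <- strsplit(transcript, "")[[1]]
  L <- length(tx)
  pairs_rc <- function(start0, mir_positions) {
    # transcript bases (5'->3') pair antiparallel with the listed miRNA
    # positions; the site base opposite the HIGHEST miRNA position comes
    # first on the transcript.
    k <- length(mir_positions)
    if (start0 + k > L) return(FALSE)
    for (j in seq_len(k)) {
      mpos <- rev(mir_positions)[j]
      tb <- tx[start0 + j]
      if (is.na(wc[mir[mpos]]) || tb != wc[mir[mpos]]) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (s in 0:(L - 1)) {
    if (pairs_rc(s, 2:7) && s + 6 <= L)
      out[[length(out) + 1]] <- c(s, s + 6, "6mer")
    if (pairs_rc(s, 2:7) && s + 7 <= L && tx[s + 7] == "A")
      out[[length(out) + 1]] <- c(s, s + 7, "7mer-A1")
    if (pairs_rc(s, 2:8) && s + 7 <= L)
      out[[length(out) + 1]] <- c(s, s + 7, "7mer-m8")
    if (pairs_rc(s, 2:8) && s + 8 <= L && tx[s + 8] == "A")
      out[[length(out) + 1]] <- c(s, s + 8, "8mer")
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      site_class = character(), stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  df <- data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
                   site_class = m[, 3], stringsAsFactors = FALSE)
  df[order(df$start, df$site_class), ]
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")
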