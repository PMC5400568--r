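#' Rank coding genes by correlation with a lncRNA profile
#'
#' Genes are scored by the Pearson correlation of their expression with
#' the lncRNA's profile across all samples (log2 intensities) and sorted
#' in descending score order, ties broken alphabetically by gene symbol.
#'
#' @param es An `expression_set`.
#' @param lncrna_id Probe ID of the lncRNA.
#' @param coding_ids Probe IDs of the coding genes to rank.
#' @return Named numeric vector of scores, sorted descending; names are
#'   uppercased gene identifiers.
#' @export
rank_by_correlation <- function(es, lncrna_id, coding_ids) {
  m <- es$expr
  if (identical(es$scale_tag, "linear")) m <- .to_log2(m, "linear")
  if (!lncrna_id %in% rownames(m)) .stop("lncRNA '%s' not in matrix", lncrna_id)
  if (ncol(m) < 3) .stop("need >= 3 samples to rank by correlation")
  prof <- m[lncrna_id, ]
  if (stats::sd(prof) == 0) .stop("constant lncRNA profile: ranking undefined")
  scores <- as.vector(stats::cor(prof, t(m[coding_ids, , drop = FALSE])))
  names(scores) <- toupper(coding_ids)
  .sort_ranked(scores)
}

.sort_ranked <- function(scores) {
  scores[order(-scores, names(scores), method = "radix")]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|score|^weight_p` (normalized over
#' set hits) at member genes and `1/(N - Nh)` at non-members; the
#' enrichment score is the running-sum deviation of maximum magnitude,
#' with its sign.
#'
#' @param ranked Named numeric vector sorted descending (see
#'   [rank_by_correlation()]).
#' @param gene_set Character vector of member symbols.
#' @param weight_p Score-weighting exponent (default 1, the standard
#'   weighted statistic; 0 gives the classic Kolmogorov-Smirnov form).
#' @return List with `es` and the `running` sum vector, or NULL when the
#'   set has no overlap with the list or covers it entirely (degenerate).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  if (anyDuplicated(names(ranked))) .stop("ranked list has duplicate genes")
  hit <- names(ranked) %in% toupper(gene_set)
  N <- length(ranked); nh <- sum(hit)
  if (nh == 0L || nh == N) return(NULL)
  w <- abs(ranked)^weight_p
  denom <- sum(w[hit])
  inc <- if (denom > 0) ifelse(hit, w / denom, 0) else ifelse(hit, 1 / nh, 0)
  dec <- ifelse(hit, 0, 1 / (N - nh))
  running <- cumsum(inc - dec)
  # max deviation from zero; a tie (to numerical tolerance) resolves to
  # the negative side
  maxp <- max(running); minn <- min(running)
  es <- if (maxp + minn > 1e-12) maxp else minn
  list(es = unname(es), running = unname(running))
}

# ES for many sets against one ranked list; returns named numeric
# (NA for degenerate sets).
.es_all_sets <- function(ranked, gene_sets, weight_p) {
  vapply(gene_sets, function(gs) {
    r <- enrichment_score(ranked, gs, weight_p)
    if (is.null(r)) NA_real_ else r$es
  }, numeric(1))
}

#' Permutation GSEA of genes correlated with a lncRNA
#'
#' For each gene set, computes the observed enrichment score on genes
#' ranked by correlation with the lncRNA, then builds a null distribution
#' by permuting the lncRNA profile across samples and re-ranking (the
#' sample-level null for a continuous phenotype). The normalized
#' enrichment score divides ES by the mean magnitude of same-sign null
#' scores; the nominal p is the same-sign null tail; FDR q is the
#' sign-stratified ratio of null to observed NES tail fractions.
#' Deterministic given `seed`.
#'
#' @param es An `expression_set`.
#' @param lncrna_id lncRNA probe ID (the continuous phenotype).
#' @param coding_ids Coding gene probe IDs.
#' @param gene_sets Named list of member-symbol vectors (see [read_gmt()]).
#' @param n_perm Number of sample permutations (default 1000).
#' @param weight_p Weighting exponent (default 1).
#' @param seed Optional RNG seed.
#' @return Data frame of class `gsea_result`: `set_name`, `size`, `es`,
#'   `nes`, `p_nominal`, `fdr_q`; degenerate sets (no overlap, or covering
#'   the whole list) are skipped with a notice.
#' @export
permutation_gsea <- function(es, lncrna_id, coding_ids, gene_sets,
                             n_perm = 1000, weight_p = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- es$expr
  if (identical(es$scale_tag, "linear")) m <- .to_log2(m, "linear")
  prof <- m[lncrna_id, ]
  genes <- t(m[coding_ids, , drop = FALSE])   # samples x genes
  obs_ranked <- rank_by_correlation(es, lncrna_id, coding_ids)

  obs_es <- .es_all_sets(obs_ranked, gene_sets, weight_p)
  skipped <- names(obs_es)[is.na(obs_es)]
  if (length(skipped))
    message("skipping degenerate gene set(s): ", paste(skipped, collapse = ", "))
  keep <- !is.na(obs_es)
  gene_sets <- gene_sets[keep]; obs_es <- obs_es[keep]
  if (!length(gene_sets))
    return(.empty_gsea())

  # permuted profiles -> correlation scores per permutation (vectorized)
  nsamp <- length(prof)
  perm_mat <- vapply(seq_len(n_perm), function(i) prof[sample.int(nsamp)],
                     numeric(nsamp))
  cors <- stats::cor(perm_mat, genes)         # n_perm x genes
  gsyms <- toupper(coding_ids)
  null_es <- matrix(NA_real_, n_perm, length(gene_sets),
                    dimnames = list(NULL, names(gene_sets)))
  for (b in seq_len(n_perm)) {
    sc <- cors[b, ]
    names(sc) <- gsyms
    null_es[b, ] <- .es_all_sets(.sort_ranked(sc), gene_sets, weight_p)
  }

  # per-set sign-matched normalization of observed and null ES
  nes <- numeric(length(obs_es)); p_nom <- numeric(length(obs_es))
  null_nes <- null_es
  for (j in seq_along(obs_es)) {
    nj <- null_es[, j]
    pos_mean <- mean(nj[nj >= 0]); neg_mean <- mean(abs(nj[nj < 0]))
    null_nes[, j] <- ifelse(nj >= 0,
                            if (is.nan(pos_mean)) NA else nj / pos_mean,
                            if (is.nan(neg_mean)) NA else nj / neg_mean)
    if (obs_es[j] >= 0) {
      tail_n <- nj[nj >= 0]
      p_nom[j] <- if (length(tail_n)) mean(tail_n >= obs_es[j]) else 1
      nes[j] <- if (is.nan(pos_mean)) NA_real_ else obs_es[j] / pos_mean
    } else {
      tail_n <- nj[nj < 0]
      p_nom[j] <- if (length(tail_n)) mean(tail_n <= obs_es[j]) else 1
      nes[j] <- if (is.nan(neg_mean)) NA_real_ else obs_es[j] / neg_mean
    }
  }

  fdr_q <- .gsea_fdr(nes, null_nes)
  out <- data.frame(set_name = names(gene_sets),
                    size = vapply(gene_sets, function(g)
                      sum(names(obs_ranked) %in% toupper(g)), integer(1)),
                    es = unname(obs_es), nes = unname(nes),
                    p_nominal = p_nom, fdr_q = fdr_q,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gsea_result", class(out))
  out
}

# Sign-stratified permutation FDR on the NES scale: for a positive NES*,
# q = P(null NES >= NES* | null NES >= 0) / P(obs NES >= NES* | obs >= 0),
# mirrored for negative scores, clipped to [0, 1].
.gsea_fdr <- function(nes, null_nes) {
  null_v <- as.vector(null_nes)
  null_v <- null_v[!is.na(null_v)]
  q <- rep(NA_real_, length(nes))
  for (j in seq_along(nes)) {
    s <- nes[j]
    if (is.na(s)) next
    if (s >= 0) {
      null_pos <- null_v[null_v >= 0]
      obs_pos <- nes[!is.na(nes) & nes >= 0]
      num <- if (length(null_pos)) mean(null_pos >= s) else 0
      den <- mean(obs_pos >= s)
    } else {
      null_neg <- null_v[null_v < 0]
      obs_neg <- nes[!is.na(nes) & nes < 0]
      num <- if (length(null_neg)) mean(null_neg <= s) else 0
      den <- mean(obs_neg <= s)
    }
    q[j] <- min(1, if (den > 0) num / den else 1)
  }
  q
}

.empty_gsea <- function() {
  out <- data.frame(set_name = character(), size = integer(), es = numeric(),
                    nes = numeric(), p_nominal = numeric(), fdr_q = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("gsea_result", class(out))
  out
}

#' Filter GSEA results at the significance thresholds
#'
#' @param results A `gsea_result` data frame.
#' @param nes_min Minimum |NES|, exclusive (default 1.0).
#' @param fdr_max Strict FDR q ceiling (default 0.2).
#' @return Filtered rows.
#' @export
significant_sets <- function(results, nes_min = 1.0, fdr_max = 0.2) {
  keep <- !is.na(results$nes) & abs(results$nes) > nes_min &
    !is.na(results$fdr_q) & results$fdr_q < fdr_max
  results[keep, , drop = FALSE]
}

#' Hypergeometric over-representation test
#'
#' One-sided Fisher/hypergeometric enrichment p for the overlap between a
#' differentially expressed gene list and a gene set within a stated
#' universe.
#'
#' @param de_genes Character vector of DE gene symbols (must be a subset
#'   of `universe`).
#' @param universe Character vector, the tested universe.
#' @param gene_set Character vector of set members.
#' @return List: `p`, `overlap`, `set_in_universe`, `n_de`, `n_universe`.
#' @export
over_representation <- function(de_genes, universe, gene_set) {
  de_genes <- unique(toupper(de_genes)); universe <- unique(toupper(universe))
  gene_set <- unique(toupper(gene_set))
  if (length(setdiff(de_genes, universe)))
    .stop("de_genes must be a subset of the universe")
  set_u <- intersect(gene_set, universe)
  k <- length(intersect(de_genes, set_u))
  if (!length(set_u)) {
    message("gene set has no overlap with the universe; p = 1")
    return(list(p = 1, overlap = 0L, set_in_universe = 0L,
                n_de = length(de_genes), n_universe = length(universe)))
  }
  p <- stats::phyper(k - 1, length(set_u), length(universe) - length(set_u),
                     length(de_genes), lower.tail = FALSE)
  list(p = p, overlap = k, set_in_universe = length(set_u),
       n_de = length(de_genes), n_universe = length(universe))
}
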