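#' Pearson correlation coefficient
#'
#' Standard product-moment coefficient; both vectors must be non-constant.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) .stop("x and y must have equal length")
  if (length(x) < 3) .stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .stop("constant vector: correlation undefined")
  stats::cor(x, y, method = "pearson")
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with n - 2
#' degrees of freedom. Perfect correlations (|r| = 1) give p = 0 with a
#' `degenerate` attribute set.
#'
#' @param r Correlation coefficient(s).
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value(s).
#' @export
correlation_p <- function(r, n) {
  if (any(n < 3)) .stop("need n >= 3 for a correlation p-value")
  if (any(abs(r) > 1 + 1e-12)) .stop("|r| cannot exceed 1")
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  tstat <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  if (any(!ok)) attr(p, "degenerate") <- which(!ok)
  p
}

#' Coding/non-coding co-expression screen
#'
#' Computes the Pearson correlation between every candidate mRNA and every
#' lncRNA across all samples (tumor and normal jointly) on log2
#' intensities, derives two-sided p-values from the t transform, applies
#' Benjamini-Hochberg over the full tested-pair family, and retains edges
#' with `|r| >= pcc_min` and `q < fdr_max`.
#'
#' @param es An `expression_set`.
#' @param mrna_ids Candidate mRNA probe IDs (rows of the matrix).
#' @param lncrna_ids lncRNA probe IDs to test against.
#' @param pcc_min Minimum absolute correlation (default 0.995).
#' @param fdr_max Strict BH q ceiling (default 0.05).
#' @param log2_transform Correlate on log2 intensities (default TRUE; set
#'   FALSE if the matrix is already log2 or linear-scale correlation is
#'   wanted).
#' @return Data frame of retained edges: `lncRNA_id`, `mRNA_id`, `r`, `p`,
#'   `q`, `sign`; the full tested table is attached as attribute
#'   `all_pairs`.
#' @export
build_cnc <- function(es, mrna_ids, lncrna_ids,
                      pcc_min = 0.995, fdr_max = 0.05,
                      log2_transform = TRUE) {
  missing_ids <- setdiff(c(mrna_ids, lncrna_ids), rownames(es$expr))
  if (length(missing_ids))
    .stop("probe '%s' not in expression matrix", missing_ids[1])
  if (!length(mrna_ids) || !length(lncrna_ids))
    return(.empty_cnc())
  m <- es$expr
  if (log2_transform && identical(es$scale_tag, "linear"))
    m <- .to_log2(m, "linear")
  n <- ncol(m)
  # cor() on samples-by-probes matrices: result is lncRNA x mRNA
  rmat <- stats::cor(t(m[lncrna_ids, , drop = FALSE]),
                     t(m[mrna_ids, , drop = FALSE]))
  pairs <- expand.grid(lncRNA_id = lncrna_ids, mRNA_id = mrna_ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs$r <- as.vector(rmat)
  if (anyNA(pairs$r)) {
    warning("dropping pairs involving constant probes", call. = FALSE)
    pairs <- pairs[!is.na(pairs$r), , drop = FALSE]
    if (!nrow(pairs)) return(.empty_cnc())
  }
  pairs$p <- as.numeric(correlation_p(pairs$r, n))
  pairs$q <- bh_fdr(pairs$p)
  pairs$sign <- ifelse(pairs$r > 0, "positive", "negative")
  keep <- abs(pairs$r) >= pcc_min & pairs$q < fdr_max
  edges <- pairs[keep, , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "all_pairs") <- pairs
  edges
}

.empty_cnc <- function() {
  data.frame(lncRNA_id = character(), mRNA_id = character(), r = numeric(),
             p = numeric(), q = numeric(), sign = character(),
             stringsAsFactors = FALSE)
}
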