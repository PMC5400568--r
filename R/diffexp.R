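#' Linear-scale fold change between tumor and normal group means
#'
#' Fold change is reported as a magnitude >= 1 (the larger group mean over
#' the smaller) with a direction label: `up` when the tumor mean exceeds
#' the normal mean, `down` otherwise. Equal means are labelled `up` so the
#' output ordering is deterministic.
#'
#' @param mean_tumor,mean_normal Positive linear-scale group means
#'   (vectorized).
#' @return Data frame with columns `fc` and `direction`.
#' @export
fold_change <- function(mean_tumor, mean_normal) {
  if (any(mean_tumor <= 0) || any(mean_normal <= 0))
    .stop("group means must be positive for fold-change computation")
  data.frame(
    fc = pmax(mean_tumor / mean_normal, mean_normal / mean_tumor),
    direction = ifelse(mean_tumor >= mean_normal, "up", "down"),
    stringsAsFactors = FALSE
  )
}

# Vectorized two-sided Welch t-test over matrix rows (tumor vs normal).
# Returns t, Welch df, p. Rows where both groups are constant get p = NA.
.welch_rows <- function(xt, xn) {
  n1 <- ncol(xt); n2 <- ncol(xn)
  if (n1 < 2 || n2 < 2) .stop("need >=2 samples per group for the t-test")
  m1 <- rowMeans(xt); m2 <- rowMeans(xn)
  v1 <- .row_vars(xt); v2 <- .row_vars(xn)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  tstat[zero] <- NA_real_; df[zero] <- NA_real_; p[zero] <- NA_real_
  list(t = tstat, df = df, p = p)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up BH adjustment, order-preserving with the input vector.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  .check_prob(p)
  stats::p.adjust(p, method = "BH")
}

#' Per-probe differential expression between tumor and normal samples
#'
#' Computes linear-scale fold change with direction, a two-sided Welch
#' (unequal-variance) unpaired t-test on log2 intensities, and BH-adjusted
#' q-values. Probes whose intensities are constant in both groups have an
#' undefined test and are flagged (`p = NA`) and excluded from the BH
#' family.
#'
#' @param es An `expression_set` (see [read_expression()]).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Data frame of class `de_result`: `probe_id`, `biotype`,
#'   `mean_tumor`, `mean_normal`, `fc`, `direction`, `t`, `df`, `p`, `q`.
#' @export
run_diffexp <- function(es, var_equal = FALSE) {
  xt_lin <- subset_group(es, "tumor")
  xn_lin <- subset_group(es, "normal")
  if (identical(es$scale_tag, "log2")) {
    lt <- xt_lin; ln <- xn_lin
    xt_lin <- 2^xt_lin; xn_lin <- 2^xn_lin
  } else {
    lt <- .to_log2(xt_lin, "linear"); ln <- .to_log2(xn_lin, "linear")
  }
  mt <- rowMeans(xt_lin); mn <- rowMeans(xn_lin)
  fcd <- fold_change(mt, mn)
  tt <- if (var_equal) .pooled_rows(lt, ln) else .welch_rows(lt, ln)
  q <- rep(NA_real_, length(tt$p))
  ok <- !is.na(tt$p)
  q[ok] <- bh_fdr(tt$p[ok])
  bt <- es$annotation$biotype[match(rownames(es$expr), es$annotation$probe_id)]
  out <- data.frame(probe_id = rownames(es$expr), biotype = bt,
                    mean_tumor = mt, mean_normal = mn,
                    fc = fcd$fc, direction = fcd$direction,
                    t = tt$t, df = tt$df, p = tt$p, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", class(out))
  out
}

# Pooled-variance (classical) unpaired t, for the var_equal option.
.pooled_rows <- function(xt, xn) {
  n1 <- ncol(xt); n2 <- ncol(xn)
  m1 <- rowMeans(xt); m2 <- rowMeans(xn)
  sp2 <- ((n1 - 1) * .row_vars(xt) + (n2 - 1) * .row_vars(xn)) / (n1 + n2 - 2)
  se2 <- sp2 * (1 / n1 + 1 / n2)
  tstat <- (m1 - m2) / sqrt(se2)
  df <- rep(n1 + n2 - 2, length(tstat))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  tstat[zero] <- NA_real_; p[zero] <- NA_real_
  list(t = tstat, df = df, p = p)
}

#' Threshold a differential-expression table into up/down lists
#'
#' Retains probes with fold change at or above `fc_min` (inclusive) and
#' raw p-value strictly below `p_max`, partitioned by direction. The raw p
#' (not the BH q) is thresholded; q is carried along for reporting.
#'
#' @param de A `de_result` data frame from [run_diffexp()].
#' @param fc_min Minimum fold-change magnitude (default 2.0).
#' @param p_max Strict p-value ceiling (default 0.05).
#' @return List with data frames `up` and `down`.
#' @export
filter_de <- function(de, fc_min = 2.0, p_max = 0.05) {
  keep <- !is.na(de$p) & de$fc >= fc_min & de$p < p_max
  list(up = de[keep & de$direction == "up", , drop = FALSE],
       down = de[keep & de$direction == "down", , drop = FALSE])
}
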