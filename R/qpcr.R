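#' Relative expression by the 2^-DeltaCt method
#'
#' DeltaCt = target Ct minus reference Ct (GAPDH for mRNA/lncRNA, U6 for
#' miRNA); relative expression is `2^-DeltaCt`.
#'
#' @param ct Target threshold cycle(s).
#' @param reference_ct Matched reference-gene threshold cycle(s).
#' @return Unitless relative expression, vectorized.
#' @export
relative_expression <- function(ct, reference_ct) {
  if (any(!is.finite(ct)) || any(!is.finite(reference_ct)))
    .stop("Ct values must be finite")
  2^-(ct - reference_ct)
}

#' Read a qPCR Ct table
#'
#' TSV with columns `sample_id`, `tissue` (tumor/normal), `target_name`,
#' `ct`, `reference_name`, `reference_ct`. Technical replicates (repeated
#' rows per sample/target) are averaged on the Ct scale.
#'
#' @param path TSV path.
#' @return Data frame with one row per (sample, target) and a computed
#'   `expression` column (2^-DeltaCt).
#' @export
read_ct_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "tissue", "target_name", "ct",
            "reference_name", "reference_ct")
  if (!all(need %in% names(df)))
    .stop("Ct table must have columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0) ||
      any(!is.finite(df$reference_ct)) || any(df$reference_ct <= 0))
    .stop("Ct values must be finite and positive")
  agg <- stats::aggregate(cbind(ct, reference_ct) ~
                            sample_id + tissue + target_name + reference_name,
                          data = df, FUN = mean)
  agg$expression <- relative_expression(agg$ct, agg$reference_ct)
  agg
}

#' Tumor/normal comparison of relative expression
#'
#' Two-tailed t-test on log2 relative expression (equivalently on
#' -DeltaCt), paired by patient by default. Zero-variance paired
#' differences make the statistic degenerate; the result is then flagged
#' with `p = NA` and `degenerate = TRUE`.
#'
#' @param tumor,normal Relative expression values; when `paired = TRUE`
#'   they must be aligned by patient pair.
#' @param paired Pair the samples by position (default TRUE, matching a
#'   matched tumor/non-tumor design).
#' @return List: `mean_tumor`, `mean_normal`, `p`, `degenerate`.
#' @export
paired_comparison <- function(tumor, normal, paired = TRUE) {
  if (paired && length(tumor) != length(normal))
    .stop("paired comparison needs aligned tumor/normal vectors")
  if (length(tumor) < 2 || length(normal) < 2)
    .stop("need at least 2 pairs")
  lt <- log2(tumor); ln <- log2(normal)
  p <- NA_real_; degenerate <- FALSE
  if (paired && stats::sd(lt - ln) == 0) {
    # zero-variance differences: no dispersion to test against
    if (all(lt == ln)) p <- 1 else degenerate <- TRUE
  } else {
    res <- tryCatch(
      stats::t.test(lt, ln, paired = paired, var.equal = FALSE),
      error = function(e) NULL)
    if (is.null(res)) degenerate <- TRUE else p <- unname(res$p.value)
  }
  list(mean_tumor = mean(tumor), mean_normal = mean(normal),
       p = p, degenerate = degenerate)
}

#' Correlation between two genes' relative expression
#'
#' Pearson correlation with a two-sided p-value from the t transform
#' (shared with the co-expression screen).
#'
#' @param expr_a,expr_b Paired relative expression values, n >= 3.
#' @return List with `r` and `p`.
#' @export
expression_correlation <- function(expr_a, expr_b) {
  r <- pearson_r(expr_a, expr_b)
  list(r = r, p = as.numeric(correlation_p(r, length(expr_a))))
}

#' Per-target qPCR validation summary
#'
#' For every target in a Ct table, compares tumor versus normal relative
#' expression with [paired_comparison()] (pairs aligned by `sample_id`
#' prefix shared between tissues, i.e. the patient identifier).
#'
#' @param ct_table Output of [read_ct_table()].
#' @param pair_id Optional vector mapping each row to a patient pair; by
#'   default the `sample_id` is used as the pair key (one tumor and one
#'   normal row per sample_id/target).
#' @param paired Use the paired test (default TRUE).
#' @return Data frame: `target_name`, `mean_tumor`, `mean_normal`,
#'   `ratio`, `p`, `n_pairs`.
#' @export
qpcr_summary <- function(ct_table, pair_id = NULL, paired = TRUE) {
  ct_table$pair <- if (is.null(pair_id)) ct_table$sample_id else pair_id
  targets <- sort(unique(ct_table$target_name))
  rows <- lapply(targets, function(tg) {
    sub <- ct_table[ct_table$target_name == tg, ]
    tum <- sub[sub$tissue == "tumor", ]
    nor <- sub[sub$tissue == "normal", ]
    common <- intersect(tum$pair, nor$pair)
    tum <- tum[match(common, tum$pair), ]
    nor <- nor[match(common, nor$pair), ]
    cmp <- paired_comparison(tum$expression, nor$expression, paired = paired)
    data.frame(target_name = tg, mean_tumor = cmp$mean_tumor,
               mean_normal = cmp$mean_normal,
               ratio = cmp$mean_tumor / cmp$mean_normal,
               p = cmp$p, n_pairs = length(common),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
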