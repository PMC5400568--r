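#' Read a miRNA-overexpression response table
#'
#' TSV with columns `gene_symbol`, `fc` (magnitude >= 1), `direction`
#' (`up`/`down` upon miRNA overexpression) and `p`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with harmonized (uppercased) gene symbols.
#' @export
read_response_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene_symbol", "fc", "direction", "p")
  if (!all(need %in% names(df)))
    .stop("response table must have columns: %s", paste(need, collapse = ", "))
  if (any(df$fc < 1)) .stop("response fold changes must be magnitudes >= 1")
  .check_prob(df$p, "response p")
  df$gene_symbol <- toupper(as.character(df$gene_symbol))
  df
}

#' Select candidate miRNA target genes from the combined analysis
#'
#' Implements the combined-microarray inclusion criteria: genes
#' down-regulated upon miRNA overexpression (fold change >= `fc_min`,
#' p < `p_max`), up-regulated in tumor versus normal on the expression
#' array at the same thresholds, and possessing a miRNA response element.
#' The mirror configuration (up on overexpression, down in tumor) is
#' available for miRNAs acting in the opposite sense.
#'
#' Gene symbols are harmonized by uppercasing on both sides; response-table
#' symbols absent from the DE table are dropped silently (they cannot
#' satisfy the tumor criterion).
#'
#' @param response Response table (see [read_response_table()]).
#' @param de A `de_result` table whose probes carry gene symbols either as
#'   `gene_symbol` column or as `probe_id`.
#' @param mre_genes Character vector of gene symbols with MRE support.
#' @param fc_min,p_max Thresholds applied to both arrays (defaults 2.0 and
#'   0.05).
#' @param response_direction Required direction on overexpression
#'   (default `"down"`).
#' @param tumor_direction Required direction in tumor (default `"up"`).
#' @return Data frame (one row per candidate) with per-gene evidence:
#'   response fc/p, tumor fc/p, and the MRE flag. Empty inputs give an
#'   empty set with a warning.
#' @export
select_candidates <- function(response, de, mre_genes,
                              fc_min = 2.0, p_max = 0.05,
                              response_direction = "down",
                              tumor_direction = "up") {
  if (!nrow(response) || !nrow(de)) {
    warning("empty input table; candidate set is empty", call. = FALSE)
    return(.empty_candidates())
  }
  sym <- if ("gene_symbol" %in% names(de)) de$gene_symbol else de$probe_id
  de$.sym <- toupper(as.character(sym))
  mre_genes <- toupper(mre_genes)

  resp_ok <- response[response$direction == response_direction &
                        response$fc >= fc_min & response$p < p_max, ]
  de_ok <- de[!is.na(de$p) & de$direction == tumor_direction &
                de$fc >= fc_min & de$p < p_max, ]
  genes <- intersect(intersect(resp_ok$gene_symbol, de_ok$.sym), mre_genes)
  genes <- sort(genes)
  if (!length(genes)) return(.empty_candidates())
  ri <- match(genes, resp_ok$gene_symbol)
  di <- match(genes, de_ok$.sym)
  data.frame(gene_symbol = genes,
             response_fc = resp_ok$fc[ri], response_p = resp_ok$p[ri],
             tumor_fc = de_ok$fc[di], tumor_p = de_ok$p[di],
             mre = TRUE, row.names = NULL, stringsAsFactors = FALSE)
}

.empty_candidates <- function() {
  data.frame(gene_symbol = character(), response_fc = numeric(),
             response_p = numeric(), tumor_fc = numeric(),
             tumor_p = numeric(), mre = logical(),
             stringsAsFactors = FALSE)
}
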