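#' Load the packaged miR-133b worked example
#'
#' Bundled fixture tables for the colorectal-cancer miR-133b case study:
#' the overexpression response table, tumor DE records for the mRNA and
#' lncRNA sides, MRE gene flags, the dual-predictor lncRNA prediction
#' records, and the co-expression edges of the published network. Gene
#' and transcript memberships follow the published screen; the numeric
#' statistics are synthetic stand-ins that encode which criteria each
#' entry passes (the originals are not printed per gene).
#'
#' @return Named list of data frames / vectors: `response`, `de_mrna`,
#'   `mre_genes`, `predictions`, `de_lncrna`, `cnc_edges`.
#' @export
mir133b_example <- function() {
  d <- system.file("extdata", "mir133b", package = "ceRNAforge")
  mre <- readLines(file.path(d, "mre_genes.txt"))
  mre <- trimws(mre[!startsWith(mre, "#") & nzchar(mre)])
  list(
    response = read_response_table(file.path(d, "response_mir133b.tsv")),
    de_mrna = .read_tsv(file.path(d, "de_mrna_tumor.tsv")),
    mre_genes = mre,
    predictions = .read_tsv(file.path(d, "predictions_lncrna.tsv")),
    de_lncrna = .read_tsv(file.path(d, "de_lncrna_tumor.tsv")),
    cnc_edges = .read_tsv(file.path(d, "cnc_edges_network.tsv"))
  )
}

#' Reconstruct the worked-example ceRNA network
#'
#' Runs the candidate selection, dual-predictor consensus and network
#' assembly over the packaged miR-133b fixtures; with the default
#' thresholds this reproduces the published 9-lncRNA / 3-mRNA network
#' around UBD, EPAS1 and CES1.
#'
#' @param fc_min,p_max Selection thresholds (defaults 2.0 and 0.05).
#' @return List: `candidates`, `mre_lncrnas`, `network`.
#' @export
mir133b_network <- function(fc_min = 2.0, p_max = 0.05) {
  ex <- mir133b_example()
  candidates <- select_candidates(ex$response, ex$de_mrna, ex$mre_genes,
                                  fc_min = fc_min, p_max = p_max)
  mre_lnc <- consensus_mre(ex$predictions,
                           required_predictors = c("RNA22", "PITA"),
                           mirna_name = "miR-133b")
  net <- assemble_network(ex$de_lncrna, ex$cnc_edges, candidates,
                          mre_lncrnas = mre_lnc, mirna_name = "miR-133b")
  list(candidates = candidates, mre_lncrnas = mre_lnc, network = net)
}
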