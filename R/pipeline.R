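#' Pipeline configuration with the study-default thresholds
#'
#' Defaults are the canonical screen thresholds: DE fold change >= 2.0
#' with p < 0.05, co-expression |PCC| >= 0.995 with BH FDR < 0.05, GSEA
#' |NES| > 1 with FDR < 0.2 and 1000 sample permutations. Any deviation
#' must be set explicitly; the run manifest echoes the effective values.
#'
#' @param fc_min,p_max Differential-expression thresholds.
#' @param pcc_min,cnc_fdr_max Co-expression screen thresholds.
#' @param nes_min,gsea_fdr_max,n_perm GSEA thresholds and permutations.
#' @param predictors Predictor labels whose intersection defines MRE
#'   consensus (default `"builtin"`, the packaged seed-match scanner; set
#'   to `c("RNA22", "PITA")` when ingesting external prediction tables).
#' @param min_site_class Weakest seed-site class the built-in scanner
#'   accepts as MRE evidence (default `"7mer-A1"`).
#' @param seed RNG seed for stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fc_min = 2.0, p_max = 0.05,
                            pcc_min = 0.995, cnc_fdr_max = 0.05,
                            nes_min = 1.0, gsea_fdr_max = 0.2,
                            n_perm = 1000,
                            predictors = "builtin",
                            min_site_class = "7mer-A1",
                            seed = 1) {
  chk <- function(x, lo, hi, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
      .stop("config '%s' must be a number in [%s, %s]", name, lo, hi)
  }
  chk(fc_min, 1, Inf, "fc_min"); chk(p_max, 0, 1, "p_max")
  chk(pcc_min, 0, 1, "pcc_min"); chk(cnc_fdr_max, 0, 1, "cnc_fdr_max")
  chk(nes_min, 0, Inf, "nes_min"); chk(gsea_fdr_max, 0, 1, "gsea_fdr_max")
  chk(n_perm, 1, Inf, "n_perm")
  structure(as.list(environment())[setdiff(ls(), "chk")],
            class = "pipeline_config")
}

#' Read a YAML pipeline configuration
#'
#' Threshold keys override [pipeline_config()] defaults; path keys
#' (`matrix`, `design`, `annotation`, `fasta`, `perturbation`, `gmt`,
#' prediction tables) are returned alongside under `paths`.
#'
#' @param path YAML file.
#' @return List with `config` (a `pipeline_config`) and `paths`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr_keys <- names(formals(pipeline_config))
  thr <- y[intersect(names(y), thr_keys)]
  cfg <- do.call(pipeline_config, thr)
  list(config = cfg, paths = y[setdiff(names(y), thr_keys)])
}

#' Run the full ceRNA construction pipeline
#'
#' Executes, in order: differential expression on all probes; DE
#' filtering split by biotype; MRE scanning of the supplied transcripts
#' with the built-in scanner (plus any external prediction records) and
#' the consensus rule; candidate target selection against the
#' miRNA-overexpression response table; the coding/non-coding
#' co-expression screen of candidates against all lncRNAs; and network
#' assembly. A manifest records the seed, effective thresholds, per-stage
#' row counts and a content digest of the triplet set.
#'
#' @param es An `expression_set`.
#' @param perturbation Response table (`gene_symbol`, `fc`, `direction`,
#'   `p`).
#' @param sequences Named RNA sequences for the probes' transcripts.
#' @param mirna A [mature_mirna()].
#' @param config A [pipeline_config()].
#' @param prediction_records Optional external predictor records to merge
#'   with the built-in scanner's.
#' @return List of class `cerna_pipeline_result`: `de`, `de_filtered`,
#'   `mre_sites`, `mre_consensus`, `candidates`, `cnc_edges`, `network`,
#'   `manifest`.
#' @export
run_pipeline <- function(es, perturbation, sequences, mirna,
                         config = pipeline_config(),
                         prediction_records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  de <- run_diffexp(es)
  flt <- filter_de(de, config$fc_min, config$p_max)
  de_lnc <- rbind(flt$up[flt$up$biotype == "lncRNA", ],
                  flt$down[flt$down$biotype == "lncRNA", ])
  de_mrna_up <- flt$up[flt$up$biotype == "mRNA", ]

  sites <- seed_match_scan(mirna, sequences)
  records <- sites_to_predictions(sites, mirna$name,
                                  min_class = config$min_site_class)
  if (!is.null(prediction_records)) records <- rbind(records, prediction_records)
  mre_ids <- consensus_mre(records, required_predictors = config$predictors,
                           mirna_name = mirna$name)

  ann <- es$annotation
  mre_genes <- ann$gene_symbol[ann$probe_id %in% mre_ids]
  de_mrna <- de[de$biotype == "mRNA", ]
  candidates <- suppressWarnings(
    select_candidates(perturbation, de_mrna, mre_genes,
                      fc_min = config$fc_min, p_max = config$p_max))

  lnc_ids <- ann$probe_id[ann$biotype == "lncRNA"]
  cand_probes <- ann$probe_id[toupper(ann$gene_symbol) %in%
                                toupper(candidates$gene_symbol)]
  cnc <- if (nrow(candidates)) {
    build_cnc(es, cand_probes, lnc_ids,
              pcc_min = config$pcc_min, fdr_max = config$cnc_fdr_max)
  } else .empty_cnc()

  net <- assemble_network(de_lnc, cnc, candidates,
                          mre_lncrnas = intersect(mre_ids, lnc_ids),
                          mirna_name = mirna$name)
  s <- summary(net)
  manifest <- list(
    seed = config$seed,
    thresholds = config[c("fc_min", "p_max", "pcc_min", "cnc_fdr_max",
                          "nes_min", "gsea_fdr_max", "n_perm",
                          "min_site_class")],
    predictors = config$predictors,
    counts = list(probes = nrow(de),
                  de_lncRNA = nrow(de_lnc),
                  de_mRNA_up = nrow(de_mrna_up),
                  mre_transcripts = length(mre_ids),
                  candidates = nrow(candidates),
                  cnc_edges = nrow(cnc),
                  network_lncRNA = s$n_lncRNA,
                  network_mRNA = s$n_mRNA,
                  triplets = s$n_triplets),
    triplet_digest = paste(sprintf("%s|%s|%s", net$triplets$lncRNA_id,
                                   net$triplets$mRNA_id, net$triplets$sign),
                           collapse = ";"))
  structure(list(de = de, de_filtered = flt, mre_sites = sites,
                 mre_consensus = mre_ids, candidates = candidates,
                 cnc_edges = cnc, network = net, manifest = manifest),
            class = "cerna_pipeline_result")
}

#' Write pipeline outputs to a directory
#'
#' Emits the DE table, candidate set, co-expression edges, network files
#' (SIF, GraphML, TSV) and the JSON run manifest.
#'
#' @param result A `cerna_pipeline_result`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(result$de, file.path(dir, "diffexp.tsv"))
  .write_tsv(result$candidates, file.path(dir, "candidates.tsv"))
  .write_tsv(result$cnc_edges, file.path(dir, "cnc_edges.tsv"))
  export_network(result$network, file.path(dir, "network.sif"), "sif")
  export_network(result$network, file.path(dir, "network.graphml"), "graphml")
  export_network(result$network, file.path(dir, "network_edges.tsv"), "tsv")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
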