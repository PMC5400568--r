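#' Assemble the miRNA-mediated lncRNA-mRNA ceRNA network
#'
#' A lncRNA-miRNA-mRNA triplet is retained when (i) the lncRNA passed the
#' differential-expression filter and is correlated with a candidate
#' target mRNA at the co-expression thresholds (the supplied `cnc_edges`
#' are taken to be already thresholded), and (ii) the lncRNA possesses an
#' MRE for the miRNA by the consensus rule. The mRNA side's MRE evidence
#' is inherited from the candidate set, whose inclusion criteria already
#' required it. The result is a tripartite network with one miRNA hub:
#' sequence-match edges from the hub to every lncRNA and mRNA node, and
#' signed correlation edges between lncRNAs and mRNAs.
#'
#' @param de_lncrnas Data frame of lncRNAs passing the DE filter; needs
#'   columns `probe_id` and `direction` (e.g. rbind of [filter_de()]'s
#'   `up` and `down` restricted to lncRNA probes).
#' @param cnc_edges Thresholded edge list from [build_cnc()].
#' @param candidates Candidate target set from [select_candidates()]
#'   (gene symbols matched against `cnc_edges$mRNA_id`, case-insensitive).
#' @param mre_lncrnas Transcript IDs with consensus MRE support, from
#'   [consensus_mre()].
#' @param mirna_name Name of the hub miRNA.
#' @return Object of class `cerna_network`: list with `mirna`, `nodes`
#'   (id, type), `edges` (from, to, type) and `triplets`.
#' @export
assemble_network <- function(de_lncrnas, cnc_edges, candidates,
                             mre_lncrnas, mirna_name) {
  cand_syms <- toupper(candidates$gene_symbol)
  trip <- cnc_edges[
    cnc_edges$lncRNA_id %in% de_lncrnas$probe_id &
      cnc_edges$lncRNA_id %in% mre_lncrnas &
      toupper(cnc_edges$mRNA_id) %in% cand_syms, , drop = FALSE]
  trip <- trip[order(trip$lncRNA_id, trip$mRNA_id), , drop = FALSE]
  rownames(trip) <- NULL
  if (nrow(trip)) {
    trip$lncRNA_direction <-
      de_lncrnas$direction[match(trip$lncRNA_id, de_lncrnas$probe_id)]
  } else {
    trip$lncRNA_direction <- character(0)
  }

  lnc_nodes <- sort(unique(trip$lncRNA_id))
  mrna_nodes <- sort(unique(trip$mRNA_id))
  nodes <- data.frame(
    id = c(mirna_name, lnc_nodes, mrna_nodes),
    type = c("miRNA", rep("lncRNA", length(lnc_nodes)),
             rep("mRNA", length(mrna_nodes))),
    stringsAsFactors = FALSE)
  n_seq <- length(lnc_nodes) + length(mrna_nodes)
  seq_edges <- data.frame(
    from = rep(mirna_name, n_seq),
    to = c(lnc_nodes, mrna_nodes),
    type = rep("sequence-match", n_seq), stringsAsFactors = FALSE)
  cor_edges <- data.frame(
    from = trip$lncRNA_id, to = trip$mRNA_id,
    type = if (nrow(trip)) paste0(trip$sign, "-correlation") else character(0),
    stringsAsFactors = FALSE)
  structure(list(mirna = mirna_name, nodes = nodes,
                 edges = rbind(seq_edges, cor_edges), triplets = trip),
            class = "cerna_network")
}

#' Summary counts of a ceRNA network
#'
#' @param object A `cerna_network`.
#' @param ... Unused.
#' @return List: `n_lncRNA`, `n_mRNA`, `n_triplets` and edge counts by
#'   type.
#' @method summary cerna_network
#' @export
summary.cerna_network <- function(object, ...) {
  et <- table(factor(object$edges$type,
                     levels = c("sequence-match", "positive-correlation",
                                "negative-correlation")))
  list(n_lncRNA = sum(object$nodes$type == "lncRNA"),
       n_mRNA = sum(object$nodes$type == "mRNA"),
       n_triplets = nrow(object$triplets),
       edges = as.list(et))
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("ceRNA network for %s: %d lncRNA node(s), %d mRNA node(s), %d edge(s)\n",
              x$mirna, s$n_lncRNA, s$n_mRNA, nrow(x$edges)))
  invisible(x)
}

#' Export a ceRNA network for Cytoscape
#'
#' `sif` writes simple-interaction lines (`source TAB interaction TAB
#' target`); `graphml` preserves node `type` and edge `type` attributes
#' via igraph; `tsv` writes the typed edge list.
#'
#' @param network A `cerna_network`.
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    lines <- if (nrow(e)) paste(e$from, e$type, e$to, sep = "\t") else character()
    writeLines(lines, path)
  } else if (format == "tsv") {
    .write_tsv(e, path)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(e)) e else data.frame(from = character(), to = character(),
                                     type = character()),
      directed = FALSE, vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-verify every triplet of an assembled network
#'
#' Independent predicate check used as an internal consistency oracle:
#' each reported triplet must re-pass the DE-membership, MRE-membership
#' and candidate-membership predicates one gene at a time.
#'
#' @inheritParams assemble_network
#' @param network The assembled `cerna_network`.
#' @return TRUE if all triplets re-pass; otherwise stops.
#' @export
verify_triplets <- function(network, de_lncrnas, candidates, mre_lncrnas) {
  t <- network$triplets
  for (i in seq_len(nrow(t))) {
    ok <- t$lncRNA_id[i] %in% de_lncrnas$probe_id &&
      t$lncRNA_id[i] %in% mre_lncrnas &&
      toupper(t$mRNA_id[i]) %in% toupper(candidates$gene_symbol)
    if (!ok) .stop("triplet %s-%s fails re-verification",
                   t$lncRNA_id[i], t$mRNA_id[i])
  }
  TRUE
}
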