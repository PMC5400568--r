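# In-code fixture builders shared across test files.

# Minimal paired expression set: `values` is a probes x samples matrix
# (linear scale unless scale_tag says otherwise).
make_es <- function(values, n_pairs = ncol(values) / 2,
                    scale_tag = "linear",
                    probe_ids = sprintf("PR%02d", seq_len(nrow(values))),
                    biotype = rep("mRNA", nrow(values))) {
  pair_ids <- sprintf("P%02d", seq_len(n_pairs))
  sample_ids <- c(paste0(pair_ids, "T"), paste0(pair_ids, "N"))
  stopifnot(length(sample_ids) == ncol(values))
  dimnames(values) <- list(probe_ids, sample_ids)
  design <- data.frame(sample_id = sample_ids,
                       group = rep(c("tumor", "normal"), each = n_pairs),
                       pair_id = rep(pair_ids, 2),
                       stringsAsFactors = FALSE)
  ann <- data.frame(probe_id = probe_ids, biotype = biotype,
                    gene_symbol = probe_ids, stringsAsFactors = FALSE)
  validate_expression_set(values, design, ann, scale_tag)
}

# Write a tiny matrix/design/annotation TSV triple into `dir`.
write_tiny_tsvs <- function(dir, values, probe_ids, sample_ids,
                            biotype = rep("mRNA", length(probe_ids))) {
  mpath <- file.path(dir, "m.tsv"); dpath <- file.path(dir, "d.tsv")
  apath <- file.path(dir, "a.tsv")
  df <- data.frame(probe_id = probe_ids, values, check.names = FALSE)
  colnames(df) <- c("probe_id", sample_ids)
  write.table(df, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  n <- length(sample_ids)
  design <- data.frame(sample_id = sample_ids,
                       group = rep(c("tumor", "normal"), length.out = n),
                       pair_id = sprintf("P%02d", rep(seq_len(ceiling(n / 2)),
                                                      each = 2))[seq_len(n)])
  write.table(design, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(probe_id = probe_ids, biotype = biotype)
  write.table(ann, apath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mpath, design = dpath, annotation = apath)
}
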