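#' Read and validate an expression matrix with its design and annotation
#'
#' Reads a probes-by-samples intensity matrix (TSV, first column probe IDs,
#' header row of sample IDs), a sample design table (`sample_id`, `group`,
#' `pair_id`) describing the paired tumor/normal layout, and a probe
#' annotation table (`probe_id`, `biotype`, optional `gene_symbol`,
#' `transcript_id`) classifying each probe as lncRNA or mRNA.
#'
#' Probes containing any missing value are dropped with a warning;
#' missing-value imputation is out of scope.
#'
#' @param matrix_path Path to the TSV expression matrix.
#' @param design_path Path to the TSV sample design table.
#' @param annotation_path Path to the TSV probe annotation table.
#' @param scale_tag Either `"linear"` (non-negative intensities; default) or
#'   `"log2"`, recording the scale of the stored values. Statistics that
#'   require log2 intensities transform internally based on this tag.
#' @return A list of class `expression_set` with elements `expr` (numeric
#'   matrix), `design` (data.frame), `annotation` (data.frame) and
#'   `scale_tag`.
#' @export
read_expression <- function(matrix_path, design_path, annotation_path,
                            scale_tag = c("linear", "log2")) {
  scale_tag <- match.arg(scale_tag)
  raw <- .read_tsv(matrix_path)
  if (ncol(raw) < 2) .stop("expression matrix needs a probe column plus >=1 sample")
  probe_ids <- as.character(raw[[1L]])
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      coerced <- suppressWarnings(as.numeric(vals[[j]]))
      bad <- which(is.na(coerced) & !is.na(vals[[j]]))
      if (length(bad))
        .stop("non-numeric cell at probe '%s', sample '%s'",
              probe_ids[bad[1]], names(vals)[j])
      vals[[j]] <- coerced
    }
  }
  m <- as.matrix(vals)
  inf <- which(is.infinite(m), arr.ind = TRUE)
  if (nrow(inf))
    .stop("non-finite value at probe '%s', sample '%s'",
          probe_ids[inf[1, 1]], colnames(m)[inf[1, 2]])
  rownames(m) <- probe_ids
  design <- .read_tsv(design_path)
  annotation <- .read_tsv(annotation_path)
  validate_expression_set(m, design, annotation, scale_tag)
}

#' Validate the expression matrix / design / annotation triple
#'
#' Enforces the container invariants: unique probe and sample identifiers,
#' finite values, every design sample present in the matrix, at most one
#' tumor and one normal per patient pair, and a mandatory lncRNA/mRNA
#' biotype per annotated probe. Probes with missing values are dropped
#' with a warning.
#'
#' @param expr Numeric probes-by-samples matrix with dimnames.
#' @param design Data frame with columns `sample_id`, `group`, `pair_id`.
#' @param annotation Data frame with columns `probe_id`, `biotype`.
#' @param scale_tag `"linear"` or `"log2"`.
#' @return An `expression_set` list.
#' @export
validate_expression_set <- function(expr, design, annotation,
                                    scale_tag = "linear") {
  probe_ids <- rownames(expr)
  sample_ids <- colnames(expr)
  if (is.null(probe_ids) || is.null(sample_ids))
    .stop("expression matrix must carry probe and sample dimnames")
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup)) .stop("duplicated probe ID: '%s'", dup[1])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) .stop("duplicated sample ID: '%s'", dup[1])
  if (anyNA(expr)) {
    drop <- rowSums(is.na(expr)) > 0
    warning(sprintf("dropping %d probe(s) with missing values", sum(drop)),
            call. = FALSE)
    expr <- expr[!drop, , drop = FALSE]
    probe_ids <- rownames(expr)
  }
  if (identical(scale_tag, "linear") && any(expr < 0))
    .stop("linear-scale intensities must be non-negative")

  need <- c("sample_id", "group", "pair_id")
  if (!all(need %in% names(design)))
    .stop("design table must have columns: %s", paste(need, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  design$group <- as.character(design$group)
  design$pair_id <- as.character(design$pair_id)
  if (!all(design$group %in% c("tumor", "normal")))
    .stop("design group must be 'tumor' or 'normal'")
  missing_s <- setdiff(design$sample_id, sample_ids)
  if (length(missing_s))
    .stop("design sample '%s' absent from expression matrix", missing_s[1])
  tab <- table(design$pair_id, design$group)
  if (any(tab > 1))
    .stop("pair '%s' has more than one sample of the same group",
          rownames(tab)[which(rowSums(tab > 1) > 0)[1]])

  need <- c("probe_id", "biotype")
  if (!all(need %in% names(annotation)))
    .stop("annotation table must have columns: %s", paste(need, collapse = ", "))
  annotation$probe_id <- as.character(annotation$probe_id)
  dup <- annotation$probe_id[duplicated(annotation$probe_id)]
  if (length(dup)) .stop("duplicated annotation probe ID: '%s'", dup[1])
  if (!all(annotation$biotype %in% c("lncRNA", "mRNA")))
    .stop("annotation biotype must be 'lncRNA' or 'mRNA'")

  structure(list(expr = expr, design = design, annotation = annotation,
                 scale_tag = scale_tag),
            class = "expression_set")
}

#' Write an expression set back to its three TSV files
#'
#' @param es An `expression_set`.
#' @param matrix_path,design_path,annotation_path Output TSV paths.
#' @return Invisibly, the matrix path.
#' @export
write_expression <- function(es, matrix_path, design_path, annotation_path) {
  df <- data.frame(probe_id = rownames(es$expr), es$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, matrix_path)
  .write_tsv(es$design, design_path)
  .write_tsv(es$annotation, annotation_path)
  invisible(matrix_path)
}

#' Subset an expression set by sample group
#'
#' @param es An `expression_set`.
#' @param group `"tumor"` or `"normal"`.
#' @return Numeric matrix restricted to that group's samples, probe order
#'   unchanged.
#' @export
subset_group <- function(es, group = c("tumor", "normal")) {
  group <- match.arg(group)
  ids <- es$design$sample_id[es$design$group == group]
  es$expr[, ids, drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one gene set per line, `name TAB description TAB member...`.
#' Member order is preserved; symbols are uppercased for matching.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (member gene symbols), with a
#'   `description` attribute per element.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stop("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      .stop("GMT line %d has fewer than 3 fields", i)
    name <- f[1]
    if (name %in% names(sets)) .stop("duplicate gene-set name '%s'", name)
    members <- toupper(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) .stop("GMT line %d ('%s') has no members", i, name)
    attr(members, "description") <- f[2]
    sets[[name]] <- members
  }
  sets
}

#' Read transcript sequences from FASTA as RNA
#'
#' Sequences are uppercased and DNA T is normalized to U (all scanning is
#' done in the RNA alphabet). IDs are the first whitespace-delimited token
#' of each header and must be unique.
#'
#' @param path Path to a FASTA file over the alphabet A/C/G/T/U/N.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta_rna <- function(path) {
  if (!file.exists(path)) .stop("file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) .stop("duplicate FASTA record ID: '%s'", dup[1])
  seqs <- chartr("T", "U", toupper(as.character(ss)))
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad))
    .stop("record '%s' contains characters outside A/C/G/T/U/N", ids[which(bad)[1]])
  names(seqs) <- ids
  seqs
}

#' Write RNA sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    writeLines(seqs[[id]], con)
  }
  invisible(path)
}
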