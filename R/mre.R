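#' Construct a mature miRNA object
#'
#' @param name miRNA name (e.g. `"miR-133b"`).
#' @param sequence Mature sequence, 5' to 3', RNA alphabet (T is accepted
#'   and normalized to U); length >= 8 so that all seed classes are defined.
#' @return A list of class `mature_mirna`.
#' @export
mature_mirna <- function(name, sequence) {
  sequence <- chartr("T", "U", toupper(sequence))
  if (grepl("[^ACGU]", sequence))
    .stop("miRNA sequence must be over A/C/G/U")
  if (nchar(sequence) < 8)
    .stop("miRNA sequence must be at least 8 nt (seed classes need positions 1-8)")
  structure(list(name = name, sequence = sequence), class = "mature_mirna")
}

# Reverse complement in the RNA alphabet (Watson-Crick only; no wobble).
.rna_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

# Target-site patterns (transcript 5'->3') for the four canonical seed
# classes. The site opposite miRNA position 1 is required to be an A for
# the A1 classes, regardless of the miRNA's own first base.
.seed_patterns <- function(mirna) {
  seed27 <- substr(mirna$sequence, 2, 7)
  seed28 <- substr(mirna$sequence, 2, 8)
  rc6 <- .rna_revcomp(seed27)
  rc7 <- .rna_revcomp(seed28)
  c(`6mer` = rc6,
    `7mer-A1` = paste0(rc6, "A"),
    `7mer-m8` = rc7,
    `8mer` = paste0(rc7, "A"))
}

#' Scan transcripts for canonical miRNA seed-match sites
#'
#' Reports every occurrence of the four canonical site classes on the
#' transcript sense strand: `6mer` (Watson-Crick pairing to miRNA
#' positions 2-7), `7mer-m8` (2-8), `7mer-A1` (2-7 plus an A opposite
#' position 1) and `8mer` (2-8 plus the A). Overlapping occurrences of
#' different classes are each reported; an 8mer therefore also yields its
#' nested 7mer and 6mer sites at consistent coordinates. G:U wobble pairs
#' are not counted. Coordinates are 0-based half-open on the transcript.
#'
#' @param mirna A [mature_mirna()].
#' @param transcripts Named character vector of RNA sequences (see
#'   [read_fasta_rna()]); sequences shorter than 8 nt yield no sites.
#' @return Data frame with columns `transcript_id`, `start`, `end`,
#'   `site_class`.
#' @export
seed_match_scan <- function(mirna, transcripts) {
  stopifnot(inherits(mirna, "mature_mirna"))
  if (is.null(names(transcripts)) && length(transcripts))
    .stop("transcripts must be named")
  pats <- .seed_patterns(mirna)
  out <- vector("list", length(transcripts) * length(pats))
  k <- 0L
  for (i in seq_along(transcripts)) {
    seq_i <- transcripts[[i]]
    if (nchar(seq_i) < 8) next
    for (cls in names(pats)) {
      hits <- gregexpr(pats[[cls]], seq_i, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      k <- k + 1L
      w <- nchar(pats[[cls]])
      out[[k]] <- data.frame(transcript_id = names(transcripts)[i],
                             start = as.integer(hits) - 1L,
                             end = as.integer(hits) - 1L + w,
                             site_class = cls,
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), site_class = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$transcript_id, res$start, res$site_class), ]
  rownames(res) <- NULL
  res
}

#' Convert scanner sites into prediction records
#'
#' One record per transcript with at least one site at or above
#' `min_class`, labelled with the `builtin` predictor, so the built-in
#' scanner can participate in the consensus rule alongside external
#' predictor tables.
#'
#' @param sites Output of [seed_match_scan()].
#' @param mirna_name miRNA name for the records.
#' @param min_class Weakest accepted class, in the strength order
#'   `6mer < 7mer-A1 < 7mer-m8 < 8mer` (default `"7mer-A1"`).
#' @return Data frame `transcript_id`, `mirna_name`, `predictor`.
#' @export
sites_to_predictions <- function(sites, mirna_name,
                                 min_class = c("7mer-A1", "6mer", "7mer-m8", "8mer")) {
  min_class <- match.arg(min_class)
  order_cls <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)
  keep <- sites[order_cls[sites$site_class] >= order_cls[min_class], ]
  ids <- sort(unique(keep$transcript_id))
  data.frame(transcript_id = ids,
             mirna_name = rep(mirna_name, length(ids)),
             predictor = rep("builtin", length(ids)),
             stringsAsFactors = FALSE)
}

#' Load an external MRE prediction table
#'
#' Ingests precomputed predictor output (RNA22- or PITA-style) as a table
#' with `transcript_id` and `mirna_name` columns; duplicated rows are
#' collapsed (set semantics).
#'
#' @param path Path to a TSV file.
#' @param predictor_label Label recorded on each row (e.g. `"RNA22"`).
#' @return Data frame `transcript_id`, `mirna_name`, `predictor`.
#' @export
load_prediction_table <- function(path, predictor_label) {
  df <- .read_tsv(path)
  need <- c("transcript_id", "mirna_name")
  if (!all(need %in% names(df)))
    .stop("prediction table must have columns: %s", paste(need, collapse = ", "))
  df <- unique(df[, need])
  df$predictor <- rep(predictor_label, nrow(df))
  rownames(df) <- NULL
  df
}

#' Dual-predictor MRE consensus
#'
#' Returns the transcripts supported by every predictor in
#' `required_predictors` (intersection rule). With an empty requirement the
#' conjunction is vacuous and any transcript with at least one record
#' qualifies.
#'
#' @param records Data frame of prediction records
#'   (`transcript_id`, `mirna_name`, `predictor`), e.g. from
#'   [load_prediction_table()] and/or [sites_to_predictions()], rbind-ed.
#' @param required_predictors Character vector of predictor labels that
#'   must all support a transcript (default `c("RNA22", "PITA")`).
#' @param mirna_name Optional: restrict records to this miRNA first.
#' @return Sorted character vector of transcript IDs.
#' @export
consensus_mre <- function(records, required_predictors = c("RNA22", "PITA"),
                          mirna_name = NULL) {
  if (!is.null(mirna_name))
    records <- records[records$mirna_name == mirna_name, , drop = FALSE]
  known <- union(c("builtin", "RNA22", "PITA"), unique(records$predictor))
  unknown <- setdiff(required_predictors, known)
  if (length(unknown))
    .stop("unknown predictor label: '%s'", unknown[1])
  if (!length(required_predictors))
    return(sort(unique(records$transcript_id)))
  sets <- lapply(required_predictors, function(pr)
    unique(records$transcript_id[records$predictor == pr]))
  sort(Reduce(intersect, sets))
}
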