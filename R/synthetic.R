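#' Specification for a synthetic paired tumor/normal cohort
#'
#' Defines the study conditions the generator emulates: a paired
#' tumor/normal microarray covering lncRNA and mRNA probes, with a chosen
#' number of planted ceRNA triplets. Each planted triplet is a
#' lncRNA/mRNA pair sharing a tumor-elevated latent factor, so that both
#' probes are up-regulated (fold change `planted_fc`) and near-perfectly
#' correlated (theoretical Pearson r = `planted_r` across the full
#' cohort); the pair's transcripts additionally carry a planted miRNA
#' seed-match site, and the mRNA responds to miRNA overexpression.
#'
#' @param n_pairs Patient pairs (tumor + normal each; default 20).
#' @param n_lncRNA,n_mRNA Probe counts (defaults 500 and 2000).
#' @param n_triplets Planted ceRNA triplets (default 5).
#' @param n_de_only Extra planted DE-only probes, split between biotypes
#'   and directions, that carry no correlation partner and no MRE
#'   (default 20).
#' @param planted_fc Tumor/normal fold change of planted probes
#'   (default 4).
#' @param planted_r Target Pearson correlation of planted pairs
#'   (default 0.999).
#' @param noise_sd Log2-scale residual SD of unplanted probes
#'   (default 0.25).
#' @param baseline_log2_mean,baseline_log2_sd Per-probe baseline log2
#'   intensity distribution (defaults 8 and 1.5).
#' @param latent_sd SD of the shared latent factor of a planted pair,
#'   log2 scale (default 0.5).
#' @param transcript_length Length of the generated transcripts, nt
#'   (default 500).
#' @param mirna_name,mirna_sequence Hub miRNA (default miR-133b,
#'   `UUUGGUCCCCUUCAACCAGCUA`).
#' @param seed RNG seed (default 1).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pairs = 20, n_lncRNA = 500, n_mRNA = 2000,
                           n_triplets = 5, n_de_only = 20,
                           planted_fc = 4, planted_r = 0.999,
                           noise_sd = 0.25,
                           baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                           latent_sd = 0.5, transcript_length = 500,
                           mirna_name = "miR-133b",
                           mirna_sequence = "UUUGGUCCCCUUCAACCAGCUA",
                           seed = 1) {
  if (n_triplets > min(n_lncRNA, n_mRNA))
    .stop("n_triplets cannot exceed min(n_lncRNA, n_mRNA)")
  if (planted_r <= 0 || planted_r >= 1) .stop("planted_r must be in (0, 1)")
  if (planted_fc < 1) .stop("planted_fc must be >= 1")
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate the synthetic paired cohort with its truth table
#'
#' Intensities are log-normal: per-probe baseline log2 means are drawn
#' from N(`baseline_log2_mean`, `baseline_log2_sd`); null probes add iid
#' N(0, `noise_sd`) per sample. Planted triplet pairs share a per-triplet
#' latent factor `z = log2(planted_fc) * 1[tumor] + N(0, latent_sd)`,
#' plus a residual whose SD is solved from `planted_r` so the pair's
#' theoretical correlation across the cohort equals `planted_r`.
#' DE-only probes shift their tumor mean by +/- log2(planted_fc) with
#' `noise_sd` residuals. Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_cohort`: an `expression_set` in `es`
#'   (linear scale) and a `truth` data frame (probe_id, biotype, role,
#'   true_direction, true_fc, partner).
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  n_s <- 2 * spec$n_pairs
  pair_ids <- sprintf("P%02d", seq_len(spec$n_pairs))
  sample_ids <- c(paste0(pair_ids, "T"), paste0(pair_ids, "N"))
  design <- data.frame(
    sample_id = sample_ids,
    group = rep(c("tumor", "normal"), each = spec$n_pairs),
    pair_id = rep(pair_ids, 2), stringsAsFactors = FALSE)
  tumor <- design$group == "tumor"

  lnc_ids <- sprintf("LNC%04d", seq_len(spec$n_lncRNA))
  mrna_ids <- sprintf("GENE%04d", seq_len(spec$n_mRNA))
  probe_ids <- c(lnc_ids, mrna_ids)
  annotation <- data.frame(
    probe_id = probe_ids,
    biotype = c(rep("lncRNA", spec$n_lncRNA), rep("mRNA", spec$n_mRNA)),
    gene_symbol = probe_ids, transcript_id = probe_ids,
    stringsAsFactors = FALSE)

  fcl <- log2(spec$planted_fc)
  # latent variance across samples: Bernoulli(1/2) tumor indicator + noise
  var_latent <- fcl^2 / 4 + spec$latent_sd^2
  res_sd <- sqrt(var_latent * (1 / spec$planted_r - 1))

  roles <- rep("null", length(probe_ids))
  true_dir <- rep(NA_character_, length(probe_ids))
  true_fc <- rep(1, length(probe_ids))
  partner <- rep(NA_character_, length(probe_ids))

  m <- matrix(0, length(probe_ids), n_s,
              dimnames = list(probe_ids, sample_ids))
  mu <- stats::rnorm(length(probe_ids), spec$baseline_log2_mean,
                     spec$baseline_log2_sd)
  m[] <- mu + matrix(stats::rnorm(length(probe_ids) * n_s, 0, spec$noise_sd),
                     length(probe_ids), n_s)

  # planted triplets: first n_triplets lncRNAs paired with first mRNAs
  for (t in seq_len(spec$n_triplets)) {
    li <- t; mi <- spec$n_lncRNA + t
    z <- fcl * tumor + stats::rnorm(n_s, 0, spec$latent_sd)
    m[li, ] <- mu[li] + z + stats::rnorm(n_s, 0, res_sd)
    m[mi, ] <- mu[mi] + z + stats::rnorm(n_s, 0, res_sd)
    roles[c(li, mi)] <- c("triplet_lncRNA", "triplet_mRNA")
    true_dir[c(li, mi)] <- "up"
    true_fc[c(li, mi)] <- spec$planted_fc
    partner[li] <- probe_ids[mi]; partner[mi] <- probe_ids[li]
  }

  # DE-only probes: after the triplet block, alternating direction/biotype
  if (spec$n_de_only > 0) {
    half <- ceiling(spec$n_de_only / 2)
    de_idx <- c(spec$n_triplets + seq_len(half),
                spec$n_lncRNA + spec$n_triplets + seq_len(spec$n_de_only - half))
    for (k in seq_along(de_idx)) {
      i <- de_idx[k]
      dir_up <- k %% 2 == 1
      shift <- if (dir_up) fcl else -fcl
      m[i, ] <- mu[i] + shift * tumor + stats::rnorm(n_s, 0, spec$noise_sd)
      roles[i] <- "de_only"
      true_dir[i] <- if (dir_up) "up" else "down"
      true_fc[i] <- spec$planted_fc
    }
  }

  truth <- data.frame(probe_id = probe_ids, biotype = annotation$biotype,
                      role = roles, true_direction = true_dir,
                      true_fc = true_fc, partner = partner,
                      stringsAsFactors = FALSE)
  es <- validate_expression_set(2^m, design, annotation, "linear")
  structure(list(es = es, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' Generate the miRNA-overexpression response table
#'
#' Planted triplet mRNAs are marked down-regulated on overexpression
#' (fold change uniform in \[2.5, 4\], p uniform in \[1e-5, 1e-3\]); every
#' other gene gets a null response with fold change `2^|N(0, 0.1)|`
#' (about 1-1.3) and p uniform in \[0.05, 1\].
#'
#' @param cohort A `synthetic_cohort`.
#' @return Data frame: `gene_symbol`, `fc`, `direction`, `p`.
#' @export
generate_perturbation <- function(cohort) {
  set.seed(cohort$spec$seed + 1L)
  truth <- cohort$truth
  genes <- truth$probe_id[truth$biotype == "mRNA"]
  is_target <- truth$role[match(genes, truth$probe_id)] == "triplet_mRNA"
  n <- length(genes)
  fc <- 2^abs(stats::rnorm(n, 0, 0.1))
  dir <- sample(c("up", "down"), n, replace = TRUE)
  p <- stats::runif(n, 0.05, 1)
  fc[is_target] <- stats::runif(sum(is_target), 2.5, 4)
  dir[is_target] <- "down"
  p[is_target] <- stats::runif(sum(is_target), 1e-5, 1e-3)
  data.frame(gene_symbol = genes, fc = fc, direction = dir, p = p,
             stringsAsFactors = FALSE)
}

#' Generate transcript sequences with planted seed-match sites
#'
#' Null transcripts are rejection-sampled against the built-in scanner so
#' they contain no canonical site for the spec's miRNA; planted triplet
#' transcripts (lncRNA and mRNA) receive one inserted 8mer site at a
#' recorded position. The truth of site placement is returned alongside.
#'
#' @param cohort A `synthetic_cohort`.
#' @return List: `sequences` (named RNA character vector) and
#'   `site_truth` (data frame probe_id, start, end, site_class for the
#'   planted sites).
#' @export
generate_sequences <- function(cohort) {
  spec <- cohort$spec
  set.seed(spec$seed + 2L)
  mirna <- mature_mirna(spec$mirna_name, spec$mirna_sequence)
  pats <- .seed_patterns(mirna)
  len <- spec$transcript_length
  bases <- c("A", "C", "G", "U")

  draw_null <- function() {
    repeat {
      s <- paste(sample(bases, len, replace = TRUE), collapse = "")
      if (!any(vapply(pats, function(p) grepl(p, s, fixed = TRUE), logical(1))))
        return(s)
    }
  }

  truth <- cohort$truth
  planted <- truth$probe_id[truth$role %in% c("triplet_lncRNA", "triplet_mRNA")]
  seqs <- character(nrow(truth)); names(seqs) <- truth$probe_id
  site_rows <- list()
  site8 <- pats[["8mer"]]
  for (id in truth$probe_id) {
    s <- draw_null()
    if (id %in% planted) {
      pos <- sample.int(len - nchar(site8) + 1L, 1L)    # 1-based insert
      substr(s, pos, pos + nchar(site8) - 1L) <- site8
      site_rows[[id]] <- data.frame(probe_id = id, start = pos - 1L,
                                    end = pos - 1L + nchar(site8),
                                    site_class = "8mer",
                                    stringsAsFactors = FALSE)
    }
    seqs[[id]] <- s
  }
  list(sequences = seqs,
       site_truth = if (length(site_rows)) do.call(rbind, site_rows)
       else data.frame(probe_id = character(), start = integer(),
                       end = integer(), site_class = character()))
}

#' Generate a qPCR Ct table consistent with the planted expression
#'
#' For each validation target (by default the hub miRNA, the first
#' planted triplet mRNA and its partner lncRNA), per-sample Ct values are
#' `reference_ct - log2(relative expression) + N(0, 0.15)`, where the
#' relative log2 expression is the planted signal (tumor shift plus
#' latent noise); lncRNA/mRNA targets reference GAPDH, the miRNA
#' references U6. The miRNA is planted down-regulated in tumor, as a
#' tumor-suppressor miRNA would be.
#'
#' @param cohort A `synthetic_cohort`.
#' @return Data frame in the Ct-table layout of [read_ct_table()].
#' @export
generate_ct_table <- function(cohort) {
  spec <- cohort$spec
  set.seed(spec$seed + 3L)
  truth <- cohort$truth
  design <- cohort$es$design
  tumor <- design$group == "tumor"
  n_s <- nrow(design)
  fcl <- log2(spec$planted_fc)

  first_m <- truth$probe_id[truth$role == "triplet_mRNA"][1]
  first_l <- if (!is.na(first_m)) truth$partner[match(first_m, truth$probe_id)] else NA

  targets <- list()
  targets[[spec$mirna_name]] <- list(ref = "U6", shift = -fcl)
  if (!is.na(first_m)) targets[[first_m]] <- list(ref = "GAPDH", shift = fcl)
  if (!is.na(first_l) && !is.na(first_m))
    targets[[first_l]] <- list(ref = "GAPDH", shift = fcl)

  rows <- lapply(names(targets), function(tg) {
    ref <- targets[[tg]]$ref
    x <- targets[[tg]]$shift * tumor + stats::rnorm(n_s, 0, spec$latent_sd)
    ref_ct <- stats::rnorm(n_s, if (ref == "U6") 22 else 18, 0.2)
    ct <- ref_ct - x + stats::rnorm(n_s, 0, 0.15)
    data.frame(sample_id = design$pair_id, tissue = design$group,
               target_name = tg, ct = ct, reference_name = ref,
               reference_ct = ref_ct, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write all synthetic inputs to a directory in pipeline formats
#'
#' Emits matrix.tsv, design.tsv, annotation.tsv, sequences.fasta,
#' perturbation.tsv, ct.tsv and truth.tsv — the exact formats the readers
#' consume.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$es,
                   file.path(dir, "matrix.tsv"),
                   file.path(dir, "design.tsv"),
                   file.path(dir, "annotation.tsv"))
  sq <- generate_sequences(cohort)
  write_fasta(sq$sequences, file.path(dir, "sequences.fasta"))
  .write_tsv(generate_perturbation(cohort), file.path(dir, "perturbation.tsv"))
  .write_tsv(generate_ct_table(cohort), file.path(dir, "ct.tsv"))
  .write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
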