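# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop <- function(...) stop(sprintf(...), call. = FALSE)

.check_prob <- function(p, what = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    .stop("%s values must be numeric in [0, 1]", what)
  invisible(p)
}

# Row-wise variance without forming a matrixStats dependency.
.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# Linear-scale intensities -> log2, guarding against non-positive values.
.to_log2 <- function(m, scale_tag) {
  if (identical(scale_tag, "log2")) return(m)
  if (any(m <= 0)) .stop("linear-scale intensities must be positive for log2 transform")
  log2(m)
}

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) .stop("file not found: %s", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#", ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
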