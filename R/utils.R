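#' @useDynLib midcount, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnbinom dpois lm coef optimize rbinom rnorm rpois runif
#'   quantile setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Codons that do not terminate translation (standard genetic code).
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Phred+33 quality string -> integer vector
decode_phred <- function(qual) {
  utf8ToInt(qual) - 33L
}

encode_phred <- function(q) {
  intToUtf8(q + 33L)
}

mean_phred <- function(qual) {
  .mean_phred_cpp(as.character(qual))
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  .collapse_rows_cpp(m)
}

# Random in-frame coding sequence built from non-stop codons; trimmed to
# `len` nucleotides (frame starts at position 1).
random_coding_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste0,
                  collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  k <- ceiling(len / 3)
  m <- matrix(sample(codons, n * k, replace = TRUE), nrow = n)
  substr(.collapse_rows_cpp(m), 1L, len)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
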