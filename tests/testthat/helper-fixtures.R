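# Independent dynamic-programming oracle for edit distance (base R).
lv_ref <- function(a, b) {
  as.integer(utils::adist(a, b))
}

# Quality string of uniform Phred score q (default 30 -> "?").
qual_str <- function(len, q = 30L) {
  strrep(intToUtf8(q + 33L), len)
}

# Hand-built prepared-read rows.
make_reads <- function(payloads, mids, quals = NULL,
                       ids = sprintf("r%03d", seq_along(payloads))) {
  if (is.null(quals)) quals <- vapply(nchar(payloads), qual_str, character(1))
  data.frame(id = ids, mid = mids, payload = payloads, qual = quals,
             mean_quality = midcount:::mean_phred(quals),
             stringsAsFactors = FALSE)
}

# Write a FASTQ from vectors of lines
write_fastq_lines <- function(ids, seqs, quals, path) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# Small default simulation for cross-module tests (error-prone, fast).
small_sim_config <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(K = 30L, alpha = 2.5, m = 3L, mid_length = 8L,
         reads_per_molecule_mean = 20, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Run preprocess on simulated reads with the matching layout.
prepare_sim <- function(sim) {
  cfg <- sim$truth$config
  pc <- preprocess_config(anchor = cfg$anchor, mid_length = cfg$mid_length,
                          payload_length = cfg$payload_length)
  prepare_reads(sim$reads, pc)
}
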