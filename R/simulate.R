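#' Simulation configuration
#'
#' Describes a synthetic MID-barcoded TCR sequencing experiment with full
#' ground truth: a repertoire of `K` clones whose cell counts follow a
#' discrete power law with exponent `alpha`, a fixed `m` transcripts per cell,
#' uniform random MID tagging, PCR amplification with per-base substitution
#' errors (which hit MID and payload bases alike, so erroneous-MID satellites
#' arise naturally), and per-base sequencing errors with a declining quality
#' profile. Read layout matches the preprocessing defaults: MID, then the
#' constant-region anchor, then the variable payload.
#'
#' @param K Number of clones.
#' @param alpha Power-law exponent of clone cell counts (> 1).
#' @param m Transcript copies per cell (positive integer).
#' @param mid_length MID length (default 12).
#' @param anchor Constant-region sequence placed after the MID. The default is
#'   a 21-nt stop-free sequence, so the payload reading frame starts at
#'   offset 0.
#' @param payload_length Total payload length (anchor + variable region).
#' @param pcr_cycles,pcr_efficiency PCR cycles and per-cycle duplication
#'   probability.
#' @param pcr_error_rate Substitution probability per base per duplication.
#' @param seq_error_rate Substitution probability per base per read.
#' @param reads_per_molecule_mean Mean sequencing depth per molecule (Poisson).
#' @param nonproductive_fraction Fraction of clones given an in-frame stop
#'   codon in the variable region.
#' @param spike_ins Optional spike-in controls: a data.frame with columns
#'   `copies` (molecule count) and optionally `seq` (full payload including
#'   the anchor; `NA` sequences are generated like clone sequences), or an
#'   integer vector of copy counts.
#' @param clone_separation Minimum pairwise Levenshtein distance enforced
#'   between clone payloads (default 25, comfortably above the 22-edit
#'   clustering threshold for 150-nt payloads so that sub-clustering is
#'   exercised in its separable regime).
#' @param max_verify Pairwise separation is verified exhaustively up to this
#'   many sequences; beyond it a random subset of pairs is checked (random
#'   stop-free sequences of this length exceed the separation with
#'   overwhelming probability).
#' @param pool_cap PCR mutation lineages are tracked explicitly until the
#'   per-molecule amplicon pool reaches this size; later-cycle errors are
#'   folded into independent per-read substitutions (see the package
#'   vignette).
#' @param xmax Truncation of the clone-size power law.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(K = 500L, alpha = 2.5, m = 3L, mid_length = 12L,
                       anchor = "ACCGAGGACCTGAACAAGGTG",
                       payload_length = 150L, pcr_cycles = 20L,
                       pcr_efficiency = 0.9, pcr_error_rate = 1e-4,
                       seq_error_rate = 3e-3, reads_per_molecule_mean = 30,
                       nonproductive_fraction = 0, spike_ins = NULL,
                       clone_separation = 25L, max_verify = 1000L,
                       pool_cap = 64L, xmax = 1e6, seed = 1L) {
  stopifnot(K >= 1L, alpha > 1, m >= 1L, mid_length >= 1L,
            nchar(anchor) >= 1L, payload_length > nchar(anchor),
            pcr_cycles >= 0L, pcr_efficiency >= 0, pcr_efficiency <= 1,
            pcr_error_rate >= 0, pcr_error_rate <= 1, seq_error_rate >= 0,
            seq_error_rate <= 1, reads_per_molecule_mean > 0,
            nonproductive_fraction >= 0, nonproductive_fraction <= 1,
            clone_separation >= 1L, pool_cap >= 2L)
  if (!is.null(spike_ins) && !is.data.frame(spike_ins))
    spike_ins <- data.frame(copies = as.integer(spike_ins),
                            seq = NA_character_, stringsAsFactors = FALSE)
  if (is.data.frame(spike_ins)) {
    if (is.null(spike_ins$seq)) spike_ins$seq <- NA_character_
    stopifnot(all(spike_ins$copies >= 1L))
  }
  structure(list(K = as.integer(K), alpha = alpha, m = as.integer(m),
                 mid_length = as.integer(mid_length),
                 anchor = toupper(anchor),
                 payload_length = as.integer(payload_length),
                 pcr_cycles = as.integer(pcr_cycles),
                 pcr_efficiency = pcr_efficiency,
                 pcr_error_rate = pcr_error_rate,
                 seq_error_rate = seq_error_rate,
                 reads_per_molecule_mean = reads_per_molecule_mean,
                 nonproductive_fraction = nonproductive_fraction,
                 spike_ins = spike_ins,
                 clone_separation = as.integer(clone_separation),
                 max_verify = as.integer(max_verify),
                 pool_cap = as.integer(pool_cap), xmax = xmax,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulated repertoire config: K = %d clones (alpha %.2f), m = %d copies/cell\n",
              x$K, x$alpha, x$m))
  cat(sprintf("  MID %d nt, payload %d nt, PCR %d cycles (eff %.2f, err %.1e/base), seq err %.1e/base, depth %.0f reads/molecule\n",
              x$mid_length, x$payload_length, x$pcr_cycles, x$pcr_efficiency,
              x$pcr_error_rate, x$seq_error_rate, x$reads_per_molecule_mean))
  if (!is.null(x$spike_ins))
    cat("  spike-ins:", paste(x$spike_ins$copies, collapse = ", "),
        "copies\n")
  invisible(x)
}

# Regenerate sequences until all pairwise Levenshtein distances are >= sep.
# Exhaustive check up to max_verify sequences, random-pair check beyond.
ensure_separation <- function(seqs, generate, sep, max_verify,
                              max_rounds = 20L) {
  K <- length(seqs)
  check_against <- function(i, seqs) {
    d <- levenshtein(seqs[i], seqs[-i], max_dist = sep - 1L)
    any(d < sep)
  }
  for (round in seq_len(max_rounds)) {
    bad <- integer(0)
    if (K <= max_verify) {
      for (i in seq_len(K - 1L)) {
        d <- levenshtein(seqs[i], seqs[(i + 1L):K], max_dist = sep - 1L)
        if (any(d < sep)) bad <- c(bad, i + which(d < sep))
      }
    } else {
      # duplicate screen plus a random-pair spot check
      bad <- which(duplicated(seqs))
      ii <- sample.int(K, min(K, 1000L))
      jj <- sample.int(K, min(K, 1000L))
      keep <- ii != jj
      d <- levenshtein(seqs[ii[keep]], seqs[jj[keep]], max_dist = sep - 1L)
      bad <- c(bad, jj[keep][d < sep])
    }
    bad <- unique(bad)
    if (length(bad) == 0L) return(seqs)
    seqs[bad] <- generate(length(bad))
  }
  stop("could not achieve pairwise clone separation of ", sep,
       " edits after ", max_rounds, " rounds")
}

#' Simulate a repertoire: clones, molecules, and MID assignments
#'
#' Draws clone cell counts from the power law, builds stop-free clone payload
#' sequences (anchor + random coding variable region) with enforced pairwise
#' separation, gives every cell exactly `m` transcript molecules, tags each
#' molecule with an independent uniform random MID, and appends spike-in
#' molecules.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_truth`: `clones` (data.frame `clone_id`,
#'   `seq`, `cell_count`, `productive`, `is_spike`), `molecules` (data.frame
#'   `molecule_id`, `clone_id`, `mid`), and the `config`.
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    K <- config$K
    var_len <- config$payload_length - nchar(config$anchor)
    x <- sample_clone_sizes(K, config$alpha, xmax = config$xmax)
    gen_payload <- function(n) paste0(config$anchor,
                                      random_coding_dna(n, var_len))
    seqs <- ensure_separation(gen_payload(K), gen_payload,
                              config$clone_separation, config$max_verify)
    productive <- runif(K) >= config$nonproductive_fraction
    if (any(!productive)) {
      # place a stop codon at a payload-frame codon inside the variable region
      first_codon <- nchar(config$anchor) %/% 3L + 1L
      n_codons <- config$payload_length %/% 3L
      for (i in which(!productive)) {
        cs <- 3L * (sample(first_codon:n_codons, 1L) - 1L) + 1L
        substr(seqs[i], cs, cs + 2L) <- sample(STOP_CODONS, 1L)
      }
    }
    clones <- data.frame(clone_id = seq_len(K), seq = seqs, cell_count = x,
                         productive = productive, is_spike = FALSE,
                         stringsAsFactors = FALSE)
    if (!is.null(config$spike_ins)) {
      sp <- config$spike_ins
      need <- is.na(sp$seq)
      if (any(need)) {
        cand <- ensure_separation(c(seqs, gen_payload(sum(need))),
                                  gen_payload, config$clone_separation,
                                  config$max_verify)
        sp$seq[need] <- utils::tail(cand, sum(need))
      }
      clones <- rbind(clones,
                      data.frame(clone_id = K + seq_len(nrow(sp)),
                                 seq = sp$seq, cell_count = NA_integer_,
                                 productive = TRUE, is_spike = TRUE,
                                 stringsAsFactors = FALSE))
    }
    copies <- integer(nrow(clones))
    copies[!clones$is_spike] <- config$m * clones$cell_count[!clones$is_spike]
    if (any(clones$is_spike))
      copies[clones$is_spike] <- as.integer(config$spike_ins$copies)
    molecules <- data.frame(
      molecule_id = seq_len(sum(copies)),
      clone_id = rep(clones$clone_id, copies),
      mid = random_dna(sum(copies), config$mid_length),
      stringsAsFactors = FALSE)
    structure(list(clones = clones, molecules = molecules, config = config),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulated ground truth: %d clones (%d spike-ins), %d molecules\n",
              nrow(x$clones), sum(x$clones$is_spike), nrow(x$molecules)))
  invisible(x)
}

# map a base to a random different base
mutate_bases <- function(old) {
  alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"),
               N = c("A", "C", "G"))
  alt[cbind(match(old, rownames(alt)), sample.int(3L, length(old),
                                                  replace = TRUE))]
}

#' Amplify molecules and sequence reads
#'
#' Emulates the error process the pipeline corrects. Each molecule's PCR
#' genealogy is tracked explicitly over the early cycles (until the amplicon
#' pool reaches `pool_cap` copies): a substitution arising in cycle `t`
#' founds a mutant lineage carried by a `1/(1+eff)^t` share of the final pool
#' and hence by a binomial share of that molecule's reads — this is what
#' creates erroneous-MID satellite sub-clusters with multiple reads.
#' Later-cycle PCR errors reach only negligible lineage shares and are folded
#' into independent per-read substitutions along with sequencing errors.
#' Qualities follow a declining position profile with Gaussian noise.
#'
#' @param truth A `sim_truth` from [simulate_repertoire()].
#' @param config The same [sim_config()].
#' @param seed Seed for the amplification stage (default `config$seed + 1`).
#' @return A list with `reads` (data.frame `id`, `seq`, `qual`) and
#'   `read_map` (data.frame `id`, `molecule_id`).
#' @export
amplify_and_sequence <- function(truth, config = truth$config,
                                 seed = config$seed + 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  with_seed(seed, {
    mol <- truth$molecules
    N <- nrow(mol)
    templates <- paste0(mol$mid, truth$clones$seq[mol$clone_id])
    L <- nchar(templates)
    depth <- rpois(N, config$reads_per_molecule_mean)
    mol_of_read <- rep.int(seq_len(N), depth)
    R <- length(mol_of_read)
    eff <- config$pcr_efficiency
    rate <- config$pcr_error_rate
    # tracked early cycles: pool(t) = (1+eff)^t up to pool_cap
    T_track <- if (config$pcr_cycles == 0L || eff == 0 || rate == 0) 0L else
      min(config$pcr_cycles,
          as.integer(ceiling(log(config$pool_cap) / log1p(eff))))
    ev_mol <- integer(0)
    ev_share <- numeric(0)
    if (T_track > 0L) {
      for (t in seq_len(T_track)) {
        lambda <- (1 + eff)^(t - 1) * eff * L * rate
        cnt <- rpois(N, lambda)
        if (any(cnt > 0L)) {
          ev_mol <- c(ev_mol, rep.int(which(cnt > 0L), cnt[cnt > 0L]))
          ev_share <- c(ev_share, rep.int(1 / (1 + eff)^t, sum(cnt)))
        }
      }
    }
    read_seq <- templates[mol_of_read]
    if (length(ev_mol) > 0L) {
      ord <- order(ev_mol, -ev_share)
      ev_mol <- ev_mol[ord]
      ev_share <- ev_share[ord]
      pos <- ceiling(runif(length(ev_mol)) * L[ev_mol])
      old <- substring(templates[ev_mol], pos, pos)
      tmpl_ev <- .apply_substitutions_cpp(templates[ev_mol],
                                          seq_along(ev_mol), pos,
                                          mutate_bases(old))
      # assign reads to mutant lineages by cumulative share
      cs <- stats::ave(ev_share, ev_mol, FUN = cumsum)
      cumprev <- cs - ev_share
      cs <- pmin(cs, 1)
      ev_per_mol <- tabulate(ev_mol, N)
      first_row <- integer(N)
      firsts <- !duplicated(ev_mol)
      first_row[ev_mol[firsts]] <- which(firsts)
      has <- ev_per_mol[mol_of_read] > 0L
      r_idx <- which(has)
      if (length(r_idx) > 0L) {
        kk <- ev_per_mol[mol_of_read[r_idx]]
        pair_read <- rep.int(r_idx, kk)
        pair_ev <- first_row[mol_of_read[pair_read]] + (sequence(kk) - 1L)
        u <- runif(R)
        hit <- u[pair_read] >= cumprev[pair_ev] & u[pair_read] < cs[pair_ev]
        read_seq[pair_read[hit]] <- tmpl_ev[pair_ev[hit]]
      }
    }
    # independent per-read errors: sequencing plus untracked late-cycle PCR
    p_err <- config$seq_error_rate +
      max(0L, config$pcr_cycles - T_track) * rate * eff / (1 + eff)
    L_read <- L[mol_of_read]
    n_err <- rbinom(R, L_read, p_err)
    if (any(n_err > 0L)) {
      idx <- rep.int(which(n_err > 0L), n_err[n_err > 0L])
      pos <- ceiling(runif(length(idx)) * L_read[idx])
      old <- substring(read_seq[idx], pos, pos)
      read_seq <- .apply_substitutions_cpp(read_seq, idx, pos,
                                           mutate_bases(old))
    }
    qual <- sim_quals(L_read)
    ids <- sprintf("r%08d", seq_len(R))
    list(reads = data.frame(id = ids, seq = read_seq, qual = qual,
                            stringsAsFactors = FALSE),
         read_map = data.frame(id = ids, molecule_id = mol_of_read,
                               stringsAsFactors = FALSE))
  })
}

# Declining quality profile: mean 37 at the 5' end falling to ~29 at the
# 3' end, Gaussian noise sd 4, clipped to [2, 40]. Generated in chunks to
# bound memory.
sim_quals <- function(lens, chunk = 20000L) {
  out <- character(length(lens))
  for (len in unique(lens)) {
    rows <- which(lens == len)
    profile <- 37 - 8 * ((seq_len(len) - 1L) / max(1L, len - 1L))^2
    for (s in seq(1L, length(rows), by = chunk)) {
      ii <- rows[s:min(s + chunk - 1L, length(rows))]
      q <- matrix(profile, nrow = length(ii), ncol = len, byrow = TRUE) +
        rnorm(length(ii) * len, sd = 4)
      q <- matrix(as.integer(pmin(40, pmax(2, round(q)))), nrow = length(ii))
      out[ii] <- .phred_strings_cpp(q)
    }
  }
  out
}

#' Simulate a complete sequencing run
#'
#' Convenience wrapper: [simulate_repertoire()] followed by
#' [amplify_and_sequence()].
#'
#' @param config A [sim_config()].
#' @return A list with `truth`, `reads`, and `read_map`.
#' @export
simulate_reads <- function(config) {
  truth <- simulate_repertoire(config)
  seqd <- amplify_and_sequence(truth, config)
  list(truth = truth, reads = seqd$reads, read_map = seqd$read_map)
}

#' Write / read a simulated fixture
#'
#' Persists a simulated run as `reads.fastq.gz`, `truth_clones.tsv`,
#' `truth_molecules.tsv`, `truth_reads.tsv`, and `config.yaml`; the round trip
#' is lossless.
#'
#' @param sim A list as returned by [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @return `write_fixture` returns `dir` invisibly; `read_fixture` returns the
#'   same structure as [simulate_reads()].
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- gzfile(file.path(dir, "reads.fastq.gz"), "wt")
  writeLines(as.vector(rbind(paste0("@", sim$reads$id), sim$reads$seq, "+",
                             sim$reads$qual)), con)
  close(con)
  write_tsv(sim$truth$clones, file.path(dir, "truth_clones.tsv"))
  write_tsv(sim$truth$molecules, file.path(dir, "truth_molecules.tsv"))
  write_tsv(sim$read_map, file.path(dir, "truth_reads.tsv"))
  cfg <- unclass(sim$truth$config)
  if (is.data.frame(cfg$spike_ins)) cfg$spike_ins <- as.list(cfg$spike_ins)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  if (!is.null(cfg$spike_ins))
    cfg$spike_ins <- as.data.frame(cfg$spike_ins, stringsAsFactors = FALSE)
  config <- do.call(sim_config, cfg)
  clones <- read_tsv(file.path(dir, "truth_clones.tsv"),
                     colClasses = c(seq = "character"))
  molecules <- read_tsv(file.path(dir, "truth_molecules.tsv"),
                        colClasses = c(mid = "character"))
  reads <- read_fastq(file.path(dir, "reads.fastq.gz"))
  read_map <- read_tsv(file.path(dir, "truth_reads.tsv"),
                       colClasses = c(id = "character"))
  truth <- structure(list(clones = clones, molecules = molecules,
                          config = config), class = "sim_truth")
  list(truth = truth, reads = reads, read_map = read_map)
}
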