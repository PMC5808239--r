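# midcount

Error correction and digital RNA molecule counting for molecular-identifier
(MID/UMI) barcoded immune repertoire sequencing, with companion probability
models for barcode occupancy, clone-size distributions, diversity coverage,
and per-cell transcript copy number.

## The problem

In MID-barcoded TCR-seq, each RNA molecule receives a random 12-nt barcode
during reverse transcription, so PCR duplicates can be collapsed and
molecules counted digitally. Two error modes corrupt the naive count:

1. **MID sharing.** Barcode tagging is a balls-in-bins process: the number of
   molecules carrying a given MID is Poisson with rate `N/M`
   (`M = 4^12 ≈ 1.68e7`). Among occupied MIDs, a fraction

   `F(k>1) = [1 − e^(−N/M) − (N/M)·e^(−N/M)] / (1 − e^(−N/M))`

   tags two or more distinct molecules — approximately linear in `N` below
   five million molecules. Building one consensus per MID then merges reads
   from different molecules into **chimeric sequences** that inflate
   diversity estimates.
2. **MID errors.** PCR and sequencing errors hit barcode bases too, spawning
   satellite MIDs that inflate molecule counts without bound as sequencing
   depth grows.

`midcount` implements the corrective pipeline: reads sharing an MID are split
into **sub-clusters** by greedy quality-threshold clustering with a
Levenshtein threshold of 15% of the read length (22 edits for 150-nt
payloads); each sub-cluster gets a quality-weighted consensus (two-read
sub-clusters must agree exactly); identical consensus sequences merge into
clonotypes; and three filters clean the result — non-functional (in-frame
stop) flagging, one-edit neighbour collapse, and removal of MID entries with
fewer than 20% of the clonotype's maximum read count (the threshold justified
by a two-component negative-binomial fit to read counts per MID).

The model layer adds: collision undercount for identical molecules
(`E[distinct] = M(1 − (1 − 1/M)^n)`), discrete power-law clone sizes
`f(x) ∝ x^(−α)` with MLE/KS fitting, hypergeometric expected diversity
`E(D) = K − Σᵢ C(N − m·xᵢ, n)/C(N, n)`, and least-squares integer estimation
of the per-cell copy number `m` from diversity-coverage curves. A read
simulator with full ground truth (clone structure, molecule-to-MID map, PCR
lineage errors, sequencing errors) makes every stage testable.

## Worked example

Simulate a repertoire with a 10-copy spike-in, run the pipeline, and count:

```r
library(midcount)

cfg <- sim_config(K = 200, alpha = 2.5, m = 3, reads_per_molecule_mean = 30,
                  spike_ins = 10L, seed = 4)
sim <- simulate_reads(cfg)
sim$truth
#> Simulated ground truth: 201 clones (1 spike-ins), 1144 molecules

prep <- prepare_reads(sim$reads, preprocess_config(anchor = cfg$anchor))
str(prep$stats)
#> List of 3
#>  $ parsed  : int 34585
#>  $ accepted: int 31761
#>  $ rejected: Named int [1:3] 2824 0 0

ct <- count_repertoire(prep$reads)
ct
#> Clonotype table: 201 clonotypes, 1140 molecules, 30123 reads
```

The 8% of reads rejected carry an error inside the constant-region anchor
(exact anchor matching is required). The corrected count, 1,140 molecules,
sits within 0.4% of the 1,144 true molecules, all 201 clone sequences are
recovered with no chimeric sequence, and the spike-in is counted at its full
10 copies:

```r
spike_seq <- sim$truth$clones$seq[sim$truth$clones$is_spike]
ct$molecule_count[match(spike_seq, ct$seq)]
#> [1] 10

expansion_summary(ct, threshold = 20)
#> Expansion summary (> 20 RNA copies): 9 of 201 clones expanded, 25.96% of 1140 molecules
```

Model-layer calls follow the same vocabulary:

```r
fit_power_law_alpha(sample_clone_sizes(1e5, 2.5, seed = 1))
#> Power-law fit (mle): alpha = 2.497, xmin = 1, n_tail = 100000, KS = 0.0007

cu <- collision_undercount(M = mid_space_size(12), n_identical = 2e5)
round(100 * cu$undercount, 3)
#> [1] 0.594
```

That last number is the expected percentage of 200,000 identical RNA
molecules lost to two copies drawing the same 12-nt MID — about 0.6%, which
is why a 12-nt identifier suffices even for strongly expanded clones.

See `vignette source in vignettes/digital-molecule-counting.Rmd` for the
models, their assumptions, and the design decisions.

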