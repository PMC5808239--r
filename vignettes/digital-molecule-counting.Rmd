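---
title: "Digital molecule counting with MID sub-clustering: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital molecule counting with MID sub-clustering: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midcount)
```

## The counting problem

Molecular identifiers (MIDs, also called UMIs) let a sequencing library be
read as a census: every RNA molecule picks a random 12-nt barcode at reverse
transcription, PCR multiplies molecule–barcode pairs together, and after
sequencing each barcode group should collapse back to one molecule. Two
failure modes spoil this picture, and `midcount` exists to correct both.

**Shared barcodes.** Tagging is uniform and independent, so the occupancy of
a given MID is Poisson with rate $\lambda = N/M$, where $N$ is the number of
tagged molecules and $M = 4^{12}$ the barcode space. Among *occupied* MIDs,
the fraction holding two or more distinct molecules is

$$F(k>1) \;=\; \frac{1 - e^{-N/M} - (N/M)\,e^{-N/M}}{1 - e^{-N/M}},$$

which `frac_needing_subclustering()` evaluates (with `expm1` guards for small
ratios). For $N < 5\times 10^6$ this is nearly linear in $N$ — the package's
acceptance tests verify $R^2 > 0.999$ on that range. Ignoring the effect and
building one consensus per MID merges reads from different molecules, and
because the consensus is a per-position vote, the merged sequence is often a
mosaic that matches *neither* parent: a chimera that inflates apparent
diversity.

**Erroneous barcodes.** PCR and sequencing errors strike barcode bases as
readily as payload bases. An early-cycle PCR error in the MID founds a
satellite barcode carrying a large share of the molecule's reads; late errors
and sequencing errors produce low-count satellites. Satellites inflate the
molecule count, and the inflation grows with sequencing depth because ever
smaller lineage shares clear the two-read threshold.

## The pipeline

`count_repertoire()` chains the stages; each is exported separately.

1. **Preprocessing** (`prepare_reads()`): reads must contain the
   constant-region anchor *exactly* (configurable mismatch allowance, default
   0); the payload is cut to 150 nt from the anchor start; reads with `N` in
   the MID are rejected (an ambiguous identifier cannot be grouped); payloads
   shorter than `min_payload` (default 100 nt) are rejected. The lower bound
   is a package choice: trimming to a fixed 150 nt needs a floor below which
   a truncated read carries too little sequence to cluster reliably. No
   quality trimming is performed before the cut.
2. **Sub-clustering** (`subcluster_reads()`): within an MID group, greedy
   seeded quality-threshold clustering. The unassigned read with the highest
   summed base quality seeds a cluster (ties break to the smallest read id);
   all unassigned reads within `round(0.15 × seed length)` Levenshtein edits
   join it; repeat. The 15% threshold is the published clustering radius for
   separating molecules that share an MID; rounding is half-to-even, so a
   150-nt payload gives a threshold of 22. Clusters need `min_reads = 2`;
   two-read clusters must agree exactly (a lone disagreeing pair cannot be
   voted on). Members of failed clusters are discarded, matching the
   removal of unverifiable singletons. The greedy seeded scheme is a design
   decision: quality-threshold clustering is named but not specified in
   detail in the method literature, and the greedy variant is deterministic,
   near-linear per group, and identical to the exhaustive variant whenever
   molecules are farther apart than twice the threshold — the regime the
   clone-separation guarantee of the simulator (and of real V(D)J diversity
   at this payload length) puts us in.
3. **Consensus** (`build_consensus()`): per position, the base with the
   largest summed Phred quality wins; ties break in the fixed order
   A &lt; C &lt; G &lt; T for determinism; `N` votes with weight zero;
   members whose length differs from the modal length do not vote. The
   length-voting rule avoids a multiple alignment; with substitution-
   dominated errors, off-modal lengths are rare.
4. **Clonotypes and filters** (`merge_identical()`, `filter_clonotypes()`):
   identical consensus sequences merge; each surviving sub-cluster remains
   one countable molecule (keyed MID + index, so the same sequence under the
   same MID twice counts twice). Then, in order: in-frame-stop flagging
   (flagged clonotypes are kept in output but excluded from productive
   tallies — full V/J junction annotation is out of scope, so the stop codon
   relative to the anchor frame is the operational proxy); one-edit
   neighbour collapse (a clonotype at Levenshtein distance exactly 1 from a
   clonotype with strictly more molecules is removed; decisions are taken
   against the pre-filter state in a single pass so genuine 1-edit clone
   pairs cannot be chain-collapsed, and ties keep both); and the MID
   read-count filter (within a clonotype, MID entries below 20% of the
   maximum read count are dropped). The fixed 20%-of-maximum rule is the
   operational filter; `fit_nb_mixture()` provides the diagnostic that
   justifies it — an EM fit of two negative binomials to per-sub-cluster
   read counts, deterministically initialized at the 10th and 90th count
   percentiles, with a likelihood-ratio guard that flags data better served
   by a single component, and a posterior crossover count that can serve as
   a data-driven threshold where preferred. The 20% rule is applied per
   clonotype, as stated, rather than globally.

## The models

**Collision undercount** (`collision_undercount()`): when $n$ *identical*
molecules draw MIDs uniformly, copies sharing an MID are merged by design.
$E[\text{distinct}] = M(1 - (1 - 1/M)^n)$, so the expected fractional
undercount is $(n - E[\text{distinct}])/n$ — about 0.6% for $n = 2\times
10^5$ at $M = 4^{12}$. The per-molecule probability of sharing,
$1 - (1-1/M)^{n-1}$ (about 1.2% at the same operating point), is exposed as a
companion value because the informal "percentage of identical molecules
tagged with the same MID" can be read either way; the undercount form is the
one bounded in the acceptance tests, being the quantity that actually
distorts a clone-size estimate.

**Clone sizes** (`sample_clone_sizes()`, `fit_power_law_alpha()`): cell
counts per clone follow a discrete power law $f(x) \propto x^{-\alpha}$,
sampled by inverse CDF on the exact normalized pmf truncated at `xmax`
(default $10^6$ — large enough that the truncated tail mass is negligible
for every $\alpha > 1.5$ used here). Fitting is by maximum likelihood with a
Kolmogorov–Smirnov scan over the cutoff `xmin`, delegated to
`igraph::fit_power_law()` — the same implementation used in the repertoire
literature; a count-weighted log–log histogram slope is available as the
alternative (`method = "loglog"`), since exponents are sometimes averaged
across libraries that way. No default $\alpha$ is baked in: it must be
fitted or supplied.

**Diversity coverage** (`expected_diversity()`, `diversity_coverage()`): a
clone of $x_i$ cells holds $m x_i$ molecules of $N = m\sum x_i$; sampling $n$
molecules without replacement misses it with probability
$\binom{N - m x_i}{n}/\binom{N}{n}$, so
$E(D) = K - \sum_i \binom{N-m x_i}{n}\big/\binom{N}{n}$ and $P(D) = E(D)/K$.
Ratios are computed as differences of `lchoose` (log-gamma), since $N$
reaches $10^6$–$10^7$ where factorials overflow; terms with $n > N - m x_i$
are exactly zero. Test oracles are brute-force without-replacement sampling
at $N \le 200$.

**Copy number** (`estimate_copy_number()`): integer candidates $m$ are
scored by $\min_m \sum_i (P(D_i \mid m, x) - D_{\mathrm{obs},i})^2$, both
curves scaled to equal 1 at the reference input fraction (default 0.9).
The clone-size vector is drawn once from the fitted power law under a fixed
seed shared across candidates, so residual differences reflect $m$ alone —
the sampling protocol for $x$ is otherwise open, and regenerating
independently per candidate would leak Monte-Carlo noise into the argmin.
Sampled molecule counts map to input fractions as $n = f \cdot N$; capture
efficiency is absorbed into the effective $m$. Non-unique minimizers return
the smallest $m$, flagged. Acceptance tests confirm exact recovery of the
generating $m \in \{2,\dots,6\}$ in at least 18 of 20 seeded replicates at
$K = 10^4$.

**Expansion** (`expansion_summary()`, `fold_expansion()`): clonotypes with
more than 20 RNA molecules count as expanded, and the expansion of a clone is
its population share divided by the precursor frequency of the specificity.

## What the simulator emulates — and what it does not

`simulate_reads()` generates: power-law cell counts; a fixed $m$ transcripts
per cell; stop-free random coding payloads behind a shared anchor, with
pairwise Levenshtein separation at least 25 (comfortably above the 22-edit
clustering threshold, isolating algorithm correctness from biological
ambiguity — a smaller separation can be configured for stress testing);
uniform random MID tagging; PCR with per-cycle duplication probability,
substitution errors on MID and payload alike; Poisson read depth per
molecule; sequencing errors; and a declining quality profile. Spike-in
controls with fixed copy numbers emulate sensitivity experiments.

The PCR genealogy is tracked explicitly only while the per-molecule amplicon
pool is below `pool_cap` (default 64 copies): a mutation in cycle $t$ founds
a lineage with deterministic final share $(1+\text{eff})^{-t}$, and each read
adopts a lineage by its share. Later-cycle errors can only reach negligible
shares, so they are folded into independent per-read substitutions at rate
$(C - T)\,r\,\text{eff}/(1+\text{eff})$ per base. This keeps the simulation
linear in reads while preserving the one feature that matters for barcode
correction: satellite MIDs whose read counts are a sizable but minority
share of their molecule's reads. Not emulated: indels (consensus is
alignment-free by design; an indel rate would require the length-voting rule
to discard affected reads, which is exactly how the pipeline treats them),
V(D)J recombination structure, quality-correlated error placement, and
sequencer-specific error profiles. Consequently, passing tests demonstrate
correctness of the counting logic under substitution-dominated noise with
well-separated clones; they do not certify behaviour on repertoires with
1-edit-adjacent true clones, where the neighbour collapse deliberately
trades a small false-collapse risk for satellite removal.

## Numerical and scale choices

Distances use a banded dynamic program with early exit at the threshold (a
Hamming bound short-circuits the common equal-length case); base-R `adist`
serves as the independent oracle in tests. One-edit neighbour pairs are found
by hashing half-length prefixes and suffixes (two strings at distance 1 must
share one or the other) and verifying candidates exactly. EM for the
negative-binomial mixture stops at a $10^{-8}$ log-likelihood change or 500
iterations; degenerate input (a single distinct count) short-circuits with a
flag. Subsample grids default to fractions 0.1–1.0 in steps of 0.1, giving 9
adjacent overlap values; overlap curves use nested subsamples (one shared
permutation) so that adjacent comparisons are well defined — independent
draws are available by flag, as either protocol is defensible.

Test and acceptance problem sizes are chosen so the full suite runs in
minutes while keeping every statistical check well powered: end-to-end
recovery at ~300 clones and 30 reads/molecule; chimera formation at 6-nt
MIDs and ~800 molecules (where ~10% of identifiers are shared); saturation
at ~2,000 molecules across ten depth fractions; spike-in sensitivity at 10
copies against $10^5$ background molecules over 20 seeds with a mean depth
of 5 reads per molecule, which already detects every spike molecule that
attracts at least two reads. The pairwise-separation guarantee of the clone
generator is verified exhaustively up to 1,000 sequences and by duplicate
screening plus a random-pair check beyond that; random stop-free sequences
of 129 nt have pairwise distances concentrated far above 25, so the residual
risk is negligible.

## Known limitations

- Indel errors are not corrected, only excluded from voting; a systematic
  homopolymer indel process would shift counts.
- The non-functional flag is a stop-codon test in the anchor frame, not a
  junction-productivity call.
- The neighbour collapse can, in principle, remove a genuine clone that sits
  one edit from a much larger clone; at TCR payload lengths this is rare but
  not impossible.
- `estimate_copy_number()` treats capture efficiency as part of $m$; the
  returned integer is the effective recovered copies per cell, a lower bound
  on the biological transcript count.
- The collision model assumes perfectly uniform MID usage; synthesis bias
  toward some barcodes would raise the collision rate above the bound.
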