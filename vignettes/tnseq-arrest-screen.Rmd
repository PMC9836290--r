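---
title: "Methods: Tn-seq analysis of replication-arrest survival screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Tn-seq analysis of replication-arrest survival screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnscreen)
```

## The experiment and its analysis model

A saturated transposon insertion library (~10^5 unique insertion sites,
about one per 37 bp, ~19 sites per non-essential gene) is split in two.
One half is exposed for one hour to a reversible inhibitor of the
replicative DNA polymerase, which arrests replication forks without
damaging DNA; the other half grows untreated. Both pools then recover,
and aliquots are sequenced hourly. A gene whose disruption impairs
survival of the arrest loses its insertion mutants from the treated pool
(depletion, log2 fold change < 0); a gene whose product is detrimental
during arrest shows the opposite (enrichment, FC > 0).

`run_screen()` executes a fixed stage order on a per-position read-count
table:

1. **Position filter.** Any genomic position with fewer than 3 reads in
   a sample is discarded from that sample (strict `<`; exactly 3 reads
   is retained). One- and two-read positions are dominated by rare
   mispriming/misalignment artefacts rather than real clones.
2. **Inter-sample quantile normalization.** Each sample's count
   distribution is forced onto the common distribution of across-sample
   rank means, so read counts are comparable between libraries of
   different depth and complexity. Normalization is computed over the
   union of positions retained in at least one sample, with absent
   positions contributing zeros; a sample keeps only its own retained
   positions afterwards (the zeros filled for the computation are not
   re-introduced as insertion sites). Tied values receive the mean of
   the rank means their ranks span. Two consequences worth knowing:
   column totals are always equalized, but with ties each sample's
   sorted vector is no longer exactly the common reference (the tie
   rule averages within tie groups); and the transform is rank-based,
   which matters for strong signals (see *Limitations*).
3. **Gene aggregation over the internal window.** Reads are summed over
   the central 5–95% of each gene; insertions in gene extremities are
   sometimes tolerated even in essential genes and are ignored. The
   window on a gene of span `[start, end]` and length `L` is
   `[start + floor(0.05 L), end - floor(0.05 L)]`, strand-independent
   (terminal tolerance is a property of both ends). Each margin floors
   independently, so the window overshoots the nominal 90% of `L` by
   less than 2 bp and never undershoots it. The per-gene statistics are
   the normalized read sum, the number of distinct retained sites, and
   the genome-wide read frequency (read sum divided by the sample's
   total retained normalized reads, intergenic positions included),
   which makes fold changes depth-invariant.
4. **Generation-matched pairing.** The treated pool loses one division
   generation during the 1 h arrest, so each treated sample at `t` h of
   recovery is compared with the control harvested at `t − 1` h;
   comparing pools expanded for different generation counts would
   confound fitness with expansion time. Pairing is mandatory — a
   treated sample with no matching control is an error.
5. **log2 fold changes.** `log2(freq_treated / freq_control)` per gene
   per pair. No pseudocount is used by default: a zero control with a
   positive treated frequency yields `+Inf`, the converse `-Inf`, and
   both-zero is undefined (`NA`, always serialized explicitly). A
   pseudocount option exists for users who prefer shrunk ratios.
6. **Classification.** A candidate must satisfy four criteria:
   (i) length > 200 bp; (ii) more than 5 distinct insertion sites in
   the control of the final (4 h) pair — "insertions" counts unique
   sites, not reads, matching how library complexity is quoted;
   (iii) |log2 FC| > 1 at 4 h — magnitude, since depleted and enriched
   genes are both of interest; (iv) an amplified change over time.
   Hits are `depleted_hit`/`enriched_hit` by the sign of the final FC;
   genes failing (i) or (ii) are `excluded` (unassayable), genes
   failing only (iii) or (iv) are `neutral`. All thresholds are strict
   at their boundaries.

## Operationalizing "amplified change over time"

Criterion (iv) is stated as a requirement, not a formula, so the
package has to choose one. All variants require every defined fold change in the series to
share the sign of the final one. The default (`amplified_mode =
"endpoint"`) additionally requires `|FC(4 h)| ≥ |FC(first defined
time)|`: the change must have grown over the recovery window. Two
stricter per-step variants (`"monotone"`: non-decreasing at every step;
`"strict"`: strictly increasing) are available.

The endpoint reading is the default for a statistical reason. Fold
changes at successive times are separately sampled estimates; a
per-step monotonicity requirement on a 3-point series asks every
pairwise step to exceed its own sampling noise, and for a genuinely
amplifying gene whose per-hour growth in measured |FC| is small —
which rank-based normalization guarantees for strongly enriched genes,
see below — the per-step test rejects most of them (a flat noisy
3-point series is non-decreasing with probability ~1/6). Comparing the
endpoints pools the full amplification against the noise of only two
time points and retains the same scientific content: the change grew.

## The simulator

`simulate_tnseq()` generates the study conditions end to end so the
screen's operating characteristics are measurable against a known
truth:

* **Annotation** — non-overlapping genes with normal lengths (mean
  900 bp, sd 250, minimum 150) tiled along one contig, leftover bp
  spread multinomially over the intergenic gaps.
* **Truth** — each gene is `neutral`, `protective`, `detrimental` or
  `essential`. The baseline survival of the arrest is `s0 = 0.05`,
  matching the few-percent wild-type survival of a prolonged arrest
  measured by viability assays; protective-gene mutants survive at
  `0.1 × s0` and detrimental-gene mutants at `10 × s0` (capped at 1),
  mirroring the ~10-fold survival differences reported for validated
  mutants. Effects are planted only in genes longer than 250 bp so
  every planted effect is in principle assayable.
* **Library** — 10^4 distinct sites (default, scaled down from 10^5)
  sampled uniformly — or from TA dinucleotides of a generated sequence
  when `ta_restricted`, reflecting mariner-transposon target
  preference — excluding the internal windows of essential genes.
  Founding clone abundances are log-normal (`sdlog = 1`).
* **Experiment** — the treated pool passes a single binomial survival
  bottleneck at the start of recovery (the arrest kills; deaths during
  recovery are folded into growth rates), then regrows with a
  one-generation lag: at harvest time `t` the treated pool has
  `(t − 1)` hours of growth versus `t` for the control. Planted genes
  also carry a recovery growth effect *in the treated pool only*
  (protective 0.5×, detrimental 1.5× per generation). This is a
  modeling necessity, not a free flourish: under generation-matched
  pairing the treated sample at `t` and the control at `t − 1` have
  identical generation counts, so any growth-rate difference expressed
  in *both* pools cancels exactly and a pure bottleneck effect
  produces a time-constant fold change — nothing would ever satisfy
  criterion (iv). Biologically, mutants that survive arrest poorly
  also recover from it poorly, and that continued phenotype is what
  "amplified change over time" detects. Sequencing draws `depth`
  (5×10^5) reads per sample multinomially from clone proportions, with
  an optional per-site gamma over-dispersion for robustness testing.

Default problem sizes (500 kb genome, 200 genes, 10^4 sites, depth
5×10^5) preserve the real screen's per-gene site density while keeping
a full simulate–screen–evaluate cycle under two seconds;
`sim_config_fullscale()` provides full-scale parameters (3.7 Mb, 10^5
sites, one insertion per 37 bp).

What the simulator does *not* emulate: PCR duplicates and mapping
noise, sequence-dependent insertion bias beyond the optional TA rule,
SOS induction or prophage-mediated killing, batch effects between
libraries, and any coupling between a clone's founding abundance and
its fitness. Passing recovery tests therefore demonstrates the
pipeline's statistical behaviour under the generative model, not
robustness to every artefact of real sequencing data.

## Numerical and degenerate-input choices

* Window arithmetic uses `floor` on both margins with a `1e-9` guard
  against floating-point noise at exact fraction multiples; windows of
  very short genes may be empty, in which case the gene scores zero
  reads and sites (flagged, not an error).
* Quantile-normalization ties take the mean of the spanned rank means
  (cumulative-sum implementation, O(n log n) per sample); the test
  suite checks equality with an independent brute-force oracle to
  1e-9 on random matrices with ties and zeros.
* Replicates, when present, are paired within replicate and fold
  changes averaged per treated time over defined values; the
  single-replicate path reproduces the single-library screen design exactly.
* A sample listed in the sheet but absent from the counts is treated
  as an all-zero profile; a gene on a contig with no counts scores
  zero. Overlapping genes each count any shared position.
* All simulator randomness flows from one seed; stage seeds are
  derived deterministically, so every stage is individually and
  jointly reproducible, and the CLI writes a manifest (seed, resolved
  config, input digests) sufficient to reproduce outputs byte for
  byte.

## Known limitations

**Rank saturation.** Quantile normalization maps values through ranks.
A strongly enriched gene whose sites already occupy the top ranks of
the treated samples gains almost no normalized value as its true
abundance keeps growing, so measured |FC| for strong enrichment is
compressed and its growth over time flattened. Depletion has more
dynamic range (values fall towards the filter floor and eventually to
zero). This asymmetry is inherent to this normalization
choice, and it is the main reason the endpoint reading of criterion
(iv) is the default.

**Rank displacement under composition shift.** When a noticeable
fraction of the treated pool belongs to truly enriched clones, those
clones occupy the top ranks and displace the big neutral clones
downward; with heavy-tailed clone abundances the top rank means are
widely spaced, so a displacement of a few hundred ranks deflates a
neutral gene dominated by one large clone by two- to three-fold —
enough to cross the |FC| > 1 threshold with a negative, slowly growing
signature. In scaled-down simulations (200 genes, 20 planted strong
effects occupying ~15% of the treated pool) this costs 2–5 false
positives per run and holds measured specificity near 0.97 over the
planted-neutral genes. At realistic scale (~4000 genes, planted
fraction well under 1% of the pool) the displacement is an order of
magnitude smaller. Users screening small engineered libraries with few,
strong expected effects should treat depleted calls for clone-dominated
genes with suspicion — the per-sample site counts in the results table
make such genes easy to spot.

**Hard thresholds.** The classification uses hard threshold
criteria, not significance testing; there is no false-discovery-rate
control, and validation of candidates by targeted disruption remains
the decisive evidence.
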