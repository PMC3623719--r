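---
title: "Modelling flow-space errors in semiconductor sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flow-space errors in semiconductor sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionflow)
```

## The problem

Semiconductor (Ion Torrent PGM) sequencers dispense nucleotides in a
fixed periodic order and measure, for every *flow*, a signal roughly
proportional to the number of template bases incorporated. Base-calling
rounds each flow-value to the nearest integer, so the platform's
characteristic errors are *homopolymer* errors: a flow-value drifting
across the rounding boundary inserts or deletes bases. Because the
dispensation order (the period-32 *Samba* pattern) is fixed, every flow
has a *position-in-cycle* (PIC, the flow index modulo the period) and a
*cycle number*, and error rates vary systematically with both.
`ionflow` works directly in this flow coordinate system: alignments are
projected onto flows, error rates are computed with flow denominators,
and the flow-values themselves are modelled.

Conventions used throughout: flows and cycles are 0-based, base
positions 1-based; a flow-value below 0.50 is a *negative flow* calling
zero bases, and exactly 0.50 calls one base (round half up — the
strictly-below-0.50 definition of a negative flow fixes the tie
direction; values are kept on the hundredth grid end to end, because
boundary values such as 0.51 and 1.49 are meaningful to trimming and to
the substitution signature).

## The flow-value model

For flows whose true homopolymer length is $h \ge 1$, flow-values are
modelled as Gaussian with a separate linear predictor for the mean and
for the log-variance (a double generalised linear model, DGLM):

$$y \sim \mathcal{N}(\mu, \sigma^2), \qquad
\mu = a_0 + a_h h + a_c c + a_{sp} + a_{chip} + a_{kit} + a_{k},$$
$$\log \sigma^2 = b_0 + b_h h + b_c c + b_{sp} + b_{chip} + b_{kit} + b_{k},$$

where $c$ is the cycle number and $a_k, b_k$ are per-PIC offsets.
Factors are treatment-coded with baselines *B. amyloliquefaciens*, chip
314, the 100 bp OneTouch kit, and PIC 0. The fitted coefficient set for
the platform ships as `pgm_flow_model()`; its two most consequential
features are a homopolymer-length mean multiplier of 0.9754 (each added
base lowers the mean flow-value by ~0.025 relative to the ideal integer,
which is why deletions overtake insertions on long homopolymers) and a
dispersion that grows with both homopolymer length (0.486 per base on
the log-variance scale) and cycle number (0.147 per cycle).

True zero-length homopolymer flows are kept out of the Gaussian model: a
distribution truncated at zero with most mass near zero is poorly
approximated by a Normal. They are summarised separately
(`zero_overcall_rates()`) and simulated from their own truncated
Gaussian (below).

### Fitting

`fit_dglm()` uses the classical alternating scheme: (i) weighted least
squares for the mean with weights $1/\hat\sigma^2_i$; (ii) a gamma GLM
with log link fitted to the squared mean residuals for the dispersion
(the gamma dispersion parameter is 2, the squared-Gaussian convention,
which only scales standard errors and not the coefficients). Iteration
stops when the largest absolute coefficient change falls below `tol`
(default 1e-8, reached in 3–5 iterations in practice; hard stop at 50
with an error). The fit is deterministic given the data and invariant to
row order. Degenerate limits are exact: an intercept-only dispersion
reproduces ordinary least squares for the mean, and an intercept-only
model reproduces the sample mean and the maximum-likelihood
(divide-by-n) variance.

Other fitting choices:

* Homopolymer lengths above `h_cap` (default 8) are excluded when
  assembling observations — the sparse long-h tail destabilises the
  dispersion fit and such flows are rare.
* `retain_terms()` drops terms whose largest contribution to the *mean*
  linear predictor over the training data is at or below 0.001
  flow-value units (|coefficient| × max |x| for numeric covariates; a
  factor is dropped only if every level qualifies). The threshold is an
  effect-size criterion, not a significance test: with hundreds of
  thousands of observations, practically irrelevant terms are routinely
  statistically significant.
* `compare_models()` performs the likelihood-ratio comparison of nested
  fits using the Gaussian log-likelihood with per-observation fitted
  variances; degrees of freedom count both predictors.

## The synthetic-data generator

The simulator is the ground-truth engine that makes every downstream
stage testable without platform data. It emulates:

* **Fragments**: start positions uniform over the reference, strand
  Bernoulli(0.5), template length 1.2× the kit's nominal read length so
  the flow budget (1.6 flows per base, rounded up to whole cycles —
  random sequence consumes about 1.68 flows/base under Samba) is
  normally the binding constraint, as on the instrument.
* **Flow-values**: $h \ge 1$ flows from the Gaussian DGLM above
  (truncated at zero, quantised to hundredths); $h = 0$ flows from a
  truncated Gaussian with defaults mean 0.12, sd 0.15, chosen once so
  that zero-mer call accuracy falls inside the empirically observed
  98.75–99.72% band. Key flows (the TACG prefix) are synthesised
  noise-free: the instrument normalises flow-values to the key, so key
  flows are near-ideal by construction, and this keeps the first four
  called bases equal to the key.
* **Substitutions**: each match-aligned base flips with probability
  `sub_rate`; when the base sits in a called 1-mer flow its flow-value
  is set to 0.51, the low-confidence signature observed on real
  substitutions (a 0.51 value is incompatible with a called length of
  two or more, so bases inside longer runs are flipped without touching
  the flow-value).
* **High-frequency indel (HFI) sites**: planted as single-base template
  edits applied, per covering read, with the site's penetrance and
  optional strand restriction. Edits are restricted to
  structure-preserving forms — an insertion duplicates an existing base
  (extending its run), a deletion removes one base from a run of length
  ≥ 2 — so the flow correspondence between read and reference is exact
  and the truth ledger can record per-flow truth without alignment
  composition. The cost is that all planted HFIs are homopolymeric,
  whereas on the platform only a minority are; detection power at
  non-homopolymeric sites is therefore not exercised by the simulator.
  Insertions are biased towards A/T and deletions towards C/G, the
  observed type spectrum.
* **Truth outputs**: a per-flow ledger (true h, called h, substitution
  flag, flow-value) restricted to alignment-visible flows, and a truth
  SAM. Indels in the truth CIGARs are left-aligned in reference
  coordinates — the normalisation every mainstream aligner applies —
  which in physical flow order means indel-before-match on the forward
  strand and the mirror on the reverse strand. (Right-aligning instead
  would split one site's events across two coordinates in a
  strand-dependent way and fabricate strand asymmetry.)

All randomness derives from one mandatory seed through named substreams
(genome, starts, HFI penetrance, flows, subsampling), so each stage is
independently reproducible.

What the simulator deliberately does *not* emulate: polyclonal beads and
the residual-based polyclonal filter, chip-surface (x/y) effects,
non-zero PIC effects by default (they are configurable but default to
zero), the vendor's six-predictor quality lookup table (qualities come
from a pluggable map, by default monotone in the absolute flow
residual), non-homopolymeric HFIs, and the bimodal read-length artifact.
Passing tests on simulated data therefore demonstrate correctness of the
analysis machinery under the stated generative model, not robustness to
every artifact of real runs.

## Alignment classification and flow projection

`classify_alignment()` splits CIGAR `M` columns into match/substitution
by base comparison (aligners report both as `M`), and positions events
physically: base positions count from the read's 5' end as sequenced,
and a deletion is reported at the read base immediately 5' of the gap
(falling back to the 3' flank at an alignment edge). The analysis trim
keeps base positions ≥ 10 (avoiding 5' misalignment and key-adjacent
homopolymers) and caps at the kit's nominal length (100 or 200 bp); a
deletion is kept only when both flanks are inside the window.

`project_to_flows()` recovers per-flow (true h, called h) pairs: read
bases map to flows through the SFF per-base flow index; a deleted
reference base is attributed to the flow that *should have* incorporated
it — the current flow when its nucleotide matches, otherwise the first
later flow dispensing that nucleotide, bounded by the next aligned
base's flow (an alignment violating the dispensation order is flagged,
counted and excluded). Flows overlapping substitution columns are
flagged and excluded from homopolymer statistics (the substitution
mechanism is modelled separately; the exclusion count is reported).
Flows with called bases outside the aligned region (soft-clipped) are
dropped and counted. Error rates use the convention that matters for
this platform: base-level denominators are alignment columns (so
deletions depress the rate's denominator correctly), and per-h flow
denominators count flows that were, *or should have been*, an h-mer.

Base-level and flow-level accounting reconcile exactly: total inserted
bases equal the summed positive part of (called − true) over flows, and
symmetrically for deletions.

## HFI detection

Differences from the reference are tested per site as
$X \sim \mathrm{Binomial}(n, p_0)$ with the exact upper tail
$P(X \ge x)$ (the alternative of interest is an excess). The
substitution null is the mean substitution rate; the indel null is
parameterised on the reference homopolymer length, with sparse long
lengths pooled into the largest well-covered one. For single-base
insertions the coverage is the maximum over the two bases flanking the
junction, and insertion sites are keyed to the junction's left base —
note that a left-aligned insertion extending a run is detected at the
base *before* the run. Holm correction is applied per type per run
(matching how site counts are reported per type); significance at
adjusted p < 0.05. Strand asymmetry at significant indel sites uses the
two-sided Fisher exact test (sum of hypergeometric probabilities not
exceeding the observed table's), Holm-corrected over the family of all
testable sites in the run; single-strand sites are untestable and
excluded from the family. Site sets are intersected across runs keyed by
(position, type) — on the platform most HFI sites are private to a run,
which is what distinguishes them from genuine polymorphisms.

A site-level caveat observed on simulated data: genuinely elevated
per-site error rates (very long homopolymers whose pooled null
understates the rate) surface as significant sites. This mirrors the
platform, where such systematic sites are exactly what the masking step
removes before flow-value modelling.

## G+C coverage bias

Coverage is averaged over disjoint 100 bp windows (reference span of
each alignment, deletions covered, insertions adding no depth), windows
overlapping the 120 bp reference ends or any masked base are dropped
(strictest reading; a fractional threshold is available), each run is
normalised by its own mean (the per-run mean of normalised coverage is 1
to machine precision) and square-root transformed — on this fold-change
scale a value of 2 means four times the run mean. Windows beyond
median + 10×MAD of normalised coverage (e.g. unmasked rRNA repeats) are
flagged and optionally excluded. The model is
`sqrt(norm cov) ~ gc * species`, reported as one intercept+slope pair
per species.

## Quality scores and trimming

Empirical recalibration compares each assigned Phred score with the
observed error rate of bases carrying it (insertions and substitutions
only — deletions have no base to carry a score); zero-error cells report
the rule-of-three bound $-10\log_{10}(3/n)$ flagged as a bound, never
infinity. The homopolymer profile reports the relative quality change
$(q_1 - q_x)/q_1$ from the first base of each called homopolymer, split
by correct versus over-called flows, on a 20,000-read sample.

Trimming treatments nest: analysis trim (AT, the kit-length cap), plus
the SFF quality/adapter clip (QT; the more stringent of the two when
both are set, and a windowed fallback — clip at the first 30 bp window
with mean quality ≤ 9 — when neither is stored), plus high-residual
ionogram (HRI) trimming. An HRI 1-mer has a flow-value in [0.50, 0.59]
or [1.40, 1.49], a 2-mer in [1.50, 1.59] or [2.41, 2.49], and (in the
3-mer variant) a 3-mer in [2.50, 2.59] or [3.40, 3.49]; membership is
exact on the hundredth grid. Flows are removed from the 3' end one flow
at a time — the finest unit consistent with flow-space trimming, bases
following their flows — until HRI 1/2-mers are ≤ 3% of all 1/2-mer
calls in the *retained* read (numerator and denominator recomputed on
the retained prefix at each step; this equals the longest prefix
satisfying the rule, which is how the implementation computes it in one
pass over prefix sums). Reads shorter than 4 bases after clipping are
discarded. HRI percentages are computed on the full called read, before
the analysis window is applied, since the instrument trims before any
analysis window exists. Treatment metrics (indel rates within the
retained window at positions ≥ 10, length percentiles, % bases
retained, % error-free reads, errors-per-read percentiles) reconcile
with the per-read trim table by construction.

## Validation problem sizes

The test suite validates each stage at sizes chosen to give tight Monte
Carlo error while remaining quick to run: DGLM parameter recovery on
5×10^5 simulated observations (mean coefficients recovered within
0.005, dispersion within 0.05); detector calibration on 200 site-level
null simulations at coverage 100 over a 10 kb reference (family-wise
error within binomial noise of 0.05, planted penetrance-0.3 sites
detected in ≥ 90%); exact-oracle equivalence for every 2×2 table with
total ≤ 40 and binomial tails to n = 200; truth-ledger equality on a
10^4-read simulated run; HRI-trim equality with a brute-force suffix
scan on 10^4 random flowgrams; G+C slope recovery over 100 seeds; and
bit-exact SFF round-trips on 1000 reads. The `analysis/` drivers use six
runs of 2–3×10^3 reads on 10 kb references — small enough to run in
minutes, with ~30–50× coverage so site-level testing has power.

## Known limitations

* The DGLM is Gaussian; real flow-value distributions show mild
  asymmetry and over-popular boundary values (0.51, 1.49, …), which the
  model smooths over.
* PIC coefficients default to zero in the simulator; analyses exercise
  the PIC machinery but not recovery of a specific published PIC
  vector.
* Planted HFIs are homopolymeric by construction (see above).
* Inverted (reverse-complement) repeats are not masked — only
  forward-strand exact repeats, the conventional perfect-match
  definition.
* The SFF layer implements the standard v1.0 layout; index blocks are
  ignored on read and not written.
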