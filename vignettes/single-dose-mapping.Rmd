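---
title: "Integrated linkage maps from single-dose markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated linkage maps from single-dose markers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmap)
```

## The mapping problem

Highly polyploid, highly heterozygous crops — sugarcane is the canonical
case — cannot be mapped through inbred-line crosses. The practical design
is a biparental F1 population scored for *dominant single-dose markers*:
band-presence polymorphisms (AFLP fragments, EST-SSR alleles scored as
bands, retrotransposon-anchored fingerprint fragments) present as a single
allele copy among the homo(eo)logs of one parent or of both. Under regular
bivalent pairing, a single-dose locus transmits like a diploid
heterozygote, so classical two-point and multipoint machinery applies
after this "diploidization":

* **D1** loci are heterozygous for band presence in parent 1 only and
  segregate 1:1 in the progeny;
* **D2** loci are heterozygous in parent 2 only, also 1:1;
* **C** loci are simplex in both parents and segregate 3:1 (band present
  : absent).

D1 and D2 markers carry information about different meioses; a D1 x D2
pair is mutually uninformative at two points. C loci see both meioses and
act as *bridges*, which is what makes a single integrated map of both
parents possible.

## Segregation screening

Each marker is classified from its parental scores, tested against its
expected ratio with a 1-df Pearson chi-square (no continuity correction)
over the non-missing progeny, and kept only if its p-value exceeds the
Bonferroni-adjusted level `alpha / n_tests`. `n_tests` counts the markers
with a valid cross type and at least one scored progeny; missing progeny
scores are dropped from the counts, not imputed. Under null simulation
the family-wise exclusion rate is controlled at `alpha` (the acceptance
suite verifies this at n = 188 with about 1,000 markers per replicate).

## Two-point estimation

For a marker pair, the hidden quantity per individual is the pair of
parental transmissions; each parent is recombinant between the loci with
probability `r`, independently, with one shared `r` for both parental
meioses (the integrated-map convention). Mapping transmissions to bands
through the single-dose rules gives closed-form joint pattern
probabilities for every pair class and relative phase (coupling =
band alleles on the same homolog, repulsion = opposite homologs, per
parent). `estimate_pair()` maximizes the multinomial likelihood over
`r` in [0, 0.5] for each admissible phase — closed form for D-type
pairs, golden-section search (60 iterations, endpoints checked) for the
classes involving C markers — picks the phase with the highest maximized
likelihood, and reports `LOD = log10 L(r_hat) - log10 L(0.5)`.

Two properties deserve emphasis:

* Phase ties are broken toward coupling, the configuration that dominates
  real polyploid data.
* The C x C phase subfamily is *non-identified* at two points:
  coupling-repulsion at `r` and repulsion-repulsion at `sqrt(r(1-r))`
  generate identical pattern tables. Two-point phase calls between C
  markers are therefore unreliable at small `r`; the multipoint stage is
  designed not to depend on them (below).

## Grouping

Co-segregation groups (CGs) are the connected components of the graph
whose edges are informative pairs with `LOD >= 6` and `rf <= 0.35` (both
configurable). D1 x D2 pairs never form an edge regardless of their
counts; integration across parents happens only through C bridges.
Markers in no edge are reported unlinked and excluded from ordering.
Components are ordered deterministically (size, then smallest member), so
the partition is invariant to input order.

## Multipoint ordering

Within a CG the model is a hidden Markov chain over the four transmission
states `(a, b)` — the homolog transmitted by each parent — with
transitions factorizing over parents at one shared recombination fraction
per interval, uniform initial distribution, and deterministic single-dose
emissions (missing scores emit 1). There is no genotyping-error term in
the emission, matching the software generation the procedure mirrors;
robustness to simulated error is tested empirically instead. Interval
recombination fractions are fitted by Baum-Welch EM: the E-step
accumulates expected recombination events per interval and per parent,
the M-step pools both parents over `2N` meioses. The log-likelihood is
non-decreasing across iterations; convergence is declared at `em_tol`
(default 1e-6 on the log-likelihood, cap 200 iterations). The
forward/EM kernels are compiled code; a 2-locus chain reproduces the
two-point likelihood to 1e-9 and a 3-marker chain matches an independent
grid-search oracle to 1e-3 on `r`.

**Phases.** Absolute 0/1 phases per marker and parent are propagated
along a candidate order from the two-point relative phases. Each marker
anchors on the previously placed marker whose pair best resolves its
phase in that parent: D-type pairs (D1 x D1, D1 x C for parent 1) are
preferred outright over C x C pairs, with pair LOD breaking ties — a
direct consequence of the C x C non-identifiability above. After the
final EM fit, each marker's phase components are re-checked by
likelihood: any flip that improves the multipoint likelihood is accepted
(up to three sweeps). This is the package's post-hoc re-check of the
phases fixed from two-point estimates.

**Search.** Groups of up to `exhaustive_max = 6` markers are ordered by
evaluating every order up to reversal with EM-fitted intervals
(`compare_orders()`). Larger groups use `order_seq()`: a seed frame of
the `frame_size = 5` markers with the highest within-group LOD
connectivity is ordered exhaustively, and the remaining markers are
inserted one at a time (most-connected first) at their likelihood-best
position. Candidate positions are screened with plug-in two-point
recombination fractions — a cheap forward pass, no refitting — and only
the two best positions are refitted by EM; if their refitted likelihoods
differ by less than `insertion_lod_threshold = 3` log10 units the
placement is considered ambiguous, the marker is force-placed at the
better position and flagged in the group's `ambiguous` list. `ripple()`
then slides a window (default 4) over the order, screens all window
permutations the same cheap way, refits the best candidate by EM and
accepts any strict improvement, repeating until a pass changes nothing.
During search, EM runs at a coarsened tolerance (1e-4, 50 iterations);
every accepted order is refitted at full precision. These screening
shortcuts trade an exhaustive EM per candidate for tractability at the
scale of hundreds of markers; the acceptance suite verifies that the
full stack recovers a true 8-marker order (up to reversal) in at least
80% of seeded replicates at n = 188 and 10 cM spacing.

Fitted intervals are converted to positions with the Kosambi map
function, `d = 25 ln((1+2r)/(1-2r))` cM.

## Homo(eo)logous groups

EST-SSR loci are multiallelic: alleles of one locus map to different CGs
that represent homo(eo)logous chromosomes. CGs sharing at least two
distinct SSR locus codes are core members of one homo(eo)logous group
(HG), closed transitively; CGs sharing a single locus with a group's
core are attached as putative members. HGs are numbered with Roman
numerals by total marker count descending (the published convention
never states the rule; size ordering reproduces its largest-first
numbering), CGs within a group are renamed `<HG>-k` by genetic length
descending, and CGs in no group become `U-k`. A locus duplicated within
one CG is not evidence (no self-edges), and duplications are excluded
from HG support.

## Retrotransposon analyses

**Clustering test.** The map is divided into 10 cM bins (per CG, from
position 0; a trailing partial bin counts as one bin, and the final bin
is closed on the right so the terminal marker, which defines the CG
length, is counted — the two conventions "ceiling bin count" and
"half-open bins" conflict exactly at multiples of the bin width, and
this is the documented resolution; whole-map binning is available as an
option). If target markers are placed at random the per-bin counts are
Poisson; `poisson_gof()` compares observed class counts (x = 0..max)
with `n_bins * lambda^x e^(-lambda) / x!` at `lambda` = mean count per
bin, with `df = c - 1 - 1` for the one estimated parameter. The default
keeps all observed classes unpooled — mirroring the published usage with
four classes and 2 df — but that inclusion of near-empty tail classes is
anti-conservative (type-I error around 10-16% at sparse lambda in the
package's own null simulations). The `pool = TRUE` mode merges the tail
into a final `>= K` class with expected count at least 1 and calibrates
to about 5% for lambda above roughly 0.3 (slightly conservative below);
calibration and power claims in the test suite use the pooled mode.

**Cluster calling.** Within each CG, target-system markers in map order
(other systems ignored) form a cluster when every consecutive gap is
strictly below 5 cM and the run has at least two members; the span is
the first-to-last distance.

**Copy number.** Each fingerprint combination detects (nearly) every
genomic copy of the target element once, so total bands divided by the
number of combinations estimates the copy number (half-up rounding for
the reported integer; per-parent totals give per-parent estimates).

## The synthetic population generator

No genotype matrix is deposited for the study this package re-implements,
so `simulate_population()` provides populations with known truth. Its
defaults are the study conditions: 188 F1 individuals; 730 single-dose
markers split 197/192/146 (AFLP D1/D2/C), 41/60/29 (EST-SSR) and
23/32/10 (retrotransposon); 46 chromosomes of 105 cM (about 4,800 cM of
map, with CG sizes in the two-to-tens range that polyploid maps show,
one chromosome per bivalent under the single-dose reduction);
retrotransposon markers placed as 6 clusters of 3 with within-cluster
gaps below 2 cM, the rest uniform; 3% missing scores and 1% call errors
(values in the range practitioners report for silver-stained gels,
chosen once as the package's defaults); chromosomes cycled into 7
homeology groups whose SSR markers share locus-code pools.

Meioses are simulated with no crossover interference: the transmitted
homolog along a chromosome is a Markov switch chain whose interval
switch probabilities are the Haldane transforms of the inter-marker
distances — distributionally identical to thinning a rate-1-per-100-cM
Poisson crossover process at the marker positions. The published map
uses Kosambi distances, but no simulation model is stated there; since
every recovery test compares estimates with this generator's own truth,
the choice is internally consistent. One genetic length is shared by
both parental meioses, matching the one-`r`-per-interval integrated
model. Ploidy is not simulated explicitly: under the simplex/bivalent
assumption a single-dose marker's transmission is exactly that of a
diploid heterozygote — the model reduction the whole design rests on.
Distorted markers (for filter tests) are generated unlinked with a
forced band-presence probability.

What the generator does *not* emulate: multivalent pairing and double
reduction, aneuploid dosage, duplex and higher-dose markers,
segregation-distortion gradients along chromosomes, scoring artifacts
that correlate across gel lanes, and per-parent map-length differences.
Passing recovery tests therefore demonstrate correctness of the
estimators under the stated single-dose model, not robustness of the
biology behind real sugarcane data.

`simulate_nbs_profiles()` emulates the fingerprint band counts behind
the copy-number estimator: each enzyme-primer combination detects each
of the `true_copy_number` element copies with `detection_prob`, and a
detected copy is absent from a given parent with probability
`polymorphism_rate / 2` per parent.

## Problem sizes used by the checks

The test suite runs its recovery and calibration checks at the study's
population size (n = 188) with 3-20 markers per chromosome, 50 seeds for
order recovery, 200 replicates for filter calibration and test power,
and 500 for the Poisson null; the acceptance script runs one full
pipeline at the default scale (730 markers, 46 chromosomes). These sizes
are the package's chosen compromise between statistical resolution and a
desk-scale run.

## Known limitations

* Phases are fixed before multipoint fitting (with the likelihood
  re-check above); a fully joint phase-order-rf search is out of scope.
* No error model in the HMM emissions; heavy genotyping error inflates
  map lengths, as it does in the software generation mirrored here.
* `order_seq()`'s ambiguity measure compares only the two best screened
  insertion positions, so a multimodal placement can be flagged on a
  slightly optimistic gap.
* The Poisson clustering test's default (unpooled) mode reproduces the
  published procedure rather than exact calibration; use `pool = TRUE`
  when the size of the test matters.
* Copy-number estimation assumes one band per element copy per
  combination; co-migrating fragments and partial digestion violate
  this in real gels.
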