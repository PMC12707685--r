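---
title: "Methods: quantifying the giant fiber escape circuit"
author: "escapeCircuit package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the giant fiber escape circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escapeCircuit)
```

# Scope

The *Drosophila* giant fiber (GF) escape circuit relays a visual threat
from the retina through the optic lobe, via the LC4 and LPLC2 visual
projection neuron types, onto the GF descending neuron and onwards to
the jump (TTM) and flight (DLM) muscles. This package implements the
quantitative analyses used to characterize that circuit:

1. **Connectome pathway analysis** — building a synapse-count-weighted
   directed graph from exported connectivity tables, computing
   photoreceptor-to-GF pathways, and summarizing which relay cell type
   each pathway converges through.
2. **Circuit electrophysiology metrics** — short-/long-latency response
   classification, refractory period, following frequency 50% and latency
   dispersion, all computed from stimulus/response event times.
3. **Habituation statistics** — response-probability curves over long
   stimulus trains and the consecutive-failure-onset statistic.
4. **3-D synaptic puncta counting** — scale-normalized
   Laplacian-of-Gaussian (LoG) blob detection with Otsu background
   thresholding and membrane-mask colocalization on anisotropic
   two-channel stacks.
5. **Synthetic data generators** with planted ground truth for each of
   the above, so every stage is testable without multi-gigabyte
   connectome downloads or microscope data.

# Connectome graphs and pathway convergence

## Graph construction

`buildConnectome()` aggregates a synapse table per (pre, post) neuron
pair — summing across postsynaptic compartments — and keeps connections
whose aggregated count reaches `minSynapses` (default 5, the filter used
for the public-connectome analyses). "Connection" here means the neuron
pair, not an individual synapse annotation: the count threshold is
applied after aggregation. Self-loops are dropped because they cannot
participate in source-to-target pathways. An optional hemisphere filter
requires *both* endpoints on the stated side; neurons annotated
`center` pass any filter, a permissive convention for midline-ambiguous
cells that is configurable rather than hard-coded. Neurons missing from
the annotation table are kept with cell type `unannotated` and reported,
never silently dropped, so synapse totals are conserved.

## Pathways and the synapse-count tie-break

A *hop* is one edge, i.e. one synaptic crossing; a monosynaptic
connection is one hop. `shortestPathways()` computes the unweighted
(minimal-hop) shortest paths from a source to the target and, where
several exist, retains only those with the maximal total synapse count
along the path. The relay class of a pathway is the cell type of its
penultimate node (`classifyRelay()`), with `LC4`, `LPLC2` and `other`
as default classes.

`convergenceFractions()` exposes two aggregation units because circuit
statements come in two forms: *per-source* ("x% of photoreceptors reach
the target via LC4") assigns each source fractionally across the
classes of its retained pathways; *per-path* ("x% of pathways converge
through LC4/LPLC2") counts every retained path once. Sources with no
pathway are excluded from the denominator and reported separately;
a zero denominator yields missing fractions, never zeros, so
"unreachable" is distinguishable from "reaches via other".

## Bounded-hop censuses

`boundedHopCensus()` enumerates *simple* paths (no node revisits) of
length at most (or exactly) k hops for k = 2..kMax, by depth-first
search pruned with precomputed hop distances to the target. Simple
paths rather than walks match standard path-enumeration tooling and the
"pathway" reading of the question. No synapse-count tie-break is applied
within the bound — the tie-break is a shortest-path rule only. A
per-source path cap (default 10^6) guards combinatorial blow-up; an
exceeded cap flags the summary as partial rather than silently
truncating. The default census mode is `le` (paths of length <= k),
which reads "within k steps" literally; `exact` is exposed for
sensitivity checks.

## Input census and in-silico silencing

`inputCensus()` sums direct input synapses of a target by source relay
class, optionally restricted to one postsynaptic compartment (for
analyses of a specific dendritic domain such as the GF visual dendrite)
and optionally partitioned by whether sources receive input within a
stated neuropil set (e.g. lobula / lobula plate / accessory medulla,
separating optic-lobe inputs from central-brain inputs). The
compartment column is an explicit input dependency: how a synapse was
assigned to a dendritic domain upstream (ROI labels vs manual
compartments) is outside this package's control and therefore surfaced
as configuration.

`removeCellType()` deletes all neurons of a cell type — the graph-level
analogue of blocking a type's synaptic output (as tetanus-toxin
expression does physiologically). Deleting a relay class drives its
convergence fraction to zero while the other classes renormalize, which
the test suite verifies on planted connectomes.

# Electrophysiology metrics

All times are milliseconds. `pairResponses()` matches each stimulus to
the earliest unconsumed event in `(stimulus, stimulus + window]`; the
window (default 10 ms) must stay below the minimal inter-stimulus
interval or pairing would be ambiguous, which is rejected as a
configuration error.

Latency bands (defaults: SLR `[0.5, 2.5)` ms, LLR `[2.5, 8.0)` ms) are
configuration, not constants: empirically the short-latency response to
direct GF stimulation sits near 0.9–1.4 ms and the long-latency
response to retinal stimulation near 3.4–5 ms, so the boundary is
placed in the empty gap between the clusters. Latencies outside all
bands are `unclassified` rather than force-assigned.

The refractory period is defined over an explicit paired-pulse trial
table — the minimal ISI whose second stimulus was answered — because
the staircase controller that chooses ISIs during acquisition is
hardware-side and out of scope. FF50 is the highest tested frequency
transmitting at least 50% of stimuli; non-monotone inputs are allowed
and the definition applied literally. Both statistics are
permutation-invariant in their inputs and return missing (never 0)
when no trial qualifies. The coefficient of variation is `sd/mean`,
reported at 3 decimals (a 3.92 ± 0.11 ms latency gives 0.028).

# Habituation statistics

`responseProbabilityCurve()` pools animals per stimulus index (the
index-wise mean), then optionally applies a centered moving average
with edge truncation. The default window is 1 — the raw index-wise
probability — because any smoothing of published probability curves is
typically unstated; smoothing here is explicit configuration.

`consecutiveFailureOnset()` returns the 1-based index of the stimulus
*completing* the first run of m consecutive failures ("up to and
including" convention), so onset(m) >= m and onset is nondecreasing in
m — both enforced as class invariants and tested. Animals that never
reach m consecutive failures (non-habituating trains, e.g. after
potassium-channel knock-down) are censored from the log10 group
summaries and reported as counts, not imputed, since no imputation rule
is defensible from the data.

`frequencyDependence()` compares two profiles at a checkpoint stimulus
index (default 100, inside the window where habituation completes) and
flags whether the decline at the higher frequency is at least as strong
as at the lower; ties count as frequency-dependent, a deliberate
convention so that the flag reads "not slower at 10 Hz".

`fitHabituationDecay()` is a descriptive exponential-decay fit used
only for parameter-recovery checks. It is a binomial GLM with log link
on per-index success counts (log p linear in the index), which gives an
honest delta-method standard error for the decay constant; nonlinear
least squares on the probability curve was rejected because its
residual-variance-based SE is badly calibrated for Bernoulli data.

# Puncta counting in anisotropic stacks

Blob scales are specified in nanometres and converted per axis to
voxels (defaults 50 × 50 nm in-plane, 190 nm z-steps), so blob
roundness is physical rather than voxel-space. For each of `nScales`
geometrically spaced scales the volume is smoothed by a separable
Gaussian (edge-renormalized truncated kernels), the physical-space
Laplacian is formed by finite differences, and the scale-normalized
response `-sigma^2 * Laplacian` is computed. Detections are local
maxima over space and adjacent scales that exceed the response
threshold and lie above the Otsu background threshold of the intensity
image (256 histogram bins by default). Overlapping detections — centre
distance below the sum of the `sqrt(3)*sigma` radii — are merged
keeping the stronger. Detection runs in 3-D by default; a per-slice
2-D mode is available for comparison with slice-wise workflows.

The original workflow set the response threshold per stack "so that no
false positives were counted", an operator judgment. For
reproducibility this package replaces it with an explicit parameter
plus an automatic mode. Two automatic rules were implemented and
compared on planted ground truth: Otsu on the LoG response
distribution, and a per-scale noise floor (threshold = 5 × the RMS of
the negative response half, exploiting that the LoG response of
background noise is symmetric about zero while bright round structures
only add a positive tail). The Otsu rule collapses at low SNR when
blobs occupy a tiny volume fraction — at SNR 3 it over-detects by more
than an order of magnitude — so the noise-floor rule is the default
(`responseThreshold = "noise"`), with `"otsu"` kept as an option. With
the default, planted counts are recovered exactly over 20 seeds at
both SNR 10 and SNR 3 in the test suite.

Mask colocalization (`restrictToMask()`) binarizes the membrane
channel (Otsu by default), dilates by one voxel (configurable; the
original mask construction is unstated, so it is exposed as
configuration) and keeps detections whose centre lies inside.
`integratedDensity()` is the plain masked intensity sum used for
terminal-intensity comparisons.

# Synthetic data generators

Each generator is a pure function of its configuration and a mandatory
seed (global RNG state is saved and restored), returning the dataset
plus a ground-truth record.

**Connectome** (`simulateConnectome()`): a strict feedforward layering
source → two interneuron layers → relay layer → target, mirroring the
escape circuit's depth so 4-hop shortest paths and 5-hop detours are
exercised. Each source is deterministically routed through one relay
class so the planted split (default 60/40 LC4/LPLC2) is realized
*exactly* — recovery tests compare against construction, not
simulation noise. Kept edges draw synapse counts as 5 plus a geometric
excess; sub-threshold noise edges (counts 1–4, directed backward so
they can never shorten a source-target route) exercise the build-time
filter. Detour nodes (default probability 0.25 per source) add
strictly longer alternative simple paths, half of which rejoin through
a different relay class.

**Habituation** (`simulateHabituationTrains()`): independent Bernoulli
responses with p_i = p0·exp(−i/τ(f)), τ(10 Hz) < τ(5 Hz) (defaults
τ = 30 and 15 stimuli, p0 = 1), chosen so habituation completes within
the first 50–100 stimuli at 5 Hz and faster at 10 Hz, matching the
reported phenomenology. The exponential form is the generator's own
modeling choice — the statistics modules never assume it.

**Ephys** (`simulateEphys()`): truncated-normal latencies per class
(defaults SLR 1.4 ± 0.05 ms, LLR 3.92 ± 0.11 ms), a deterministic
refractory cutoff (default 3 ms) probed over a 0.5-ms ISI grid, and
frequency trains with logistic transmission (midpoint 180 Hz, slope
5 Hz, 20 stimuli per train over a 100–250 Hz grid in 10-Hz steps) so
FF50 recovery is accurate to one grid step.

**Puncta** (`simulatePunctaStack()`): Gaussian spots (default σ =
200 nm, a plausible size for postsynaptic marker puncta) at random
positions with minimum pairwise separation 4σ on the 50 × 50 × 190 nm
grid, plus Gaussian noise at a stated peak-to-SD SNR; the membrane
channel labels a half-volume slab and a stated fraction of puncta is
planted inside it, so colocalization is checkable against construction.

## What the generators do and do not emulate

The generators reproduce the *structure* each analysis assumes —
layered convergence, all-or-none decaying response trains, round
anisotropic puncta — not the realism of the source data: no attempt is
made to match real connectome degree distributions, biological latency
drift, state-dependent habituation, or microscope PSF side lobes and
photon statistics. Passing recovery tests therefore demonstrates
correctness of the computations under their stated assumptions, not
robustness to every property of real recordings.

# Numerical choices and problem sizes

Fractions are validated to sum to 1 within 1e-9 wherever a denominator
is nonzero. Shortest-path ties are compared within 1e-9 of the maximal
synapse total. The Otsu threshold is returned as a bin edge; on a flat
between-class-variance plateau the first maximizing edge is chosen.
Degenerate inputs are explicit: constant images are rejected by
`otsuThreshold()` but yield an empty detection set in the blob
pipeline; empty masks warn and return zero detections; single-animal
onset summaries report SEM 0 with n = 1 visible.

The test suite and the acceptance script run entirely on synthetic
data at deliberately modest sizes — random oracle graphs of up to 30
nodes, 100 simulated animals, stacks of 16 × 96 × 96 voxels with 10–25
planted puncta — sizes at which brute-force enumeration oracles remain
exact and the full suite completes in well under a minute per module.
Reproducing the published full-connectome convergence percentages
requires the pinned public exports (several gigabytes); the pipeline
accepts them directly (`synapseDialect("fafb")`), and the
corresponding test documents where to place them.

# Known limitations

- Bounded-hop enumeration is exponential in the worst case; the cap
  turns blow-ups into flagged partial results rather than preventing
  them.
- The LoG detector assumes approximately round, approximately
  equal-sized bright puncta on a darker background; elongated or
  touching structures (< 4σ apart) will be merged or missed.
- Latency-band classification is only as good as the configured bands;
  atypical preparations need explicit band configuration.
- The habituation decay fit is descriptive; it will not represent
  non-exponential (e.g. biphasic) habituation well, and its SE assumes
  independence across stimuli within an animal.
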