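---
title: "Inferring kinase and phosphatase regulators from multi-strain phosphoproteomics"
author: "phosphoKinNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring kinase and phosphatase regulators from multi-strain phosphoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoKinNet)
```

## The problem

When a yeast strain panel — a progenitor, an intermediate and an evolved
strain — is profiled by quantitative phosphoproteomics under contrasting
conditions (here, anaerobic versus aerobic growth on xylose), thousands of
phospho-peptides change, but the kinases and phosphatases driving those
changes are not observed directly. phosphoKinNet infers candidate regulators
from four pieces of indirect evidence:

1. **Response pattern.** Peptides whose phosphorylation changes in a
   coherent pattern across the panel are candidates for shared regulation.
2. **Phospho-motif.** Kinases recognize sequence context around the
   phospho-acceptor, so co-regulated peptides tend to share a motif.
3. **Physical interaction.** A regulator should physically touch an
   unexpectedly large fraction of a module's proteins in a background
   interaction network.
4. **Specificity match.** For kinases with measured specificity, the
   module's sequence preferences should resemble the kinase's.

Each stage is usable on its own; `inferRegulators()` (and its file-based
wrapper `runPipeline()`) chains all four.

## Stage 1: response classification

Inputs are replicate-level log2 fold-changes per strain (the contrast — for
the study data, xylose −O~2~ versus xylose +O~2~ — is fixed upstream and the
classifier is contrast-agnostic). With replicate-averaged values
$(v_1, v_2, v_3)$ in panel order and threshold $t = \log_2(1.5)$:

* **Class A (progressive)**: $v_2 - v_1 \ge t$ and $v_3 - v_2 \ge t$
  (increasing), or the mirror image (decreasing);
* **Class B (evolved-specific)**: $v_3$ at least $t$ beyond *both* earlier
  strains, with $|v_2 - v_1| < \log_2(1.5)$;
* **none** otherwise.

Two reading choices deserve note. "At least a 1.5-fold difference in
replicate-averaged log2 changes" is interpreted as a *difference of log2
values* of at least $\log_2 1.5 \approx 0.585$ — i.e. the underlying
fold-changes differ by a factor of 1.5. Multiplying a log2 value by 1.5 is
ill-defined near zero and not used. Second, Class B's "no significant
difference" between the first two strains is operationalized as a
fold-equivalence bound ($|v_2-v_1| < \log_2 1.5$): with two replicates per
strain a per-peptide test has essentially no power, so a bound on the
effect size is the honest alternative. Both thresholds are configurable in
`classificationParams()`. A profile satisfying both an A and a B rule
(impossible at the defaults) is labeled A. The same code path serves
gene-level expression profiles, where the increasing branch identifies
progressively induced genes, and `classifyReproducibleContrast()` implements
the stricter two-condition rule (every replicate pair must clear the fold
threshold) used when comparing deletion strains.

## Stage 2: motif modules

Within each class, peptides are partitioned into modules sharing a
phospho-motif by an iterative greedy binomial-enrichment algorithm in the
style of motif-x, with width 13 (positions −6..+6), central residue s* or
t*, minimum 10 occurrences and significance $10^{-6}$
(`motifParams()`). At each step, every free (position, residue) pair is
scored by the upper-tail binomial probability of its foreground count
against the *running* background frequency; the best pair is fixed if
$p \le 10^{-6}$ and count $\ge 10$, non-matching windows are removed from
both foreground and background, and the search repeats. When no pair
qualifies, the matched windows are emitted as a module and extraction
restarts on the remainder against the full background.

Numerical and procedural choices:

* The inner test is the one-sided binomial tail (`stats::pbinom`); ties on
  p-value break by larger count, then smaller $|$position$|$, then
  alphabetical residue, making builds deterministic.
* Background frequencies are recomputed after every fixation (running
  conditional background) rather than frozen at the start.
* Terminal-padding characters (`-`) never count as occurrences and are
  excluded from the trial count at their position.
* S- and T-centered windows are processed separately; Y support is a
  parameter.
* The background is every proteome window centered on a central residue
  (`backgroundWindows()`); whether to condition it per class is left to the
  caller by passing a different background to `motifxPartition()`.

## Stage 3: shared interactors

For each module, every network protein outside the module is tested for
interacting with more module constituents than expected by chance: an
upper-tail hypergeometric test with population = all network proteins
except the candidate, successes = module proteins present in the network,
draws = the candidate's distinct partners (any edge type or direction).
Benjamini–Hochberg correction is applied jointly across all (candidate,
module) pairs within a class, and candidates need $q < 0.05$ and at least 2
module partners. The candidate-exclusion, the per-class BH family and the
minimum overlap of 2 are design choices (`enrichmentParams()`): a protein
cannot be its own partner, a joint family is the conservative reading when
the correction scope is unstated, and a single shared edge can never be
"more than expected" in a stable way.

Directionality then narrows candidates to known kinases/phosphatases whose
directed edges with the module point predominantly *toward* members
(`toward_fraction >= 0.5`) or whose module edges are all undirected.

`enrichAnnotation()` exposes the same hypergeometric/BH machinery for
GO-term or TF-target sets.

## Stage 4: specificity matching

Kinase spot-array intensities (20 amino acids × positions, typically −5..+4
around the acceptor) become position weight matrices by per-column
pseudocount-and-normalize (default pseudocount 0.01, removing zeros);
module PWMs are built from all member windows with pad-aware counts. Match
quality is the Kullback–Leibler divergence in bits,

$$D(\text{module} \,\|\, \text{kinase}) = \sum_{j}\sum_{a}
  p_{ja} \log_2 \frac{p_{ja}}{q_{ja}},$$

computed over the position intersection of the two matrices, center
excluded (a fixed S/T carries no information). The direction — module as
$p$, pseudocounted kinase as strictly positive reference $q$ — means module
zeros are harmless and no division by zero can occur; the base only scales
scores, never rankings or FDRs.

Significance is an empirical FDR: each library PWM is shuffled 1000 times
(values permuted within each column, then column order permuted — a
permutation, not a re-draw, so columns remain stochastic without
renormalization), every shuffle is scored against the module PWM, and the
null is pooled across the whole library (null size = 1000 × library size;
with a 63-entry library this yields 63,000 null scores per module). The FDR
is the fraction of null scores *strictly* smaller (better) than the
observed score, so ties do not count against a match. Matches need FDR <
0.05. Phosphatases have no spot-array specificities, so they are retained
on interaction and directionality evidence alone; `assembleNetwork()`
applies the match requirement only to regulators present in the library.

## The synthetic benchmark

`generateScenario()` emits a complete, internally consistent bundle whose
defaults are the package's reference benchmark: 4 planted kinases × 40
substrate peptides, 400 decoy peptides, an 800-protein network with
undirected background edges at probability 0.01 plus directed
kinase→substrate edges, kinase PWMs drawn column-wise from a symmetric
Dirichlet with concentration 0.05 (sharp, near-point-mass motifs), 3
strains × 2 replicates, a log2 step of 1.0 between consecutive strains and
replicate noise of 0.2 log2 units. Two replicates mirror the practical
limits of TMT phosphoproteomics; the class step of 1.0 with noise 0.2 makes
classification accurate but not trivial (roughly 2% of steps fall under
the 0.585 threshold by chance).

Choices the generator makes where the data model is open:

* **Classes are assigned per kinase** (largest-remainder apportionment of
  `plantedClassMix` over kinases), not per peptide: a regulator drives one
  coherent response, and this keeps the module structure the inference
  assumes. Each kinase also has a fixed acceptor residue (alternating S/T),
  as kinase specificity dictates in reality.
* Substrate proteins carry a single peptide each, at a fixed interior site
  (position 31 of 61), avoiding multi-site ambiguity and window padding.
* Intensity libraries are emitted on a 0–100 scale so intensity
  normalization is exercised non-trivially.

What the generator does **not** emulate: missing values, multi-site
proteins, correlated replicate noise, non-uniform proteome composition,
overlapping kinase specificities, and identification error. Passing the
planted-recovery benchmark therefore shows the chain of inference is
implemented correctly and calibrated under its own assumptions — not that
it will reach the same sensitivity on real phosphoproteomes, where motif
overlap and network incompleteness are the dominant difficulties.

## Calibration and verification

The test suite checks, among others:

* the hypergeometric tail against exhaustive enumeration of all draws for
  every instance with population ≤ 12 (difference < 1e-12), and worked
  arithmetic identities against independent brute-force oracles;
* KLD non-negativity and zero-iff-equal on 1000 random PWM pairs;
* null calibration — background-sampled module PWMs matched against a
  sharp 10-kinase library reach FDR < 0.05 in ≤ 10% of cases, and
  shared-interactor q-values on unstructured 120-node networks reject at
  ≈ the nominal rate (200 modules and 100 network scenarios; sizes chosen
  to keep the default test run fast while leaving Monte-Carlo error well
  below the margins tested);
* end-to-end planted recovery: in ≥ 8 of 10 seeds of the reference
  benchmark, at least 3 of 4 planted kinases are reported as regulators of
  their planted modules with at most one false kinase edge;
* byte-identical outputs for identical configuration and seed.

## Degenerate inputs and edge behavior

Empty peptide tables parse to empty sets with a warning; self-loop edges
are dropped with a warning; duplicate intensity cells are an *error*
(silent averaging could mask a malformed library); an all-pad PWM column or
an empty motif background is an error naming the offender; modules whose
proteins all fall outside the network are skipped with a warning;
candidates without a library entry are reported unmatched rather than
silently dropped. All output tables are sorted deterministically and floats
rendered at 6 significant digits so golden-file comparisons are stable; a
single master seed is fanned out to per-stage substreams.

## Known limitations

* The motif extractor implements the stated parameterization only, not the
  multiple-testing correction variants of the original program.
* The hypergeometric "interact" relation counts directed kinase–substrate
  edges as interactions; with networks whose directed edges mean something
  else, prefilter the edge list.
* With two replicates the classifier is a threshold rule, not a test; its
  false-call rate scales directly with replicate noise.
* The empirical FDR has resolution 1/null-size; with small libraries use
  more shuffles.
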