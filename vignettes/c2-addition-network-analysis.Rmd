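---
title: "Untargeted analysis of C2-addition chemistry by mass-difference networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted analysis of C2-addition chemistry by mass-difference networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c2netms)
```

## The problem this package addresses

Abiotic reaction mixtures evolving from simple gases (acetylene, carbon
monoxide) over a metal-sulfide catalyst produce thousands of organic
products within days. Direct-infusion FT-ICR mass spectrometry resolves
these mixtures into exact-mass peak lists, but turning peak lists into
chemistry requires several inference steps: assigning an elemental
composition (CcHhOoSs) to each mass, deciding how many carbons of each
compound derive from CO rather than acetylene (via stable-isotope
labelling), grouping compositions into compound classes, and following
each compound's intensity through time. `c2netms` implements that chain of
inference as a reusable, tested pipeline, together with a synthetic-data
generator that emulates the C2-addition chemistry closely enough that
every stage can be validated against a known ground truth.

## The analysis model

### Formula assignment by mass-difference networks

At FT-ICR accuracy (a few tenths of a ppm) the mass differences of known
reactions are themselves exact quantities. Six reactions plausible in an
acetylene/CO/H2O/NiS system serve as edges:

```{r}
transformations()[c("name", "formula", "delta_mass")]
```

Assignment starts from a small set of seed peaks whose composition is
unambiguous (by exhaustive enumeration within element bounds at the
working tolerance) and propagates breadth-first: if peak A is assigned
composition X, a peak within tolerance of the ion m/z of X +/- one
reaction delta receives the shifted composition. Three properties of the
implementation matter numerically:

* Predicted m/z values are always recomputed from the *composition*, never
  chained from the observed m/z, so mass errors do not accumulate along
  propagation paths; each assignment's `error_ppm` is its own peak's error.
* Conflicts resolve by smaller absolute mass error, then fewer heteroatoms,
  then the lexicographic formula string — a strict total order, so the
  fixed point is unique and reproducible regardless of queue order.
* The default tolerance is 0.5 ppm, typical of internally recalibrated
  broadband FT-ICR spectra; it is configurable everywhere.

A brute-force enumeration (`brute_force_assign()`) over c <= 40, o <= 10,
s <= 5 with the hydrogen count solved from the mass residual serves as an
independent oracle: on noiseless synthetic data the network assignment
must agree with the enumeration's top candidate essentially everywhere
(the test suite requires >= 99% agreement). Peaks detected at two or more
timepoints that the network cannot reach can optionally be rescued by a
unique enumeration hit at a tighter tolerance (0.3 ppm); such annotations
are tagged `source = "brute-force"`.

Annotations must satisfy H/C in [0.5, 2.5] (closed interval) and
O/C < 1.5 (strict), applied both during propagation and as a final filter.

### Replicate consensus and feature alignment

Technical triplicates are aligned by single-linkage grouping on sorted m/z
within the working tolerance; a group is retained when present in *more
than* 66% of replicates, so 2 of 3 (66.7%) passes. Group m/z is the
median, intensity the mean over contributing replicates. Consensus lists
from all timepoints are aligned the same way into features carrying a
per-timepoint intensity vector.

Before assignment, features sitting exactly one 13C shift (+1.00336 u)
above a co-detected feature of more than twice their intensity, or one
34S shift (+1.99580 u) above one of more than three times their
intensity, are flagged as isotopologue satellites and excluded — they are
measurements of an already-counted compound, not new compounds. The
spacing test cannot collide with real compound pairs: the closest
elemental spacing (H2 at 2.01565 u vs 34S at 1.99580 u) differs by
0.02 u, orders of magnitude above the matching window.

Two further peak-level filters reconstruct unpublished in-house artifact
filters: `remove_34s_isotopes()` (satellites at +1.99580 u whose relative
intensity is compatible with natural 34S abundance, 4.21% per sulfur) and
`remove_wiggle_artifacts()` (faint satellites within 0.01 u of a dominant
peak). Both are heuristic reconstructions, disabled by default, and log
every removal for audit; the pipeline's isotopologue flagging makes the
34S filter redundant on synthetic data.

### Labelling-degree classification

Comparing the unlabeled channel with a 13CO-labelled (or
13C-acetylene-labelled) channel reveals how many carbons of each
composition derive from each gas. For degree k the classifier looks up
the labelled-channel intensity at the annotation's monoisotopic m/z plus
k x 1.00336 u and calls the degree when that intensity — relative to the
unlabeled channel's monoisotopic peak after total-intensity normalization
— is at least *twice* the expected natural-abundance signal ("surpassing
natural 13C by 100%").

The expected natural signal is the per-carbon convention `p x c` with
p = 0.01: linear in the carbon count and independent of the degree. This
choice has a practical property worth spelling out: a genuinely labelled
isotopologue carries its own natural M+1 satellite (relative intensity
~ 0.011 x (c - k)) one shift above the labelled peak, and an enrichment
residual one shift below. Both sit well below `2 x 0.01 x c`, so the
linear threshold absorbs them. A binomial expectation
(`choose(c, k) p^k (1-p)^(c-k)`), the naively more accurate model for
k >= 2, is so small that those satellites would be systematically
miscalled as additional degrees; it is available via
`threshold_rule = "binomial"` and is then combined with an
isotopologue-aware correction that adds the satellites implied by already
called lower degrees to the expectation. The default is the linear rule.

Degree 0 ("unlabeled even in the labelled channel") is called when the
unshifted monoisotopic peak survives in the labelled channel above twice
the residual-unlabeled expectation (default 0.01, matching the assumed
99% isotopic purity of the labelled gas).

Two open conventions are resolved as follows and are configurable: the
intensity reference is the unlabeled channel's monoisotopic peak (not the
total ion current), and each composition is classified at the timepoint
where its unlabeled intensity is maximal rather than only at the final
timepoint — early-peaking compounds (notably sulfur-rich ones) are
otherwise already gone from the last sample. Compositions called at two
or more degrees are *mixed* annotations: co-eluting isomers with
different synthesis histories. Compositions whose CO-degree k and
acetylene-degree k' satisfy k + k' = c are flagged as closed over the two
carbon sources (`cross_channel_check()`).

### Compound classes

Annotations partition exhaustively by their (O, S) heteroatom counts,
ignoring sodium (adducts are evidence attached to the neutral
composition). Within a subspace the mean H/C ratio per labelling degree
summarizes saturation; mixed annotations contribute to every degree they
carry. In the O4 subspace, degree-2 annotations with an [M-2H+Na]-
companion peak are dicarboxylic-acid candidates (a doubly deprotonated
species can retain Na+ and stay singly charged); degree-2 without
adduct are hydroxy-keto candidates, degree-1 dihydroxy-acid candidates,
degree-3 diketo-acid candidates; a degree-1 annotation with an adduct
contradicts the logic and is flagged. These labels are candidates, not
identifications: exact mass cannot place functional groups.
C2-homologous series — maximal chains of compositions differing by
repeated C2H2 within one labelling degree — are detected by following
unique predecessor/successor links, so each composition belongs to at
most one maximal chain per degree.

### Molecular network and temporal statistics

The network's nodes are the unique neutral annotated compositions; an
undirected edge joins two nodes when their element-wise difference equals
one of the six deltas *exactly* — matching on composition, not on an m/z
window, so isobars can never be joined. The connectivity fraction is the
percentage of nodes with at least one edge. Per-timepoint sulfur-class
shares (percentage of S-containing annotations per sulfur count) and
oxygen-class shares quantify how the sulfur-rich early population gives
way to sulfur-poor later compounds.

### SOM clustering of temporal profiles

Each annotation's per-timepoint intensity vector is min-max scaled to
[0, 1] (constant vectors map to zero) and clustered by a classic online
self-organizing map on a 2 x 4 rectangular grid: Euclidean best-matching
unit, Gaussian neighborhood, learning rate 0.1, 50,000 iterations, one
random profile per iteration. Parameters the method statement leaves
open are fixed as: initial neighborhood radius sigma = 1.0 decaying
linearly to 0.01, learning rate decaying linearly to 0.01, weights
initialized uniformly in the unit cube from the run seed. Each grid unit
is one cluster ("node = cluster"); a cluster's peak time is the timepoint
at which its mean member profile is maximal, ties resolving to the
earliest timepoint. Training is deterministic given the seed. Note that
an online SOM's result necessarily depends on the order in which profiles
are drawn; reproducibility therefore comes from the seeded sampling
stream, not from order-invariance of the algorithm.

## The synthetic-data generator

The generator provides ground truth with the statistical structure the
analysis assumes. What it emulates, and the defaults chosen as the study
conditions:

* **Growth chemistry.** Molecules grow from seed compositions
  (acetaldehyde C2H4O, acrylic acid C3H4O2, thioacetic acid C2H4OS) by
  the six reactions, each applied per generation with configurable
  probability (defaults 0.5 for C2H2 addition, 0.3 for carbonylation with
  H2O, 0.2 for the others) over 5 generations. Every reaction except the
  C2H2 addition adds across a double or triple bond, so the generator
  gates them on at least one ring-or-double-bond equivalent
  (DBE = c - h/2 + 1 >= 1) in the substrate; the C2H2 addition brings its
  own unsaturation. This keeps the population unsaturated, as an
  acetylene-fed system is.
* **Label bookkeeping.** Each carbonylation adds one CO-derived carbon;
  the 13CO channel renders the molecule with that many 13C substitutions
  (at 99% isotopic purity, binomially), the 13C-acetylene channel with
  the complementary count. Within the six-reaction space the CO-carbon
  count is essentially determined by the composition (every delta carries
  exactly two hydrogens, which pins the total step count), so mixed label
  degrees are injected explicitly: a configurable fraction of
  compositions (default 10%) receives a second molecule with the CO-count
  shifted by one, standing for isomers formed through reactions outside
  the core six-edge set. `feasible_co_counts()` documents the underlying
  multiset arithmetic.
* **Temporal structure.** Peak times follow the sulfur count (0, 1, 2,
  >= 3 sulfur map to 168, 72, 24, 2 h), with a configurable jitter
  probability (default 0.15) of moving one step on the grid — sulfur-rich
  compounds appear early and fade. Intensities follow a log-normal
  amplitude (median 2000) times a Gaussian-in-log-time kernel (width 0.8
  log-units) around the peak time, so every profile is unimodal.
* **Measurement physics.** Natural M+1 13C satellites (1.1% per carbon),
  natural 34S satellites (4.21% per sulfur), [M-2H+Na]- adducts for
  dicarboxylic molecules (30% of the main intensity), Gaussian m/z error
  (0.2 ppm sd), per-replicate peak dropout (5%), and 30 noise peaks per
  spectrum, half of them persistent contaminants recurring across the
  replicates of a timepoint. Signal-to-noise is intensity over a fixed
  noise floor (50), so the median true peak enters at s/n ~ 40 and most
  noise falls below the s/n >= 4 threshold, while a minority survives to
  exercise false-positive handling.

What it does **not** emulate — and hence what passing tests cannot show
about real data: peak shape and resolution (peaks are points, not
profiles), space-charge and calibration drift (mass error is i.i.d.
Gaussian; `recalibrate()` exists but the generator does not produce
systematic drift by default), isotopologue overlap between distinct
compounds, ion suppression, chemical kinetics (the temporal kernel is
phenomenological), charge states other than -1, and chemistry outside
the six-reaction edge set plus the injected isomer variants.

## Evaluation conventions

`evaluate_recovery()` scores a run against its ground truth. Formula
matching is exact composition equality. Recall is reported over the
*observable* truth (molecules whose deprotonated ion falls inside the
configured mass window) and additionally over the observable truth inside
the H/C–O/C annotation window (`formula_recall_admissible`): a molecule
whose true composition violates the mandated ratio filters — chemically
real, e.g. small saturated polyols — cannot be annotated by this method
by construction. Label accuracy is the fraction of annotated truth
molecules whose CO-carbon count appears among the called degrees. The
noise false-annotation rate is the fraction of features matching no
rendered true m/z that nevertheless received a formula. On the default
conditions the test suite requires recall and label accuracy >= 0.95 and
a noise false-annotation rate <= 0.05; on noiseless data it requires
exact network/oracle agreement (>= 99%) and 100% network connectivity,
which holds by construction because every non-seed molecule differs from
its parent by one reaction delta.

Two property scenarios widen the mass window to 40–1000 u instead of the
default 122–1000 u: connectivity closure and oracle equivalence are
statements about the generator–annotation pair as a whole, and the
default window would cut the seed molecules and first-generation products
out of the observable set, truncating lineages for reasons unrelated to
the property under test.

## Problem sizes and runtime

The default configuration simulates roughly 150–250 molecules (about 500
consensus features per channel), which a full pipeline run — 54 rendered
spectra, consensus, assignment, labelling, network, and a 50,000-iteration
SOM — processes in well under a minute on one core. The SOM cardinality
check uses 320 synthetic profiles (40 per archetype); within-archetype
variation in peak position and width makes the profile family a
two-dimensional manifold, which is what a 2 x 4 map needs to occupy all
units reliably. These sizes were chosen so the entire test suite and the
acceptance script complete in a few minutes while keeping every estimate
comfortably away from small-sample artifacts.

## Known limitations

* The two in-house artifact filters are reconstructions from a one-line
  description; their parameters are exposed and their action logged, but
  they should be re-tuned against real instrument data before use.
* The seed-selection rule (unique enumeration hit below 200 u) assumes
  the low-mass region contains confidently assignable peaks; very sparse
  or high-mass-only data would need user-supplied seeds.
* The linear labelling threshold grows with the carbon count; for c > 40
  it would exceed a 50/50 isomer split and mixed annotations of very
  large compounds would be under-called.
* Class labels (dicarboxylic, hydroxy-keto, ...) are candidates
  constrained by label degree and adduct behavior, not structural
  identifications.
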