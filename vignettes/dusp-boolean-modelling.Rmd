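---
title: "Methods: Boolean modelling of DUSP regulation under Herceptin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Boolean modelling of DUSP regulation under Herceptin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duspboolnet)
```

## The biological question

HER2-positive breast cancer cells signal through the MAP kinases ERK, JNK
and p38. Dual-specificity phosphatases (DUSPs) dephosphorylate the TXY
motif of these kinases, closing negative-feedback loops: a kinase induces
transcription of a DUSP, which in turn inactivates the kinase. Herceptin
(trastuzumab) blocks HER2 dimerization and cuts the upstream drive. This
package asks, qualitatively: given what is known about which kinases
induce each DUSP and which kinases each DUSP dephosphorylates, what
expression dynamics should a DUSP show in the first 24 h of Herceptin
exposure — and, for DUSPs whose inducing kinase is unknown, which induction
hypothesis best explains the measured dynamics?

Everything is modelled with Boolean logic: each node (receptor, kinase,
phosphatase, survival readout) is ON (1) or OFF (0), and all reactions
share one arbitrary time unit. This is deliberately coarse — it captures
the order of qualitative events (decays, pulses, oscillations), not rate
constants, and it is the right resolution for comparing against
five-point qPCR time courses.

## The Boolean engine

Models are plain text, one rule per line (`ERK* = (HER2 or Basal) and not
DUSP2`), with `#input:` directives for clamped nodes and `Name =
True/False` lines for initial values. Parsing translates `and`/`or`/`not`
into R's logical operators and evaluates rules with base R, so operator
precedence is the standard NOT > AND > OR.

Synchronous updating (all nodes recomputed at once) is canonical;
asynchronous updating (one uniformly chosen non-input node per step,
seeded) is a confirmation mode. The synchronous successor map is
deterministic, so every trajectory eventually repeats a state; for `k`
free nodes this happens within `2^k + 1` steps. `find_attractor()` runs
until the first repeat and splits the run into transient and cycle;
its correctness is tested against an independent oracle that tabulates
the full `2^k`-state transition graph.

Long-run behaviour of a node is summarized as one of five pattern
classes. A node is `OSCILLATING` iff it is non-constant within the cycle,
`CONSTANT_ON`/`CONSTANT_OFF` iff it holds one value through transient and
cycle, and otherwise `ON_THEN_OFF`/`OFF_THEN_ON` by the constant value it
settles to in the cycle versus the state it occupied during the
transient. (We deliberately classify by "attains 1, settles at 0" rather
than "starts at 1", so that a node pulsing ON during the transient before
settling OFF still gets a label; for all shipped models the two readings
agree.) Because classification reads the attractor, it is invariant to
simulating any number of extra steps.

## The DUSP model scaffold

The full signalling maps behind the published figures are not available
as machine-readable models, so the package reconstructs a minimal
scaffold from the textual regulation statements. One scaffold rule set
serves every DUSP:

* `HER2* = not Herceptin` — receptor blockade.
* Substrate kinases: `K* = (HER2 or Basal) and not DUSP`. `Basal` is a
  clamped, Herceptin-insensitive drive; it is the minimal addition that
  keeps the DUSP negative-feedback loop engaged after HER2 shuts down,
  which is what produces the reported oscillations. Non-substrate
  kinases follow HER2 alone (`K* = HER2`) and therefore decay under
  treatment.
* `DUSP* = OR of its inducers` — induction statements never assert joint
  (AND) action, and the convention reserves AND for explicitly collective
  regulation.
* `Survival* = ERK or not (JNK and p38)` — proliferative ERK signalling
  sustains survival, and simultaneous activity of both stress kinases
  triggers apoptosis. A pure apoptosis gate (`not (JNK and p38)`) was
  considered first, but in the three-substrate models (DUSP3, DUSP23) the
  basal-driven JNK and p38 oscillate in phase and the pure gate would make
  Survival oscillate, contradicting the reported constant-ON survival in
  every model except DUSP16. Adding the ERK disjunct reproduces all
  reported outcomes and is biologically standard (basal MAPK activity is
  proliferative).

The default initial condition is the pre-treatment steady state: ERK ON,
JNK and p38 OFF (held in check by DUSPs before treatment — this is
precisely why cancer cells evade apoptosis), the DUSP ON, Survival ON,
and HER2 already at `1 - Herceptin`: antibody-receptor binding is fast
compared with the transcription-scale Boolean step, so the receptor is
treated as blocked from the first instant of a treated simulation. An
all-kinases-ON start would pulse JNK and p38 together and force a
spurious transient apoptosis signal in every model. The initial state is
exposed in full (`initial_state()`, overrides per node), so other
conventions are one argument away.

With this scaffold and Herceptin clamped ON, the shipped models reproduce
every reported outcome, which is asserted by the test suite:

```{r outcomes, eval = FALSE}
do.call(rbind, lapply(regulation_facts_table()$dusp, check_expected_outcomes))
```

DUSP2, DUSP4 and DUSP5 oscillate with period 4 (the canonical two-node
negative-feedback limit cycle), DUSP1 stays on briefly and then decays,
and in the DUSP16 model the loss of the phosphatase releases both stress
kinases, so Survival switches OFF after a finite transient — the one model
in which the drug's effect reaches the apoptosis gate.

## qPCR processing

Threshold-cycle tables (gene x time x 2 biological x 3 technical
replicates) are processed with the standard efficiency-2 ΔΔCT method. Per
replicate, ΔCT = CT(gene) − mean CT of the two reference genes (Actinb,
GAPDH) measured in the same well set; ΔΔCT subtracts the mean control
(t = 0) ΔCT; fold change is `2^-ΔΔCT`. Two conventions matter:

* ΔΔCT is computed per replicate and then aggregated — not on averaged
  CTs — so replicate dispersion propagates into a standard error.
* The series-level fold change is `2^(-mean ΔΔCT)` (the geometric mean on
  the expression scale, standard for ratio-scale data); this makes the
  control time point exactly 1 by construction. The reported `se` is the
  standard error of the per-replicate fold changes.

Significance against the control uses a two-sided Welch t-test on the
per-replicate ΔCT values, flagged at α = 0.05 with no multiple-testing
correction (matching per-gene asterisk-style reporting; a limitation, not
a recommendation). Degenerate zero-variance comparisons return p = 1 when
the means agree, p = 0 otherwise. Because ΔΔCT differences cancel any
constant CT offset, plate-level shifts leave fold changes untouched — a
property the suite asserts.

## Correlation clustering

Expression time courses are compared as Pearson correlations of their
log10 fold changes (so per-gene multiplicative rescaling is irrelevant),
with negative correlations clipped to zero — clusters are meant to contain
only positively co-varying genes. Each gene's feature vector is its row
of the clipped correlation matrix; genes are agglomerated with average
linkage on euclidean distances and the tree is cut at a height exposed in
configuration. Constant series have undefined correlation and are
recorded as 0 with a warning. Genes that remain singletons at the cut are
reported `UNCLUSTERED`.

The default cut height of 0.5 was calibrated once on the default
synthetic fixture: across seeds the within-template merges complete below
about 0.3 and distinct templates merge above about 0.6, so 0.5 sits in
the gap and recovers the planted seven clusters plus six singletons
(adjusted Rand index ≈ 0.95-0.99 over 20 seeds). With real data the cut
is a user decision informed by the dendrogram.

Cluster dynamics are summarized as direction-symbol strings: the sign of
each consecutive difference of the cluster-mean log10 fold change, with a
dead band |Δlog10| < 0.05 reading as `0` to suppress replicate wobble.
These strings are the interface between the experimental data and the
Boolean models.

## Inducer inference

For DUSP3, DUSP9, DUSP16 and DUSP23 the substrate specificity is known
but the inducing kinase is not. `infer_regulators()` enumerates all seven
non-empty OR-combined subsets of {ERK, JNK, p38}, builds and simulates
each model variant under Herceptin, extracts the DUSP node's symbol
string over transient plus one cycle, and scores agreement with the
experimental string as `1 − normalized Levenshtein distance`, plus a
bonus of 0.1 (capped at 1) when the simulated pattern class is compatible
with the experimental string (e.g. an oscillating class against a string
containing both `+` and `-`). Edit distance on symbol strings is used
because Boolean time units are arbitrary: only the order of qualitative
events can be compared, not their clock positions.

Where the scaffold treats JNK and p38 identically (true for all four
targets), swapping the two labels yields an isomorphic network, so
hypotheses related by the swap are merged into one symmetry class and
necessarily share a score (asserted exactly, not approximately). Classes
with equal scores share a rank; ties are reported jointly and never
broken arbitrarily. This matters because the minimal scaffold makes some
non-equivalent hypotheses genuinely indistinguishable — in the DUSP9 model
(substrate: ERK only) JNK and p38 have no persistent drive and sit at
OFF, so {JNK}, {p38} and {JNK, p38} produce bitwise-identical dynamics.
Reporting such degeneracy honestly is more informative than forcing an
order.

The closed-loop property the suite enforces is self-consistency: for
every target DUSP and every planted inducer subset, generating the
"experimental" string from the planted model and running inference ranks
the planted hypothesis's symmetry class first (28/28), with score exactly
1 for the planted hypothesis itself.

A known limitation: with this minimal scaffold, oscillating or late-rise
experimental patterns top-rank the ERK-containing classes for DUSP9,
DUSP23 and DUSP3, because only the ERK loop can oscillate when ERK is the
kinase carrying the basal drive. Published model-based predictions that
those DUSPs are JNK-induced relied on richer map topologies that exist
only as figures and cannot be reconstructed from text; the package
reproduces the stated qualitative behaviours (survival readouts, pattern
classes, JNK/p38 symmetry) and the ERK prediction for DUSP16, but makes
no claim to reproduce the JNK predictions, and the inference report
should be read accordingly.

## The synthetic data generator

No raw qPCR measurements are deposited with the study — expression values
exist only in figures — so the generator emulates the study design for
end-to-end testing: 21 DUSP genes at 0/2/4/12/24 h, two biological
repeats in triplicate, dual reference genes. Each of the seven planted
clusters follows a log2 fold-change template transcribing the verbal
cluster shapes (e.g. cluster 1: dip, sharp rise to a 12 h peak, drop);
template amplitudes are design parameters of this package, not measured
values. Six further genes get singleton templates and are planted
UNCLUSTERED. CTs are assembled as reference baseline + per-gene
expression offset − log2 fold change + Gaussian cycle noise (default sd
0.15 cycles, typical qPCR technical noise), with a per-gene template
jitter (sd 0.1 log2 units) providing within-cluster biological
variation. The planted truth (assignment and realized fold changes) is
returned as a separate artifact and never written into the CT table.

What passing tests on these data do and do not show: they verify that
the pipeline's arithmetic and clustering recover a planted structure of
realistic shape and noise scale; they cannot validate the published
cluster memberships, amplification-efficiency effects, plate layouts, or
any feature of the real measurements the generator does not model.

## Problem sizes and numerical choices

The default test and acceptance workloads are sized for a desk run:
networks of up to 8 free nodes against the exhaustive `2^k` oracle (100
random networks), 20 generator seeds for clustering recovery, and the
full 4 x 7 planted-inducer grid for inference — each suite completes in
seconds. Attractor detection is exact, not heuristic; the only tolerances
in the package are the pattern dead band (0.05 log10 units), the α = 0.05
significance level, and machine-precision comparisons in the noise-free
round trip. Tie-breaks are never random: hypothesis enumeration is
ordered (size, then ERK < JNK < p38), cluster ids follow first gene
appearance, and tied inference ranks are shared.
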