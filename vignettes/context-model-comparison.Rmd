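---
title: "Comparing condition-specific metabolic models by flux-range similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing condition-specific metabolic models by flux-range similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the pipeline answers

Two groups of cell lines — say, patient-derived and control — are profiled
by RNA-seq. Which parts of metabolism do the two groups *use* differently?
Expression alone answers which genes differ; a genome-scale metabolic
model (GEM) lets one ask the sharper question of which *reactions and
pathways* remain operable in each group, and how much flux each pathway
could carry. This package implements that comparison as a reusable
pipeline:

1. turn each cell line's TPM table into expressed/unexpressed gene calls;
2. extract, for each cell line, the subnetwork of a reference GEM that is
   flux-consistent and contains every reaction whose gene-protein-reaction
   (GPR) rule is expressed, under a fixed growth medium;
3. compare the condition groups structurally — which genes, reactions and
   metabolites are shared within a condition and absent from the other —
   and attribute the differences to pathway subsystems;
4. compare the groups functionally: flux variability analysis (FVA) under
   an ATP-demand objective, summarised per subsystem by a flux-range
   similarity index (SI).

```{r, eval = FALSE}
library(fluxcsm)
report <- run_demo("demo_out", seed = 1)
report$results$similarity
```

## Models and calls

A `metabolic_model` is a stoichiometric matrix $S$ (metabolites x
reactions), flux bounds $l \le v \le u$ in mmol/gDW/h, GPR rules, and
subsystem labels. Reversibility lives purely in the bounds; missing or
infinite bounds canonicalise to $\pm 1000$, the COBRA convention. A
reaction with exactly one nonzero stoichiometric entry is an exchange:
negative flux imports the metabolite, positive flux exports it. Media are
applied only to exchanges: listed metabolites get their uptake bound, all
other uptakes close, secretion stays free — so applying the same medium
twice is a no-op. Subsystem labels are read from SBML groups first, then
from a `SUBSYSTEM:` note, because public reconstructions vary in where
they store them.

Expression preparation follows a fixed order per cell line: drop genes
whose TPM is zero in *all* of that line's technical replicates, take the
replicate median (midpoint for even counts), collapse transcript isoforms
to their gene by keeping the isoform with the highest median (ties to the
lexicographically smallest transcript id, so runs are reproducible), and
discretize. The zero-filter is applied per cell line, not across the
whole table: a gene silent in one line but active in another should count
as measured-and-absent only where it is silent.

Discretization is deliberately simple and explicit, rather than a
re-implementation of any published tool's internals. The default calls a
gene expressed iff its TPM reaches the 50th percentile of the line's
*nonzero* values — a rank rule that is monotone (raising a gene's
expression can never turn it off) and insensitive to the arbitrary TPM
scale. A two-component Gaussian mixture on log2(TPM+1) of the nonzero
values is available (`method = "mixture"`), fit with `mclust`, whose
hierarchical initialisation makes it deterministic; a degenerate fit
falls back to the percentile rule with a warning. Zero-TPM genes are
always unexpressed. Genes in the model but absent from the call set
evaluate to *unknown* in GPRs — three-valued logic with
unexpressed < unknown < expressed, AND = min, OR = max — so an unmeasured
gene neither forces a reaction into the core nor pushes it out.

## Context extraction

The core is the set of reactions whose GPR evaluates to expressed. The
extraction must return a subnetwork that (i) contains the whole core,
(ii) is flux-consistent — every retained reaction can carry a flux of at
least `tol` (default 1e-4) in some steady state of the retained
subnetwork — and (iii) adds as few non-core reactions as possible. This
is the FASTCORE family of algorithms: a consistency sweep first
(support-maximising LPs with direction flipping for reversible reactions,
the FASTCC scheme, cross-checked in the tests against exhaustive
per-reaction LPs), then the two-phase search that alternates an LP
activating the unsatisfied core with an L1-penalised LP that minimises
flux through non-core reactions.

Two numerical choices matter here. First, the support threshold: a
reaction counts as active when its flux magnitude reaches 0.99 x `tol`.
Second, the union of L1-sparse supports can, on unusual topologies, omit
a carrier whose flux in a mode fell below that threshold, leaving a
retained set that is not self-consistent. The extractor therefore
verifies its own output with per-reaction LPs and repairs it
deterministically: blocked non-core reactions are dropped, a blocked core
reaction is re-supported by the full support of a witness flux vector,
and if the tug-of-war does not settle within a bounded number of rounds
the whole consistent subnetwork — always valid, merely non-minimal — is
returned. On the package's reference networks the first check passes and
the repair is a no-op; the exhaustive-minimum tests confirm that the
retained set is cardinality-minimal there.

All linear programs run on the package's own bounded-variable two-phase
simplex (`lp_solve`), with Dantzig pricing, a Bland's-rule fallback
against cycling, and deterministic index-order tie-breaking — the whole
pipeline is reproducible bit for bit given a seed. The test suite
cross-checks the solver against an independent interior-point/simplex
implementation (HiGHS, through Python's scipy) on hundreds of flux LPs.

The per-line builder (`build_condition_model`) orchestrates media,
consistency, GPR evaluation and extraction, and accepts a protected
reaction list that is always added to the core; the pipeline protects the
objective (the ATP demand) by default, since a demand without a GPR would
otherwise be non-core and could be pruned away, leaving nothing to
optimise.

## Structural comparison

Within a condition, the shared set is the intersection across its models
(per element kind: genes in retained GPRs, retained reactions, touched
metabolites). For uniqueness two comparison modes exist because "absent
from the other condition" is genuinely ambiguous when an element sits in
some but not all models of the other group:

* `vs-union` (default): unique means absent from *every* model of the
  other condition;
* `vs-shared`: the literal set difference of the two shared sets.

`vs-union` unique sets are provably contained in `vs-shared` ones; both
are exposed, the default follows the stricter reading. Unique reactions
of the two conditions are pooled per subsystem and expressed as a
percentage of the subsystem's size in the reference model. Subsystems
qualify for flux analysis when size exceeds 20 reactions *and* more than
20% of their reactions differ — both strict inequalities — with two
amendments: central energy subsystems (glycolysis, pentose phosphate
pathway, citric acid cycle, oxidative phosphorylation in a genome-scale
setting) can be forced in regardless of the thresholds, and subsystems
absent from all models of one condition are excluded, since no
comparison is possible for them. Reactions without a subsystem pool under
`"(unassigned)"`, which never qualifies.

## Flux-range similarity

FVA fixes the objective at a fraction `gamma` of its FBA optimum and
computes, per reaction, the attainable flux interval [vmin, vmax]. For
two models and one shared reaction the similarity index is

$$\mathrm{SI} = \max\!\left(0,\;
  \frac{\min(v^{1}_{max}, v^{2}_{max}) - \max(v^{1}_{min}, v^{2}_{min})
        + \varepsilon}
       {\max(v^{1}_{max}, v^{2}_{max}) - \min(v^{1}_{min}, v^{2}_{min})
        + \varepsilon}\right)$$

— the signed overlap of the two intervals over the width of their union:
1 for identical flux variability, 0 for disjoint ranges. The denominator
is read as the union width, the only reading that keeps SI in [0, 1]
with those endpoint meanings. With $\varepsilon = 0$ (the convention when
only shared reactions are compared) two identical point ranges give 0/0,
defined as 1 by continuity — two reactions pinned to the same flux are
maximally similar. SI is symmetric and invariant to translating both
ranges, and `eps` must be non-negative.

Per subsystem, SI is aggregated as the unweighted mean over shared
reactions (`aggregation = "mean"`); pooling each subsystem's ranges into
one interval per model before comparing (`"pooled"`) is available, since
either convention is defensible and they answer slightly different
questions (typical reaction agreement vs envelope agreement). Subsystems
with no shared reaction report `NA`, never 0: absence of evidence is not
complete mismatch. With two models per group, `group_comparison` emits
the four cross-group pairs, the two within-group pairs, and the
cross-group aggregate = the arithmetic mean of the four cross pairs —
within-group values calibrate how much of the cross-group difference is
ordinary line-to-line variability.

`gamma` defaults to 1 in `fva()` (the common FVA default). The demo
pipeline uses `gamma = 0.9`: at the strict optimum every unit of carbon
is committed to the objective and all side-pathway ranges collapse to
points, so a strict-optimum comparison is vacuous on small networks;
releasing 10% of the budget gives the side pathways non-degenerate
ranges to compare.

## What the synthetic generator emulates — and what it does not

`generate_network` builds a carbon backbone (uptake exchange, transport,
a central reaction yielding `objective_yield` ATP per carbon, an ATP
demand, a waste exchange) plus one branch module per subsystem: a gateway
from cytosolic carbon, a linear chain to waste whose genes can be
silenced, and a small always-on leak (capacity `leak_capacity` = 0.5).
The leak is the deliberate piece of realism: when a subsystem's chain is
silenced, the subsystem loses most of its reactions but keeps a shared,
operable remnant — as partially inactivated pathways do in real context
models — so cross-group SI for that subsystem is low but defined, rather
than the subsystem vanishing from the comparison entirely. Inert
boundary exchanges (blocked, as in real reconstructions) exercise the
consistency sweep.

`generate_expression` draws log-normal TPM: expressed genes around a
high mode (gene baseline log2 ~ N(6, 1), line and replicate noise with
sd `noise_sd` = 0.5), plus as many decoy background genes as model genes
around a low mode (log2 ~ N(-0.5, 0.5)). The decoys make each profile
bimodal the way a transcriptome is — most genes off, metabolic genes on —
which is what gives the 50th-percentile rule and the mixture model a
sensible threshold to find. Silenced genes read exactly 0 with
probability 0.9 per replicate and near 0 otherwise, so the all-zero
filter fires for most, but not all, silenced gene-line pairs, exercising
both removal and unexpressed-call paths. Defaults: two conditions, two
cell lines each, three technical replicates, six subsystems of 4-6
reactions, one silenced subsystem in the second condition.

The generator does *not* model read counts, gene length or library-size
effects, isoform switching (the optional second isoform is an attenuated
copy), regulatory correlation between genes, or growth-media differences
between conditions. Passing the end-to-end tests therefore shows the
pipeline's logic is sound — filtering, calls, extraction, set algebra and
SI behave as specified on data with known truth — not that any particular
discretization will be well-calibrated on real RNA-seq, where the
expressed/unexpressed boundary is much blurrier.

## Numerical and design choices, in one place

* Flux threshold `tol` = 1e-4, LP tolerances 1e-9, support threshold
  0.99 x `tol`: COBRA-scale defaults.
* Default bounds ±1000 mmol/gDW/h; compartment suffixes like `[c]` are
  part of the metabolite identity and survive SBML round trips via
  codepoint-escaped ids.
* Discretization default: percentile, p = 50 on nonzero values; both the
  method and p are configuration.
* Structural mode default `vs-union`; subsystem selection strictly
  greater than size 20 / 20% different; the demo lowers the size gate to
  3 because synthetic subsystems have 4-6 reactions (the gate is a
  genome-scale calibration, not a constant of the method).
* SI: eps = 0, mean aggregation, 0/0 -> 1 by continuity.
* The pipeline compares exactly two conditions; each extra model per
  group adds its pairs automatically. A group with one model loses its
  within-group column, with a note.
* Determinism everywhere: simplex tie-breaks by index, isoform ties by
  transcript id, mixture fit by deterministic initialisation, generator
  under `set.seed` with the caller's RNG state restored.

## Known limitations

* The LP solver is dense and refactorises the basis each iteration —
  right for networks up to a few hundred reactions, not for a raw
  genome-scale model with tens of thousands. The module boundaries would
  admit a sparse solver backend without API changes.
* FVA's optimality constraint `c'v >= gamma * optimum` assumes a
  non-negative optimum (true for demand objectives).
* Exchange reactions are assumed written in export orientation (negative
  coefficient on the boundary metabolite), the near-universal convention.
* `vs-shared` mode can attribute an element to "unique" that is present
  in one model of the other condition; this is the documented literal
  reading, not a bug.
* Extraction minimality is guaranteed only as far as FASTCORE's L1
  heuristic: the tests verify exact cardinality-minimality on the bundled
  reference networks (<= 12 reactions, against exhaustive enumeration),
  not in general — no polynomial algorithm could.

## Problem sizes used by the tests

The suite runs the full pipeline on synthetic networks of ~36 reactions,
23 metabolites and 4 cell lines (seconds per run), exhaustive extraction
oracles on networks of <= 12 reactions, solver cross-checks on hundreds
of random LPs, and 10-seed end-to-end recovery of the planted subsystem.
These sizes keep every oracle exact; nothing in the method is specific
to them.
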