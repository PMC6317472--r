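---
title: "Deconvolving glycan mixtures from lectin and exoglycosidase profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving glycan mixtures from lectin and exoglycosidase profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmapsolve)
```

## The measurement and the model

On-chip glycan modification and probing interrogates the glycans of a
microspotted protein indirectly: parallel arrays are digested with different
exoglycosidase sequences and probed with lectins, and each (treatment,
lectin) pair contributes one channel of a response vector. A single glycan
structure produces a characteristic pattern across channels — its *model
response vector* — and a glycoprotein, carrying a mixture of glycans,
produces approximately a nonnegative superposition of such patterns. The
package's model is that superposition:

$$\min_a \; \lVert C a - d \rVert_2^2 \quad \text{s.t. } a \ge 0,$$

with $C$ the $N \times M$ matrix of model response vectors, $d$ the observed
response vector, and $a$ the relative-abundance weights. Three modelling
layers feed $C$, each with deliberate simplifications:

**Digestion** is simulated by recognition/replace motif substitution. An
enzyme is a pair of glycan-shaped templates; wherever the recognition
template matches (by default anchored at non-reducing termini, since
exoglycosidases act there), the residues present in the recognition but
absent from the replace template are deleted, repeatedly until no site
remains. Digestion is all-or-none to exhaustion — no kinetics, no partial
products. Sites are processed outermost-first in a deterministic order;
since substitutions only prune at the non-reducing side, the fixed point is
unique, and each application is idempotent (both properties are enforced by
tests). A substitution that fails to remove at least one residue raises an
error rather than looping.

**Lectin binding** is predicted from motif binding scores: dimensionless
levels, on the kind of 0–1 scale that emerges from normalized glycan-array
analyses, attached to each motif a lectin binds. Where several of a lectin's
motifs match a structure, the default aggregation takes the *maximum* score:
lectin binding at these assay concentrations is treated as presence-driven
rather than site-additive. This is a genuine design choice; `"sum"` and
`"site_count"` modes are provided for sensitivity analysis, and site-count
aggregation would make binding scale with antenna multiplicity instead.
Matching is exact on residue identity; anomericity and position fields may
be wildcards in the *pattern* only — an unknown linkage stored in a glycan
never satisfies a specific pattern, which keeps enzyme and lectin
specificity conservative.

**Normalization** divides every lectin's block of values by the block
maximum: over all conditions *and all candidate glycans* for the model
matrix, and over the conditions of the sample for an observed vector.
Normalizing the model per lectin jointly over glycans keeps the columns of
$C$ mutually comparable, which is what allows the fitted weights to be read
as relative abundances. Normalizing observed data by the per-sample maximum
is a calibration assumption — it equates the sample's strongest binding per
lectin with the model's — and it is the main approximation incurred when
fitting real fluorescence data; the synthetic benchmark (below) bypasses it
by construction so that solver properties can be tested separately from
calibration error. All-zero blocks are left untouched, and normalization is
idempotent. Negative background-subtracted signals are kept by default
(clamping at zero is opt-in) so that averaging remains unbiased near zero.

## Solver decisions

*Colinearity.* Candidates whose columns are pairwise proportional (cosine
similarity within $10^{-9}$ of 1, or both all-zero) are indistinguishable to
the fit at any weight; each such group is collapsed to the member with the
most residues covered by at least one lectin motif (ties: total residue
count, then id). Only *pairwise proportionality* is removed here — general
linear dependence is deliberately left to the alternative-sampling step,
which is the mechanism that expresses residual ambiguity instead of hiding
it.

*Alternative fits.* Starting from the initial NNLS fit, each initially
predicted glycan (descending initial weight) is excluded and the model
refit on all remaining candidates; a refit is accepted when its $R^2$ is
within 0.05 of the initial fit *and* it uses at most two additional glycans
outside the initial predicted set. Accepted fits are recursed into along the
exclusion path, with the recursion depth capped at the size of the initial
predicted set and a global budget of 100 refits per initially predicted
glycan. The exploration is a deterministic depth-first search with each
exclusion set evaluated at most once, so results are reproducible without a
seed; the budget makes sampling grow proportionally with model complexity.
Refits may introduce candidates with zero initial weight — that is what
"additional glycans" means — and the initial fit itself does not count
against the budget.

*Reporting.* A glycan's inclusion frequency is the fraction of accepted fits
giving it positive weight (positive means above $10^{-8}$ on the normalized
scale); glycans under 10% are dropped. Reported weights average over *all*
accepted fits, filling zeros where a fit lacks the glycan, so that weights
remain comparable across glycans and sum consistently; averaging only over
containing fits is available as a config switch. The contribution of a
reported glycan is its mean weight times the L1 norm of its column,
normalized to sum 1 over the report — the share of the solution response
vector it explains, which serves as a per-call confidence. $R^2$ throughout
is the conventional coefficient of determination with mean-centered total
sum of squares; for a constant observed vector it is defined as 1 for an
exact fit and 0 otherwise.

*Clustering.* Candidates are grouped by complete-linkage hierarchical
clustering of their model vectors (Euclidean distance), cut at a uniform
height. The cutoff defaults to 10% of the maximum pairwise distance — small
enough that members of one cluster are plausible alternates for each other;
it is a reporting aid, not part of the fit, and is fully configurable.
Cluster labels are numbered order-independently (by each cluster's smallest
member id), and the whole solve is invariant to candidate input order
because the filtered columns are put in a canonical id order before
fitting.

*NNLS engine.* The constrained fit is delegated to the Lawson–Hanson
active-set solver (`pracma::lsqnonneg`); the test suite checks it against an
independent exhaustive support-enumeration oracle on random instances with
at least as many channels as candidates, where the minimizer is generically
unique.

## What the synthetic generator emulates — and what it does not

The generator draws N-glycans from the biosynthetic grammar the lectin and
enzyme repertoire is designed to discriminate: bi- to tetra-antennary
structures on the trimannosyl-chitobiose core with per-arm galactose
(β1-3 vs β1-4, probability of galactosylation 0.9 with 0.15 of β1-3),
per-arm sialylation (0.75, split evenly α2-3/α2-6), core fucose (0.3),
bisecting GlcNAc (0.15), plus sialylated O-core1 structures (0.1 of draws).
These rates are chosen once as typical of the complex-type N-glycomes of
serum glycoproteins; they are spec fields, not tuning knobs. Libraries are
deduplicated by canonical form, and everything is reproducible from a
single integer seed.

True mixtures are drawn to be *resolvable by the panel in the solver's own
sense of ambiguity*: the support's filtered columns are linearly
independent, the NNLS fit of the clean mixture returns exactly the true
weights, and excluding any support member leaves no acceptable alternative
(within the R² window, using at most the allowed additional glycans). This
mirrors how such experiments are actually designed — a panel is chosen so
that the structures of interest are distinguishable — and it is what makes
"exact recovery from noiseless data" a well-posed benchmark. Mixtures
violating it are not wrong, they are genuinely ambiguous, and the solver
reports them as spread inclusion frequencies; the benchmark simply does not
draw them. Mixture weights are uniform on [0.25, 1], normalized to sum 1.

Observations are rendered at spot level: `background + scale × d` per
channel with additive Gaussian noise (sd = noise fraction × scale),
replicated 6 spots × 3 arrays by default, then reduced exactly as real data
would be (background subtraction, per-array then cross-array averaging).
The simulation does not model spatial artifacts, spot morphology,
saturation, lectin cross-reactivity beyond the motif model, or the
calibration error of per-lectin normalization of real samples — so passing
benchmarks demonstrate the correctness of the computational chain, not the
accuracy of motif/score tables for any particular real lectin.

## Masses and compositions

Candidate restriction by MS uses monosaccharide compositions (e.g.
`Hex5HexNAc4Neu5Ac2`) or masses within a tolerance of a user-supplied list.
The default mass table holds monoisotopic residue masses of underivatized
glycans plus one water for the free reducing end (Hex 162.0528, HexNAc
203.0794, dHex 146.0579, Neu5Ac 291.0954, Neu5Gc 307.0903, Pent 132.0423;
water 18.0106 Da). Published mass labels frequently follow an unstated
derivatization or adduct convention and then do not equal these values; the
package therefore treats such labels as opaque and recommends matching by
composition, keeping the mass route fully overridable (tolerance in Da,
default 0.5).

## Core and terminal summaries

N-glycans are recognized by the trimannosyl-chitobiose core; antennarity
counts GlcNAc branches on the two core α-mannoses, with bisecting GlcNAc
counted as a flag rather than an antenna (a bisected biantennary glycan is
still biantennary) and core fucose likewise a flag. O-cores 1 and 2 are
detected from the reducing GalNAc. Terminal-feature fractions use
terminal-anchored motifs and per-site accounting: a glycan with one α2-3
and one α2-6 arm contributes half its weight to each feature, which also
handles partially sialylated structures naturally by counting the arms that
exist. Presence/absence accounting is available per call. All fraction
tables sum to 1 and are invariant to global weight rescaling.

## Problem sizes and numerical choices

The shipped benchmarks use 50-candidate libraries, 4-glycan mixtures, a
7-lectin × 6-condition panel (42 channels), 5% spot noise with 18 replicate
spots per channel, and 10 simulation seeds for noisy-recovery averages —
sizes at which every property of interest is already exercised and a full
suite runs in well under a minute. Proportionality uses a $1-10^{-9}$ cosine
threshold; predicted-set membership uses a $10^{-8}$ weight epsilon;
degenerate inputs (all-zero matrices or observations, constant vectors,
empty allowed sets, missing channels) are either handled with documented
conventions or raise early, named errors.

## Known limitations

- Binding scores are consumed, not derived; the fidelity of any real-data
  analysis is bounded by the quality of the motif/score tables supplied.
- The max-score aggregation discards avidity effects; multivalent binding
  that scales with site count needs the `site_count` mode and scores
  calibrated for it.
- Digestion is all-or-none; incomplete on-chip digestions will appear as
  mixtures of the treated and untreated structures.
- Per-lectin normalization of observed data assumes the sample attains each
  lectin's maximal model response; samples lacking a lectin's best ligand
  will have that block overscaled.
- Highly redundant candidate sets remain fundamentally ambiguous; the
  inclusion-frequency mechanism reports this honestly but cannot resolve
  it — only richer panels can.
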