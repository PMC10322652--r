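---
title: "Structural metabolite clustering and module analysis: methods and design"
author: "MetaboModules authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural metabolite clustering and module analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboModules)
```

## What the package computes

`MetaboModules` groups a metabolite panel by molecular structure and then
asks biological questions of the resulting groups. The chain is:

SMILES → fingerprints → Tanimoto dissimilarity → classical MDS →
accuracy-maximization 2-D embedding → silhouette-selected consensus
clustering → (per cluster) branch modules → eigen-metabolite summaries →
group tests → metabocard attribute enrichment.

The first half is pure cheminformatics and uses only the SMILES; the
second half joins the structural organization to the concentration matrix
and the HMDB annotation. This vignette records the model at each stage,
the tunable parameters and their defaults, the numerical conventions, and
the choices made where the design was genuinely open.

## Fingerprints and dissimilarity

Every SMILES is first converted to OpenBabel canonical SMILES, so
equivalent notations (`CCO`, `OCC`; kekulized vs aromatic benzene) map to
one representation. Strings that fail to parse are flagged `valid = FALSE`
at panel construction, kept in the panel for bookkeeping, and excluded
from all structural computations; the count of exclusions is reported.

The default fingerprint is a **circular (Morgan-style) scheme, radius 2,
folded to 1024 bits**, computed on the molecular graph: each atom starts
from an identifier hashing (element, degree, bond-order sum), identifiers
are iteratively re-hashed with the sorted (bond order, neighbor
identifier) list, and every environment hash up to the radius sets one
bit. Circular fingerprints are the de facto standard for Tanimoto
similarity; they also behave sensibly for single-atom molecules (methane
yields a non-empty bit set), which path-based schemes do not encode at
all. OpenBabel's path-based FP2 and the 166-key MACCS set are available
through `fingerprintScheme("fp2")` / `fingerprintScheme("maccs")` for
sensitivity analyses.

Tanimoto dissimilarity between bit sets is `1 - |A ∩ B| / |A ∪ B|`. Two
all-zero fingerprints have dissimilarity 0 by convention: their
representations are identical, and 0/0 is resolved in favor of identity.

## Classical MDS

`mdsEmbed()` uses Torgerson scaling (`stats::cmdscale`) with **50
dimensions as default**, keeping at most the number of strictly positive
eigenvalues. Tanimoto matrices need not be Euclidean, so the negative part
of the spectrum is truncated rather than fitted; a matrix with no positive
eigenvalues (e.g. all zeros) is rejected as degenerate. Torgerson scaling
was chosen over an iterative stress optimizer because it is deterministic
and exact for Euclidean inputs, which keeps the whole chain reproducible
from a single seed.

## Accuracy maximization

The 2-D "chemical distance" map is produced by an accuracy-maximization
procedure in the spirit of KODAMA. Per cycle:

1. assign each point a random label from **5 starting classes**;
2. repeat (at most **20 inner sweeps**): visit the currently
   misclassified points in random order and reassign each to its
   leave-one-out 1-nearest-neighbor prediction whenever the move does not
   decrease the cross-validated accuracy; stop when a sweep changes
   nothing or all points are self-consistent.

Across **20 cycles** (default) the fraction of cycles in which two points
end with the same label forms a proximity matrix `P`; by construction its
entries lie exactly on the grid `{0, 1/cycles, ..., 1}`. The final map is
the classical MDS of `1 - P` in two dimensions. All four knobs
(`startClasses`, `maxInner`, `cycles`, and the classifier being 1-NN) are
exposed.

Conventions for degenerate geometry: points with identical coordinates
are indistinguishable to any distance-based classifier and are constrained
to share a label within every cycle, so exact structural duplicates reach
proximity 1; a configuration whose proximities are all 1 (one tight blob)
embeds to coincident points at the origin rather than erroring.

Two properties of this variant are worth knowing. First, accuracy-neutral
moves are accepted, so label-domain boundaries drift between cycles and a
connected nearest-neighbor component — such as a homologous series, whose
chain-length gaps shrink monotonically — homogenizes to a single label
almost every cycle. Second, reassignment can only follow nearest-neighbor
edges, so separate mutual-NN components of a diffuse cloud never exchange
labels; diffuse Gaussian-style clusters therefore sharpen less than
homologous series. This matches the intended use: chemical classes are
graded series, not isotropic clouds. The procedure is deterministic for a
fixed master seed (per-cycle seeds are derived from it), and bit-level
parity with other accuracy-maximization implementations is explicitly not
a goal — only the behavioral contract above is.

## Cluster detection

`detectClusters()` runs the whole chain. The stochastic stage (the
embedding) is repeated **10 times** by default with derived seeds; MDS is
deterministic, so repeats re-randomize only the accuracy-maximization
stage. For every repeat, Ward (`ward.D2`) hierarchical clustering of the
2-D map is cut at each `k` in `2..kmax` and Rousseeuw's mean silhouette is
recorded; `k*` maximizes the repeat-averaged silhouette, with ties broken
toward the smallest `k` (parsimony). `kmax` defaults to `min(30, n - 1)`
and an explicit `kmax >= n` is a parameter error.

The paper-facing quantity is the averaged silhouette profile; the final
labels additionally need a rule, and the package uses a **co-association
consensus**: the fraction of repeats in which two metabolites share a
cluster at `k*` defines a similarity, and average-linkage clustering of
its complement, cut at `k*`, gives the labels. This uses all repeats
instead of promoting an arbitrary representative run, and it is invariant
to the order of the repeats. Singleton clusters contribute silhouette 0,
as do points whose within- and between-cluster mean distances are both
zero (coincident clusters).

## WMCSA: modules, eigen-metabolites, tests

Within a selected cluster, the structural dendrogram (Ward on the 2-D
embedding of its members) is cut at *every* branch: each internal node
with at least `minSize` leaves is a candidate module. `minSize` defaults
to **3** — a 2-member "module" is just a pair — and modules are numbered
by depth-first preorder from the root, which is stable for a fixed tree.
Nested and overlapping modules are all reported; ancestors are never
pruned, and nested modules are summarized independently (no
orthogonalization).

The **eigen-metabolite** of a module is the first principal component of
its members' concentration profiles: profiles are log-transformed
(metabolomics intensities are approximately log-normal; `transform =
"none"` is available for already-transformed matrices), standardized to
zero mean and unit variance per metabolite, and decomposed by SVD. Scores
are the first left singular vector scaled by its singular value, so they
have zero mean over samples; the sign is chosen so the mean correlation
with member profiles is non-negative; `varianceExplained` is the first
eigenvalue over the trace. Standardization makes the summary invariant to
per-metabolite scale factors. Missing concentrations are imputed
per-metabolite by the observed minimum (the usual floor convention for
sub-detection-limit values; median imputation and strict `"none"` are
configurable). Members constant across samples are dropped with a
warning; a module collapsing below two members is degenerate and excluded
from the summary matrix.

Group differences per module are tested on the eigen-metabolite scores
with a **two-sided Mann–Whitney U test** (Welch's t selectable) and
Benjamini–Hochberg adjustment across modules, significant at adjusted
p < 0.05 by default. The rank test was chosen because the motivating
designs have ~6 samples per group, where normality is unverifiable; note
that at 6 vs 6 the exact test's smallest achievable two-sided p-value is
2/924 ≈ 0.0022, which bounds how many modules can survive a multiplicity
adjustment.

## Metabocard annotation and enrichment

`readMetabocard()` parses one HMDB metabocard XML (root `<metabolite>`,
v4/v5 element names, namespace tolerated, both spellings of the
monoisotopic-mass element). Absent blocks produce empty fields. Five
attribute kinds are extracted: substituents, taxonomy (encoded as
`rank:value` over kingdom/super_class/class/sub_class), enzymes
(gene and protein names), diseases, and pathways.

Enrichment is a **one-sided Fisher's exact test** per (module, attribute
value) on the 2×2 membership table, BH-adjusted across all pairs — the
standard over-representation construction. Only values carried by at
least two universe metabolites are tested. The universe is the set of
valid panel metabolites with a parsed card (not all of HMDB): the
analysis is desk-scale and self-contained, and the universe is
configurable. A value carried by every universe member yields p = 1 and a
0/0 sample odds ratio, reported as 1 (no discrimination); a zero margin
with a non-zero numerator is reported as `Inf`. Cards are read from local
files only; nothing is downloaded.

## The synthetic generator

`generateStructuralPanel()` builds families as **homologous series** —
straight-chain fatty acids (`CCCC(=O)O`, ...), alkyl α-amino acids
(`NC(C)C(=O)O`, ...), N-alkyl imidazoles (`Cn1ccnc1`, ...), linear sugar
alcohols — rather than random SMILES. Templating guarantees graded
within-family similarity, like real chemical classes, and the series'
monotonically shrinking Tanimoto gaps make each family a single
nearest-neighbor component (see the accuracy-maximization notes above).
Defaults are 3 families × 8 members.

`generateConcentrations()` simulates, on the log scale,

```
x[s, m] = baseline[m] + z[module(m)][s] + effect * noiseSd * 1(group(s) shifted) + e[s, m]
```

with `z` a per-module latent score (SD `latentSd`, default 1, loading 1
for members), `e` i.i.d. Gaussian noise (SD `noiseSd`, default 0.3), and
exponentiation to positive, log-normal concentrations. Defaults emulate a
small two-group design with **6 replicates per group**. Effects are
expressed in noise-SD units and shift every group except the first.

What the generator does **not** emulate: batch effects and drift,
structured missingness, heteroscedastic instrument noise, and the
chemical diversity of a real panel (hundreds of metabolites across many
classes). Passing tests on these fixtures demonstrate that the machinery
recovers planted structure under clean conditions; they do not establish
performance on real acquisitions.

## Calibration and power of the module test

The type-I error of the differential test is checked by simulating 20
latent-covariance modules with no group effect (6 vs 6) and verifying
that the raw p < 0.05 fraction stays near the nominal level over 200
simulations.

Power is evaluated for a 2-noise-SD shift planted on **structure-only
modules** (`latentSd = 0`): modules whose members share chemistry but no
residual co-regulation beyond the group effect. This is the setting the
method targets — modules are defined by structure, not by correlation —
and it is where eigen-metabolite averaging pays off: the score's
within-group spread shrinks like `noiseSd / sqrt(module size)`, so a
2-noise-SD shift on a 5-member module separates the groups almost
completely and survives BH adjustment across 20 modules in well over 90%
of simulations. The complementary limitation should be stated plainly:
when members share strong latent biological variation (latent SD
comparable to or larger than the noise SD), that variation does not
average out, and a shift of a few noise-SDs becomes undetectable at 6 per
group — by any test, since it is small relative to the score's true
within-group spread.

## Numerical conventions and problem sizes

* One master seed drives everything; stage and cycle seeds are derived by
  a fixed integer recurrence, so any stage can be reproduced in
  isolation and a run manifest reproduces all outputs byte-identically.
* Distance ties in 1-NN search resolve to the lowest index; equal
  silhouette means resolve to the smallest `k`; `cutree` label numbering
  follows first appearance.
* Proximity entries are exact multiples of `1/cycles`; tabular outputs
  are written with 17 significant digits so that resumed stages operate
  on bit-identical inputs.
* The bundled analyses and tests run at desk scale by design — panels of
  24 metabolites (3 × 8), 12 samples, 200-replicate simulations, 10
  master seeds for recovery checks — sizes chosen so that the full suite
  re-runs quickly anywhere while still exercising every code path; the
  implementation itself is vectorized and handles panels of several
  hundred metabolites.

## Known limitations

* No 3-D conformers, no InChI input, no substructure search; structural
  resolution is whatever the chosen fingerprint captures.
* Only hierarchical clustering is offered (by design); density- or
  graph-based alternatives are out of scope.
* The accuracy-maximization variant is deterministic-by-seed and
  contract-compatible with, but not numerically identical to, other
  implementations of the idea.
* Enrichment universes are panel-sized; attribute p-values are
  conditional on the panel, not on the metabolome.
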