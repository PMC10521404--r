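---
title: "Cortical thickness similarity networks and well-being: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical thickness similarity networks and well-being: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctnetwb)
```

## The analysis in one paragraph

`ctnetwb` implements a single-subject morphological brain-network
analysis. For each subject, the distribution of cortical thickness
inside each of 32 cortical parcels (Yeo-7 networks, both hemispheres,
parcels under 50 surface vertices excluded) is summarised as a
histogram; the similarity of every parcel pair is the absolute Pearson
correlation of their two histograms computed on a shared 30-bin
support. The resulting 32 x 32 similarity matrix is sparsified without
an arbitrary threshold by aggregating successive edge-disjoint minimum
spanning trees (orthogonal MSTs) and keeping the aggregation that
maximises global cost efficiency; the surviving edges are binarised.
Seven topology measures are computed on the binary graph — global,
nodal and local efficiency, and degree, betweenness, eigenvector and
pagerank centrality — and each node-level measure is related to
Mental Health Continuum Short Form (MHC-SF) well-being scores through
an ordinary least squares model with age, sex, education, intracranial
volume and mean cortical thickness as covariates, with
Benjamini-Hochberg FDR control across the 32 parcels of each
(metric x well-being dimension) family. Because raw cohort data of
this kind are not publicly deposited, the package ships a
synthetic-cohort generator that emulates the study conditions
(65 subjects, the bundled parcel table with its real vertex counts)
and supports planting a known topology-behaviour effect for
calibration and power studies.

## Network construction

**Histograms.** For a parcel pair the two thickness vectors are pooled
and 30 equal-width bins are laid over `[min, max]` of the pooled
values. Bins are right-closed, with the first bin also closed at the
minimum, so counts conserve vertex totals exactly. A shared support is
essential: correlating histograms binned on different supports would
compare unrelated quantities. Counts rather than proportions are used;
Pearson correlation is invariant to that choice. With constant bin
width, 30 bins across a pooled range of roughly 1.5-2.5 mm gives bins
of 0.05-0.08 mm, fine enough to resolve mixture structure in parcels
of 50+ vertices without leaving most bins empty.

**Similarity.** The edge weight is `|cor(freq_x, freq_y)|`. The
absolute value is applied to the correlation, never to the inputs, and
the fraction of negative raw correlations is recorded per subject (it
is typically ~1% on synthetic cohorts, matching the premise that
anti-correlated distribution shapes are rare). The diagonal is fixed
at zero; self-connections carry no information and are excluded from
topology. A pair is *degenerate* when the pooled values are all
identical or a count vector has zero variance; such pairs get
similarity 0 with an aggregated warning, and more than 10% degenerate
pairs aborts the run as a data pathology.

**OMST sparsification.** Similarities are converted to distances by
`d = 1/w` (the convention of the OMST literature; `1 - w` is available
behind a flag for sensitivity analysis). Round *m* extracts a minimum
spanning tree (or forest, once earlier removals disconnect the graph)
of the graph with all previous rounds' edges removed, using Kruskal's
algorithm with a lexicographic node-pair tie-break so equal weights
can never make the output run-dependent. After each round the
cumulative edge set is scored by global cost efficiency,
`gce = Eglob_w - cost`, where `cost` is the retained fraction of total
similarity weight and `Eglob_w` is the weighted global efficiency of
the selected subgraph (path lengths on `1/w` distances). The
aggregation with maximal gce wins (first maximum on ties) and is
binarised. The efficiency term is computed on the weighted subgraph —
binarisation happens only after selection. Extraction stops early
after three consecutive declining rounds; the gce curve on these
dense, small (N = 32) graphs is unimodal in practice, and the already
attained maximum is never affected. The first tree guarantees the
binary network is connected, which the centrality definitions below
rely on.

## Topology measures

All measures operate on the binary adjacency. Unreachable pairs
contribute 0 to efficiency sums (the usual 1/infinity = 0 convention);
local efficiency is 0 for nodes with fewer than two neighbours, whose
neighbour subgraph is degenerate. Betweenness is the sum over
*ordered* pairs of the fraction of shortest paths through the node,
with no halving and no normalisation — the definition taken literally —
so values on undirected graphs are twice the halved convention used by
some libraries; the test suite checks ours against `2 *
igraph::betweenness()`. Eigenvector centrality is the leading
eigenvector of the adjacency in Perron orientation (nonnegative) with
unit Euclidean norm, obtained from a dense symmetric
eigendecomposition and verified against the eigen equation at 1e-10.
Pagerank uses damping 0.85 and the scaling in which the values sum to
N (any regular graph is uniformly 1); at N = 32 it is solved as a
dense linear system rather than by power iteration and verified
against its fixed-point equation at 1e-12. Every measure is also
validated against independent brute-force oracles (Floyd-Warshall
distances, matrix-power path counts, exhaustive path enumeration,
shifted power iteration, fixed-point iteration) exhaustively over all
labelled connected graphs with up to 5 nodes and over hundreds of
random 6-8-node graphs. Exhaustive enumeration beyond 5 nodes is not
attempted: there are on the order of a million labelled connected
graphs on 7 nodes, which buys no additional confidence over dense
random sampling at these sizes.

## Behaviour scoring and the association model

The MHC-SF has 14 items answered on a 6-point frequency scale. Items
are coded 0-5 by default, which yields the conventional subscale
ranges — emotional 0-15 (3 items), social 0-25 (5 items),
psychological 0-30 (6 items), total 0-70 — matching the observed
ranges in cohorts scored this way; a `c(1, 6)` coding is available as
a switch. The default item-to-subscale map follows the standard form
(items 1-3 emotional, 4-8 social, 9-14 psychological) and is an
explicit argument, since translated forms can reorder items.
Cronbach's alpha uses sample (n-1) variances.

Each well-being score is regressed on age, sex, education, ICV, mean
cortical thickness (vertex-weighted by default; parcel-weighted behind
a flag) and one parcel's metric. The reported effect size is the
partial correlation of metric and outcome given the covariates,
recovered from the t statistic, `partial_r = sign(t) *
sqrt(t^2/(t^2 + df))`; a covariate-adjusted model reported alongside an
"r" is most naturally read as a partial correlation, and a zero-order
correlation column is available behind a flag for comparison. FDR is
Benjamini-Hochberg within each (metric x dimension) family of 32
parcel tests — the correction is explicitly "for 32 parcels" — with
pooling across metrics available behind a flag for sensitivity. Global
efficiency, a single value per subject, is tested per dimension
without parcel looping or FDR. Parcels whose metric is constant across
subjects (possible in very sparse networks) are reported with NA
statistics and excluded from the family rather than silently given
p = 1. For any (metric, parcel) significant for the total score,
`effect_sizes()` reports the per-dimension partial correlations from
the same model refitted per dimension; "effect size" is not otherwise
standardised, and this choice keeps one estimand throughout.

## The synthetic cohort generator

The generator replaces unavailable MRI-derived inputs and defines the
conditions under which the pipeline's statistical behaviour is tested.

**Scale and covariates.** Defaults: 65 subjects; the bundled 32-parcel
table with its true fsaverage5 vertex counts (about 13,000 vertices
per subject); age 37.3 +/- 13.1 years; education 15.4 +/- 3.2 years
with a target age-education correlation of -0.401 through a Gaussian
copula; ICV 1.45e6 +/- 1.3e5 mm^3 (a conventional adult value,
uncorrelated by default); sex a fair binary draw. Covariates are drawn
independently per subject, which realises the copula law exactly and
keeps subjects independent.

**Thickness.** Vertex thickness is Gaussian around 2.5 +/- 0.3 mm.
Each parcel carries a fixed characteristic mean offset (spread 0.10 mm),
the same pattern in every cohort — parcel means are anatomy, not
sampling noise — plus a subject-by-parcel jitter (sd 0.10 mm). These
two scales were chosen so that, after histogram construction and OMST,
the binary networks retain two to three spanning trees for nearly all
subjects: much noisier blocks collapse to a single tree (where local
efficiency is identically zero and the measure is uninformative),
while a nearly deterministic block makes tree selection an artefact of
ties.

**The planted effect.** When enabled, one target parcel and a small
neighbour set (by default the three largest same-hemisphere,
same-network parcels) form a shape-defined island: neighbours draw
from a sharply bimodal mixture (separation 1.2 mm, component sd
0.15 mm) around a common, jitter-free mean. The target parcel draws
each vertex from that island shape with probability
`plogis(gain * effect_size * latent)` and otherwise from a twice-wider
bimodal shape. High-latent subjects therefore have a target parcel
embedded in a mutually similar clique (high local efficiency); low-
latent subjects have a "loner" parcel whose network neighbours are
scattered and mutually unconnected (low local efficiency). Both
endpoint shapes are about equally dissimilar to the unimodal
background, so the latent leaks minimally into the rest of the
network — an important property, because spanning-tree selection is
global and any latent-linked change elsewhere would create spurious
competitor associations. The logistic gain (3.5) was calibrated by
simulation so that `effect_size = 0.4` yields a realized partial
correlation near 0.4 at n = 65 after the full
histogram-OMST-topology-GLM chain; `effect_size` is thus a target on
the scale users care about rather than a raw mixture parameter.

**Behaviour.** Each of the 14 items is `latent + noise` (noise sd 1)
graded through five equally spaced cut points (-3.3 to 0.3, step 0.9).
The cut points were placed so that the marginal item distribution
reproduces a high-well-being population: expected total near 54 of 70,
with internal consistency (alpha about 0.92-0.94) arising naturally from
the shared latent factor.

**Reproducibility.** A single master seed feeds hierarchical
per-subject, per-parcel child streams, so identical configs are
bitwise reproducible and enlarging the cohort never changes existing
subjects. Setting `effect_size = 0` disables the effect entirely; a
named effect parcel with zero effect size draws from the same law as
the null cohort.

**What the generator does not emulate.** Real cortical thickness has
spatial autocorrelation across the surface, hemispheric asymmetries,
age-related thinning, scanner- and segmentation-induced artefacts, and
genuine anatomical covariance between specific regions. Passing tests
on synthetic cohorts therefore demonstrates that the pipeline computes
its quantities correctly and is statistically calibrated under a known
null and power under a known alternative — not that real cohorts
carry effects of any particular size.

## Simulation designs used by the checks

Two statistical checks run at study scale (n = 65, 32 parcels, all
vertex counts as bundled). *Null calibration*: 40 independent null
cohorts are pushed through the full network chain; 1000 replicate
outcome draws (each an independent latent and item table) are paired
with these metric sets in rotation, the local-efficiency x total-score
family is fitted each time, and the checks assert pointwise p-value
uniformity and a family false-positive rate within binomial error of
the 0.05 FDR level. Reusing each cohort's metrics for ~25 outcome
replicates is valid under the null because outcome draws are
independent of the metric side; it trades a small dependence between
replicates for a fourfold reduction in compute. *Effect recovery*: 100
cohorts with a planted local-efficiency effect (`effect_size = 0.4`)
at RH_Default_PCC; the check asserts the planted parcel is the
family's top hit in a majority of seeds and that the realized partial
correlation sits near the target. Problem sizes (40 cohorts, 1000
replicates, 100 seeds) were chosen as the smallest giving useful
binomial resolution at these rates.

## Numerical and design choices, in brief

- Histogram bins: right-closed, first bin left-closed; shared pooled
  support per pair; counts conserved exactly.
- Distance transform `1/w` with `1 - w` behind a flag; both strictly
  monotone, so MST structure depends only on weight ranks.
- Kruskal with lexicographic tie-break: deterministic under ties.
- gce efficiency on the weighted subgraph; binarisation after
  selection.
- Betweenness over ordered pairs exactly as defined (documented
  difference from halved conventions).
- Eigenvector centrality: Perron orientation, unit norm, residual
  checked at 1e-10. Pagerank: dense solve, residual at 1e-12, sum N.
- Mean CT: vertex-weighted across retained parcels (parcel-weighted
  behind a flag); the covariate definition is not otherwise pinned
  down.
- Sex coded 0/1; covariates unstandardised (OLS t statistics are
  invariant to affine rescaling).
- Item coding 0-5 by default (the subscale maxima force it when totals
  range to 70); 1-6 behind a switch.
- Degenerate similarity pairs: similarity 0 with warning; > 10%
  degenerate aborts.
- Constant metric columns: NA rows excluded from FDR families.

## Known limitations

- The binary networks from two or three spanning trees on 32 nodes are
  sparse; local efficiency is zero-inflated, and associations with it
  behave accordingly (the planted-effect recovery operates in exactly
  this regime).
- The generator's planted mechanism moves distribution *shape* only;
  it cannot emulate effects carried by parcel mean differences, which
  the similarity measure is designed to be insensitive to.
- Whether reported correlations in covariate-adjusted analyses of this
  kind are partial or zero-order is often ambiguous; this package
  reports partial correlations and offers zero-order values alongside,
  but comparisons against published values should mind the convention.
- FreeSurfer-native surface formats are not parsed; conversion to the
  documented TSV interchange format is upstream of this package.
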