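---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcircuit)
```

This vignette is the package's account of the science it implements: the
models and formulas, the tunable parameters with their defaults and units,
what the synthetic-data generators do and do not emulate, and the numerical
and design decisions taken where the problem left them open.

## The analysis problem

A glomerular olfactory network — the *Drosophila* antennal lobe is the
template — contains on the order of 200 local interneurons (LNs) of mixed
morphological types. A small peptidergic subset of interest (roughly nine
neurons of the "patchy" type, whose glomerular innervation differs from
animal to animal) must be (i) identified inside a dense EM reconstruction,
(ii) characterised glomerulus by glomerulus in terms of synaptic polarity
and partner composition, (iii) characterised across animals in terms of
which glomeruli individual clones co-innervate, and (iv) characterised
functionally through calcium-imaging response metrics. Each of these steps
is a module of this package; a synthetic generator with planted ground truth
closes the loop so that the whole chain is testable.

## Candidate identification

`filter_candidates()` applies an ordered predicate chain: annotated category
is LN; subtype is the target morphological class (default `"patchy"`);
the neuron receives at least one input from a designated marker neuron set
(default id `"CSD"`, a serotonergic modulatory neuron known to contact the
target ensemble); best morphological similarity against a reference library
exceeds a threshold; tracing status is `"Traced"`. Cheap annotation
predicates run before the geometric stage purely for cost; the final set is
order-invariant. The per-stage ledger records survivors and eliminations so
that a disagreement with an expected ensemble size is attributable to a
specific criterion. The similarity threshold default is 0.80 on the
mean-normalized score, and candidates are compared against *each* reference
morphology with the maximum taken, which reads the acceptance rule "similar
to some image of the driver line" rather than "similar to their average".

## Morphological similarity scoring

Arbors are converted to dotprops: resampled to a target spacing (default
1 µm) along each unbranched segment, with the tangent at a point taken as
the first principal axis of its k = 5 nearest neighbours (sign-free). The
raw similarity of query Q against target T is

\[ s(Q, T) = \sum_{i \in Q} f(d_i, |u_i \cdot v_{nn(i)}|), \]

with `d_i` the nearest-target distance. Two scoring modes exist:

* a parametric kernel `f = exp(-d/sigma) |dot|` with `sigma` = 3000 nm — the
  default. Its self-score per point is exactly 1, so the normalized score is
  a clean fraction in [0, 1] and a 0.80 threshold is interpretable as "80%
  of a perfect match";
* a binned log-odds table read from delimited text
  (`read_scoring_table()`), for users who have a trained scoring matrix.
  Published tables are third-party data and are not bundled.

Normalization divides by the query self-score (`normalized(Q, Q) = 1`
exactly, both modes); the mean-normalized variant averages the two
directions and is what the candidate filter thresholds. Nearest neighbours
use exact brute-force distances; at the point-cloud sizes this package
targets (tens to a few hundred points per arbor) this is faster than tree
structures and has no tie ambiguity.

## Flow centrality and the segregation index

With input/output counts accumulated over the subtree at-or-distal-to each
node `v` (a synapse mapped to a node counts in that node's subtree), the
centrifugal flow is `I_d(v) (O - O_d(v))`, the centripetal flow
`(I - I_d(v)) O_d(v)`, and their sum `C(v)` counts the input→output synapse
pairs whose path crosses the edge above `v`. The split node is the `C`
maximum; ties are broken by smallest root-path distance, then smallest node
id, for determinism. The compartment holding the larger share of output
sites is labelled the axon. The segregation index uses natural-log binary
entropies,

\[ S = 1 - \frac{\sum_i n_i H(p_i)}{N\,H(p_{tot})}, \qquad
   H(p) = -p\ln p - (1-p)\ln(1-p), \]

with `0 ln 0 = 0`; `S = 0` by convention when the global entropy vanishes
(all synapses of one kind), and the degenerate case (zero inputs or zero
outputs) is flagged rather than scored. The implementation is verified
against an independent brute-force oracle that enumerates every
input–output pair's explicit tree path, on hundreds of random trees.

## Glomerular metrics

Synapse sites are assigned to glomeruli by even–odd ray casting against the
closed surface meshes (+x ray, with a small angular perturbation and restart
whenever a hit grazes an edge or vertex; surface points count as inside;
non-closed meshes are refused). For a neuron and glomerulus g, inputs
`I_g` count rows where the neuron is postsynaptic with its postsynaptic
site in g, outputs `O_g` rows where it is presynaptic with its presynaptic
site in g — i.e. the site *on the query neuron* decides, matching the
polyadic convention in which one presynaptic site pairs with several
postsynaptic partners and each pairing counts once. The ratio
`R_g = (I_g - O_g)/(I_g + O_g)` runs from −1 (pure output) to +1 (pure
input) and is undefined (null) in non-innervated glomeruli.

For the transmitter-polarity breakdown of a neuron's inputs, uniglomerular
partners (OSNs, uniglomerular PNs) are attributed to their home glomerulus,
multiglomerular partners by synapse-site containment. Where the two
attributions could both apply, home glomerulus wins for uniglomerular
partners: this precedence is a documented interpretation of a procedure
that names both rules without ordering them. Uniglomerular partners lacking
a home glomerulus are excluded and counted. When annotations carry a `side`
column, only same-side (ipsilateral) connections are tabulated.

## Clone innervation statistics

Pairwise co-innervation uses the product-moment Pearson correlation between
binary glomerulus columns with two-sided p-values from
`t = r sqrt((n-2)/(1-r^2))` on n − 2 degrees of freedom. The source
procedure's wording mentions a "rank" correlation, but the routine it names
computes product-moment r on binary data; this package follows the
computation, not the wording. No multiplicity correction is applied by
default (matching the original reporting style); a Holm switch is provided
for reanalysis. Constant columns yield flagged `NA`s, never silent zeros.
Leaf ordering uses Ward's criterion ("ward.D2") on Euclidean distances with
a deterministic tie-break (the branch containing the lower original index
leads at every merge).

The coupon-collector design question — how many clones must be sampled to
see every one of n neuron types — is answered exactly
(`E[T] = n H_n`; `P(T <= t)` by inclusion–exclusion, evaluated in log space)
and asymptotically (`n(ln n + gamma + 1/(2n))`), the latter accepting
fractional n. The two modes differ in a way that matters for reproducing
published sample sizes: for 13 types the exact expectation is 41.34
(rounding up to 42), while the asymptotic form at a mean count of 13.2
rounds up to 43. Both are exposed; the package does not decide which a
given study used.

## Calcium-imaging metrics

`compute_dff()` optionally smooths with a Gaussian kernel (sigma in frames,
default 1), optionally divides out a single-exponential bleach fit (fitted
by log-linear regression refined with nonlinear least squares on the
pre-onset frames plus the final second — the segments a transient response
does not contaminate), then takes `F0` as the mean over the 2 s before
stimulus onset and `dF/F = (F - F0)/F0`. `response_metrics()` reports the
peak `dF/F` in the onset→1 s window and the composite-Simpson AUC of the
baseline-subtracted `dF/F` over that window, where the AUC baseline is the
mean `dF/F` of the 1 s before onset. Composite Simpson integrates sample
pairs (exact through cubics) and closes an odd final interval with a
trapezoid. Two AUC window origins are supported — stimulus onset (default)
and trace start — because the source wording ("from the beginning until 1 s
after delivery") is ambiguous; onset is the default since a trace-start
origin would make the AUC depend on arbitrary pre-trial recording length.

## The synthetic generators: what they emulate, and what they do not

`make_glomeruli()` builds the neuropil as non-overlapping tessellated
ellipsoids (semiaxes 4–7 µm, 18 × 32 bands — at which density the
tessellated volume agrees with the analytic ellipsoid volume to better than
2%). `make_connectome()` plants: a patchy ensemble (default 9 neurons,
innervating each glomerulus independently with probability p, default 0.5,
with a floor of one glomerulus per neuron); background LNs (default 191, so
the LN total is the ~200 of the real network) engineered so that each decoy
class fails exactly one filter stage; resident OSNs/uPNs with home
glomeruli; a marker neuron contacting the ensemble at an extraglomerular
site; and a reference morphology library made of 100-nm-jittered copies of
the planted arbors, standing in for well-registered light-microscopy
images of a driver line.

Within an innervated glomerulus the planted input:output ratio is realised
by *balanced rounding* — `I_g = round(n_g (1+r_g)/2)` with stochastic
rounding of the fractional part — rather than by binomial thinning. The
planted ratio is thus a structural property of the ensemble, and recovery
error measures the mesh-assignment path rather than binomial sampling
noise. Innervation itself stays Bernoulli, so innervation-frequency
statistics keep their sampling variability. The default synapse load is 30
connections per innervated glomerulus per ensemble neuron, with output
connectors polyadic (up to three postsynaptic partners per presynaptic
site).

`make_clone_matrix()` samples binary clone × glomerulus matrices through a
latent-Gaussian copula: each pairwise target correlation on the *binary*
(phi) scale is mapped to a latent correlation by numerically integrating
the bivariate-normal orthant probability and inverting by bisection;
the assembled latent matrix is repaired to the nearest positive-definite
correlation matrix when needed. Unattainable phi targets (the phi range is
margin-limited) are refused with an error rather than silently truncated.
This Bernoulli/copula model is a stand-in: no distributional model of
animal-to-animal innervation variability is established for the real
system, and the generator makes no claim beyond giving the correlation
analytics a truth to recover.

`make_trace()` produces
`F(t) = baseline * exp(-t/tau_bleach) * (1 + A k(t)) + noise` with an
exponential response kernel of unit peak at onset, at the acquisition
geometry of a typical widefield trial (40 frames at ~9 Hz, onset frame 20).
It emulates scalars-per-frame ROI traces only — not image stacks, motion, or
indicator nonlinearity.

All generators are pure functions of (spec, seed); per-entity substreams
are derived from the master seed so adding a neuron does not perturb the
draws of the others.

What passing on these benchmarks shows is that the analysis chain is
*correct*: it recovers planted parameters through the same code paths real
data would take. What it cannot show is robustness to properties the
generators do not model — truncated glomeruli at volume borders,
co-transmission, annotation errors, registration distortion, or realistic
arbor geometry.

## Problem sizes and tolerances

The test-suite and acceptance benchmarks run at deliberately small scales:
filter-recovery populations of 15–200 LNs over 4–8 glomeruli; ratio
recovery at 400 synapses per glomerulus (tolerance ±0.05); copula recovery
at 10^4 clones (tolerance ±0.05 on planted correlations); the
coupon-collector Monte-Carlo at 10^5 runs (tolerance ±0.1 on the
expectation); containment checks at 10^3 random points per mesh, exact
outside a ±3% radial shell around the tessellated surface; flow-centrality
oracle equivalence on 200 random trees of up to 50 nodes, exact.

## Known limitations

* Mesh containment assumes non-overlapping, watertight glomerulus meshes;
  overlapping neuropil compartments would need a priority rule that does
  not exist here.
* The NBLAST-style scoring ships no trained log-odds table; the parametric
  kernel changes absolute score values (not the self-score normalization),
  so thresholds tuned on a trained table do not transfer numerically.
* Reciprocal connections at a single polyadic connector are not modelled;
  connection rows are strictly pre→post.
* Demographic and polarity percentages inherit every annotation caveat of
  the underlying data set (no co-transmission, coarse transmitter classes);
  the transmitter-class mapping is configuration, not code.
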