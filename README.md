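# alcircuit

Quantitative analysis of peptidergic local-interneuron (LN) ensembles in a
glomerular olfactory network — the *Drosophila* antennal lobe (AL) being the
motivating system. The package is aimed at circuit neuroscientists who need
to go from raw structural data (EM-derived skeletons, synapse tables,
glomerulus meshes) and light-microscopy clone charts to the quantitative
claims typically made about such an ensemble: which neurons belong to it,
how its synaptic input and output distribute over glomeruli, whether its
members segregate axon from dendrite, which glomeruli it co-innervates more
often than chance, and how its odor-evoked calcium responses are quantified.

Because the real data live in external repositories, the package ships a
first-class synthetic-data module that generates connectomes, clone
innervation matrices and fluorescence traces with *planted* ground truth, so
that every analysis stage is testable end to end and parameter recovery can
be demonstrated rather than assumed.

## What it computes

* **Candidate identification** — a staged predicate chain (LN category →
  "patchy" subtype → input from a marker neuron set → morphological
  similarity above a threshold → fully traced) with a per-stage elimination
  ledger, `filter_candidates()`.
* **Morphological similarity** — point-cloud scoring in the NBLAST style:
  arbors become dotprops (points + unit tangents); the raw score is
  `sum_i f(d_i, |u_i . v_i|)` over query points with nearest-target matches,
  normalized by the query self-score (`nblast()`, default kernel
  `exp(-d/sigma)|dot|`, sigma = 3 µm; delimited log-odds tables supported).
* **Synapse flow centrality and axon–dendrite split** — per node `v`,
  centrifugal flow `I_d(v) (O - O_d(v))` plus centripetal flow
  `(I - I_d(v)) O_d(v)`, the split at the flow maximum, and the entropy-based
  segregation index `S = 1 - sum_i n_i H(p_i) / (N H(p))` in [0, 1]
  (`flow_centrality()`, `segregation_index()`).
* **Per-glomerulus polarity metrics** — synapse sites assigned to glomeruli
  by watertight ray-cast containment (`assign_synapses()`), then the
  intraglomerular input:output ratio `R_g = (I_g - O_g) / (I_g + O_g)`
  (−1 pure output … +1 pure input), partner demographics, and
  transmitter-class input breakdowns (`io_ratio_table()`,
  `partner_demographics()`, `polarity_breakdown()`).
* **Clone innervation statistics** — pairwise Pearson correlations of a
  binary clones × glomeruli matrix with t-based two-sided p-values
  (`t = r sqrt((n-2)/(1-r^2))`), Ward ("ward.D2") leaf ordering, innervation
  frequency vs glomerulus volume, and the coupon-collector sampling design
  `E[T] = n H_n`, with the exact inclusion–exclusion distribution
  (`innervation_correlations()`, `ward_order()`, `coupon_collector()`).
* **Calcium-imaging metrics** — Gaussian low-pass, exponential bleach
  correction, `ΔF/F` against a 2-s pre-onset baseline, peak in the
  onset→1 s window, and Simpson's-rule AUC after 1-s-baseline subtraction
  (`compute_dff()`, `response_metrics()`), plus within-indicator max
  normalization of marker densities (`normalize_density()`).
* **Reproducible orchestration** — `run_pipeline()` chains
  simulate → validate → filter → metrics → statistics → report with explicit
  seeds, a config hash stamped into every artifact, and byte-identical
  reruns. A thin CLI lives at `inst/scripts/run_pipeline.R`.

## Worked example

```r
library(alcircuit)

sim <- make_connectome(population_spec(n_glomeruli = 5, n_patchy_lns = 4,
                                       n_other_lns = 12, seed = 7))
filter_candidates(sim$connectome, sim$references)
#> <al_filter_ledger>
#>   category      -> 16 survivors
#>   subtype       -> 10 survivors
#>   marker_input  -> 8 survivors
#>   nblast        -> 6 survivors
#>   traced        -> 4 survivors
#>   candidates: pLN_01, pLN_02, pLN_03, pLN_04
```

The 16 annotated LNs shrink stage by stage, and the four planted peptidergic
LNs are recovered exactly. Their per-glomerulus synaptic polarity:

```r
head(io_ratio_table(sim$connectome, neurons = sim$ground_truth$patchy), 3)
#>   neuron_id glomerulus n_input n_output ratio
#> 1    pLN_01        DM4      21        9   0.4
#> 2    pLN_02        DM5      21        9   0.4
#> 3    pLN_03        DM2      21        9   0.4
```

A ratio of 0.4 means the neuron receives more input than it sends within the
glomerulus (21 inputs vs 9 outputs), matching the planted generator value.
Sampling design and response quantification:

```r
coupon_collector(13)
#> <al_coupon_result> n = 13 types: E[T] = 41.3417 (exact)
coupon_collector(13, mode = "quantile", q = 0.95)$t_star
#> [1] 70

tr <- make_trace(trace_spec(amplitude = 0.4, noise_sd = 1, seed = 2))
response_metrics(compute_dff(tr))
#> <al_response_metrics> peak 0.3283 dF/F, AUC 0.2286 dF/F*s (onset)
```

Sampling 13 neuron types uniformly takes about 41.3 draws on average to see
them all (70 draws for 95% coverage); the noisy synthetic trace with a
planted 0.4 ΔF/F transient yields a peak of 0.33 after smoothing.

## Vignette

`vignettes/alcircuit-methods.Rmd` documents the models, parameter choices,
numerical decisions and the limits of what the synthetic benchmarks show.
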