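# circuitseg

Analysis of circuit segregation in volume-EM reconstructions of the
dorsal lateral geniculate nucleus (dLGN).

In albino mice, a subset of mistargeted contralateral retinal ganglion
cell (RGC) axons forms a dense, compact "island" of boutons inside the
dLGN, surrounded by a bouton-free shell of otherwise healthy neuropil
(the *exclusion zone*). The scientific question is whether this spatial
segregation is also a synaptic segregation: are thalamocortical (TC)
cells near the zone innervated exclusively by island boutons or
exclusively by non-island boutons ("captured" by one field), rather than
mixing the two?

`circuitseg` provides the quantitative toolkit for that question, for
anyone working with skeletonised EM reconstructions (SWC files plus a
synapse table):

* **Bouton field classification** — a 3D kernel-density surrogate for the
  optical identification of the island: density grid, threshold at a
  fraction of the maximum, connected components; the most compact
  component is the island, boutons in gap regions are ambiguous.
* **Exclusion-zone measurement** — ray casting from the island centroid
  to estimate the shell thickness (median/min/max).
* **Separation projection** — the rotation that shows the clearest 1D
  margin between island and non-island boutons.
* **Capture statistics** — per-TC innervation profiles, capture
  classification, and the independent-dendrite null model (below), with
  soma-to-mean-synapse offsets quantifying dendritic-arbor asymmetry.
* **Neurite geometry** — exclusion-zone crossings and the classification
  of local inhibitory neuron (LIN) neurites into long shaft dendrites,
  short synapse-dense targeted dendrites, and output-only axon-like
  branches, with per-branch field purity.
* **A synthetic circuit generator** — seeded, ground-truthed circuits
  with the same statistical structure (island ellipsoid, exclusion
  shell, surround, TCs with 2–7 RGC-connected primary dendrites, LINs),
  so every stage is testable end to end without EM data.

## The null model

For TC cell *i*, let *k&#8321;, …, k&#8345;* be the numbers of primary
dendrites (soma-adjacent subtrees) that carry at least one RGC input.
Under the null hypothesis of no selection, each dendrite independently
connects to the island or the non-island field with probability ½, so
cell *i* is fully captured with probability

&nbsp;&nbsp;&nbsp;&nbsp;*p&#7522; = 2^(1−k&#7522;)*

and the number of captured cells is Poisson-binomial distributed with
parameters *p&#8321;, …, p&#8345;*. The package computes this
distribution exactly (sequential convolution) and by Monte Carlo
simulation, and reports, for a given level (default 99%), the smallest
*m* such that at least that fraction of trials produce *m* or fewer
captured cells. Observed counts are compared to the null by exact and
empirical tail probabilities — reporting only, no significance claim.

## Worked example

```r
library(circuitseg)

## The observed per-TC dendrite counts for nine exclusion-zone TCs
null <- monte_carlo_null(c(2, 2, 3, 4, 4, 4, 5, 5, 7),
                         trials = 100000, seed = 1, levels = 0.99)
print(null)
#> <null_model_result> 9 TCs (dendrites: 2,2,3,4,4,4,5,5,7), 100000 trials, seed 1
#>   exact mean captured: 1.765625
#>   level 0.99: MC threshold 4 (exact 4)

compare_observed_to_null(9, null)[c("exact_tail", "empirical_tail")]
#> $exact_tail
#> [1] 7.450581e-09
#> $empirical_tail
#> [1] 0
```

Under the null, 99% of trials capture 4 of the 9 cells (44%) or fewer,
and on average fewer than 2 cells are captured; observing all 9 cells
captured has an exact tail probability of 2&#8315;&#178;&#8311; ≈ 7.5 ×
10&#8315;&#8313; — a substantial deviation from independent dendrites.

The full pipeline on a synthetic circuit:

```r
cfg <- run_config(generator = generator_config(seed = 1),
                  out_dir = "run1")
bundle <- run_pipeline(cfg)
str(bundle$summary$capture)
#> $ n_tc             : int 9
#> $ observed_captured: int 9
#> $ captured_fraction: num 1
#> $ thresholds       : List of 1
#>  ..$ 0.99: int 4
#> $ exact_mean       : num 1.77
```

The run directory receives `summary.json`, per-TC and per-branch CSV
tables, a run log, the resolved configuration, and four figures (bouton
projection scatter, cumulative bouton-count curve, null histogram with
the observed count marked, soma→input-centroid vectors). With the
default generator (segregation 1, the regime the reconstruction shows)
all nine TCs are captured, the measured exclusion-zone width is ~9.8 µm
for a true 10 µm shell, and all 4100 boutons are labeled to ground
truth.

A thin command-line wrapper is available at `inst/cli/circuitseg.R`
(verbs `generate` and `run`).

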