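# tcellsim

Agent-based multi-scale stochastic simulation of early T-cell lineage
commitment, with last-common-ancestor (LCA) lineage analysis and in silico
knockdown protocols.

## The problem

Early T-cell progenitors (ETP/DN1) proliferate under thymic Notch
signalling and commit to the T-cell fate when the *Bcl11b* locus opens
(DN2a → DN2b). Commitment is strikingly heterogeneous within clonal
colonies, and the *decision* to commit — the loss of a *Bcl11b*-opposing
function — precedes observable commitment by generations. `tcellsim` is
for computational and systems biologists who want to simulate this process
at single-cell resolution, trace commitment decisions through lineage
trees, and perturb the circuit in silico.

## The model

Three coupled levels per cell:

1. **Transcription** — six species (Runx1 *R*, Tcf7 *T*, Gata3 *G*, PU.1
   *P*, the Bcl11b-opposing function *X*, Notch *N*) with Shea–Ackers
   production functions and first-order decay, e.g.

   dX/dt = 1 / (1 + p₁₄·T + p₁₅·G) − γ_X·X,  dN/dt = p₁₆ / (1 + N),

   simulated exactly as a Gillespie jump process on integer counts.
2. **Epigenetics** — a 500-site regulatory region; each site is closed,
   intermediate or open, with input-driven channels (k₁X closes; k₂N + k₃R
   opens) and mediated channels, simulated with an extended Gillespie
   scheme (propensity = attempt rate × state fraction). The region, and
   hence the cell, is "open" (committed) at ≥ 75 % open sites.
3. **Proliferation** — cells divide at generation-dependent Gaussian times
   (T_div ~ N(μ_g, σ_g)); daughters copy gene counts, and inherit the
   region verbatim while X > 0 or through an opening rule (C→I, I→I/O
   coin-flip, O→O) once X is lost. Colonies run 120 h from a single cell.

Every cell of a colony is classified against its committed descendants:
**open**, **LCA n** (closed, with open descendants in both branches, the
nearest n generations down), **closed pre-LCA** / **closed post-LCA m**
(without / with an LCA ancestor). See the vignette
(`vignettes/commitment-model.Rmd`) for the full model, parameters and
design decisions.

## Worked example

```r
library(tcellsim)

tree <- classifyTree(simulateColony(simulationConfig(), seed = 1))
tree
#> LineageTree: 545 cells (273 leaves), 10 divisions, horizon 120 h
#> open cells at horizon: 42 / 273 (15.4%)
#> classified:  closed_post_LCA, closed_pre_LCA, LCA, open

ens <- runEnsemble(60, simulationConfig(), baseSeed = 1, classify = TRUE)
table(ens$summary$divisions)
#>  6  7  8  9 10 11 12 13
#>  4  3  7 14 16  8  6  2

d <- delayStatistics(ens$trees)
round(d$meanDelay, 2); d$modalLCAOrder
#> [1] 3.02
#> [1] 3

tab <- categoryStatistics(ens$trees)
tab[tab$category %in% c("LCA 4", "LCA 3", "LCA 2", "LCA 1", "open"),
    c("category", "count", "mean_T", "mean_P", "mean_X",
      "mean_openFraction")]
#>    category count mean_T mean_P mean_X mean_openFraction
#> 8     LCA 4     5   37.2      0 1.0000            0.0392
#> 9     LCA 3    27   39.7      0 0.0000            0.0670
#> 10    LCA 2    53   41.5      0 0.0189            0.2534
#> 11    LCA 1   134   40.0      0 0.0000            0.6471
#> 12     open   474   39.7      0 0.0928            0.8664
```

One colony of 545 cells reached 10 divisions with 15 % of its cells
committed; across 60 colonies the modal division count is 10 (range 6–13)
and commitment is heterogeneous. The category table shows the mechanism:
by the late LCA stages Tcf7 is high and PU.1 fully repressed (the
preparatory switch), X is lost around LCA 3, and the open-site fraction
rises steeply only across the last two LCA orders — the decision to commit
is inherited for about three generations before commitment is visible. A
knockdown run is one call:

```r
kd <- knockdownExperiment(knockdownSpec("Tcf7", factor = 0.2), 60,
                          simulationConfig(), seed = 1)
sum(vapply(kd$trees, function(tr) sum(openCells(tr)), 0))
#> [1] 0     # Tcf7 knockdown abolishes commitment
```

Trees serialize to annotated Newick/NHX (`exportTree()`/`parseTree()`,
exact round trip), plot radially via ape (`plotLineageTree()`), and a thin
command-line driver ships in `inst/scripts/tcellsim.R`
(`simulate`, `ensemble`, `classify`, `knockdown`, `report`; every run
writes a manifest with its seed and configuration).

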