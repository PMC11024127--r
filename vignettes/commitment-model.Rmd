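---
title: "A multi-scale stochastic model of T-cell lineage commitment"
author: "tcellsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale stochastic model of T-cell lineage commitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcellsim)
```

# The biological problem

Early T-cell progenitors (ETP/DN1 cells) proliferate in the thymus under
Notch signalling and eventually commit to the T-cell fate, a transition
marked by the upregulation of *Bcl11b* at the DN2a-to-DN2b boundary.
Commitment is heterogeneous: genetically identical cells of one clone turn
*Bcl11b* on generations apart, and the decision to commit appears to be
taken before commitment is observable. `tcellsim` is an agent-based
stochastic simulator of this process, built from three coupled levels, plus
an analysis layer that classifies every cell of a simulated colony by its
relation to committed descendants.

# The model

## Level 1: transcriptional network

Six species evolve inside every cell: Runx1 ($R$), Tcf7 ($T$), Gata3 ($G$),
PU.1 ($P$), an aggregate *Bcl11b*-opposing function $X$, and the Notch
signal $N$. Production follows Shea–Ackers thermodynamic regulation
functions — each gene's production rate is a ratio of statistical weights
of the bound regulator configurations — and degradation is first order:

$$
\begin{aligned}
\dot R &= \frac{p_1 R + p_2 N}{1 + p_1 R + p_2 N} - \gamma_R R, &
\dot T &= \frac{p_3 T + p_4 G + \tfrac{p_5 N}{p_6 + P}}
              {1 + p_3 T + p_4 G + p_5 N + p_7 P} - \gamma_T T, \\
\dot G &= \frac{p_8 T + \tfrac{p_9 N}{p_{10} + P}}
              {1 + p_8 T + p_9 N + p_{11} P} - \gamma_G G, &
\dot P &= \frac{p_{12} P}{1 + p_{12} P + p_{13} R\,G\,T} - \gamma_P P, \\
\dot X &= \frac{1}{1 + p_{14} T + p_{15} G} - \gamma_X X, &
\dot N &= \frac{p_{16}}{1 + N}.
\end{aligned}
$$

Tcf7 and Gata3 mutually reinforce each other and repress both PU.1 and $X$;
PU.1 represses Tcf7/Gata3 and their Notch activation; Notch has no decay
channel. At the copy numbers involved (units of molecules; parameters are
the published calibration, see `grnParameters()`) intrinsic noise matters,
so the network is simulated exactly with the Gillespie algorithm: each
production term, evaluated at the current integer counts, is a +1 channel,
and each $\gamma_i\,\mathrm{count}$ term a −1 channel. The deterministic
rate equations remain available through `integrateODE()` for validation and
knockdown sanity checks; they are never used inside colony simulation.

Because the production propensities are nonlinear, the ensemble mean of the
stochastic process is *not* the ODE solution at these low copy numbers
(Jensen-gap effects of order 10% are measurable for PU.1). SSA/ODE mean
agreement is therefore asserted in the tests only for linear (birth–death)
configurations, where the identity is exact; the full-system comparison is
a mean-field approximation, not an invariant.

## Level 2: epigenetic Bcl11b regulatory region

*Bcl11b* itself is not a network node. Its regulatory region is modelled as
$S = 500$ sites, each closed (C), intermediate (I) or open (O); the cell
counts as *Bcl11b*-open — committed — when at least 75 % of sites are open.
Nine transition channels connect the states (never C↔O directly): four are
driven by the transcriptional inputs ($k_1 X$ closes: O→I, I→C;
$k_2 N + k_3 R$ opens: C→I, I→O) and five are mediated by a second site
(rates $\alpha \ldots \varepsilon$, e.g. O→I mediated by a closed site).

The simulation uses an extended Gillespie scheme in which each channel's
rate constant is the rate at which the *region* attempts that transition; a
uniformly chosen site must match the source state for the attempt to
succeed, and mediated channels additionally require a uniformly chosen
mediator to match. Effective propensities are therefore rate × state
fraction(s), e.g. $(k_2 N + k_3 R)\,C/S$ for C→I and
$\alpha\,(O/S)(C/S)$ for mediated O→I. This design choice matters: scaling
the input channels with raw counts instead of fractions makes the region
remodel ~$S$ times faster, flipping every simulated region open within one
or two generations with $X$ still present — which abolishes the very delay
between decision and commitment the model exists to study. Under the
fraction scaling the region remodels on the timescale of days, the loss of
$X$ precedes opening, and cell division (below) is the main accelerator of
opening, all consistent with the slow cis-acting epigenetic control the
model encodes. The mediator may coincide with the transitioning site for
the I-mediated channel ($\varepsilon (I/S)^2$, no $I-1$ correction); at
$S = 500$ the difference is negligible, and the per-site oracle used in the
tests applies the same convention.

Waiting times are exponential at the current total propensity; whenever the
transcriptional inputs change (at each GRN event) the draw is restarted
with updated propensities, which is exact for piecewise-constant hazards by
memorylessness.

## Level 3: proliferation and inheritance

Each cell draws a division time at birth from a generation-dependent
Gaussian, $T_{\mathrm{div}} \sim \mathcal N(\mu_g, \sigma_g)$, resampled
until positive: $(\mu, \sigma) = (34, 13)$ h at generation 0, then
$(15, 5)$, $(13, 5)$, $(12, 4)$ and $(12, 3)$ h for all later generations.
A colony starts from one generation-0 cell (counts $R{=}1, T{=}2, G{=}1,
P{=}5, X{=}8, N{=}7$; region fully closed) and runs for 120 h; a cell whose
division would fall beyond the horizon is censored there (a division at
exactly 120 h still counts, so its daughters are zero-length leaves).

At division both daughters copy the mother's gene counts. The region is
inherited conditionally on the mother's final $X$: if $X > 0$ the site
counts are copied verbatim; if $X = 0$ every closed site becomes
intermediate, every intermediate site becomes intermediate or open with
probability ½ each (independently per daughter), and open sites stay open.
The complete loss of $X$ is thus the commitment decision: from then on each
division drives the region towards open in large steps.

## LCA classification

Within a simulated lineage tree, a *last common ancestor* (LCA) is any
*Bcl11b*-closed cell with at least one open descendant in each of its two
daughter branches; its order $n$ is the smaller of the two per-branch
minimal generation distances to an open descendant (both daughters open
⇒ order 1; open cells 5 and 6 generations down the two branches ⇒ order 5).
Open cells form their own category; remaining closed cells are *closed
post-LCA m* if they have an LCA ancestor ($m$ = generations below the most
recent one) or *closed pre-LCA* otherwise. Status is evaluated at the end
of a cell's life, matching both the tree colouring (white = open, black =
closed with $X>0$, red = closed with $X=0$) and the per-category statistics,
which use final-before-division values. Open ancestors are never LCAs, and
a closed cell with open descendants in only one branch is not one either.
`classifyTree()` implements this in two linear passes; `bruteForceLCA()`
re-derives every label by exhaustive ancestor/descendant enumeration and is
held equal to the classifier on thousands of random trees in the test
suite.

# In silico experiments

`wtReport()` reproduces the wild-type protocol (identically initialised
colonies; division-count histogram, per-colony fraction of open cells,
per-category expression means). `knockdownExperiment()` multiplies one
gene's production propensity by a knockdown factor (conventionally 0.2);
an onset-0 knockdown also scales the gene's initial count (rounded to the
nearest integer, ties away from zero — Tcf7's 2 × 0.2 becomes 0), while a
delayed knockdown leaves existing counts untouched and applies the factor
to all live cells from the onset on, inherited by their descendants.
`delayStatistics()` locates, for every committed lineage, the earliest cell
on the root-to-open path whose final $X$ is zero while its mother's was
positive, and reports the generation gap to the first open cell below it
together with the cell's LCA order.

```{r example, eval = FALSE}
cfg <- simulationConfig()                    # wild-type defaults
ens <- runEnsemble(60, cfg, baseSeed = 1, classify = TRUE)
table(ens$summary$divisions)
delayStatistics(ens$trees)$meanDelay
```

# Numerical and design choices

* **Reproducibility.** Each cell draws from its own RNG stream derived by
  `splitmix64` from the colony seed and the cell's heap index (root 0,
  children $2i{+}1$, $2i{+}2$), so a colony is bit-reproducible regardless
  of traversal order, and ensembles derive per-colony seeds from one base
  seed. All transforms (exponential, Box–Muller normal, Bernoulli-sum
  binomial) are implemented over `mt19937_64` because the standard library
  distribution adaptors are not portable across compilers.
* **Rounding.** Knockdown-scaled initial counts round half away from zero;
  the SSA requires integer counts.
* **Degenerate inputs.** Zero total propensity censors at the interval end
  (not an error); zero-length lifetimes return the birth state; trees with
  unknown (unannotated) states can be inspected but refuse classification.
* **Counting divisions.** A colony's division count is the maximum
  generation among its cells — the number of divisions along its deepest
  lineage, which coincides with the number of branching rounds when the
  colony divides near-synchronously. Only realised divisions count; a cell
  censored just before it would have divided contributes none.
* **Problem sizes.** The packaged tests and the acceptance script use 60
  wild-type and 60 knockdown colonies, 180 colonies per delayed-knockdown
  onset, $10^4$ random trees for the classifier/oracle equivalence and
  $10^4$–$10^6$ events for the conservation and distribution checks.

# What the simulator does and does not show

The generator *is* the study design: all parameters are the published
calibration and are not re-fitted here. Passing tests show that the coded
model reproduces the calibrated system's behaviour — division statistics,
knockdown phenotypes (Tcf7 knockdown abolishes commitment, Gata3 nearly so,
PU.1 knockdown increases it and depletes $X$; every knockdown narrows the
per-colony $X$ distribution), and irreversibility trends under delayed
knockdown. They do not validate the model against new experimental data,
and real thymocytes have heterogeneous starting states, additional
regulators (e.g. CD25 is deliberately absent) and possible alternative
fates for escaping cells that the model does not represent.

One quantitative caveat is documented rather than hidden: under the printed
channel rates and the attempt-rate algorithm, the mean generation gap
between $X$ loss and opening computes to ~3 (modal LCA order of $X$-loss
cells 3), one generation later than the 1–2 the calibrated study reports.
The gap is structural — a mostly-closed region needs three applications of
the division rule to cross the 75 % threshold, so a shorter delay requires
faster pre-loss remodelling than the printed rates produce. The
corresponding acceptance checks are left failing rather than rescaling any
published rate; all other statistics reproduce.

# Limitations

No cell death, no asymmetric division of molecule counts, no cell–cell
interaction, no spatial structure within the regulatory region, one region
per cell (no allele distinction), and no parameter inference. Escaping
(non-committing) cells simply remain closed; alternative lineage fates are
out of scope.
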