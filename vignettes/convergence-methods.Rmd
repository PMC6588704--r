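---
title: "Detecting convergent substitutions and modelling the muscle fuel switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent substitutions and modelling the muscle fuel switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convflight)
library(ape)
```

convflight implements a two-step comparative-genomic screen for convergent
molecular evolution between a foreground phenotype group (flight-degenerate
birds: flightless species plus weak burst-flyers) and a background group
(flying birds), together with ancestral reconstruction of two focal
lipid-metabolism codons and a kinetic model of the lipid/carbohydrate fuel
balance in flight muscle. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices made where the
methods literature leaves the design open.

## The two-step convergence screen

**Step 1 — per-site group scan.** For every alignment column we tally, for
each residue state, the number of foreground and background species carrying
it (`site_spectrum()`). The *candidate state* of a column is the state with
the largest foreground carrier count; ties are broken by fixed alphabet
order and flagged. A column is a *convergent candidate* when

* the candidate state is shared by at least `min_shared` foreground species
  (default 7, designed for an 8-species foreground; a replication design
  with ~16 foreground species uses 10), and
* the two-group frequency difference is significant by a two-sided Fisher's
  exact test at `alpha` (default 0.001).

The Fisher p-value is computed by exact hypergeometric enumeration: the sum
of probabilities of all tables with the observed margins whose point
probability does not exceed the observed table's. This is the standard
two-sided convention of mainstream implementations, and we verify exact
agreement with `stats::fisher.test()` in the test suite. The threshold
wording in the source literature wavers between "at least seven" and "more
than seven"; we take the operational Methods wording (at least seven) and
expose the cut as a parameter, since group sizes and thresholds are data,
not constants.

Missing data (`-`, `N`/`X`, `?`) are excluded from both the carrier counts
and the per-site denominators, but the sharing threshold still counts
carriers against the full foreground size. This deliberately prevents
columns that are missing in most of the foreground from reaching
significance on a tiny denominator.

**Step 2 — neutral-expectation test.** A frequency difference can arise
from a single substitution on an internal branch shared by related
foreground species; true convergence requires *independent* substitutions.
For each candidate gene we therefore:

1. compute per-site likelihoods on the fixed, rooted phylogeny by
   Felsenstein pruning under a reversible substitution model with
   discrete-gamma rate heterogeneity (`prune_likelihood()`);
2. reconstruct marginal ancestral state posteriors at every node by an
   inside–outside pass per rate category, mixing categories by their
   per-site likelihood (`marginal_ancestral()`); the per-site relative rate
   `r_s` is the posterior mean of the category rates;
3. count *observed* convergent substitutions: with every node assigned its
   maximum-posterior state (leaves keep their observed states), a site
   counts once for every foreground branch pair whose two branches both
   substitute to the same derived state;
4. compute the *expected* number under the same posteriors: for a branch of
   length `t` the probability of ending in derived state `d` after a
   substitution is `sum_{i != d} post(parent = i) P(i -> d | t r_s)`, and
   the pair expectation multiplies the two branch terms and sums over
   derived states, sites and pairs;
5. score the gene by the Poisson tail `P(X >= observed)` with mean equal to
   the expectation, retaining genes below `alpha` (default 0.01).

Counting pools parallel changes (identical parent states) with strictly
convergent ones (different parent states): both end in the same derived
state, which is what the frequency scan responds to. Foreground branches
are the terminal branches of the flight-degenerate species; branch pairs in
ancestor–descendant relation are rejected because convergence on nested
branches is not independent. Whether internal branches of foreground clades
should also enter the count is not settled in the methods literature;
terminal-only is this package's documented default.

The amino-acid workhorse model is the JTT empirical exchangeability matrix,
optionally with "+F" frequencies observed in the gene
(`model_jtt(freq = observed_frequencies(aln))`); nucleotide work uses
`model_jc()`/`model_gtr()`. All rate matrices are normalised to one
expected substitution per unit time at stationarity, so branch lengths are
expected substitutions per site. Rate heterogeneity uses the standard
discrete-gamma construction (four equal-weight categories at the
equal-probability category means, mean rate 1); the shape can be supplied
or fitted by one-dimensional likelihood maximisation (`fit_gamma_shape()`).
Branch lengths are taken from the input tree; instead of full per-branch
maximum likelihood we offer a single global tree-scale factor fitted by
golden-section search (`fit_tree_scale()`), which is proportionate to what
the test needs when lengths come from a published phylogeny.

### Numerical choices

Pruning and the outside pass rescale conditional likelihoods per column and
accumulate log scalers, so 20-state alignments of arbitrary depth do not
underflow; likelihoods are combined in log space. Transition kernels
`exp(Q t r)` come from a cached symmetric eigendecomposition of the
reversible generator (`diag(sqrt(pi)) Q diag(1/sqrt(pi))`), with negative
round-off entries clamped to zero and rows renormalised. Posterior ties at
a node are broken by fixed alphabet order and flagged. The test suite holds
the pruning likelihood and every marginal posterior to brute-force
enumeration over all ancestral state assignments on 4-taxon trees at
1e-10/1e-9 log/probability tolerance.

## Synthetic data: what it emulates and what it does not

`simulate_alignment()` draws a root sequence from the stationary
frequencies, assigns each site a gamma category uniformly, and evolves
sites down each branch with the exact matrix-exponential kernel (no
Gillespie event simulation — downstream stages only see site patterns, so
kernel exactness matters and event-level realism does not). Convergence is
*planted* by overwriting the listed foreground carriers with the derived
state, with the truth table recording the realised ancestral state; if the
root happens to draw the derived state the root is redrawn among the other
states, so plants are genuinely derived. Planting by overwrite rather than
by a biased generative process gives exact truth tables for power and
false-positive analyses. Uniform random missingness can be added; planted
carrier cells are never masked so truth tables always match the emitted
alignment.

The generator therefore emulates: aligned orthologous sequences evolving on
a fixed tree under a reversible model with gamma rates, a scattered
minority foreground carrying identical derived states at chosen sites, and
missing data. It does **not** emulate alignment error, indels, selection
(dN/dS), GC-content shifts, or biased gene conversion — so passing tests
demonstrate the statistical machinery is correct and calibrated under its
own assumptions, not that real avian genomes satisfy those assumptions.

`make_topology_variants()` generates alternative resolutions of weakly
supported branches: for each listed internal branch the tree may keep its
arrangement or take either nearest-neighbour-interchange rearrangement, and
distinct combinations (by unrooted Robinson–Foulds comparison) are
returned with the original first. How the original study sampled its 14
variant topologies from four unresolved branches is not described; the
NNI-per-weak-branch scheme is this package's explicit choice, and with four
weak branches it supports at least the 14 variants used there.

## Focal codons and the flight-phenotype map

`reconstruct_codon()` reconstructs the three positions of a codon column
marginally and combines them per node as the renormalised product of the
three position posteriors. This per-position independence approximation is
transparent and exactly testable against a per-position Bayes oracle; a
61-state codon chain is a non-goal. Posterior probabilities from
codon-model software will differ numerically; agreement on real data is not
claimed. The reported PP equals 1 only when all three positions are
posterior-certain.

`genotype_to_phenotype()` applies the fixed map from the two focal amino
acids to a flight-phenotype class: Ser(ATGL321)+Ala(ACOT7197) → sustained
flyer; Gly+Ala → non-sustained flyer; Gly+Val → flightless or weak flyer;
every other combination (including stop codons, with a warning) →
unclassified. The map is total over {Ser, Gly, other} × {Ala, Val, other}
and carries no hidden state.

Coordinates are 1-based alignment columns throughout;
`alignment_to_reference()` converts columns to ungapped positions of a
named reference species (the convention in which "codon 321" is reported).
Columns where the reference itself is gapped have no reference coordinate
and map to `NA`.

## The kinetic fuel model

Acyl-CoA (`x`, the activated fatty-acid pool) and carbohydrate (`y`)
inhibit each other's pathways:

    dx/dt = -beta1 x + alpha1 / (1 + y^n1) - alpha3 / (1 + y^n3)
    dy/dt = -beta2 y + alpha2 / (1 + x^n2)

with ATP output in carbohydrate-equivalent units `z = 2.25 x + y`, lipids
yielding ~2.25 times the energy of the same quantity of carbohydrate.
`alpha1` is ATGL's lipid-hydrolysis activity (feeds `x`), `alpha3` ACOT7's
acyl-CoA hydrolysis (drains `x`), `alpha2` the carbohydrate-pathway
activity; defaults `beta1 = beta2 = 1`, `n1 = n2 = n3 = 1`, `alpha2 = 5`
follow the published simulation design (`alpha3 = 10` while sweeping
`alpha1` from 25 down to 10; `alpha1 = 10` while sweeping `alpha3` from 1
to 10).

The carbohydrate equation *as printed* in the source model reads
`dy/dt = -beta2 x + ...`: carbohydrate consumption proportional to the
lipid pool. Under that form a healthy lipid flux extinguishes the
carbohydrate pool entirely, and lowering ATGL activity *reduces*
steady-state carbohydrate — the opposite of the narrative the model is
meant to support (impaired lipid use promoting carbohydrate use). We
default to the self-consistent corrected form `-beta2 y` and keep the
printed form available as `variant = "as_printed"`; the test suite
documents both behaviours.

For the corrected system with unit Hill coefficients the fixed point is
closed-form: with net lipid influx `delta = max(alpha1 - alpha3, 0)`, `x*`
is the positive root of
`beta1 beta2 x^2 + (beta1 beta2 + beta1 alpha2 - delta beta2) x - delta beta2 = 0`
and `y* = alpha2 / (beta2 (1 + x*))`. Numerical integration uses a fixed
fine-step classical Runge–Kutta (internal step 0.01) because the
zero-clamping of concentrations makes the vector field non-smooth at the
axes, where adaptive stiff solvers stall; fixed points of a Runge–Kutta
scheme coincide exactly with zeros of the vector field, so terminal
accuracy is set by integration time, not step size. The suite verifies
closed-form/numeric agreement to 1e-8 across a parameter lattice, and
uniqueness of the attractor from 20 random starts. Initial conditions
default to `(0, 0)`.

**Dominance criterion.** "Dominant energy source" is not defined
operationally in the source. Our default compares steady-state energy
outputs (`2.25 x*` vs `y*`); `criterion = "concentration"` compares the
pools directly, in which case symmetry of the two fixed-point equations
puts the switch exactly at `delta = alpha2`. Ties go to carbohydrate.
Under neither criterion, either equation variant, nor any steady-state
readout we could identify do the published switching values (`alpha1 = 18`,
`alpha3 = 4`) emerge from these equations; the sweeps here assert instead
the properties that are derivable — a single switch per sweep direction and
strictly monotone, opposing fuel curves — and report the detected threshold
with the full sweep table.

```{r sweep, fig.width = 6, fig.height = 3.5}
sw <- sweep_activity(kinetic_params(alpha1 = 25, alpha3 = 10),
                     "alpha1", grid = seq(25, 10, by = -0.5))
glance(sw)
autoplot(sw)
```

## Problem sizes and calibration checks

The test suite exercises the pipeline at desk scale, chosen so each check
is statistically meaningful yet the whole suite runs in about two minutes:
a 48-taxon, 8-foreground, 10,000-site null scan for Fisher calibration
(the empirical pass rate must stay within three Monte-Carlo standard errors
of `alpha`; Fisher is conservative on discrete tables); 20 null genes of
300 amino-acid sites on a 16-taxon, 4-foreground tree for Poisson-test
calibration, plus one strongly planted gene for power; and exhaustive
enumeration oracles on 4-taxon trees. The headline counts of the original
genomic study (30 candidates, 8 surviving the null test, 2 replicated)
depend on the real 48- and 103-genome panels and are deliberately not
asserted by this package.

## Known limitations

* The null test assumes the supplied topology and branch lengths; errors in
  either propagate into both observed and expected counts.
* The expectation uses the posterior-mean site rate rather than integrating
  over rate categories inside the pair term; with four categories this is a
  second-order effect, and the choice is exposed in the reconstruction
  object.
* The codon posterior's per-position independence understates uncertainty
  when positions are strongly correlated through shared topology.
* Fisher's exact test ignores phylogenetic non-independence; that is
  precisely why the second step exists, and the scan should never be
  interpreted alone.
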