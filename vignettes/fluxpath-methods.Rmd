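---
title: "Methods: flux-space sampling, differential flux analysis and omics QC in fluxpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flux-space sampling, differential flux analysis and omics QC in fluxpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxpath)
```

# The analysis fluxpath implements

fluxpath characterizes the metabolic flux state of a constraint-based model
not as a single optimal flux vector but as a distribution over the
steady-state flux polytope

$$ P = \{\, v \in \mathbb{R}^n : S v = 0,\ lb \le v \le ub \,\}, $$

where $S$ is the stoichiometric matrix. The polytope is narrowed with
experimental information — measured growth, uptake and secretion rates, and
confidence intervals on intracellular fluxes from $^{13}$C metabolic flux
analysis (MFA) — then sampled, and two conditions (for example a gene
knockout and its parent strain) are compared by testing each reaction's
sampled flux distribution. Around this core the package implements the
companion analyses of a knockout-strain characterization study: ranking
candidate reaction deletions, metabolomics quality control and testing,
growth-rate and fitness-trajectory estimation, and resequencing filters.

# Flux balance analysis and the LP layer

`fba()` maximizes the model's declared objective (usually biomass, in
h^-1^) over $P$; `flux_variability()` minimizes and maximizes each flux in
turn, optionally with the objective held at a fraction of its optimum.
Both run on an internal dense bounded-variable revised simplex
(phase 1/phase 2, Dantzig pricing with a switch to Bland's rule to
guarantee termination, periodic refactorization of the basis inverse).
Infinite bounds are capped at $10^6$ mmol gDCW^-1^ h^-1^; an optimum pinned
to that artificial cap is reported as unboundedness. Central-carbon models
here have tens of reactions, so a dense solver is entirely adequate; the
simplex returns a vertex, and with degenerate alternate optima any optimal
vertex may be reported — downstream code never depends on which.

Loop detection follows the operational definition used for knockout
screening: a reaction is *loop-involved* when it retains a nonzero
flux-variability range after all exchange reactions are closed (positive
lower bounds such as ATP maintenance are relaxed to zero first so that the
zero-flux state is admissible). Flux through such reactions is
thermodynamically infeasible cycling and excludes them from knockout
ranking.

# Measurement constraints and the discard-and-resample repair

Measured rates enter as intervals $[\bar{x} - s,\ \bar{x} + s]$ (mean ±
replicate SD), MFA results as 95% confidence intervals; both are
intersected with the existing bounds, so constraints only ever shrink the
polytope. Sign conventions: uptake negative, secretion positive, growth on
the biomass reaction in h^-1^.

Independently measured constraints can be *jointly* inconsistent with any
steady state even when each is individually plausible — most visibly on
reactions coupled one-to-one by stoichiometry, where two noisy intervals
must intersect exactly. `repair_constraints()` implements the
discard-and-resample rule: while the constrained model is infeasible, an
elastic relaxation (slack variables on every interval constraint,
minimizing total violation) is solved on the base model, the interval with
the largest violation is discarded, and the test repeats; sampling is then
rerun on the repaired model. The greedy largest-violation order is
deterministic and each discard is certified by the elastic LP.
`rates_to_ci()` lets measured rates share this machinery — in the packaged
workflow, rate and MFA intervals are pooled into one repair pass, a
deliberate generalization of repairing MFA intervals alone.

# Hit-and-run sampling and the mixed-fraction diagnostic

`sample_fluxes()` runs a single artificial-centering hit-and-run (ACHR)
chain. Fixed reactions (bound width below $10^{-9}$) are eliminated; the
chain moves in the null space of the remaining stoichiometry, computed by
SVD, so $S v = 0$ holds by construction at every step and the retained
points re-anchor to the null-space coordinates to cancel round-off drift.
Warmup points are the per-reaction minimum and maximum vertices plus an
equal number of random-direction vertices; directions are drawn as (random
warmup point − running center), the step is uniform over the feasible
chord, and the center is updated as the running mean of the chain. One
point is retained every `n_steps` steps; the defaults, 5,000 points from
5,000 steps each, are the settings under which the knockout models were
characterized. A fixed seed yields a bit-identical sample (the kernel uses
its own 64-bit generator, so the chain does not perturb R's RNG stream).

Convergence is summarized by the mixed fraction: point $i$ is paired with
point $i + n/2$ in chain order, and for each non-constant reaction (sample
SD ≥ $10^{-12}$) the fraction of pairs lying on opposite sides of that
reaction's median is computed; the diagnostic is the mean over reactions.
Independent draws give 0.5; a chain whose second half replays its first
gives 0. On the packaged network under measured-rate constraints the
5,000 × 5,000 chain sits within a few thousandths of 0.5.

ACHR is not a provably uniform sampler, but on an axis-aligned box polytope
its marginals are indistinguishable from uniform by Kolmogorov–Smirnov
tests at the sizes used here, which is the property the test suite pins
down. Sampled points are serially autocorrelated; see the caveat on
permutation tests below.

# Differential flux, utilization and clustering

For two sampled conditions A and B, each entity is scored by

* **geometric fold-change**: $\mathrm{gfc} = \log_2\!\big(
  (\mathrm{GM}(|v_A|) + \varepsilon) / (\mathrm{GM}(|v_B|) + \varepsilon)
  \big)$ with $\varepsilon = 10^{-6}$ regularizing zero fluxes. Using
  magnitudes makes the statistic robust to sign flips of reversible
  reactions (a pure direction reversal gives 0, and shows up instead in
  the reported signed means); the statistic is antisymmetric in A and B.
* **permutation p-value** on $T = |\bar{v}_A - \bar{v}_B|$ with the
  add-one estimator $p = (1 + \#\{T^\pi \ge T\}) / (1 + n_\pi)$, default
  $n_\pi = 1000$, so $p \ge 1/(n_\pi + 1)$.

An entity is significant when $p < 0.05$ and $|\mathrm{gfc}| > 0.001$.
Entities are reactions, metabolites (per-point turnover
$t_i = \sum_j \max(0, S_{ij} v_j)$, i.e. total production, which equals
total consumption at steady state), or subsystems (per-point
$\sum_{j \in k} |v_j|$). At the reaction level, demand pseudo-reactions and
reactions in excluded subsystems (transport, porins, ion transport,
nucleotide salvage, oxidative phosphorylation, unassigned) are dropped
before testing. Fold-change profiles across conditions can be clustered
with average-linkage hierarchical clustering on Euclidean distances, with
rows pre-sorted by id for a deterministic dendrogram.

Sampled points are treated as exchangeable units by the permutation test,
as the sampling-based differential analysis it reproduces does implicitly.
Autocorrelation within the chain makes this anticonservative in principle;
the calibration tests draw i.i.d. nulls and verify nominal level there, and
chains at the default thinning (5,000 steps between retained points) are
close to independent. No multiple-testing correction is applied at this
stage by default; a Benjamini–Hochberg option (`adjust = "BH"`) is exposed.

# Knockout candidate ranking

Candidates are enzymatic reactions only (exchanges, demands and the biomass
objective are not knockout targets). The exclusion screen removes
reactions that are loop-involved, spontaneous, computationally essential
(knockout FBA growth below 1% of wild type, configurable), experimentally
essential or unexpressed (caller-provided sets), or that need more than one
genetic alteration to abolish (gene count > 1 — isozymes count per gene).
Survivors are ordered lexicographically by (1) mean |sampled flux|
(descending), (2) number of measurable neighbor metabolites (descending),
(3) gene count (ascending), with reaction id as the final tie-break; the
listed priority is taken from the order in which the criteria are stated.
A signed-flux variant is available (`signed_flux = TRUE`). The top 9 are
returned by default. The screen should be run against the base media model
(pass that as `model`), not the measurement-constrained copy: pinned
exchange rates would misclassify nearly every internal reaction as
essential, since any knockout shifts secretion patterns away from the
measured values.

# Metabolomics QC, imputation, glog and testing

`qc_filter_concentrations()` drops metabolites whose medium-blank
concentration exceeds 80% of the mean biological level, whose QC-sample
RSD is ≥ 50%, or whose per-group replicate RSD is ≥ 80% (the per-group
reading of "individual component" RSD; thresholds configurable). Filters
are idempotent.

`impute_missing()` is a bootstrap-EM multivariate-normal imputer on log
concentrations: biological samples are resampled with replacement, an EM
fit with ridge-regularized covariance (ridge $10^{-4}$ of the mean
variance) is run per bootstrap set, and each missing entry is filled with
the average over fits of its conditional mean given the sample's observed
metabolites. The default of 1000 bootstrap fits follows the convention of
bootstrap-EM imputation tools; tests use fewer for speed. Entries that
remain missing — metabolites observed in no biological sample — fall back
to half the metabolite's lower limit of quantification divided by the
sample's biomass.

`glog_normalize()` applies $g(y) = \log_2\!\big((y + \sqrt{y^2 +
\lambda})/2\big)$, which is exactly $\log_2 y$ at $\lambda = 0$, strictly
increasing, and invertible ($y = z - \lambda/(4z)$ with $z = 2^g$) to
within $10^{-9}$ over the dynamic ranges used here. `lambda = "auto"`
minimizes, over a grid scaled to the data (the squared lower-quartile
intensity times $10^{-4} \ldots 10^{4}$), the spread of log per-metabolite
variances — a simple variance-stabilization target rather than a
likelihood fit. `diff_metabolites()` then runs equal-variance Student
t-tests per metabolite with Bonferroni adjustment and an adjusted-p cutoff
of 0.01.

MID (mass isotopomer distribution) tables are QC-filtered channel-wise:
replicate RSD > 50% or blank/unlabeled signal > 80% drops a channel;
fractions must sum to one within 0.01 per fragment and replicate.

Growth rates are the OLS slope of $\ln(\mathrm{OD}_{600})$ versus time,
requiring 8 points by default and 4 in automated serial-passage mode.
Fitness trajectories interpolate (cumulative time, growth rate) knots with
a monotone cubic Hermite spline (Hyman filtering); non-monotone inputs are
first replaced by their isotonic regression, so the curve always
interpolates the monotone-adjusted knots. Replicate agreement uses
pairwise Pearson correlation on log values with a 0.95 pass threshold.

# Resequencing filters

`filter_mutations()` removes records with frequency < 0.1, p-value > 0.01,
quality < 6.0, or a gene matching the deny list (crl, insertion-element
genes, rhs/rsx loci; glob patterns). All comparisons are strict, exactly
as the rule is stated, so records at a threshold survive.
`call_duplications()` reports maximal runs of at least 200 consecutive
positions with depth strictly above twice the track-wide mean ("two times
greater" read as > 2×, configurable). The per-position rule presumes
coverage deep enough that a duplicated region rarely dips below the
threshold — at background depth 500× a 2.4× duplication breaks through
essentially everywhere, which is what the simulator emulates; at tens-fold
coverage the rule fragments and a windowed approach would be needed (out
of scope here).

# The synthetic network and what the generators do (and do not) emulate

`build_toy_network()` returns a 45-reaction, 35-metabolite model of
glucose-grown central carbon metabolism: upper glycolysis with a lumped
lower half, oxidative PPP (G6PDH, GND), reversible non-oxidative PPP,
a lumped Entner–Doudoroff route, TCA cycle with separate SUCDi and FRD,
glyoxylate shunt and anaplerosis, nitrogen assimilation from
2-oxoglutarate, lumped respiration, transhydrogenase, ATP maintenance, and
a biomass reaction over the canonical precursors. Two deletion phenotypes
are built in structurally: removing GND forces all 6-phosphogluconate
through the ED route and flips the non-oxidative PPP (transketolase /
transaldolase) fluxes from pentose-producing to pentose-consuming; removing
SUCDi (with FRD closed, the aerobic condition) leaves secretion as the only
fate of succinate, which the energy-limited optimum must produce. The
biomass ATP coefficient (100 mmol gDCW^-1^) and the lumped acetate-overflow
yield (0.5 ATP) were chosen so that growth is energy-limited at the
optimum, making both phenotypes hold for *every* optimal solution (verified
by flux variability at fixed optimal growth), not just for one arbitrary
vertex. Gene counts mirror E. coli isozyme structure (e.g. three fumarase
genes, two transketolases), which is what makes the multi-gene exclusion
meaningful.

Deliberate non-realism: cofactors are single lumped NADH/NADPH/ATP pools
with no protons, water or elemental balancing; respiration is one reaction;
the biomass composition is coarse. The network reproduces rerouting
*topology*, not E. coli flux values — passing tests show the pipeline
recovers planted structure from its own generators, not that it reproduces
any organism's measured fluxes.

The measurement simulators draw multiplicative log-normal noise
(concentrations, rates; the default rate CV of 0.05 is typical of
HPLC-derived physiology), latent-factor correlation across metabolites,
MCAR missingness, Poisson coverage, and always emit their ground truth
alongside the data, so every downstream stage has parameter-recovery tests.

# Numerical choices and degenerate inputs

* Steady-state tolerance $10^{-6}$, bound tolerance $10^{-9}$ (configurable
  in the validators); sampled points satisfy both by construction.
* A polytope that is a single point (all bounds fixed, or null space of
  dimension zero) makes `sample_fluxes()` return that point repeated, with
  a warning rather than an error.
* Quartiles use linear interpolation (R type 7), declared so summaries are
  comparable across tools.
* `mixed_fraction()` requires an even number (≥ 4) of points and errors on
  all-constant samples, where the diagnostic is undefined.
* Permutation p-values never return 0 (add-one estimator); two identical
  constant vectors return 1 directly.
* LP degeneracy: FBA reports an arbitrary optimal vertex; everything that
  must be robust to this (the knockout phenotypes above) is asserted
  through flux variability instead.

# Problem sizes in the packaged tests

The test suite samples the toy network at 600 points × 300 steps for
distribution-level checks and at the full 5,000 × 5,000 for the
convergence diagnostic; permutation calibration uses 1,000 replicates of
n = 50 per group at 499 permutations; metabolomics null calibration uses
40–60 simulated families. These sizes give stable Monte-Carlo margins
(3 standard errors) while keeping the whole suite under a minute of
sampling time.

# Known limitations

* The sampler is a single chain; between-chain diagnostics (potential
  scale reduction) are out of scope, and the mixed fraction is the only
  convergence summary reported.
* The permutation null ignores chain autocorrelation (see above).
* SBML import is minimal (L3 FBC bounds, stoichiometry, objective, gene
  counts); gene–protein–reaction boolean logic is reduced to a gene count
  everywhere in the package.
* The elastic repair is greedy; it certifies each individual discard but
  does not search for a globally minimal discard set.
* glog's automatic lambda is a grid heuristic, not the maximum-likelihood
  estimator of the originating transform.
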