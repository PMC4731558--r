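---
title: "Models and methods behind seapopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seapopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

seapopgen characterises the population structure and dispersal dynamics of a
marine invader sampled at multiple localities, combining mitochondrial
sequence statistics, microsatellite statistics, simulation-based inference of
introduction history, and biophysical larval-dispersal modelling. This
vignette explains the models implemented, the tunable parameters that matter,
the synthetic-data generator's assumptions, and the numerical choices made
where the design was genuinely open. Nothing here states an empirical result
that the package's tests do not themselves compute.

## Sequence statistics

**Haplotypes and diversity.** An alignment is collapsed to haplotypes by
exact string identity (`collapse_haplotypes()`); ambiguous characters are
kept as written and handled at the distance stage. Haplotype diversity is
Nei's sample-size-corrected `h = (n/(n-1))(1 - sum p_k^2)`; nucleotide
diversity is the frequency-weighted mean pairwise distance per site. Under
the default Hamming model, `pi` equals mean pairwise differences divided by
the alignment length; with a per-site model distance (p or TN93) the division
by `L` is dropped because the distance is already per site. Which convention
a given legacy program used for its printed `pi` is often unclear, so both
model options are exposed and Hamming is the default.

**TN93 with gamma rates.** `tn93_gamma_distance()` implements the
Tamura–Nei (1993) distance; with a finite gamma shape `alpha` every
`-log(w)` term becomes `alpha (w^(-1/alpha) - 1)`, recovering plain TN93 as
`alpha -> Inf`. Sites with `N` or `-` in either sequence are excluded
pairwise (pairwise deletion) — the module's documented policy for ambiguous
bases, since common usage does not pin one down. A non-positive logarithm
argument raises a saturation error rather than returning a negative or
complex distance. The default shape for differentiation statistics is
`alpha = 0.023`, a strongly heterogeneous rate profile typical of COI data.
Gamma shapes this small inflate distances sharply; because the fixation
indices are ratios of variance components, they are insensitive to the
common inflation, which is why the Hamming model gives nearly identical
Phi-ST on the same data.

**Phi-ST and AMOVA.** Differentiation uses the molecular analysis of
variance on *squared* model distances between individual sequences: for a
pair of populations, `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`
from the standard sums-of-squares decomposition; negative estimates are
retained and reported (they are the estimator's way of saying "less
between-population variance than expected under random mating"). The
three-level `amova_hierarchical()` adds a grouping layer and reports F_CT,
F_SC and F_ST with their conventional permutation schemes (whole populations
among groups for F_CT; individuals among populations within groups for
F_SC). All permutation p-values in the package use the positively biased
`(b+1)/(m+1)` estimator, one-sided in the direction of differentiation;
with heavily tied permutation distributions (small samples) this estimator
is conservative by construction.

**Demographic expansion.** `mismatch_distribution()` counts raw pairwise
site differences (mismatch theory is defined on observed differences, so no
model correction is applied). `fit_sudden_expansion()` least-squares fits
the three-parameter sudden-expansion curve

`F_i = F^eq_i(theta1) + exp(-tau (theta1+1)/theta1) sum_j (tau^j/j!)
(F^eq_{i-j}(theta0) - F^eq_{i-j}(theta1))`, `F^eq_i(theta) =
theta^i/(1+theta)^(i+1)`,

in log-parameter space with Nelder–Mead (the `theta1 > theta0` ordering is
enforced by parameterising `theta1 = theta0 + exp(s)`). Harpending's
raggedness is `sum (x_i - x_{i-1})^2` over the observed classes with one
empty class appended beyond the largest difference; raggedness conventions
differ between sources, so this one is fixed here and used consistently.
`p(SSD)` and `p(R)` come from a parametric bootstrap: coalescent samples of
the same size are simulated under the fitted two-epoch history, refitted,
and exceedance proportions reported.

**Neutrality tests.** Tajima's D uses the standard constants; its p-value
conditions on the observed number of segregating sites `S` (mutations are
placed multinomially on simulated neutral genealogies proportional to branch
length), sidestepping the unknown mutation parameter. Fu's Fs takes
`theta = pi` (the mean pairwise difference count), evaluates
`S' = P(K >= k_obs)` by the Ewens sampling formula with unsigned Stirling
numbers, and reports `Fs = ln(S'/(1-S'))`; its p-value simulates neutral
genealogies at that theta. Following the usual recommendation, pipeline
reports flag Fs as significant at the 0.02 level. The gamma shape used for
these significance simulations is not knowable from a published table, so
the tests condition on `S` (for D) and on `theta_pi` (for Fs) instead.

**Haplotype network.** `haplotype_mst()` builds the minimum spanning tree on
Hamming distances with Kruskal's algorithm and a deterministic
`(distance, lower index, higher index)` tie-break, so the tree weight is
invariant to input order and repeated runs are identical.

## Microsatellite statistics

Expected heterozygosity is Nei's unbiased `(2n/(2n-1))(1 - sum p^2)`;
`F_IS = 1 - Ho/He`. The Hardy–Weinberg test shuffles gene copies into new
diploid genotypes and recomputes F_IS; the one-sided heterozygote-deficit p
is the scientifically relevant tail (null alleles and inbreeding both push
it). The two-sided p is computed from `|F|` and is conservative whenever the
permutation distribution is skewed — which it typically is. The linkage test
is a permutation G-test on the genotype-by-genotype contingency table,
shuffling one locus within populations. Rarefied allelic richness uses the
exact hypergeometric rarefaction formula at `g` gene copies (default 34,
i.e. 17 diploid individuals, a common panel-wide minimum).

**Null alleles.** Two generating models are provided by the synthetic
module and matter for interpretation:

* `apply_null_alleles()` hides each gene copy independently with probability
  `r` — a *technical* dropout model. It biases heterozygosity but leaves
  allele frequencies essentially unbiased, so it barely biases theta.
* `apply_null_lineages()` designates whole allelic classes as null — the
  *genetic* model of a primer-site mutation carried by particular lineages,
  whose frequency drifts between populations like any allele. This is the
  phenomenon null-allele corrections were designed for, and the one that
  biases theta upwards.

`null_allele_em()` estimates the null frequency per locus and population by
EM under Hardy–Weinberg: observed homozygotes are apportioned between true
homozygotes and visible-null heterozygotes; blanks between null homozygotes
and technical failures. The failure probability `beta` is estimated by
default ("with blanks"), which is the right reporting model when panels
contain genuine amplification failures. Inside the ENA correction, however,
a free failure rate is confounded with frequent nulls (blanks are then
mostly null homozygotes), so `theta_fst_ena()` uses the
`estimate_failures = FALSE` variant; this measurably improves the corrected
estimator's accuracy when nulls are common.

**Theta and the ENA correction.** `theta_fst()` is the Weir–Cockerham
multi-allele, multi-locus estimator (per-allele variance components summed
over alleles and loci). `theta_fst_ena()` recomputes it after treating the
null as an additional allelic state with its EM frequency; because true
genotype composition is unobservable under nulls, the heterozygosity terms
use their Hardy–Weinberg expectations at the corrected frequencies. When
the estimated null frequency at a locus is negligible the genotype-based
(uncorrected) components are used unchanged, so the correction reduces to
the uncorrected estimator in null-free data.

**Bottleneck test.** For each polymorphic locus, coalescent samples are
simulated under the two-phase model (fraction `p_smm` single-step, the rest
geometric multi-step with the stated variance; the geometric parameter
solves `(1-q)/q^2 = variance`). The scaled mutation rate is tuned by
bisection so the expected allele count matches the observation, and only
simulations matching the observed count exactly are retained, yielding the
equilibrium-heterozygosity distribution. The one-tailed Wilcoxon signed-rank
test across loci (exact, since panels here have few loci) flags
heterozygosity excess. Defaults sit mid-range of the conventional settings:
80% stepwise, variance 20.

## ABC scenario choice

Invasion scenarios are rooted trees of population splits without migration
(introduction histories have no recurrent-migration term). The shipped
library (`invasion_scenarios()`) contains four global topologies contrasting
candidate native regions and two regional topologies contrasting a
south-to-north colonisation of a brackish marginal sea with a Ponto-Caspian
origin of its northern part; they are schematic reconstructions of the kinds
of histories tested for invasive barnacles. Priors are independent uniforms
(Ne 1e4–1e5 for sequence runs and 1e4–2e5 for microsatellite runs; split
times 10–10,000 generations; mutation rates 1e-8–1e-6 per site for
sequences and 1e-4–1e-3 per locus for microsatellites); draws violating the
scenario's ancestry ordering are rejected and redrawn, ties allowed so
degenerate point priors remain drawable. Whether split-time priors are
shared or independent across scenarios is a free choice; independent
uniforms are used.

Summary statistics follow the conventional marker-specific sets: per
population, mean allele number and expected heterozygosity (microsatellites)
or haplotype number and mean pairwise differences (sequences); per pair,
F_ST plus Goldstein's `dmu2` (squared difference of mean allele size in
repeat units) or F_ST plus mean between-population differences. Monomorphic
realisations would leave pairwise F_ST undefined; they are encoded as 0 so
the statistic vector keeps a fixed schema for regression. `abc_posterior()`
standardises statistics by the reference table's moments, retains the
closest fraction (default 1%), and fits a weighted polychotomous logistic
regression (Epanechnikov weights in the distance; a small ridge penalty to
survive collinear statistics) evaluated at zero difference; the raw
rejection frequencies are reported alongside and are the fallback if the
regression fails. `prior_predictive_check()` locates the observation
relative to the simulated cloud before any model choice is trusted.

## The coalescent engine

One serial Kingman coalescent underlies sequence simulation, microsatellite
simulation, neutrality-test p-values, the expansion bootstrap and the
bottleneck test: gene copies coalesce at rate `C(k,2)/(2 Ne)` per generation
within each population, merge instantaneously at split events (equal-time
events are processed deepest-first so a population always empties before its
own origin), and piecewise-constant size changes are supported. The same
`2 Ne` gene-copy scaling is used for both markers, so
`E[pi] = 4 Ne mu L` for sequences and the strict stepwise model obeys
`He = 1 - 1/sqrt(1 + 2 theta)`; the smaller effective size of mtDNA is
absorbed into its Ne priors rather than hard-coded. Mutations are placed on
branches as Poisson events: for sequences at a uniform per-site rate scaled
by a per-site gamma multiplier drawn once per simulation (the "+G"
convention), the replacement base drawn from the TN93 exchange
probabilities conditional on the current base — a mutation-and-transition
scheme chosen so the per-site rate is base-independent and the theta
calibration above holds exactly; for microsatellites as geometric +/- steps
(`p_gsm = 0.78` by default, i.e. mean step ~1.3 repeat units) reflecting at
±40 repeat units around the ancestral size to keep allele sizes bounded and
GENEPOP-encodable. A slower, list-based reference implementation of the
genealogy simulator is retained internally and cross-checked against the
fast one in the test suite.

## Synthetic seascape

`make_velocity_field()` builds a rectangular shelf basin (default 40 x 30
cells at 3.7 km, a 2-cell land frame, a shallow coastal shelf and a deeper
interior) and a time-varying flow derived from a discrete stream function:
an oscillating basin-scale double gyre (amplitude 1200 m^2/s, period 10
days) plus three low-order Fourier eddy modes with random phases and periods
(relative amplitude 0.9). Velocities are central differences of the stream
function, which makes the same central-difference divergence vanish exactly
at interior water nodes; land cells carry zero velocity. The regime is
deliberately eddy-dominated with near-zero time-mean flow and coastal speeds
of a few cm/s — the situation in which larvae make excursions in both
directions along the coast and minimum (two-way) connectivity is a
meaningful quantity. Habitat is laid out as seven localities of ten cells
(5 x 2) along the shallow coastal strip, excluding cells deeper than 100 m.

What this generator does *not* emulate: real bathymetry and coastline
geometry, salinity-driven circulation, vertical larval behaviour, seasonal
stratification, or inter-annual forcing. Passing tests therefore demonstrate
that the estimators and the tracking/connectivity machinery are correct and
well calibrated on data with the assumed statistical structure — not that
any particular real seascape behaves like the synthetic one.

`advect()` integrates particles with classical RK4 at the tracking step
(15 min by default; tests use coarser steps since the fields are smooth),
bilinear in space and linear in time. Releases are spread over the
localities' cells and a sequence of release times spanning one gyre period
(so both current directions are sampled); each particle draws an independent
uniform pelagic larval duration in [20, 30] days and settles wherever it is
when that duration expires — an end-of-PLD rule rather than
first-contact-with-habitat, matching the convention of counting end
positions. Land encounters are resolved free-slip (the along-shore component
of a step is kept; a dead-end holds the particle). Connectivity divides
endpoint counts by particles released, so rows are sub-stochastic and
`1 - rowsum` is the lost fraction. Multi-generation stepping-stone
connectivity is the matrix power `C^G` (all routes summed), computed by
repeated squaring; min-symmetrization `min(C_ij, C_ji)` makes it comparable
with symmetric genetic distances, the minimum being the two-way exchange a
pair actually sustains.

## Seascape correlation and the end-to-end experiment

`mantel()` correlates off-diagonal elements under joint row/column
permutation, one-tailed by default in the hypothesised direction (positive
for isolation-by-distance, negative for connectivity) with the two-tailed
version available; connectivity enters raw by default, with a log option.
`simulate_metapopulation()` provides the generative counterpart: allele
frequencies drifting in demes of size Ne with per-generation migration
proportional to a supplied connectivity matrix, genotypes sampled under
Hardy–Weinberg at the end.

The end-to-end experiment in the acceptance suite wires these together: a
synthetic flow field yields single-generation connectivity, its
min-symmetrized 16-generation product S — the quantity the correlation
analysis itself treats as the gene-flow proxy — drives a metapopulation
(Ne 300, 120 generations, 16 loci, 25 diploids sampled per deme), and
linearized pairwise theta is then correlated with S and with along-coast
shipping distances (random legs of 120–420 km). Because the eddy-dominated
flow decouples exchange from simple alongshore distance, the connectivity
Mantel correlation should exceed the distance correlation in magnitude in
most runs — the regional pattern this kind of seascape analysis is designed
to detect. With a strongly distance-like flow the two covariates would be
confounded and no method could separate them.

## Problem sizes and numerical choices

Simulation-based checks in the test suite run at deliberately modest sizes
chosen to keep Monte-Carlo error well inside the asserted bounds: 150–300
replicates for calibration checks, 100 replicates for estimator-comparison
experiments, 10,000 simulations per scenario for the ABC recovery
experiment, 200 particles per locality and 3-hour tracking steps for
dispersal runs, and 20 independent seeds for the end-to-end experiment.
Degenerate inputs are handled explicitly throughout: monomorphic loci give
`He = 0` with flagged F_IS, `S = 0` leaves Tajima's D undefined rather than
zero, constant matrices give a flagged NA Mantel correlation, fixation
indices at 1 map to infinity under linearization, and permutation p-values
never return 0. Ties in the MST and in equal-time split events are broken
deterministically as described above.
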