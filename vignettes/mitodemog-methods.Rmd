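---
title: "Models and methods behind mitodemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitodemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitodemog` reimplements, as one coherent package, the demographic
analysis chain routinely applied to mitogenome haplogroup data with
DnaSP, Arlequin and PopART: diversity summaries, neutrality tests,
sudden-expansion mismatch analysis, time conversion under time-dependent
rates, and median-joining networks. This vignette records the models, the
parameter conventions, the numerical choices, and the places where the
design was genuinely open.

## Data model and missing-data conventions

An alignment is a rectangular n × L character matrix over the IUPAC DNA
alphabet. Only unambiguous bases (A, C, G, T) ever contribute to a
statistic: gaps, N and ambiguity codes are treated as missing, never as
partial matches — the conservative convention shared by DnaSP and
Arlequin. Difference counting supports two policies: *pairwise deletion*
(default; a site is skipped only for the pairs it is missing in, matching
DnaSP's Table-style summaries) and *complete deletion* (a column with any
missing symbol is dropped for all pairs). For gap-free data the identity
π·L/100 = K holds exactly under either policy, and the test suite asserts
it. Column cleaning (`clean_columns`) offers *drop-gap-columns* (the
mitogenome workflow that produces a 16,038-column matrix) and the stricter
*drop-gap-or-ambiguous-columns*; since the original workflow's handling of
ambiguity is not documented, both are exposed and the choice is echoed in
reports. Coordinates are 0-based half-open internally and 1-based in every
user-facing report.

## Diversity statistics

`summarize_diversity` reports n, H, Hd, S, π (%) and K. Hd uses the
sample-size-corrected estimator (n/(n−1))(1 − Σpᵢ²). S counts columns with
at least two distinct *unambiguous* bases, so columns varying only in
gaps or Ns never contribute. π is the mean per-pair fraction of differing
effective sites, reported in percent to mirror the conventional table
layout; K is the raw mean difference count. Under complete deletion
π = 100·K/L is an exact identity.

## Neutrality tests

Tajima's D follows the 1989 constants (a₁…e₂). It requires n ≥ 4 (the
variance degenerates below that) and S ≥ 1; a monomorphic input is an
explicit `undefined statistic` error rather than NaN.

Fu's Fs sets θ̂ = K and computes S′ = Pr(H ≥ H_obs) under the Ewens
sampling distribution. Rather than evaluating unsigned Stirling numbers
(which overflow doubles near n ≈ 170), the allele-count distribution is
built by the sequential (Chinese-restaurant) recurrence
P(n+1, h) = P(n, h)·n/(θ+n) + P(n, h−1)·θ/(θ+n), which is exact and
stable for any n. The test suite validates it against two independent
oracles: Stirling numbers from polynomial expansion of the rising
factorial (n ≤ 8) and exhaustive permutation cycle counts (n ≤ 6).

Significance is assessed by simulating the package's own constant-size
coalescent null with matched n and θ set to observed K — conditioning on
the θ estimate, as in Fu's construction and Arlequin's test — and taking
lower-tail p-values, the direction in which expansion pushes both
statistics (a two-sided option exists). Fu's recommendation to call Fs
significant at the 5% level only when p < 0.02 is exposed as `fu_rule`
but defaults off, since the original table's marking rule is not stated;
the report records which rule was active.

## The sudden-expansion model and its fit

The observed mismatch distribution is the histogram of pairwise
difference counts over classes 0..d_max. The model expectation is the
Rogers–Harpending transient

F_j(τ, θ₀, θ₁) = F̂_j(θ₁) + e^(−τ(θ₁+1)/θ₁) Σ_{i=0}^{j} τ^(j−i)/(j−i)! (F̂ᵢ(θ₀) − F̂ᵢ(θ₁)),
F̂_j(θ) = θʲ/(θ+1)ʲ⁺¹.

Numerically the Poisson weights are evaluated as `dpois(j−i, τ)` with the
residual factor e^(−τ/θ₁), so nothing overflows even at θ₁ = 10⁵ and
large τ; equilibrium terms are computed in log space. The transcription
of the formula is verified two ways in the tests: the τ = 0 and τ → ∞
limits reduce to the equilibria at θ₀ and θ₁, and — the decisive check —
the mean simulated mismatch distribution over 5,000 coalescent draws at
(τ = 5, θ₀ = 0.5, θ₁ = 200) matches the closed form within three Monte
Carlo standard errors per class.

Fitting minimises the plain SSD between observed frequencies and the
model over classes 0..d_max, with the model's tail mass folded into the
last class so both sides remain normalised. (Whether the original
workflow used plain or generalised least squares is not stated; plain SSD
is the quantity its test statistic is defined on.) The optimiser is
derivative-free Nelder–Mead on log-transformed parameters from 8
deterministic multi-starts spread around the moment initialisation
τ₀ = mean of the distribution; θ₁ is parameterised as θ₀ + e^x so the
ordering θ₀ ≤ θ₁ holds by construction, and is capped at 10⁵ —
effectively infinite, where the SSD surface is flat for expansion-shaped
data. Noiseless self-consistency (feeding the model's own output back)
recovers τ to within 2%.

The raggedness index uses Harpending's closed convention
r = Σ_{i=1}^{d+1} (xᵢ − xᵢ₋₁)² with the terminal zero x_{d+1} = 0; the
convention is stated explicitly because published implementations differ
on the boundary term.

The parametric bootstrap simulates `reps` coalescent datasets under the
fitted parameters with matched n, re-fits each, and reports
p_SSD = Pr(SSD* ≥ SSD_obs) and p_r = Pr(r* ≥ r_obs); a non-significant
p_SSD means the expansion model is not rejected. The τ interval is the
percentile interval of the replicate estimates (level 0.95 by default —
the published tables print intervals without stating a level). A
percentile interval is not guaranteed to contain the point estimate, so
the interval is widened to include it when necessary; this at most
lengthens one end. Replicates whose re-fit fails are dropped and counted,
with more than 20% failures aborting the run. The production default is
1,000 replicates; the test suite scales to 100–200 for runtime and says
so where it does.

## Chronology

T = τ/(2μk) converts mutational time to years; the generation-time form
t = τ/(2uk), u = μg is documented but g cancels in T = t·g, so the
package carries g as metadata only. k defaults to the analysis alignment
length (16,038 for the study-scale data) and is echoed in every report
because T depends on it. The rate ledger is a small editable table of
(locus, tier, rate, window, alternative): ancient (>100 ky) Cytb 3.0×10⁻⁸
and mitogenome 2.4×10⁻⁸ (the 80% locus scaling, `calibrate_locus_rate`),
intermediate (50–60 ky) 4.7×10⁻⁸, recent (<20 ky) 1.1×10⁻⁷ with the
scaled 0.9×10⁻⁷ and the high literature alternatives 2.0×10⁻⁷ and
4.0×10⁻⁷ flagged as alternatives that `rate_for_age` never auto-selects.
Ages falling between windows (e.g. 20–50 ky) raise an explicit coverage
error: the ledger defines no rate there and interpolating would invent
one.

A reproduction note: converting the published τ values at k = 16,038
reproduces the printed expansion times at the 1.1, 2.0 and 4.0 ×10⁻⁷
rates for most rows exactly, but the 0.9×10⁻⁷ column (and a few isolated
cells) cannot be reproduced from T = τ/(2μk) with any consistent rounding
(e.g. 3306 printed where the formula gives 3299, plausibly from an
unrounded 0.88×10⁻⁷ or unrounded τ). The package reports the formula
value; the acceptance tests assert only the reproducible cells and
document the deviating ones.

## Median-joining networks

Characters are the variable alignment columns treated as multistate DNA.
The construction alternates two steps to fixation: (1) the ε-relaxed
minimum spanning network — a link {u, v} is kept iff d(u, v) ≤ δ(u, v) + ε,
where δ is the level at which u and v first become connected in a
Kruskal sweep; (2) quasi-medians of triplets with at least two network
links are generated (majority state per column; columns where all three
states differ expand combinatorially, capped at three such columns per
triplet), and the candidates with minimal connection cost
d(u,m)+d(v,m)+d(w,m) (within ε) are inserted. Obsolete median vectors —
unsampled nodes of degree ≤ 2, or not on any minimal path between
observed haplotypes — are pruned at the end, so surviving medians have
degree ≥ 3. Determinism comes from processing haplotypes in lexicographic
order of their variable-site strings. ε defaults to 0. Node-for-node
concordance with PopART is not claimed: PopART applies its own
pre-filtering defaults that are not documented in the original analysis.

The star-likeness score is the fraction of observed haplotypes one edge
step from the network's central (maximum-degree) node, ties broken
observed-first. Centrality, not multiplicity, defines the centre
deliberately: under a sudden expansion at mutational age τ the ancestral
haplotype is sampled with probability ≈ e^(−τ/2) (about 2% at τ = 8) and
almost always enters the network as a reconstructed median hub instead.
Scoring adjacency to the modal *observed* haplotype would therefore
*fall* under expansion — the simulation comparison in the test suite
(τ = 8, θ₀ = 0.5 versus constant θ = 8, n = 30) measures 0.77 vs 0.34
for the hub definition and an inverted 0.13 vs 0.22 for the modal one.
A perfect star still scores exactly 1 and a path scores below 1.

## The coalescent simulator: what it emulates and what it does not

Units are chosen so the simulator and the analytic model share a
parameterisation: time is mutational, mutations fall at rate 1/2 per
lineage per unit, and the coalescence rate for i lineages is
i(i−1)/(2θ(t)) with θ(t) = θ₁ for t < τ and θ₀ beyond. Then θ is exactly
the expected pairwise difference at equilibrium, τ is the mismatch crest,
and no generation time or per-site rate enters. Consequences used by the
tests: E[K] = θ for constant size, E[K] = τ + θ₀ for a hard expansion,
and the mean mismatch distribution converges to the closed form.

One parameter-surface wrinkle: with τ = 0 the epoch rule makes θ₀ govern
all of history, which matches the analytic model's τ = 0 limit
(equilibrium at θ₀) but reads oddly against "constant size at θ₁".
`sim_config` therefore accepts a single `theta` that sets both epochs, so
constant-size configurations are unambiguous.

Mutations follow the infinite-sites idealisation placed onto L concrete
positions: each mutation takes a distinct uniformly chosen site of an
all-A ancestor (collisions avoided by drawing without replacement —
equivalent to redrawing) and a uniform alternative base. This is
deliberate: the mismatch model itself assumes infinite sites, and at
study scale (L = 16,038, θ and τ of order 10) collisions are negligible.
A simulated mutation count above L/10 warns, above L errors. What the
generator does *not* emulate: recurrent/parallel substitution,
rate heterogeneity across sites, base-composition bias, recombination,
selection, and population structure. A green test therefore establishes
correctness of the statistics and estimators under the model's own
assumptions, not robustness to homoplasy in real mitogenomes — at these
divergence levels that approximation is the standard one.

The fixture panel mimics the study's expansion-flagged groups: n = 13,
24, 11 with the printed τ values as truth; the strong expansions use
θ₀ = 0.5 and θ₁ = 10⁵ (Arlequin's effectively-infinite convention), the
weak-signal scenario a mild contrast (θ₀ = 2, θ₁ = 30). These were fixed
once from the published group sizes and estimates, not adjusted against
test outcomes.

## Pipeline and provenance

`run_analysis` composes the stages per group, skipping groups that fail a
precondition (n < 2 for diversity; n < 4, S = 0 or a degenerate mismatch
histogram for demography) with the reason logged, never silently. Each
group draws a deterministic seed derived from the base seed, every report
carries the seed, rate ledger and k used, the demography table is checked
on every run against T = τ/(2μk), and no output carries a timestamp, so a
re-run with the same config is byte-identical. The config dialect is JSON
(no YAML parser is assumed on the host); CLI flags override config keys.

## Known limitations

- Fs for very large samples relies on θ̂ = K; alternative θ estimators are
  not offered.
- The MJ implementation caps quasi-median expansion at 3 three-state
  columns per triplet; pathological data with many such triplets may
  yield a sparser median set than full quasi-median closure would.
- The bootstrap τ interval is percentile-based; BCa or basic intervals
  are not implemented.
- No spatial-expansion mismatch model, no Bayesian skyline, no Bayesian
  node dating: these are outside the package's scope.
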