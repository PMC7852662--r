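# mitodemog

Demographic inference from mitochondrial-genome haplotype alignments.

`mitodemog` is aimed at phylogeographers who work with whole-mitogenome
(~16 kb) haploid alignments partitioned into haplogroups and who want to
ask, per group: *has this lineage undergone a recent sudden population
expansion, and when did it start?* The package implements the classical
analysis chain end to end:

- **Diversity statistics** per group: sample size *n*, haplotype count
  *H*, haplotype diversity *Hd* = (n/(n−1))(1 − Σpᵢ²), segregating sites
  *S*, nucleotide diversity *π* (reported in %), and the mean number of
  pairwise differences *K*.
- **Neutrality tests**: Tajima's *D* = (K − S/a₁)/√(e₁S + e₂S(S−1)) and
  Fu's *Fs* = ln(S′/(1−S′)) with S′ = Pr(H ≥ H_obs | θ̂ = K) under the
  Ewens sampling distribution, both with lower-tail p-values from a
  constant-size coalescent null simulated by the package itself.
- **Mismatch distributions** and the sudden-expansion model
  (Rogers–Harpending): the transient distribution
  F_j(τ, θ₀, θ₁) = F̂_j(θ₁) + e^(−τ(θ₁+1)/θ₁) Σᵢ τ^(j−i)/(j−i)! (F̂ᵢ(θ₀) − F̂ᵢ(θ₁)),
  fitted by least squares (SSD), with a parametric bootstrap for the SSD
  goodness-of-fit test, Harpending's raggedness index *r*, and a
  percentile confidence interval for τ.
- **Chronology**: T = τ/(2μk) converts mutational time to calendar years
  under a tiered, time-dependent rate ledger (ancient 2.4×10⁻⁸,
  intermediate 4.7×10⁻⁸, recent 1.1×10⁻⁷ / 0.9×10⁻⁷, alternative high
  2.0×10⁻⁷ and 4.0×10⁻⁷ substitutions/site/year), plus strict-clock
  divergence dating T = d/(2μ) and the 80% between-locus rate scaling.
- **Median-joining networks** (Bandelt–Forster–Röhl) over the variable
  sites, with inferred median (Steiner) vectors, ε-relaxation, and a
  star-likeness diagnostic for expansion-shaped genealogies.
- **A coalescent simulator** for constant-size and two-epoch
  sudden-expansion demographies, parameterised so that θ is the expected
  pairwise difference at equilibrium and τ is the mismatch crest — the
  same units as the analytic model. It backs the parametric bootstrap,
  the neutrality null, and the entire test suite.

## Worked example

Simulate a study-like expansion scenario (n = 13 mitogenomes, true
τ = 9.523, 16,038 sites) and push it through the whole chain:

```r
library(mitodemog)
panel <- make_fixture_panel("panel", seed = 20)
aln <- clean_columns(read_fasta_alignment(file.path(panel[1], "alignment.fasta")))

summarize_diversity(aln)
#>    n  H Hd  S Pi_percent        K
#> 1 13 13  1 61 0.06443031 10.33333

neutrality_test(aln, reps = 200, seed = 20)
#> Tajima's D = -2.137 (p = 0.005)**
#> Fu's Fs    = -5.590 (p = 0.005)**
#> null: constant-size coalescent, theta = K, 200 reps, lower tail

mm  <- observed_mismatch(pairwise_differences(aln))
fit <- bootstrap_expansion_test(aln, fit_sudden_expansion(mm),
                                reps = 200, seed = 21)
fit
#> sudden-expansion fit: tau = 9.086, theta0 = 1.295, theta1 = 1e+05
#>   SSD = 0.00541 (p = 0.84), raggedness r = 0.01249 (p = 0.88)
#>   tau 95% CI: (6.497, 13.831); bootstrap reps = 200
#>   expansion model not rejected

expansion_time_table(fit, k = 16038)
#>      rate T_years T_ci_low T_ci_high     k      tau
#> 1 9.0e-08    3147     2251      4791 16038 9.085896
#> 2 1.1e-07    2575     1841      3920 16038 9.085896
#> 3 2.0e-07    1416     1013      2156 16038 9.085896
#> 4 4.0e-07     708      506      1078 16038 9.085896

build_mj_network(collapse_haplotypes(aln))
#> haplotype_network: 18 nodes (13 observed, 5 median), 17 edges, epsilon=0
#>   star-likeness 0.462, reticulations 0, max degree 7
```

Reading the output: every sampled genome is a distinct haplotype
(*Hd* = 1) yet *K* is modest relative to *S* — both neutrality tests are
strongly negative and significant, the classic expansion signature. The
mismatch distribution is smooth and unimodal (small raggedness, SSD
p ≫ 0.05: the sudden-expansion model is *not* rejected), the fitted
τ̂ = 9.09 brackets the simulated truth (9.523) inside its bootstrap CI,
and at the recent mitogenome rate (1.1×10⁻⁷ substitutions/site/year) the
expansion dates to roughly 2.6 thousand years ago. The MJ network is
reticulation-free with a high-degree hub — star-like, as expected for a
rapid expansion.

The same chain runs from the command line over a FASTA + metadata pair:

```sh
inst/cli/mitodemog run-all --alignment aln.fasta --metadata meta.tsv \
    --out results --seed 1 --reps 1000
```

which writes `diversity.tsv` (group, n, H, Hd, S, Pi_percent, K),
`demography.tsv` (D, Fs, τ with CI, SSD, r, their p-values, and one time
column per rate), network exports (GraphML/NEXUS/TSV), a run log and a
JSON manifest.

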