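---
title: "Probabilistic deconvolution of sequenced MH and STR mixtures"
author: "mixdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic deconvolution of sequenced MH and STR mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixdeconv)
```

# The problem

A crime-scene DNA sample often contains material from more than one person.
Massively parallel sequencing of forensic marker panels returns, per locus,
read counts over observed alleles; *mixture deconvolution* is the inference
of each contributor's genotype from those counts, together with an estimate
of the fraction of template each contributor supplied. Two marker classes
compete for this job: short tandem repeats (STRs), whose alleles differ in
the copy number of a 3–5 bp motif and whose amplification produces stutter
artefacts one repeat below each true allele, and microhaplotypes (MHs),
short amplicons carrying two or more SNPs whose phased combination defines
the allele. MH alleles are all the same length and produce no stutter, which
should make mixed MH profiles easier to interpret than mixed STR profiles.

`mixdeconv` implements a complete simulation study of that comparison:
synthetic panels and cohorts, read-level mixture construction, allele
calling, per-panel calibration, probabilistic genotyping with
likelihood-ratio (LR) evidence evaluation, and scoring of deconvolutions
against the known contributors. Because the single-source read sets and
allele frequencies behind the original cohort study are not public, the
package ships a synthetic-data generator whose outputs have the statistical
structure such data exhibit; every downstream method is exercised against
that generator under known truth.

# The generative model of single-source reads

`generate_reads()` emits exactly `total_reads` error-free amplicon reads for
one individual. The expected read count of allele $a$ at locus $\ell$ is

$$E[y_{\ell a}] \propto e_\ell \cdot \frac{c_a}{2} \cdot
  \exp(\varepsilon_a) \cdot \exp(-\lambda r_a),$$

where $e_\ell$ is the locus amplification efficiency (log-normal across
loci, mean 1), $c_a \in \{1, 2\}$ the allele copy number,
$\varepsilon_a \sim N(0, \sigma^2)$ a per-allele heterozygote-imbalance
term, and for STRs $\lambda$ attenuates long alleles with repeat number
$r_a$ (longer alleles amplify and sequence less efficiently). Each STR
parent allele sheds a fraction $s_\ell$ of its expected reads to the
sequence one repeat shorter (back stutter); $s_\ell$ is a per-locus truth
parameter in $[0.02, 0.10]$. Noise alleles — callable sequences absent from
the genotype — arrive per locus as a Poisson process with rate
`noise_rate`, with read counts $1 + \mathrm{Geom}(p)$. Geometric counts
have a memoryless tail, so the noise that survives any analytical threshold
is still geometric with the same $p$ — the property the calibration
estimator relies on. Realised counts are one multinomial draw over all
categories, so totals are exact and counts are jointly consistent.

Defaults are the package's committed study conditions: 74 MH loci at
370,000 reads/sample and 26 STR loci at 220,000 reads/sample (the depths of
the emulated assays), 2–5 SNPs per MH amplicon of 200–300 bp, reference STR
runs of 5–30 motif copies, $\sigma = 0.15$, $\lambda = 0.015$ per repeat,
`noise_rate` 0.5/locus and $p = 0.1$. Allele frequencies are symmetric
Dirichlet(1) over the locus allele universe (6 MH haplotypes, 8 STR
alleles per locus by default) and genotypes are drawn under Hardy–Weinberg
equilibrium (HWE). None of these values were taken from the emulated
cohorts — they are not published — so the generator is calibrated to
qualitative behaviour (uneven frequency spectra, visible locus and
heterozygote imbalance, minority stutter, sparse noise), not to any
laboratory's numbers.

What the generator deliberately does not emulate: PCR error and chimeras,
base-call errors (qualities are a constant placeholder), $n{+}1$ or
double-back stutter, degradation, and inter-run effects. Passing tests
therefore show that the inference machinery is correct under its stated
model, not that the model captures every artefact of real sequencing.

# Mixtures

`mix_reads()` reimplements read-level mixture simulation: from each
single-source FASTQ the apportioned number of reads is drawn without
replacement and the union is shuffled, all seeded. Apportionment is
largest-remainder rounding (ties to the earlier contributor), the rule that
maps a 9:1 mixture of 370,000 reads to 333,000 + 37,000 and always sums
exactly. The design grids mirror the study: all $\binom{10}{2} = 45$ donor
pairs per ratio at 19:1, 9:1, 3:1 and 1:1, and 56 triples per ratio at
14:5:1, 14:3:3 and 9:9:2. Ten donors admit $\binom{10}{3} = 120$ triples
and the emulated study does not say which 56 it used; we take the first 56
in lexicographic order of the sorted id triples and record them in the
design manifest. Role assignment within a pair or triple is lexicographic
for the same reason.

# Allele calling

Because simulated reads are error-free, the full alignment machinery of
production MH/STR typing tools reduces to exact amplicon matching:
an MH read must match its locus reference everywhere outside the variant
positions and configured *ignored positions* (masked, unreliable bases),
and its allele is the concatenated variant-position bases; an STR read must
match both flanks exactly, and the enclosed region is run-length encoded
into bracketed nomenclature (`[ATCT]2 ATGT [ATCT]8`). Anything else is
counted unassigned. Alleles below the analytical threshold (AT) of 11 reads
are moved to a below-threshold audit slot; the threshold is *retain iff
count ≥ 11*, and the boundary is tested explicitly. A configuration hook
excludes loci wholesale, mirroring the practice of dropping markers that
are too imbalanced to type reliably. The AT is applied at calling time in
both calibration and deconvolution, which keeps the two phases consistent.

# Calibration

Calibration consumes single-source samples with known genotypes. Every
retained allele receives a *dose*: 0 if absent from the genotype, 1 per
heterozygous allele, 2 for a homozygote's allele. From the dosed data we
estimate:

* **Locus efficiency** $\hat e_\ell$: the locus's mean share of a sample's
  assigned reads, scaled to mean 1 across loci.
* **Dispersion** $\hat\theta$: method-of-moments negative binomial
  overdispersion of genotype-allele counts about
  $\hat\mu_s \hat e_\ell \cdot \mathrm{dose}/2$, pooled over samples
  ($\hat\mu_s$ = sample reads per locus). This absorbs heterozygote
  imbalance and any residual model misfit.
* **Noise**: the rate of dose-0 non-stutter alleles per locus-sample, and
  the geometric parameter fitted by maximum likelihood to their counts
  above the AT ($\hat p = 1/(1 + \overline{y - \mathrm{AT}})$).
* **STR stutter**: per locus, a linear model of the stutter *proportion*
  $y_{n-1}/(y_{n-1} + y_{\mathrm{parent}})$ against parent repeat number,
  with a panel-pooled fallback when a locus has fewer than three
  informative points. Stutter-product counts are read from the full count
  table including below-threshold rows; restricting to retained counts
  would truncate small stutters and bias the proportion upward. Predicted
  proportions are clamped to $[0, 0.5)$.

The estimators are symmetric functions of the samples, so calibration is
invariant to sample order. The model persists as JSON (language-neutral
and diffable, unlike a binary serialisation); loading validates a schema
tag and the model invariants.

# The mixture likelihood

The deconvolution core follows the quantitative-model lineage of
sequencing-aware probabilistic genotyping: read counts, not just allele
presence, enter the likelihood. For contributors $k = 1, \dots, K$ with
proportions $\omega$ (on the simplex), depth parameter $\mu$ (expected
reads per locus unit) and dispersion $\theta$, the expected count of allele
$a$ at locus $\ell$ under a joint genotype set $G$ is

$$E_{\ell a} = \mu \, \hat e_\ell \sum_k \omega_k \frac{c_{ka}(G)}{2},$$

redistributed for STRs by the calibrated stutter proportion (each parent
keeps $1 - s$, the $n{-}1$ sequence gains $s$ of the parent's expectation).
Observed counts are negative binomial with mean $E_{\ell a}$ and variance
$E + \theta E^2$. A genotype may propose the drop-out symbol Q in place of
an unobserved allele: all Q copies at a locus pool into one category whose
expectation contributes $P(Y < \mathrm{AT})$ — the probability the allele
fell below the threshold — which ties drop-out coherently to the AT.
Likewise a concrete genotype allele that was not retained contributes its
own below-threshold probability. Retained alleles that no genotype or
stutter explains are noise: their number is Poisson(`noise_rate`) and each
count follows the calibrated geometric law above the AT. With
`noise_rate = 0` an unexplained allele makes the locus impossible, which is
how a hypothesis can reach likelihood zero and an LR of $-\infty$
(reported explicitly, never silently clamped).

Unknown contributors are marginalised by exact enumeration of all unordered
genotype pairs over the observed alleles plus Q — $(A+1)(A+2)/2$ genotypes
per contributor — with HWE priors; Q carries the residual frequency
$\max(1 - \sum_a f_a,\ 5/2N)$ and alleles missing from the frequency table
receive the minimum-allele-count floor $5/2N$. Enumeration is capped at the
8 highest-count alleles per locus (beyond that the joint space for three
unknowns is excessive and the discarded alleles are far below any
plausible genotype's expectation); the cap is a documented approximation
that the default generator never reaches.

# Fitting, deconvolution, likelihood ratios

`fit_mixture()` maximises the product over loci of the
genotype-marginalised likelihood over $(\omega, \mu, \theta)$. The
optimiser is deliberately deterministic: a fixed 10%-step grid on the
ordered $\omega$ simplex supplies starts (with $\mu_0$ = observed reads per
locus and $\theta_0$ from calibration), the best two starts are refined by
Nelder–Mead on log-transformed parameters (relative tolerance $10^{-10}$),
and no randomness enters fitting. Identical inputs therefore give identical
fits — which is also why the degenerate comparison of a hypothesis with
itself yields an LR of exactly 1. Contributors are reported in descending
$\omega$ order; exact ties keep enumeration order.

`deconvolute()` fits the all-unknown hypothesis (the same hypothesis on
both sides, as when a mixture is deconvoluted without a suspect), then
computes each contributor's marginal genotype posterior per locus at the
fitted parameters. The top genotype is reported with its posterior; a call
is *determinate* only if the posterior is not below 0.9 — strictly-below is
Undetermined, exactly 0.9 is reported — and the genotype proposes no
drop-out. The 0.9 rule is applied to the per-contributor marginal (whether
the original software thresholds the marginal or the joint set is not
documented; the marginal is what the per-contributor tables require).

`likelihood_ratio()` computes $\mathrm{LR} = P(E \mid H_p)/P(E \mid H_d)$
with $H_p$ conditioning on the suspect plus $K-1$ unknowns and $H_d$ all
unknown, each side maximised separately (maximum-likelihood LR in the
EuroForMix tradition, no integration over parameters). Per-locus log10
terms sum to the total. The $H_d$ fit is suspect-independent and can be
shared across a suspect panel.

# Evaluation

`classify_deconvolution()` scores each (locus, contributor) as Correct
(determinate and equal to truth), Wrong (determinate with at least one
wrong allele) or Undetermined. Truth contributors are matched to fitted
contributors by proportion rank; within equal-proportion groups (1:1
mixtures, the majors of 9:9:2, the minors of 14:3:3) every pairing is
tried and the one minimising Wrong counts is kept, since labels are not
identifiable under symmetry. `consensus()` merges duplicate typings,
keeping only identical determinate calls. `random_match_probability()` is
the plain HWE product $\prod p^2$ / $\prod 2pq$ over determinate loci (no
coancestry correction), 1 for an empty profile.
`compare_proportion_estimates()` reports Shapiro–Wilk normality p-values
per group and a two-sided Wilcoxon rank sum test on absolute deviations of
the estimated major/minor ratio from the designed ratio.
`summarize_records()` emits the per-ratio, per-contributor
Correct/Wrong/Undetermined percentage tables (one decimal, rows summing to
100) and the overall error rate.

# The workflow and its scales

`experiment_config()` + `plan_experiment()` reproduce the full study's
arithmetic in closed form: 360 two-person and 336 three-person mixtures
across both panels, 50 suspects per mixture with exactly one true
contributor (the minor in two-person and 9:9:2 mixtures, the major in
14:3:3, the intermediate in 14:5:1), hence 18,000 + 16,800 = 34,800 LR
deconvolutions and 17,640/16,464 non-contributor jobs. `run_experiment()`
executes the pipeline at whatever scale the config requests and is
idempotent per panel arm when given an output directory.

Executing all 34,800 deconvolutions is not what the package's tests do.
Error-rate comparisons run at the package's desk scale — 12-locus panels,
20 mixtures per ratio, depths of 60,000 (MH) and 100,000 (STR) reads
preserving the per-locus depth of the full assays, 12 calibration samples
— where the MH/STR gap is already decisive. The balanced-mixture
proportion comparison is the one analysis that must keep the full panel
sizes (74 MH vs 26 STR loci at full depth): a 1:1 mixture's proportion
estimate is pinned by the number of informative loci, so small symmetric
panels make that comparison noisy in a way the full panels are not.
Single-condition checks (proportion recovery, LR separation) likewise run
on the full 74-locus, 370,000-read MH configuration.

# Numerical and design choices

* **Threshold semantics**: AT retains counts ≥ 11; posterior threshold
  reports ≥ 0.9. Both boundaries are tested.
* **Noise law**: Poisson allele count × geometric read counts above the AT
  — the simplest law consistent with memoryless noise tails, and
  self-consistent between generator, calibration and likelihood.
* **Drop-out**: cumulative below-threshold probability under the allele's
  own expected-count law, so drop-out probability falls with depth and
  rises for minor contributors, as it should.
* **Label switching**: descending-$\omega$ reporting with
  enumeration-order tie-breaks; evaluation resolves residual symmetry by
  minimising Wrong counts.
* **Degenerate inputs**: empty loci contribute pure drop-out/noise terms;
  a locus with a single retained allele still enumerates Q genotypes;
  zero-noise models make unexplained alleles impossible rather than
  improbable.
* **Determinism**: panels, populations, reads, mixtures and fits are pure
  functions of their seeds; FASTQ output is byte-identical across runs.

# Limitations

The generator's realism bounds the conclusions: real stutter depends on
sequence composition beyond repeat number, real noise is not geometric,
real heterozygote imbalance correlates across loci, and real mixtures
amplify contributors in one reaction rather than mixing independently
sequenced read sets. The likelihood ignores the truncation of retained
counts at the AT (a one-sided correction below 1% of locus mass at the
default depths) and does not model stutter mass shed to sequences outside
the observed allele set. NOC is an input, never estimated; relatedness and
degradation hypotheses are out of scope.
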