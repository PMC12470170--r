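# mixdeconv

Probabilistic deconvolution of forensic DNA mixtures typed by massively
parallel sequencing, comparing microhaplotype (MH) and short tandem repeat
(STR) marker panels.

Forensic casework samples frequently contain DNA from several people. Given
per-locus allele read counts from a mixed sample, mixture deconvolution
infers each contributor's genotype with a posterior probability, estimates
the mixture proportions, and weighs a suspect hypothesis against an
all-unknown hypothesis with a likelihood ratio. MH loci (short amplicons
whose alleles are SNP haplotypes, all the same length, with no stutter) are
expected to deconvolute better than STR loci (alleles differing in repeat
count, with stutter artefacts and length-dependent read yields); this
package implements the full simulated comparison as a tested pipeline,
with a synthetic-data generator standing in for non-public cohort data.

## The model

Allele read counts at locus $\ell$ are negative binomial. Under a joint
genotype set $G$ for $K$ contributors with proportions $\omega$
(the mixture proportions), depth $\mu$ and dispersion $\theta$:

$$y_{\ell a} \sim \mathrm{NB}\!\left(\mu\, e_\ell \sum_{k=1}^{K}
  \omega_k \frac{c_{ka}(G)}{2},\ \theta\right)$$

with $e_\ell$ the calibrated locus efficiency and $c_{ka}$ the copies of
allele $a$ in contributor $k$'s genotype. For STRs the calibrated stutter
proportion moves expectation mass from each parent allele to the sequence
one repeat shorter. Genotypes may propose the drop-out symbol Q, which
contributes the probability of falling below the analytical threshold
(11 reads); retained alleles no genotype explains follow a calibrated
Poisson × geometric noise law. Unknown contributors are marginalised by
exact enumeration over all genotypes of observed alleles plus Q with
Hardy–Weinberg priors; $(\omega, \mu, \theta)$ are fitted by deterministic
maximum likelihood. Deconvoluted genotypes are reported when their
posterior reaches 0.9 and no drop-out is proposed;
$\mathrm{LR} = P(E \mid H_p) / P(E \mid H_d)$ compares a suspect-inclusive
hypothesis to the all-unknown one, on the log10 scale.

The methods vignette (`vignettes/mixture-deconvolution.Rmd`) documents the
generator, the calibration estimators, the likelihood, and every numerical
and design choice.

## Worked example

A 6-locus MH panel, a 10-sample calibration cohort, and one 3:1 two-person
mixture at 20,000 reads:

```r
library(mixdeconv)

panel <- build_panel("MH", n_loci = 6, seed = 11)
pop   <- sample_population(panel, n_alleles_per_locus = 6,
                           n_individuals = 30, seed = 12)

calib <- calibrate_model(lapply(pop$profiles[1:10], function(p) {
  reads <- generate_reads(p, panel, read_params(20000, seed = 100 + match(
    p$sample_id, sapply(pop$profiles, `[[`, "sample_id"))))
  list(profile = p, counts = call_alleles(reads, panel))
}), panel)
calib
#> <mps_calibration> MH panel, 6 loci, 10 samples
#>   AT=11  dispersion=0.01205  noise rate=0.2/locus (geom p=0.114)

donors <- pop$profiles[11:12]
reads  <- lapply(donors, function(p) generate_reads(p, panel,
                   read_params(20000, seed = 200 + match(p$sample_id,
                     sapply(pop$profiles, `[[`, "sample_id")))))
spec   <- mixture_spec(c("S011", "S012"), c(0.75, 0.25), 20000,
                       seed = 5, label = "mix1")
counts <- call_alleles(mix_reads(reads, spec), panel, sample_id = "mix1")

dec <- deconvolute(counts, noc = 2, calib, pop$freqs)
dec
#> <mps_deconv> mix1: NOC=2, omega=(0.755, 0.245)
#>   12/12 (locus, contributor) calls determinate at p >= 0.90

likelihood_ratio(counts, donors[[2]], 2, calib, pop$freqs, hd_fit = dec$fit)
#> <mps_lr> suspect S012, NOC=2: log10 LR = 5.59
likelihood_ratio(counts, pop$profiles[[25]], 2, calib, pop$freqs,
                 hd_fit = dec$fit)
#> <mps_lr> suspect S025, NOC=2: log10 LR = -9.91

table(classify_deconvolution(dec, donors, c(0.75, 0.25))$classification)
#> Correct
#>      12
```

The fitted mixture proportion (0.755) recovers the designed 3:1 ratio; all
twelve (locus, contributor) genotypes are called correctly; the true minor
contributor gets very strong support (log10 LR = 5.6 from just six loci)
and a non-contributor is firmly excluded (−9.9). At the full 74-locus,
370,000-read configuration, true-contributor log10 LRs reach the 60–80
range and non-contributors fall below −200.

Scaling up, `experiment_config()` / `plan_experiment()` /
`run_experiment()` / `report_experiment()` orchestrate entire study arms —
cohort generation, calibration, the 45-pairs-per-ratio two-person and
56-triples-per-ratio three-person mixture designs, deconvolution of every
mixture, suspect LR panels, and Correct/Wrong/Undetermined scoring.

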