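---
title: "Estimating dam-line proportions in three-way crossbreds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dam-line proportions in three-way crossbreds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Terminal crosses in pig and poultry breeding commonly mate a purebred sire
line A to an F1 dam produced from two dam lines B and C. Every A(BC)
crossbred inherits exactly half of its alleles from line A through the sire,
but the maternal gamete is a recombined mosaic of B and C segments, so the
dam-line proportions `b_B` and `b_C` vary from animal to animal around their
expectation of 0.25, with `b_B + b_C = 0.5` always. Genomic prediction models
that fit line composition as a fixed regression on the expected proportions
ignore this variation; replacing the expectation by each animal's realized
composition requires estimating `b_B` and `b_C` from SNP genotypes.

**damline** implements and compares five estimators of the dam-line
proportions, the post-processing that maps raw estimates back into the
parameter space of the cross, the evaluation metrics used to compare
methods, and a forward-in-time simulator whose per-allele line-of-origin
tracking supplies the true proportions that real data never provide.

## The estimators

Let `g` be a crossbred's vector of allele counts (0/1/2 copies of the
counted allele per SNP) and let `p_A`, `p_B`, `p_C` be the line-specific
frequencies of the counted allele.

**BOA counting** (`boa_proportions()`). When each allele of a crossbred has
been assigned a line of origin — by a haplotype-based breed-of-origin
analysis, or by the simulator's exact tracking — the line proportion is
simply the fraction of assigned alleles from that line. The assignment
algorithm itself is out of scope here; the package consumes its output (an
`origin_matrix`). With complete assignment this equals the true proportion
by definition, which is what makes it a usable gold standard in real data.

**Sire-adjusted linear regression** (`lr_estimate()`). The regression of
`g` on the line mean allele counts `x = 2p`,

    g = x_A b_A + x_B b_B + x_C b_C + e,

exploits that `b_A = 0.5` exactly, moving the sire-line term to the left:
`g* = g - 0.5 x_A`, then solving `g* = x_B b_B + x_C b_C + e` by ordinary
least squares without intercept. Coding the regressors as mean allele
counts (`2p`) rather than frequencies matters: with frequency coding,
subtracting `0.5 x_A` would remove only half of the sire contribution.
`x_A` here comes from direct counting in the purebred lines.

**Supervised admixture** (`admixture_supervised_em()`). The classical
admixture likelihood with ancestral frequencies fixed at the purebred line
values: each allele is drawn from line `k` with probability `q_k`, giving
per-animal log-likelihood
`sum_m [ g_m log(sum_k q_k p_mk) + (2-g_m) log(sum_k q_k (1-p_mk)) ]`,
maximized over the 3-simplex by EM. The model assumes linkage equilibrium
between SNPs, so the panel is LD-pruned first (`indep_pairwise()`).

**Grandparent relationships** (`rel_gp_estimate()`). All line-B alleles of
an A(BC) crossbred descend from its line-B maternal grandsire, so the
realized `b_B` equals the genome fraction shared identical-by-descent with
that grandsire. As an observable proxy the package uses the
multi-population genomic relationship (`grm_cross()`), centering each
animal by twice the allele frequencies of its own population — the
grandparent by its line's frequencies, the crossbred by the blend
`0.5 p_A + 0.25 p_B + 0.25 p_C` — and scaling by the geometric mean of the
two populations' `sum 2p(1-p)`. The line frequencies for these estimators
are obtained by regressing all genotypes on the expected line proportions
(`regression_line_freqs()`), and two variants are reported: `REL_GP` takes
`G_ij` directly (exact only for a non-inbred grandparent, whose expected
self-relationship is 1) and `REL_GP_noF` divides by the grandparent's
self-relationship `G_jj`, an estimator of `1 + F`, to drop that assumption.

## Post-processing

Raw estimates of all methods are mapped into the parameter space of the
cross by `postprocess_estimates()`, separately per method and cohort, in a
single pass: (1) clip into [0, 0.5]; (2) shift each dam line's estimates so
the cohort mean is 0.25, B and C independently; (3) clip again; (4) rescale
each animal's pair so `b_B + b_C = 0.5`. After step 4 the two dam lines
carry the same information (`b_C = 0.5 - b_B`), so every evaluation metric
is identical for B and C — the package asserts this rather than assuming
it. The steps are applied once, not iterated to a fixed point: the
per-animal rescaling can move cohort means slightly off 0.25 again, which
is accepted. An animal whose clipped proportions sum to zero (possible for
badly-behaved raw estimates) is set to the expectation (0.25, 0.25) and
counted; the procedure's source description leaves this case open.

The final rescaling inflates the variance of the estimates somewhat — this
is visible as dispersion slopes below 1 — but on balance improves accuracy
for all methods whose raw estimates can leave [0, 0.5].

## Evaluation

`evaluate_estimates()` reports, per method: accuracy (Pearson correlation
of estimated with reference proportions), dispersion slope (regression
coefficient of reference on estimate; 1 = correctly scaled, below 1 =
inflated estimates, and identically `accuracy * sd(ref)/sd(est)`), maximum
absolute error, and RMSE. `method_correlation_table()` gives between-method
agreement. `fst_wc()` implements the Weir–Cockerham (1984) multi-population
theta from genotype counts, reported as the unweighted mean of per-locus
ratios over loci with a defined denominator; a pairwise mode applies it to
each pair of lines, and the mean of the three pairwise values is the
package's summary of line divergence.

`theoretical_variance()` gives the expected distribution of a dam-line
proportion for a genome of chromosome lengths `l_i` Morgan: under the
Haldane model the grandparental origin along a gamete is a two-state
process switching at crossover rate 1, so a chromosome contributes
gamete-fraction variance `v(l) = (1/(2 l^2)) (l/2 - (1 - e^{-2l})/4)`,
chromosomes combine as `sum(l_i^2 v(l_i)) / (sum l_i)^2`, and the line
proportion (half the gamete fraction, non-inbred grandparent) has variance
a quarter of that, mean 0.25. The closed form is cross-validated in the
test suite against a 100 000-gamete Monte-Carlo simulation for lengths
0.1–3.2 Morgan rather than asserted on trust; in the limit of zero length
it approaches 1/16 (a single locus comes entirely from one grandparent or
the other). `plot_proportions()` overlays this density on an observed
histogram.

## The simulator and its calibration

`simulate_scenario()` reconstructs the study conditions the estimators are
meant to face: founder haplotypes drawn independently per SNP with
frequencies uniform on (0.05, 0.95); 100 burn-in generations of random
mating at effective size Ne to build linkage disequilibrium; a split into
three lines that mate randomly within line for t generations; then the
cross — 25 line-B sires by 100 line-C dams producing 200 F1 dams, and 25
line-A sires by those dams producing 428 A(BC) crossbreds with exact
per-allele origin tracking. Meiosis follows the Haldane model (Poisson
crossover counts, uniform positions, no interference) on a sex-averaged
map of two chromosomes of 3.20 and 0.61 Morgan. The joint MAF > 0.1 filter
is applied to the combined panel, and the true proportions are computed on
the filtered panel — the same SNP set every estimator sees.

Three presets set the divergence between the lines, named for the
relatedness regime they represent and calibrated to the fixation index
each regime should show: `close` (t = 5, F_ST about 0.04), `distant`
(t = 20, 0.12) and `unrelated` (t = 50, 0.22). Two calibration choices
deserve a note:

* **Effective size.** The drift approximation
  `E[F_ST] = 1 - (1 - 1/(2 Ne))^t` suggests Ne of about 60/80/100 for the
  three presets. Measured on the simulator's own output, however, the MAF
  filter preferentially retains less-drifted loci and pulls the realized
  Weir–Cockerham estimate some 15% below that expectation. Because the
  fixation index — not Ne, which is unobservable here — is the quantity
  the presets are defined by, Ne was calibrated against the measured
  estimator instead: 55, 72 and 81, giving mean pairwise F_ST of about
  0.038, 0.117 and 0.225.
* **Founder SNP numbers.** Defaults of 10 800 + 2 060 founder sites leave
  the unrelated preset with roughly 4 800 + 900 segregating SNPs after the
  MAF filter, the 60k-chip-like density the scenarios emulate. Retention
  depends on the preset (about 4 100 SNPs for `close`, 5 400 for
  `distant`) because burn-in drift at the preset's Ne precedes the filter;
  this is a property of the reconstruction, accepted rather than tuned
  away.

What the generator does **not** emulate: mutation during divergence (drift
and recombination dominate at these time scales), selection (divergence is
by random mating), sex chromosomes, realistic marker ascertainment, and
the empirical LD structure of any particular breeding population. Passing
tests therefore demonstrate correctness of the estimators and the expected
ranking of methods under drift-generated LD and frequency divergence; they
do not certify accuracy values for any specific real population.

## Numerical choices

* EM: tolerance 1e-7 on the total log-likelihood, at most 1000 iterations,
  frequencies floored into [1e-6, 1 - 1e-6]; initialization at the
  expected composition (0.5, 0.25, 0.25), which is also the fixed point
  when the likelihood is flat (identical line frequencies). The
  log-likelihood is monotone non-decreasing, which the tests assert.
* Regression frequencies are clipped into [0, 1] after the least-squares
  solve; out-of-range solutions are rare but possible at SNPs nearly fixed
  in all lines.
* LR solves the 2-by-2 normal equations shared by all animals in one
  factorization; collinear dam-line regressors (`p_B` proportional to
  `p_C` at every SNP) are a hard error naming the degeneracy.
* LD pruning removes, within each 50-SNP window (shifted by 10), the
  lower-MAF member of the highest-r² pair until no pair exceeds the
  threshold, ties removing the later index. The guaranteed contract is the
  post-condition — no surviving within-window pair above the threshold —
  not index-level agreement with any external tool, whose tie-breaking is
  not fully published. The default threshold 0.5 is the setting at which
  the admixture estimator performs best; 0.1 discards ~95% of SNPs and
  measurably hurts it.
* Missing genotypes are rejected at ingest by default; an opt-in flag
  mean-imputes within line and reports the count. Monomorphic SNPs have
  r² defined as 0 so they can never cause a pruning removal.
* Grandparent-relationship estimates are computed only for crossbreds with
  both maternal grandparents genotyped; the comparison pipelines restrict
  *all* methods to that common subset by default so methods are compared
  on the same animals.

## Problem sizes

The full presets (1000 purebreds per line, 428 crossbreds, ~5700 SNPs) run
in about a minute each and are exercised in the acceptance tests. The unit
tests use scaled-down scenarios (tens of animals, a few hundred SNPs) that
preserve every structural property — these sizes are the package's choice
of fast, deterministic fixtures, with the full-size runs reserved for the
study-level checks of method ranking and distributional behaviour.

## Known limitations

* The BOA haplotype-assignment step itself (phasing and breed-of-origin of
  haplotypes) is not implemented; the package consumes its output or the
  simulator's exact truth. Real BOA output has a few percent unassigned
  alleles; `boa_proportions()` handles them by counting among assigned
  alleles, which is unbiased only if unassignment is unrelated to origin.
* The estimators assume the cross type is known. Verifying the cross type
  (e.g. detecting mislabelled F1s) would require running without the
  sire-adjustment and post-processing constraints.
* Four-way crosses, unsupervised admixture (estimating the number of
  ancestral populations) and downstream breeding-value estimation are out
  of scope.

```{r, eval = FALSE}
library(damline)

sim <- simulate_scenario(scenario_config("unrelated", seed = 1))
res <- estimate_all(sim$panel, sim$pedigree, sim$origins, r2_threshold = 0.5)
est <- postprocess_estimates(res$raw)
evaluate_estimates(est, sim$truth)
plot_proportions(sim$truth, chrom_lengths(sim$panel$map))
```
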