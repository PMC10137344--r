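---
title: "Kinship-index selection in simulated small-population breeding programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship-index selection in simulated small-population breeding programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(kisim)
```

## The problem

Genomic selection (GBLUP, Bayesian marker-effect regression) needs a
genotyped *and phenotyped* reference population to estimate marker effects
or genomic breeding values. Many local pig breeds are kept in populations
of a few hundred animals, where no such reference exists and routine
phenotyping is unreliable. Kinship index based selection (KIS) sidesteps
both requirements: an *ideal individual* is designed to carry the
beneficial allele at every locus linked to the breeding objective, each
candidate's genotype is compared with it locus by locus — scoring 0 for
the disadvantageous homozygote, 1 for the heterozygote, 2 for the
beneficial homozygote, times an optional per-locus weight — and the
candidates most similar to the ideal are selected. `kisim` implements the
scoring method together with a complete forward-in-time breeding-program
simulator so that KIS can be compared, on equal footing, with GBLUP,
BayesB and oracle selection on the true breeding value (TBV).

## Simulation model

**Genome.** The default genome is 10 autosomes of 1 Morgan carrying 500
equally spaced markers each (5,000 markers), founder allele frequencies
i.i.d. Uniform(0.05, 0.95). Nothing in the method depends on these
numbers; they are chosen dense enough for a stable genomic relationship
matrix and marker-effect regression while staying cheap on a single CPU,
and every one of them is configurable (`make_genome()`,
`breeding_config()`).

**Founders.** Founder haplotypes are drawn allele-by-allele at the marker
frequencies, i.e. in linkage equilibrium, with an exact 1:1 sex ratio.
Real populations carry LD; the founders here acquire LD only through the
ten generations of historical selection that precede every comparison.
This is the main respect in which the generator is idealized: results
about *relative* method performance transfer, absolute LD-dependent
accuracies do not.

**Inheritance.** Meiosis follows the Haldane model: per chromosome a
Poisson(length in Morgans) number of crossovers at uniform positions, no
interference, no mutation, a fair coin for the starting strand. The
recombinant fraction between two loci `d` Morgans apart is therefore
`(1 - exp(-2d))/2`, which the test suite verifies against 10^5 simulated
gametes.

**Traits.** A trait is a set of QTL positions with additive effects drawn
N(0,1) and then rescaled by a single factor so that the sample variance of
the TBV over the founder population is *exactly* 1 — the calibration is by
construction, not by tolerance. Two traits (100 and 500 QTLs by default)
are assigned disjoint QTL sets so their 600 loci are distinguishable from
unaffected markers. TBV is the dosage-effect dot product
`TBV_i = sum_j Z_ij a_j`; with dominance or epistasis switched on, the
*genotypic value* adds `d_j` per heterozygous QTL and `e_jk w_j w_k` on
centered dosages `w = Z - 1` (this functional form is a package choice —
indicator dominance plus additive-by-additive products — because only the
presence of the effect classes, not their parameterization, is prescribed
by the study design), and the total genetic variance is recalibrated to 1.
Consequently a larger non-additive share mechanically shrinks the additive
scale, which is exactly why selection on an additive ideal loses ground as
that share grows.

**Phenotypes.** `y = g + e`, `e ~ N(0, Var(g)(1-h2)/h2)` with `Var(g)` the
sample variance of the generation being phenotyped. The heritability of
the simulated traits is not pinned down by the study design; the package
default is `h2 = 0.5`, exposed in the configuration.

## The breeding program

A historical population of 200 (even sexes) is split at random into two
lines, A and B, with balanced sexes. Each line is selected for its own
trait by equal-weight KIS for 10 generations — 5 sires × 20 dams produce
200 offspring per generation per line. Hybridization then crosses 5 A
sires with 20 B dams (F1), and 5 B males with 20 F1 females (F2); five
further generations of purebred reproduction (G1..G5) select 5 males and
20 females each generation, under whichever criterion is being tested
(the selection method applies from the F1 cross onward; the historical
phase is part of the shared experimental substrate). Mating is balanced:
dams are split as evenly as possible among sires, offspring as evenly as
possible among dams (exactly evenly whenever the counts divide — the
default design divides), with an exact 1:1 offspring sex ratio. The
per-generation record is the mean TBV of the top `n_sires` males and top
`n_dams` females *of that generation* under the method's score; for F1
the male group is recorded even though the F2 sires come from line B,
because the F1 males are the relevant cohort of that generation.

**Scoring the multi-trait objective.** From the cross onward the target is
the sum of the two traits' TBVs, each calibrated to variance 1. The raw
KIS score (`kis_score()`) is the plain weighted 0/1/2 sum and is what the
scoring contracts and the CLI expose. For selection across trait
subsystems the package uses the comprehensive index (`kis_index()`): each
subsystem's score is normalized by its maximum (`2 × sum of weights`) and
the subsystems are combined with importance weights (equal by default).
Without this normalization a 500-locus trait would outvote a 100-locus
trait five-to-one although both contribute the same variance to the
objective.

**Comparator criteria.** GBLUP builds the VanRaden method-1 relationship
matrix `G = WW'/(2 Σ p(1-p))`, blends it with 0.01·I for invertibility,
and solves the animal model with the variance ratio treated as known from
`h2` and an overall mean as the only fixed effect; candidates without
records get EBVs through their relationships. BayesB is a single-site
Gibbs sampler with a point mass at zero (π = 0.95) and marker-specific
variances under a scaled-inverse-χ² prior (df 4.234, scale derived from
`h2` and marker heterozygosity); EBVs are centered dosages times posterior
mean effects. Both are re-fit at every selection event.

**The reference population** is the crux of the small-population setting.
Candidates are scored *before* they are phenotyped — selecting youngsters
on genomic information is the whole point of genomic selection — so their
own records never enter the fit. The default `reference_scope = "recent"`
trains on the most recent phenotyped cohort (their parents' generation;
~200–400 animals), which is what a breeding program without a phenotype
bank can actually maintain; `"accumulate"` keeps all phenotyped
generations of the running scenario. This choice matters: with an
accumulating multi-generation reference the comparators' accuracy grows
each generation, which is precisely the infrastructure small programs
lack, and the package treats the scarce-reference setting as the default
study condition.

**Negative control.** Selection against an ideal of 600 loci sampled from
markers with *no* effect (random beneficial alleles) should produce no
genetic trend; it bounds the feasibility comparison from below. A
structural note: under the control the recorded groups are effectively
random draws, so the F1 record sits at the mid-parent of lines A and B
and the later plateau at the B-line/F1 midpoint — with both traits
calibrated to equal variance the expected F1-versus-plateau contrast is
(A−B)/4 ≈ 0, so no marked F1 dip is expected under these calibrated
conditions.

## Robustness perturbations

* **False negatives** (`false_negative_ideal()`): delete 10/20/30% of the
  ideal's loci at random; one shared deletion order makes the missing
  sets nested across rates, so the rate contrast is not confounded by
  which loci happened to be dropped. Both the equal-weight and the
  effect-weighted (`|a|·scale`) ideal are run.
* **Pseudo-positives** (`false_positive_ideal()`): add 10/20/30% spurious
  loci, each the marker adjacent (+1, else −1, same chromosome) to a true
  locus, never duplicating a true locus or each other; beneficial alleles
  are a fair coin, weights 1, and each added locus joins its anchor's
  subsystem. Sharing the perturbation stream across rates nests the
  added sets the same way.
* **QTL gradients**: trait pairs 100/350, 150/400, 200/500 beside the
  base 100/500.
* **Foundation scale**: the per-generation candidate pool (and founder
  count) varies over {100, 200, 500, 1000, 2000} while 5 sires and 20
  dams are selected throughout. A pool of 50 is incompatible with the
  design: 50 founders split into two lines leave ~12 females per line,
  fewer than the 20 dams the scheme must select, so the gradient starts
  at 100 (the configuration validator rejects infeasible combinations
  rather than silently reusing dams).
* **Selection proportion**: 3/10, 5/20, 10/30, 15/40, 20/50 males/females
  selected out of 100 + 100, applied from the cross onward so that all
  levels share one historical base per replicate.
* **Non-additive architectures**: 10/20/30% of QTLs gain dominance
  effects, disjoint additive×additive pairs, or both, with recalibration.

## Experiments and statistics

`run_replicates()` drives everything from one master seed through named
sub-streams (`derive_seed()`), so that within a replicate every method
shares the genome, traits, founders, historical phase and mating
randomness — common random numbers sharpen the paired method contrasts at
small replicate counts. `anova_letters()` runs, per generation and sex, a
one-way ANOVA across groups of the replicate means, Tukey HSD pairwise
comparisons at α = 0.05, and assigns compact letters by insert-absorb
(groups share a letter iff their pairwise test is not significant; with
zero residual variance the comparison degenerates to exact equality of
means). `coefficient_of_variation()` reports sd/mean of the recorded
means across replicates, flagging zero-mean cells as undefined.

The checked-in experiment scale is 3 common-random-number replicates with
BayesB chains of 600 iterations (200 burn-in) inside scenario runs, and
the foundation gradient {100, 200, 500} in the automated checks; the full
designs (10 replicates, 2000-iteration chains, pools up to 2000) are a
configuration change away and were sized so a complete feasibility
comparison runs in minutes on one CPU.

## Numerical choices and degenerate inputs

* Truncation-selection ties are broken by a seeded uniform draw, never by
  id order, to avoid pedigree artifacts among equal scores.
* The GRM excludes monomorphic markers from centering and denominator; an
  all-monomorphic panel is an error, not a NaN.
* Trait calibration fails loudly when all QTLs are monomorphic (zero
  founder variance).
* `phenotype()` with `h2 = 1` returns the genetic values exactly; a
  single-individual vector has zero variance and hence zero noise.
* BayesB freezes marker and residual variances on request
  (`fix_common_var`), which reduces it to ridge/SNP-BLUP at π = 0 — used
  as a cross-check, and the GBLUP solution is verified against an
  independently coded SNP-BLUP to 10⁻⁶.
* Zero-length chromosomes transmit a whole parental strand; fully
  homozygous parents yield deterministic gametes.

## Limitations

Founders start in linkage equilibrium; there are no sex chromosomes, no
mutation, no genotyping errors, and no real map — the simulator is built
for method comparison under controlled conditions, not for predicting
absolute gains in a particular breed. GBLUP/BayesB variance components
are treated as known from `h2` rather than re-estimated (REML at n = 200
mostly adds noise, but a real program would have to estimate them). The
ideal individual is taken as given (or derived from the simulated
architecture); discovering beneficial genotypes from data (GWAS, variant
databases) is outside the package's scope.
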