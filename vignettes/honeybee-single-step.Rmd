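---
title: "Simulating honey bee breeding and single-step genetic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating honey bee breeding and single-step genetic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeblup)
```

## The problem

A colony trait in the honey bee (honey yield, hygienic behaviour, Varroa
resistance) is a maternally influenced trait: it mixes the queen's genetic
contribution (egg-laying rate, pheromone production - the *maternal* or queen
effect) with the workers' contribution (hoarding, brood care - the *direct*
or worker effect). Genetic evaluation must untangle the two while coping with
three peculiarities of bee breeding:

* **Uncertain paternity.** Queens mate in flight with many drones. Breeding
  programs control matings only down to a *mating station* stocked by a group
  of sister drone-producing colonies; the individual drone father is unknown.
  The pedigree therefore carries a *dummy sire* - a pseudo-individual that
  stands for the whole drone group - and the relationship recursion replaces
  the usual 0.5 sire path with a paternal path coefficient
  $P_p = 0.367$, the value used in the German national evaluation.
* **Colony phenotypes.** A record belongs to the whole colony: queen and
  workers cannot be phenotyped separately. Both the queen and a pedigree
  pseudo-individual (the *average worker*) are assigned the same record.
* **Few genotyped individuals.** Only queens are realistically genotypable,
  which argues for a single-step (unified) evaluation where genotyped and
  ungenotyped individuals are evaluated jointly.

`beeblup` simulates this system end to end and compares two evaluations of
the same maternal-effects animal model,

$$y = Xb + Z_1 u_1 + Z_2 u_2 + e,$$

where $y$ holds colony records, $b$ a single overall mean, $u_1$ direct
(worker) effects, $u_2$ maternal (queen) effects, and
$\mathrm{Var}\!\begin{pmatrix}u_1\\u_2\end{pmatrix} = G_0 \otimes K$ with
$G_0 = \begin{pmatrix}\sigma^2_w & \sigma_{qw}\\ \sigma_{qw} &
\sigma^2_q\end{pmatrix}$. The two evaluations differ only in the relationship
kernel $K$:

* **PED_BLUP** - the pedigree numerator relationship matrix $A$, built by the
  tabular recursion $a(x,y) = 0.5\,a(d,y) + P_p\,a(s,y)$ with diagonal
  $1 + 2\cdot 0.5\cdot P_p\, a(d,s)$;
* **UNI_BLUP** - the unified matrix $H$ combining $A$ with the VanRaden
  genomic matrix $G = ZZ'/2\sum_i p_i(1-p_i)$ of the genotyped queens,
  blended as $G_w = wG + (1-w)A_{11}$ with $w = 0.99$ and assembled through
  $H^{-1} = A^{-1} + \begin{pmatrix}G_w^{-1}-A_{11}^{-1} & 0\\ 0 &
  0\end{pmatrix}$.

Accuracy is the Pearson correlation between estimated and true breeding
values, reported for the 500 *juvenile queens* (last-generation candidates,
genotyped but unphenotyped) and for all 2550 queens.

## What the simulator emulates

**Genome.** Sixteen linkage groups with the real chromosome lengths
(219,629,612 bp in total) and a genome-wide recombination rate of 19 cM/Mb
(about 41.7 Morgans). Loci are biallelic. Meiosis draws interval crossovers
independently with the Haldane recombination fraction
$R = 0.5(1 - e^{-2d})$ of each adjacent-locus distance - a no-interference
crossover process. Mutation is bidirectional at $2.5\times10^{-3}$ per locus
per gamete per generation and acts only up to the base generation.

**Base population.** 500 sire queens and 50 dam queens random-mate for 1000
discrete generations (200 at the reduced preset), starting from
Bernoulli(0.5) founders, which takes allele frequencies to mutation-drift
equilibrium and builds linkage disequilibrium. From the final generation the
panel keeps the 44,000 loci (4,000 reduced) of highest minor allele frequency
(all above 5%); the 250 highest-MAF of those become QTL - 86 direct-only, 78
pleiotropic, 86 maternal-only - and the rest are the SNP marker panel.

**Breeding phase.** Five overlapping generations, each with 500 potential-dam
queens and 250 drone-producing queens. Ten percent of potential-dams are
selected (at random - accuracy, not selection response, is the quantity
of interest) as dams;
each dam mates exactly one dummy sire and each dummy sire serves two dams.
A dummy sire consists of ten sister drone-producing queens from one
generation *before* the dams (overlapping generations) and offers 20 drones
(two per member queen); each offspring queen's paternal gamete is a drone
drawn uniformly with replacement, so colony mates fall into super-sib,
full-sib and maternal half-sib classes. Each dam produces ten potential-dam
queens, and 25 of the 50 dams produce ten drone-producing queens each, which
restores the per-generation counts and forms the next dummy-sire cohort. The
base population's 500 sire queens supply the two founder dummy-sire cohorts
that mate the generation-0 and generation-1 dams. The evaluation pedigree
contains 2550 queens, one average worker per queen, and $7\times25 = 175$
dummy sires - 5275 entries.

**Traits.** QTL effects are N(0,1). Pleiotropic loci share one magnitude
between their maternal and direct effects; in the negative-correlation mode
the two signs are opposite (the realized maternal-direct correlation then
concentrates near $-78/164 \approx -0.48$, the ratio of pleiotropic to total
QTL per component), in the no-correlation mode both signs are randomized.
A queen's true breeding values are genotype-score sums over QTL
($+1$/$0$/$-1$ for the allele-2 homozygote, heterozygote, allele-1
homozygote), and her colony record is
$y = TBV_q + TBV_w + e$, $e \sim N(0, \sigma^2_e)$. Variance components are
realized per replicate from the 2550 queens' TBVs; the phenotypic variance
follows from the fixed maternal heritability,
$\sigma^2_p = \sigma^2_q / h^2_m$, and
$\sigma^2_e = \sigma^2_p - (\sigma^2_q + \sigma^2_w + 2\sigma_{qw})$.
These realized ("simulated") components are handed to the evaluator - no
variance estimation is performed.

Phenotypes exist for the 50 base dams and the potential-dams of generations
1-4 (2050 colony records); genotypes for the base dams and all potential-dams
(2550 queens, SNP panel only - QTL are excluded from $G$).

## What the simulator does not emulate

Dominance and epistasis; environmental fixed effects beyond a global mean;
explicit worker genotypes (the colony record carries the queen's own direct
TBV - the generator's convention); selection on EBVs (selection is random, so
accuracies are not distorted by selection-induced trends); queen supersedure
and swarming; crossover interference and sex-specific maps. Passing tests on
this generator therefore validate the estimation machinery under the stated
model, not the biology of any real breeding population.

## Design choices in genuinely open corners

* **Locus placement** is uniform along each chromosome by default (the map
  is silent on placement); a random-placement mode exists for sensitivity
  checks.
* **Generation arithmetic.** "Dummy sires one generation before the dams"
  forces generation-g offspring to have dams from g-1 and dummy-sire members
  from g-2. The two founder cohorts (generation-1 and generation-2 matings)
  both come from the base sire queens - the reason the base holds exactly
  $2 \times 250$ of them. Dummy-sire cohorts are also formed from the
  generation-4 and generation-5 drone-producing queens (never used as mates)
  so that every drone-producing queen group is represented; this is what
  makes the evaluation pedigree 5275 entries.
* **Every potential-dam queen is mated** (uniformly to the cohort that
  serves her generation) because every colony has workers and the worker's
  pedigree needs a sire; only the 50 selected dams' matings produce queens.
* **Pleiotropic magnitudes are shared** between the maternal and direct
  effect of a locus. With independent magnitudes the negative mode would
  realize a correlation near $-0.30$; the shared-magnitude expectation
  $-78/164 \approx -0.476$ matches the intended design conditions.
* **Per-replicate variance components** over all 2550 queens (rather than
  pooled across replicates), passed as known values to the solver.
* **Scenario pairing.** Within a replicate the simulated population is
  shared across all six scenarios: the correlation mode changes only the QTL
  effect signs and the heritability only the residual scale (one
  standard-normal residual vector per mode, scaled by $\sigma_e$). Scenario
  contrasts are therefore paired, which sharpens the method comparisons.
* **Significance testing** uses two-sided paired t-tests per contrast at
  P < 0.05 without multiplicity correction, one flag per pairwise
  contrast.

## Numerical choices

* **The solver.** The mixed-model equations (assembled by `build_mme` with
  $K^{-1}$, the partitioned $A^{-1}$ and the single-step $H^{-1}$) are the
  reference route and are exercised against a GLS oracle in the tests. The
  replicate driver solves the identical model in covariance form: with
  $V = Z(G_0\otimes K)Z' + I\sigma^2_e$ over the 2050 records,
  $\hat b = (1'V^{-1}1)^{-1}1'V^{-1}y$ and
  $\hat u = \mathrm{Cov}(u,y)V^{-1}(y-1\hat b)$. This needs $K$ (never
  $K^{-1}$) and one Cholesky of order 2050 instead of a dense solve of order
  $2\cdot5275+1$ per scenario and method; $H$ itself comes from the
  conditional (Legarra) construction
  $H_{12} = G_w A_{11}^{-1} A_{12}$,
  $H_{22} = A_{22} + A_{21}A_{11}^{-1}(G_w - A_{11})A_{11}^{-1}A_{12}$,
  whose inverse is exactly the $H^{-1}$ formula above (verified in the
  tests). Solutions agree with the MME route to $10^{-8}$.
* **Meiosis sampling.** Interval switches are drawn as a Binomial count with
  uniform positions, thinned by $R_i/R_{\max}$ per chromosome - exactly the
  independent per-interval Bernoulli law, at a fraction of the cost. Each
  chromosome starts from a fair-coin haplotype. All randomness flows through
  R's RNG, so a replicate is bit-reproducible from its seed.
* **Ties and degeneracy.** MAF ranking breaks ties by ascending locus index;
  an infeasible heritability ($\sigma^2_e \le 0$) raises an error naming
  both variances; `accuracy` refuses zero-variance inputs; symmetric
  inverses go through Cholesky with an informative condition-number message.

## Problem sizes and what the reduced preset preserves

The full design scale (1000 historical generations, 100,000 loci, 44,000
panel loci, 20 replicates) reproduces the published tables directly but
costs hours. The package's reduced preset - 200 historical generations,
10,000 loci, 4,000 panel loci, 5 evaluated replicates plus 5
simulation-only replicates for TBV-level statistics - keeps **every
structural count** of the breeding design (2550 genotyped queens, 500
juveniles, 50 dams and 25 dummy sires per generation, 20 drones per dummy
sire, 86/78/86 QTL classes) and runs the whole replicated experiment in
minutes. Realized heritabilities, the maternal-direct correlation, overall
EBV accuracies and all qualitative rankings (UNI > PED; no-correlation >
negative; accuracy increasing in $h^2_m$) are stable at this scale.

The one quantity visibly sensitive to panel density is the accuracy of the
*direct-EBV component for juvenile queens* under the unified evaluation: a
juvenile's direct EBV draws on her own genotype through markers whose
effects are learned from records attached to workers (a path of about 0.5),
so it benefits most from dense panels. At 4,000 panel loci it runs a few
hundredths below the full-scale value. Relatedly, with the stated generator
(the record carries the queen's *own* direct TBV) the maternal component is
always estimated somewhat better than the direct component. Operational
honey-bee evaluations use their own conventions for worker-group
relationships; `build_A` isolates the recursion so alternative conventions
can be swapped in.

## Known limitations

The A recursion treats dummy sires and average workers as ordinary entries
with their recorded parent links; no group-size corrections are applied
(a probe with the colony-average worker diagonal changed accuracies by less
than 0.01). REML/Gibbs variance estimation, multi-trait models, marker-effect
(SNP-BLUP) formulations, inbreeding and genetic-gain trajectories, and
large-scale sparse/APY approximations of $H^{-1}$ are out of scope.
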