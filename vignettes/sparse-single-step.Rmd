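---
title: "Sparse single-step genomic evaluation with APY core groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse single-step genomic evaluation with APY core groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Single-step genomic BLUP (ssGBLUP) evaluates all animals in a breeding
population — genotyped or not — in one mixed-model system. The single-trait
animal model is

$$y = Xb + Zu + e, \qquad \mathrm{var}(u) = H\sigma^2_a, \quad
\mathrm{var}(e) = I\sigma^2_e,$$

and Henderson's equations carry $H^{-1}\lambda$ with
$\lambda = \sigma^2_e/\sigma^2_a$ in the random-effect block. The single-step
matrix replaces the inverse pedigree relationship matrix over all animals,
$A^{-1}_{\mathrm{full}}$, by

$$H^{-1} = A^{-1}_{\mathrm{full}} +
\begin{pmatrix} 0 & 0 \\ 0 & G^{-1} - A^{-1}_{22} \end{pmatrix},$$

where block 2 indexes the genotyped animals, $A_{22}$ is their pedigree
relationship block, and $G$ is a genomic relationship matrix put on the
pedigree scale. Variance components are inputs; the package does no REML.

The genomic matrix starts from the VanRaden cross-product
$G_m = (M - 2p\mathbf{1}')(M - 2p\mathbf{1}')' / \sum_j 2p_j(1-p_j)$ with
dosages 0/1/2 and allele frequencies $p$ taken from the genotyped animals
themselves. Because those frequencies are not base-population frequencies,
$G_m$ is rescaled as $G_a = \beta G_m + \alpha$, with $\beta$ and $\alpha$
solving the two-equation system that matches mean diagonal and overall mean
of $A_{22}$; finally $G = (1-w_a)G_a + w_a A_{22}$ blends a residual
polygenic proportion $w_a$ back in. The default $w_a = 0.25$ is the value
used by routine Danish pig evaluations for daily gain; any $w_a > 0$ also
keeps $G$ safely positive definite.

## The APY approximation and core groups

Inverting $G$ costs $O(n^3)$ in the number of genotyped animals. The
algorithm for proven and young animals (APY) splits genotyped animals into
a *core* group and a *non-core* group, inverts only the core block
$G_{cc}$, and treats each non-core animal as conditionally independent
given the core:

$$G^{-1} \approx \begin{pmatrix}
G_{cc}^{-1} + G_{cc}^{-1}G_{cn}D_{nn}^{-1}G_{nc}G_{cc}^{-1} &
-G_{cc}^{-1}G_{cn}D_{nn}^{-1} \\
-D_{nn}^{-1}G_{nc}G_{cc}^{-1} & D_{nn}^{-1}
\end{pmatrix},
\qquad D_{nn,ii} = G_{ii} - G_{ic}G_{cc}^{-1}G_{ic}'.$$

The result is sparse — dense only on the core block and the core/non-core
rims, diagonal elsewhere — and exact in the sense that its inverse
reproduces $G$ on every entry involving a core animal and on the non-core
diagonal. `apy_inverse()` accepts either a dense $G$ or a row provider so
the full matrix never has to be formed; only core rows and the non-core
diagonal are read.

$A^{-1}_{22}$ is needed alongside $G^{-1}$. It is computed by absorbing the
non-genotyped ancestors of the reduced pedigree,
$A_{22}^{-1} = A^{22} - A^{21}(A^{11})^{-1}A^{12}$, so only the usually
small non-genotyped block $A^{11}$ is factorized, and then sparsified by
zeroing entries in $[-10^{-4}, 10^{-4}]$. The thresholded matrix is
symmetric but *not necessarily positive definite* — the package checks and
reports definiteness rather than enforcing it, because the assembled
$H^{-1}$ is what must (and in practice does) stay positive definite. The
threshold applies only to $A_{22}^{-1}$, never to $A^{-1}_{\mathrm{full}}$.

The scientific question the package operationalizes is how to *choose* the
core group at a fixed size. The selectors implement: random subsets of
10/30/50% (which spread core animals across generations), the oldest or
youngest animals (single-generation cores), ranking by the number of
genotyped offspring, a hybrid that ranks older animals by genotyped
offspring but samples the last birth year at random, and a
minimum-mean-kinship core found by a genetic algorithm. Two reference
solves bracket the scenarios: the full inversion of $G$ (the accuracy
benchmark) and a pedigree-only run that discards genotypes.

## Numerical choices

* **Pedigree algebra.** Inbreeding uses the Meuwissen–Luo recursion
  (compiled); $A^{-1}$ uses Henderson's rules with the inbreeding
  adjustment included by default. Whether the original evaluations included
  inbreeding is not documented, so it is a flag (`inbreeding =`) rather
  than a hard-coded choice. Animals with unknown parents are treated as
  unrelated, non-inbred base animals. A full dense $A$ is never built at
  scale; `build_A()` takes a subset and works on the reduced pedigree.
* **Ordering.** All matrices are kept in topologically sorted pedigree
  order, with the genotyped animals' positions stored explicitly
  (`geno_index`), so the genotyped block of $H^{-1}$ is addressed by an
  index map rather than a physical reordering.
* **Scaling basis.** $\beta$ and $\alpha$ are fitted on all genotyped
  animals by default; `scaling_basis = "core"` refits them on the core
  animals only, which is the variant appropriate when only core rows of
  $G_m$ exist. With the dataset-wide default, all scenarios share one $G$,
  which isolates the effect of the core choice.
* **Solver.** The mixed-model equations are solved by conjugate gradients
  with a Jacobi (diagonal) preconditioner, stopping when the squared
  relative residual $r'r/b'b$ drops below `tol` ($10^{-10}$ by default).
  Iteration counts are only comparable within one tolerance/preconditioner
  setting, so the report always carries them next to the convergence flag;
  they are an internal conditioning diagnostic, not an externally
  calibrated quantity.
* **QC.** Marker filters run in a fixed order — SNP call rate (< 0.90
  removed), minor allele frequency (< 0.01), Hardy–Weinberg 1-df chi-square
  on genotype counts (p < 10⁻⁷), then animal call rate (≤ 0.90 removed) —
  and the report records counts per rule in that order. Missing calls that
  survive QC are mean-imputed (to $2p_j$) when $G_m$ is built; this is a
  deliberate stand-in for haplotype-based imputation, which is out of
  scope, and is flagged in the QC report.
* **Genetic algorithm.** The minimum-kinship core uses fitness = mean
  *off-diagonal* $A_{22}$ value within the subset (a singleton core
  reports 0 with a flag); diagonals are excluded because self-relationships
  cannot be reduced by subset choice and would mask the minimization
  target. Defaults: population 50, tournament 3, membership-uniform
  crossover repaired to the fixed subset size, swap mutation 0.1, 200
  generations with a 30-generation stall stop, elitist survival — so the
  optimizer can never return a worse core than a random subset. No
  hyperparameters were inherited from anywhere; these are conventional
  small-GA settings and are fully configurable via `ga_params()`.
* **Tie-breaks.** Offspring-count ranking breaks boundary ties by
  ascending animal id; age selectors sort by (birth year, id). "Last year
  of birth" means the maximum birth year among genotyped animals. In the
  hybrid selector, rounding remainders are charged to the older pool so
  the total core size is exactly `round(fraction × n_genotyped)`.
* **Comparisons.** Accuracy is the Pearson correlation between a
  scenario's EBV and the full-inversion reference, over genotyped animals
  (main criterion) and over all animals. Scenario pairs are tested with
  the Williams form of the Hotelling t for dependent correlations sharing
  a variable, with $n-3$ degrees of freedom and no multiplicity
  correction; which historical variant of that test the original analyses
  used is not documented, so the standard Williams form is implemented and
  stated here. Degenerate correlation triples (non-positive determinant)
  are errors, reported as `NA` rows by `run_experiment()`.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions at desk scale: 5
year-classes (one per generation), 3,600 founders and 3,600 offspring per
generation from 300 dam litters of 12 by 120 sires, for 18,000 pedigree
animals, all phenotyped; genotyping restricted to the last four birth
years with probabilities rising from 0.04 to 0.18, giving roughly 1,500
genotyped animals (a pedigree-to-genotyped ratio near 12, matching the
order of magnitude of routine pig data where the pedigree is several-fold
deeper than the genotyped cohort); 2,000 SNPs on 5 chromosomes of 1
Morgan with founder allele frequencies uniform on (0.05, 0.95); 200 QTL;
heritability 0.3 with $\sigma^2_a = 0.3$. Mating is random with no
selection — phenotyping precedes selection decisions in the emulated
design, and random mating avoids confounding selection with core-choice
effects (a truncation-selection stress test can be built from the
components directly). Gene dropping transmits founder haplotypes with
Poisson-count crossovers at uniform positions, so Mendelian consistency
holds at every locus by construction.

The simulator does **not** calibrate linkage disequilibrium to any real
breed, include mutation or genotyping error, or reproduce commercial
family structures. Consequently, passing tests demonstrate the algebraic
identities exactly, and the *direction* of the scenario comparison —
larger random cores help; cores spread over generations and rich in
genotyped offspring beat single-generation cores — but not the printed
correlation levels of any real dataset: with 2,000 SNPs and a shallow
pedigree, the effective number of independent chromosome segments, and
hence the absolute accuracy at a 10% core, differs from a 30k-SNP pig
population.

## Problem sizes used by the checks

The test suite verifies the exact identities at moderate sizes (dense
oracles up to 2,000 equations, pedigrees up to 1,000 animals, 20 random
replicates for the absorption identity, 10 seeds for the APY identities)
and runs the scenario comparison at the default study conditions above
for 10 master seeds, asserting median orderings only. These sizes were
chosen so the full suite exercises every code path at the scale where
dense reference computations are still exact.

## Known limitations

Single trait, homogeneous residual variance, no genetic groups or
metafounders, no reliabilities/PEV, no REML. The HDF5 side of the
interface formats is not provided; all persisted formats are plain text.
APY accuracy depends on the core capturing the population's independent
chromosome segments — with very small cores on high-dimensional data,
$D_{nn}$ can approach zero and the conditional-variance error message
names the animal the core cannot explain.
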