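---
title: "Single-step evaluation with reduced animal models: methods and design"
author: "ssram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step evaluation with reduced animal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssram)
```

# The models

## Single-step GBLUP

The single-trait animal model is $y = Xb + Za + e$ with $a \sim N(0, K\sigma_a^2)$
and $e \sim N(0, R)$, solved through Henderson's mixed-model equations

$$
\begin{pmatrix} X'R^{-1}X & X'R^{-1}Z \\ Z'R^{-1}X & Z'R^{-1}Z + K^{-1}\sigma_a^{-2}
\end{pmatrix}
\begin{pmatrix} \hat b \\ \hat a \end{pmatrix} =
\begin{pmatrix} X'R^{-1}y \\ Z'R^{-1}y \end{pmatrix}.
$$

For pedigree BLUP, $K = A$, the numerator relationship matrix, whose sparse
inverse comes directly from the pedigree: each animal contributes $1/D_i$ to
its own diagonal, $-1/(2D_i)$ to animal-parent pairs and $1/(4D_i)$ to
parent-parent pairs, where $D_i$ is the Mendelian-sampling variance ratio
($0.5 - 0.25(F_s + F_d)$ with both parents known, $0.75 - 0.25F$ with one,
$1$ with none; $F$ is the inbreeding coefficient, computed here by the
Meuwissen–Luo ancestor-tracing recursion). Single-step GBLUP combines
pedigree and genomic information in one system by replacing $A^{-1}$ with

$$
H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1} \end{pmatrix},
$$

where $G$ is the genomic relationship matrix of the genotyped animals
(VanRaden's first method, $G = M_cM_c' / 2\sum_j p_j(1-p_j)$ with genotypes
centered at $2p_j$) and $A_{22}$ the pedigree relationships of the same
animals. `subsetInverse()` produces $A_{22}^{-1}$ (and every other subset
inverse in the package) without forming a dense $A$, via the Schur
complement on the discarded block of the sparse $A^{-1}$:
$A_{22}^{-1} = A^{22} - A^{21}(A^{11})^{-1}A^{12}$, using a sparse Cholesky
factorization of the discarded block. No blending or scaling of $G$ toward
$A_{22}$ is applied; a singular $G$ is reported as an error rather than
silently repaired.

## The three reduced animal models

A reduced animal model (RAM) removes a set of animals from the equations and
recovers their solutions afterwards, exactly. The package implements three
reductions, which differ in what they keep alongside the genotyped animals
(genotyped animals always stay in the system so that back-solving never
touches the dense genomic block):

1. **Method 1 — keep genotyped animals and nongenotyped parents (`p`).**
   Phenotyped absorbed nonparents keep their records, but the record row is
   replaced by a parent-average row (0.5 at each known parent) and its
   residual variance is inflated by the animal's Mendelian-sampling
   variance: $\tilde R_{ii} = R_{ii} + D_i\sigma_a^2$. The genetic precision
   is $H_{pp}^{-1} = A_{pp}^{-1} + (G^{-1} - A_{22}^{-1})$ on the genotyped
   block. Absorbed animals are recovered by the regression
   $\hat a_i = B_i(y_i - x_i'\hat b - \mathrm{PA}_i) + \mathrm{PA}_i$, with
   $B_i = D_i\sigma_a^2 / (R_{ii} + D_i\sigma_a^2)$ and $\mathrm{PA}$ the
   parent average (an unknown parent contributes zero, so a single known
   parent contributes half its solution); a nonphenotyped absorbed animal
   gets the parent average itself.

2. **Method 2 — keep genotyped animals and nongenotyped phenotyped
   animals.** Every record stays on a kept animal, so no residual inflation
   occurs; the genetic precision is the same construction on this kept set.
   The absorbed animals are all nonphenotyped, and their solutions are the
   conditional means through pedigree-inverse blocks:
   $A^{nn}\hat a_n = -A^{np}\hat a_p$ — a sparse solve with no genomic
   terms.

3. **Method 3 — keep genotyped animals and nongenotyped parents of
   phenotyped nongenotyped nonparents (`q`).** This composes the two ideas:
   the system shrinks to $H_{qq}^{-1}$ with parent-average record rows, the
   remaining nongenotyped parents (`r`) are recovered through the blocks of
   $A_{pp}^{-1}$ (the method-1 subset inverse, still free of genomic
   terms), and the nonparents are then recovered by the Mendelian-sampling
   regression, their parents all being in $q \cup r$ by construction. A
   phenotyped nongenotyped parent is always assigned to `q`, never to `r`:
   its record needs an identity row in the design, so it cannot be
   absorbed.

All three merged solution sets equal the full ssGBLUP solutions; the test
suite asserts this to $10^{-8}$ on batches of simulated datasets and at the
printed precision on the worked example shipped as `ssramExample()`.

On the regression coefficient: the package uses
$B_i = D_i\sigma_a^2/(R_{ii} + D_i\sigma_a^2)$, equivalently
$(1 + R_{ii}D_i^{-1}\sigma_a^{-2})^{-1}$. This is the form that is
simultaneously the posterior regression of the Mendelian-sampling deviation
on the adjusted record and consistent with the residual inflation
$\tilde R_{ii}$ above (other superficially similar arrangements of the same
symbols are not, and fail the equivalence property immediately).

## The single-step marker model

The marker model fits marker effects directly: for genotyped animals the
genetic merit is $u = M_2\alpha + \delta$, for nongenotyped animals
$u = M_1\alpha + \varepsilon + \delta$, where $M_1$ is imputed by the
conditional mean $A^{11}M_1 = -A^{12}M_2$, $\varepsilon$ absorbs the
deviation between true and imputed marker merit (prior precision
$A^{11}\sigma_\alpha^{-2}$, defined for nongenotyped animals only), and
$\delta$ is a residual polygenic effect (prior precision
$A^{-1}\sigma_\delta^{-2}$). The total additive variance is
$\sigma_a^2 = \sigma_\alpha^2 + \sigma_\delta^2$.

**Scaling contract.** One variance $\sigma_\alpha^2$ serves both the
marker-effect prior ($I\sigma_\alpha^{-2}$) and the deviation prior
($A^{11}\sigma_\alpha^{-2}$). That is dimensionally coherent only if
$MM'$ is on the relationship scale, so `markerData()` divides the centered
genotypes by $\sqrt{2\sum_j p_j(1-p_j)}$ by default (a `"centered"` mode
leaves raw centered genotypes for users who supply their own scaling). With
this contract the marker model is numerically equivalent to ssGBLUP run on
$G_{eq} = (M_2M_2'\sigma_\alpha^2 + A_{22}\sigma_\delta^2)/\sigma_a^2$; the
tests assert the equivalence to $10^{-6}$. With zero markers both $\alpha$
and $\varepsilon$ vanish and the model collapses to pedigree BLUP on
$\delta$.

The same three reductions apply, with the pedigree inverse replaced by the
subset inverse and the record rows/residuals treated exactly as in ssGBLUP
(the inflation uses $\sigma_a^2 = \sigma_\alpha^2 + \sigma_\delta^2$, since
the absorbed Mendelian sampling spans the marker, deviation and polygenic
parts). Back-solving recovers merit, $\varepsilon$ and $\delta$ jointly.
For an absorbed phenotyped nonparent with
$\mathrm{dev} = B_i\,(y_i - x_i'\hat b - \mathrm{PA}_{\mathrm{merit}})$:

$$
\hat u_i = \mathrm{PA}_{\mathrm{merit}} + \mathrm{dev}, \qquad
\hat\varepsilon_i = \mathrm{PA}_\varepsilon +
  \tfrac{\sigma_\alpha^2}{\sigma_a^2}\,\mathrm{dev}, \qquad
\hat\delta_i = \mathrm{PA}_\delta +
  \tfrac{\sigma_\delta^2}{\sigma_a^2}\,\mathrm{dev},
$$

where a genotyped (or unknown) parent contributes zero to
$\mathrm{PA}_\varepsilon$. The variance-share factors follow from the joint
conditional distribution of the three components given the record and the
parents: each component's regression on the record deviation is
proportional to its share of the Mendelian-sampling variance. A plain
recycling of the merit regression for $\varepsilon$ would not reproduce the
full model; the shares do, which the reduced-vs-full equivalence tests pin
to $10^{-8}$. Nonphenotyped absorbed animals and absorbed parents use the
pedigree-block conditional means applied to merit, $\varepsilon$ and
$\delta$ alike (imputation consistency guarantees the marker part obeys the
same blocks).

## Pedigree pruning

Nongenotyped animals with no pedigree path into the genotyped block within
two hops contribute nothing to, and gain nothing from, the genomic data.
`prunePartition()` classifies animals as genotyped (2), direct pedigree
neighbours — parent, progeny or mate — of genotyped animals (3), neighbours
of class 3 (4), and the removable remainder (0). `prunePedigree()` drops
class 0; the removed animals can be evaluated by pedigree BLUP separately.
Removal is exact when the removed animals are absorbed leaves or founders;
when a kept animal loses a recorded parent the fixed-effect solutions can
shift slightly, so pruning is not applied implicitly anywhere — it is an
explicit, inspectable step, and the partition is exposed for inspection
rather than asserted to be exact beyond the two-hop rule.

# Tunable parameters

| Parameter | Meaning | Default |
|---|---|---|
| `sigmaA2`, `sigmaE2` | additive and residual variances (trait units²) | user-supplied |
| `sigmaAlpha2`, `sigmaDelta2` | marker and residual polygenic variances; sum defines `sigmaA2` | user-supplied |
| `withInbreeding` | inbreeding-adjusted $D_i$ in $A^{-1}$ | `TRUE` |
| `scale` in `markerData()` | relationship scaling of centered genotypes | `"relationship"` |
| `alleleFreq` | centering frequencies | observed |
| `solver`, `tol` | direct dense solve vs. Jacobi-preconditioned CG | `"direct"`, `1e-12` |

Fixed effects are reference-coded with the first-seen level as baseline;
animal solutions are invariant to the coding (tested against sum-to-zero
contrasts). Heterogeneous residual variance is supported per record via a
`residualVariance` column.

# Numerical choices

* Dense direct factorization is the default solver; the package targets
  desk-scale systems (up to a few thousand equations), and PCG with a
  Jacobi preconditioner is available beyond that. PCG stops at relative
  residual `1e-12` and errors on non-convergence rather than returning a
  stale iterate.
* $A^{-1}$ is held sparse (`Matrix` triplet/CSC); subset inverses use a
  sparse Cholesky of the discarded block. Symmetry is enforced to within
  round-off after every assembly.
* `invertG()` requires the smallest eigenvalue to exceed `1e-8` times the
  largest. Note that a $G$ centered at *observed* allele frequencies is
  always singular (the ones vector lies in its null space), and
  $\mathrm{rank}(G) \le$ the marker count; supply external frequencies or
  more markers rather than expecting blending, which this package does not
  do.
* Degenerate inputs: absorbed animals with zero known parents get $D_i = 1$
  and an all-zero design row; absorbed animals with repeated records are
  refused (a repeatability RAM is out of scope); an empty absorbed set
  makes every back-solve a no-op; a pedigree with no genotyped animals
  cannot anchor the pruning partition and is refused.

# What the simulator emulates — and what it does not

`simulateDataset()` produces discrete-generation random-mating pedigrees,
gene-drops unlinked biallelic loci (founder alleles Bernoulli at the locus
frequency, one random allele transmitted per parent), and phenotypes
$y = Xb + u + e$. Two truth models are available:

* `"marker"` (default): $u = M_c\alpha$, $\alpha \sim N(0, \sigma_a^2/k)$
  over the gene-dropped loci. Marginally $u$ has approximately the pedigree
  covariance $A\sigma_a^2$ (gene dropping reproduces expected identity by
  descent), and the genotypes are genuinely informative about $u$ — the
  configuration under which single-step evaluation should, and in the tests
  does, beat pedigree BLUP in accuracy.
* `"polygenic"`: $u_i = (u_s + u_d)/2 + m_i$, $m_i \sim N(0, D_i\sigma_a^2)$,
  the exact $A = TDT'$ recursion. A Monte-Carlo test with $10^4$ replicates
  confirms the per-animal Mendelian-sampling variances against $D_i$.

The simulator has no linkage, no selection, no QTL architecture and no
genotyping error. Passing equivalence tests on such data demonstrates the
algebraic identity of the reduced and full systems — which holds for any
data — but says nothing about, e.g., the realism of accuracy gains under
LD or selection.

# Test design and problem sizes

The worked 12-animal example (`ssramExample()`) pins every intermediate
matrix (sparse pedigree inverse, subset inverses, genomic inverse, reduced
designs, Mendelian-sampling quantities) and every solution vector to its
known values. The equivalence properties run on 20 seeded simulated
datasets of roughly 60–90 animals each (and a 400-animal pedigree for the
accuracy and oracle checks, 50 replicates for the accuracy comparison) —
sizes chosen so the whole suite runs in well under a minute while the dense
tabular oracle remains cheap to form. All equivalences are asserted at
$10^{-8}$ (reduced vs. full) and $10^{-6}$ (marker model vs. equivalent-G
ssGBLUP) with the direct solver.

# Known limitations

Single trait, single genetic effect; no unknown-parent groups or
metafounders (unknown parents are population mean); no G blending/tuning or
APY-style approximate inverses; no variance-component estimation; no
reliabilities/PEV; RAM variants do not support repeated records on absorbed
animals or maternal-effect models.
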