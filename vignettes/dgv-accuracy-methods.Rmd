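---
title: "Estimating the accuracy of direct genomic breeding values: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the accuracy of direct genomic breeding values: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A direct genomic breeding value (DGV) predicts an animal's additive genetic
merit from its SNP genotypes alone: marker effects are estimated in a
*training* set of animals with both genotypes and trait information, and a
selection candidate's DGV is the dosage-weighted sum of those estimated
effects.  Before DGV can be blended into a national evaluation, its
*accuracy* must be known.  `dgvacc` implements a complete workflow for
estimating that accuracy in beef-cattle-style data, where trait information
arrives as expected progeny differences (EPD) with Beef Improvement
Federation (BIF) accuracies rather than raw phenotypes:

1. convert EPD/BIF output into *deregressed EBV* (DEBV) with information
   weights;
2. estimate marker effects by weighted BayesC;
3. form cross-validation groups by K-means clustering on pedigree
   relationships, so validation animals are as unrelated as possible from
   their training sets;
4. pool the five validation sets and estimate the genetic correlation
   between the trait and its DGV — the accuracy measure — with a weighted
   bivariate animal model whose relationship matrix is block-diagonal by
   cross-validation group;
5. compare selection on DGV against selection on parent-average
   information.

Because no genotype or evaluation data are distributable with this kind of
study, the package ships a synthetic-herd generator with known truth; every
stage is tested against that truth or against independent brute-force
oracles.

# Deregression and weighting

National EBVs are shrunken and contain the parent average (PA), so they are
unusable as regression responses: siblings' EBVs would be correlated purely
through their shared PA, and low-reliability EBVs would be over-shrunk.
Each animal's EBV (= 2 EPD) with reliability $r^2 = 1 - (1 -
\mathrm{BIF})^2$ is therefore deregressed through the 2x2 mixed-model
information system in the unknowns (parent average, individual).  With
$\lambda = (1-h^2)/h^2$, $\alpha = 1/(0.5 - r^2_{PA})$ and $\delta = (0.5 -
r^2_{PA})/(1 - r^2)$,

$$Z'Z_{PA} = \lambda(0.5\alpha - 4) + 0.5\lambda\sqrt{\alpha^2 + 16/\delta},
\qquad Z'Z_i = \delta\, Z'Z_{PA} + 2\lambda(2\delta - 1),$$

the DEBV is the individual right-hand side divided by its own information,
and its reliability is $r^2_{DEBV} = Z'Z_i / (Z'Z_i + \lambda)$.  The
information weight used everywhere downstream is

$$w = \frac{1 - h^2}{\left(c + \frac{1 - r^2_{DEBV}}{r^2_{DEBV}}\right) h^2},$$

with $c = 0.40$ the proportion of genetic variance not captured by markers.
Records with $r^2 \le r^2_{PA}$ contain no own or progeny information; they
are flagged uninformative and dropped from training, which is why training
counts differ between traits.

Two boundary conventions are worth stating.  When an animal's parents are
unknown (or carry no information), the computation switches to simple
deregression, $\mathrm{DEBV} = \mathrm{EBV}/r^2$ with $r^2_{DEBV} = r^2$;
this is *not* the continuous limit of the 2x2 system as $r^2_{PA} \to 0$
(fitting a zero-information PA effect changes the implied own-information),
but it is the correct model for a record that never contained a parent
average.  And parent-average reliability is computed as $(r^2_{sire} +
r^2_{dam})/4$, the standard additive-model value, from the parents' current
(progeny-inflated) evaluations.

# Weighted BayesC and DGV prediction

Marker effects are estimated under

$$y_i = \mu + \sum_{j=1}^k z_{ij} u_j + e_i,\qquad
u_j \sim \begin{cases} 0 & \text{with probability } \pi\\
N(0, \sigma^2_u) & \text{with probability } 1 - \pi \end{cases},\qquad
\mathrm{Var}(e_i) = \sigma^2_e / w_i,$$

with $\pi = 0.95$ fixed, by a single-site Gibbs sampler (compiled code;
marker inclusion sampled from the marginalized conditional odds, effects
from their Gaussian full conditionals, variances from scaled-inverse-
chi-square full conditionals with prior degrees of freedom 4).  Prior scale
parameters come from a variance partition of the full training data:
genetic scale $h^2 \mathrm{Var}(y)$ spread over the expected heterozygosity
of the included marker fraction, residual scale $(1 - h^2)\mathrm{Var}(y)$.
The DGV is $\mathrm{DGV}_i = \sum_j z_{ij}\hat u_j$ over posterior-mean
effects, on raw 0-2 dosages and without the intercept — a constant shift
cannot affect the correlations and variances evaluated downstream, and
group-mean differences are absorbed by the bivariate model's group fixed
effects.

The sampler's defaults follow the reference protocol (41 000 sweeps, 1000
burn-in); the analysis scripts and tests run 2500/500 and 1500/300
respectively, which is enough for posterior means of effects at these
problem sizes (checked against the closed-form SNP-BLUP solution at
$\pi = 0$ within Monte-Carlo error).

# Cross-validation by relatedness clustering

Random cross-validation folds leave close relatives of every validation
animal in training, which inflates apparent accuracy through family means
rather than marker-QTL association.  Instead, the numerator relationship
matrix $A$ over the genotyped animals (built by the tabular method over the
full pedigree, so ungenotyped ancestors still inform every coefficient) is
turned into a difference matrix $D = \max(A) - A$ (diagonal zeroed; using
the matrix maximum rather than 1 keeps inbred diagonals from producing
negative dissimilarities), and the rows of $D$ — each animal's
dissimilarity profile — are clustered by Hartigan-Wong K-means into $K = 5$
groups, best of 50 seeded restarts.  Each fold trains on four groups and
predicts the fifth, so no animal's DEBV influences its own DGV; per-fold
seeds derive deterministically from the master seed so folds are
reproducible in isolation and independent of execution order.

Clustering quality is reported as each animal's maximum relationship to its
own group (`amax_within`) and to all other groups (`amax_between`),
excluding the self-relationship; successful clustering shows within >
between in every group.

# The bivariate animal model

Accuracy is estimated as the genetic correlation $r_g(T, \mathrm{DGV})$
from a two-trait animal model on the stacked vector (DEBV, DGV) of all
cross-validated animals: fixed effects are the trait mean (DEBV side) and
the five group class effects (DGV side); the additive effects of the two
variables share a relationship matrix $G$ that keeps pedigree relationships
*within* each cross-validation group and zeroes them *between* groups.
Zeroing makes the restricted likelihood separate over groups — estimation
pools the per-group information about a common parameter set — and removes
the cross-products between an animal's DGV and the DEBV of the animals that
trained it.  Residuals are uncorrelated across variables; the DEBV residual
is heterogeneous, $\mathrm{Var}(e_{1i}) = \sigma^2_{e1}/w_i$ with the same
weights as training, and the DGV residual homoscedastic.  (The alternative
placement of the weights on the DGV residual is available via
`weight_side = "dgv"` for comparison; weighting the DEBV residual is the
internally consistent choice, since the weights are defined by DEBV
reliability and the DGV of a noiseless genotype function has essentially no
residual at all.)

REML is computed by direct maximization of the restricted log-likelihood
over a log-Cholesky parameterization of the 2x2 genetic covariance matrix
(which enforces positive semidefiniteness) plus log residual variances,
with two Nelder-Mead passes at relative tolerance 1e-12.  Within each
group, the likelihood is evaluated in the eigenbasis of the group's
relationship block (decomposed once per fit): the homoscedastic side
becomes diagonal there, and each evaluation reduces to a single Cholesky of
an $n_g \times n_g$ Schur complement, which is what makes fits at a few
thousand animals take seconds rather than hours.  Residual variances are
floored at $10^{-8}$ of the corresponding phenotypic variance;
`sigma2_e_dgv` sitting on that floor is reported as converged-at-boundary
and is the expected outcome when the DGV is an exact genotype function
(heritability 1).  Standard errors come from the numerically differentiated
observed information at the optimum and the delta method for $r_g$ and
$h^2_{DGV}$; at a boundary they are reported as `NA` rather than from an
invalid quadratic approximation.  This estimator was chosen over
EM-with-average-information iteration for robustness at exactly that
boundary; on interior problems the two coincide, and the implementation is
tested for equality with an independent dense-likelihood maximization at
$n \le 40$ and for parameter recovery (true $r_g = 0.6$, $n = 600$, 20
replicates, mean within $\pm 0.05$).

Selection efficiency per trait is $r_g(T,\mathrm{DGV}) / \sqrt{R^2_{PA}}$,
the ratio of the two accuracies under equal selection intensity and
generation interval.  The trait-level $R^2_{PA}$ is the cohort mean of the
per-animal values (the aggregation is not uniquely defined by the published
tables; the per-animal distribution is always retained so the choice is
auditable, and per-animal efficiencies routinely exceed 1 for
low-$R^2_{PA}$ animals even when the trait-level efficiency is below 1).

# The synthetic herd

The generator produces the study conditions every test runs under:

* **Pedigree** — founders split into 8 semi-closed clans (herd lines);
  each later generation keeps the population size, draws 2 heavily used
  AI-like sires per clan (unequal half-sib family sizes via Dirichlet
  weights) plus natural-mating bulls for 40% of matings, and 5% of dams
  migrate between clans.  Clan structure gives the relatedness clustering
  genuine signal; the AI/natural sire split reproduces the bimodal
  parent-average reliability pattern.
* **Genotypes** — unlinked biallelic SNPs gene-dropped through the
  pedigree: founders drawn from Hardy-Weinberg at frequencies uniform on
  (0.05, 0.95), each gamete carrying the B allele with probability
  dosage/2.  No linkage map is simulated: none of the estimation stages
  uses linkage, so independence exercises every code path while keeping
  the truth analytically checkable.
* **Trait** — a sparse subset of markers (default 5% of the panel) receives
  normal effects; the residual variance is set so the realized heritability
  equals the target exactly.
* **Evaluations** — each animal gets a target reliability from a mixture
  (high for heavily used sires, around the configured mean otherwise), and
  EBVs are built recursively in pedigree order as
  $\mathrm{EBV}_i = (1-b)\,\mathrm{PA}_i + b\,\mathrm{TBV}_i + e_i$ with
  $b = (r^2 - r^2_{PA})/(1 - r^2_{PA})$ and
  $\mathrm{Var}(e) = b(1-b)(1-r^2_{PA})\mathrm{Var(TBV)}$.  This keeps the
  regression property ($\mathrm{Var(EBV)} = \mathrm{Cov(EBV, TBV)} = r^2
  \mathrm{Var(TBV)}$, so the squared EBV-TBV correlation equals the
  assigned reliability) while embedding a real parent-average component —
  the component deregression exists to remove.  An earlier design that
  generated EBVs as independent blends of TBV and noise made the
  deregression *add* parental noise instead of removing shared signal,
  inflating DEBV residual variance several-fold and pushing the estimated
  $r_g$ to the boundary; the blend construction fixed this, and for
  founders it reduces exactly to $r^2\,\mathrm{TBV}$ plus noise.

What the generator does **not** emulate: linkage and LD (so accuracy here
flows entirely through genotyped causal loci, not marker-QTL LD decay),
genotyping error, selection (no Bulmer effect — parent-average reliabilities
are taken at face value, as in the efficiency tables), multi-breed
admixture, and maternal/direct trait pairs.  Passing tests therefore show
the estimation machinery is correct under the stated model, not that field
accuracies for any particular breed are reproduced — those depend on the
unavailable proprietary data.

# Problem sizes and numerical conventions

The analysis scripts run the full pipeline at 2000 genotyped animals x
2000 SNPs with 2500-sweep chains (about five minutes end to end); the test
suite uses 200-600 animals and chains of a few hundred to a few thousand
sweeps, sized so the whole suite finishes in minutes while Monte-Carlo
error stays well inside each assertion's band.  Other conventions:
monomorphic markers get a Hardy-Weinberg p-value of 1 and are removed by
the MAF rule instead; QC statistics are computed on the analysis dataset
itself; K-means ties break by first-found under the seeded restart order,
and an initialization that produces an empty cluster is discarded; report
tables round half-away-from-zero to 2 decimals (with a 1e-9 epsilon so
decimal halves sitting just under .5 in binary round the way they read);
genetic correlations outside [-1, 1] by numerical rounding are clamped and
logged.
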