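---
title: "Quantifying morphological divergence among clonal strains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying morphological divergence among clonal strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonodiverge)
```

## The problem

In parthenogenetic (clonal) arthropods every individual of a strain is
genetically identical, so any systematic difference between strains in a
morphological character is genetic. clonodiverge analyses tables of
per-individual character counts — the kind of chaetotaxy data scored under a
light microscope for springtails: numbers of setae and sensilla on named body
parts, presence/absence of structures, sometimes scored separately on the
left and right body side — and asks four questions:

1. Which characters differ between strains at all?
2. How heritable is each character, in the broad sense?
3. What tree relates the strains cladistically (parsimony on coded states)?
4. What tree relates them phenetically (UPGMA on scaled means), and how
   strongly does the data support each cluster?

Because such datasets are small (a dozen strains, around ten individuals
each) every stage is also exercised against a synthetic generator with known
ground truth, so the pipeline can be validated without any particular
dataset.

## Character models and the divergence test

Characters come in three shapes. Pure binary characters (a seta aligned or
not, a claw tooth present or not) and wide-range counts (18–32 setae on a
segment) are modelled directly as binomial (logit link) or Poisson (log
link) responses. Between these sit "near-binary" counts: almost all
observations take one of two adjacent values, with rare single outliers. A
`threshold_rule` maps such a character onto two states — every value at or
below an integer cut versus the rest — so it can be analysed as binomial.
The rule is total and monotone; which side is coded 1 does not matter
because the likelihood-ratio statistic is invariant to flipping the coding
(this is a tested property).

The divergence test for a character is an analysis of deviance: the GLM with
strain as a factor versus the intercept-only model,

$$\chi^2 = D_{\text{null}} - D_{\text{strain}}, \qquad
  \mathrm{df} = n_{\text{strains}} - 1,$$

with the p-value from the upper chi-square tail. A single chi-square on
(strains − 1) degrees of freedom per character is exactly what a
model-comparison deviance test produces, which is why the likelihood-ratio
form was chosen over a Wald test. The GLM itself is fitted by iteratively
reweighted least squares written out in `fit_glm()` rather than delegated,
because the degenerate cells endemic to this kind of data (a strain fixed at
0 or 1 for a binary character) need explicit handling: boundary coefficients
are clamped at ±20 on the link scale, which puts each cell's deviance within
about 1e-8 of its mathematical limit while keeping every likelihood-ratio
statistic finite. The test suite checks `fit_glm()` against a generic
numerical maximizer of the exact likelihood (BFGS on the log-likelihood) on
random instances, to 1e-6 in deviance.

Per-strain means and 95% intervals come from the strain-factor model without
intercept: each coefficient is the strain's MLE on the link scale, with Wald
intervals (±1.96 standard errors from the Fisher information)
back-transformed to the response scale. Boundary cells report the exact mean
with a `degenerate` flag instead of a sham interval.

Missing observations are dropped per character (complete cases per
character): in real material not every character is visible on every slide.
Bilateral characters contribute one observation per side, treated as
independent; the degrees of freedom of the divergence test do not depend on
how many observations a cell has, only on how many strains are observed.
No multiple-testing correction is applied; the summary exposes raw p-values
and the 0.05 flag, and α = 0.05 is the (configurable) gate that admits
characters to all downstream stages.

## Broad-sense heritability

For clonal strains, broad-sense heritability is the intraclass correlation

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_E},$$

where σ²G is the between-strain variance of a random-intercept generalized
linear mixed model and σ²E is the residual variance. The GLMM is fitted by
penalized quasi-likelihood: iterate (a) the IRLS linearization of the
response around the current fit and (b) REML estimation of the variance
components of the resulting working linear mixed model, until σ²G changes by
less than 1e-6 (relative). For a single random intercept the REML profile
has closed-form group sums, so the inner step is a one-dimensional
optimization; the estimate may sit at the σ²G = 0 boundary and is reported
there without jitter. The implementation agrees with `MASS::glmmPQL` to
within a few percent on the same data (a test cross-checks this).

σ²E has to be pinned to a scale because a GLM has no free residual variance.
We use the latent-scale convention that makes H² comparable across
characters: π²/3 (the logistic variance) for binomial characters, and
log(1 + 1/λ̄) for Poisson characters (the lognormal-Poisson approximation,
with λ̄ the grand mean count). The synthetic generator records the same
quantity as its ground truth, so recovery can be tested: at 50 strains × 50
individuals the mean estimate is within ±0.05 of truth for H² ∈ {0.2, 0.5}
in both families and for Poisson at 0.8, and the estimate is monotone in the
generative σ²G (Spearman ρ > 0.9 across a six-point grid). See Limitations
for the one setting where PQL falls marginally short.

Only characters that passed the divergence test enter the heritability
table: a character with no detectable between-strain variation has no
meaningful H².

## Character coding and parsimony

The cladistic matrix codes each significant character per strain: centre the
strain means by their unweighted average over strains, scale by their
standard deviation, and assign state 1 where the scaled value is strictly
positive. Strains at or below the average take state 0 — the boundary goes
with "not greater", since the defining rule assigns 0 to strains *below* the
average. Scaling cannot change a sign, so the parsimony input is insensitive
to the scaling constant (a tested invariant, along with invariance to any
positive affine rescaling of a character's means).

Tree length is Fitch parsimony — characters unordered, equally weighted,
reversible — computed by the two-pass set-intersection algorithm on an
arbitrary rooting. The search for *all* minimum-length trees is an exact
branch and bound: taxa are added stepwise in sorted-label order (making the
search deterministic), each partial tree is scored, and a branch is
abandoned when its length plus a lower bound on the remaining taxa exceeds
the best complete length. The bound adds one change for every
(character, state) pair present among unplaced taxa but absent from the
placed ones; the initial best length comes from a greedy addition tree.
Because pruning only ever discards branches whose completions provably
exceed the optimum, the returned set equals exhaustive enumeration — the
acceptance suite verifies score, tree count and the exact tree set against
enumeration of all 945 seven-taxon topologies. Uninformative columns are
retained in the score (they add a constant) and counted. Weakly structured
matrices can have very many minimum-length trees, so the number of *stored*
topologies is capped (default 500); the score, the count and the
strict-consensus splits are accumulated during the search and remain exact
regardless of the cap.

The strict consensus contains exactly the nontrivial splits shared by every
minimum-length tree, multifurcating where they disagree. Rooting between two
externally defined clades (for instance clades established by prior
molecular work — config data, not code) picks the edge whose bipartition
separates the clades; a taxon belonging to neither clade is assigned to
whichever side it attaches to, and when several edges qualify the one
placing the fewest taxa on the first clade's side is chosen,
deterministically. Re-rooting never changes the unrooted split set.

## UPGMA and multiscale-bootstrap support

The phenetic companion tree is average-linkage (UPGMA) clustering of
Euclidean distances between rows of the scaled strain-mean matrix. Merge
height is half the merge distance, so the dendrogram is ultrametric, branch
lengths are height differences, and ultrametric input is reproduced exactly
(cophenetic = input, a tested oracle; random matrices are checked against
`stats::hclust(method = "average")`). Ties are broken toward the
lexicographically smallest pair of cluster labels — on degenerate inputs tie
order can change the topology, so it must be deterministic.

Cluster support uses multiscale bootstrap resampling with characters
(columns) as the resampling unit, since the rows being clustered are strain
profiles over characters. For each scale r in {0.5, …, 1.4} the data are
resampled to round(r·m) columns n_boot times (default 1000), columns are
re-standardized within each resample (a toggle exposes the alternative), and
BP_r is the fraction of resamples whose UPGMA dendrogram contains the
cluster. The signed distance and curvature (v, c) are fitted by weighted
least squares from

$$\psi_r = \Phi^{-1}(1 - \mathrm{BP}_r) = v\sqrt{r} + c/\sqrt{r},$$

with binomial delta-method weights, and the approximately unbiased p-value
is AU = 1 − Φ(v − c). Scales where BP is exactly 0 or 1 carry no
information about ψ and are excluded from the fit; a cluster recovered in
every usable resample gets AU = 1, one never recovered gets AU = 0, and a
cluster with fewer than two informative scales is flagged undefined. The fit
is exercised on noiseless synthetic BP curves (exact recovery of v and c)
and the whole procedure is bit-reproducible under a fixed seed, which the
interface makes mandatory.

## The synthetic generator

`generate_observations()` simulates the generative model the analysis
assumes: per character, strain effects on the link scale are
Normal(0, σ²G), optionally shifted ±clade_effect/2 by clade membership
(scaled by a per-character sign, so a clade can be "hairier" in some
characters and balder in one); individuals (and sides, drawn independently)
are binomial or Poisson draws through the canonical link. Near-binary counts
are emitted as a base count plus the binary state, with rare ±1–2 outlier
excursions mimicking variants that occur singly; observations go missing at
a configurable rate. The truth record keeps every latent value and the
implied latent-scale H², so recovery tests never need re-simulation.

Defaults mirror the study system the package was designed around: 12
strains, 8–12 individuals each, 18 characters spanning pure binary,
near-binary and wide-count shapes, with latent variances spanning
non-heritable to highly heritable (on the latent scale, an H² of 90% for a
binary trait corresponds to a very large logit variance — strains close to
fixation — which is exactly what highly heritable presence/absence
characters look like). The two-clade configuration used for end-to-end
checks puts 5 + 7 strains in two clades with a logit-scale clade effect of
2.0 against a within-clade latent sd of 0.5, i.e. the between-clade shift
is four within-clade standard deviations; with 8 informative characters
both the parsimony consensus and the UPGMA dendrogram recover the two-clade
split in ≥90% of seeds (tested over 50).

What the generator does *not* emulate: left–right correlation within an
individual (sides are independent draws), age or size covariates,
observer effects, and any specific strain-by-strain distribution of a real
dataset — only the statistical shapes. Passing tests therefore validate the
statistical machinery, not any claim about a particular organism.

## Problem sizes used in the tests

The acceptance suite runs at fixed, pre-registered sizes chosen to make the
Monte-Carlo error small relative to the tolerances: 1000 simulated null
characters at 12 strains × 10 individuals for the type-I check (expected
rate 5% ± 2%); 20 replicates at 50 strains × 50 individuals per
heritability setting; 20 random 7-taxon matrices against full enumeration;
50 seeds for the end-to-end two-clade recovery. The whole suite runs in a
few minutes on one core.

## Limitations

* **PQL bias for extreme binary heritabilities.** For binary characters with
  very large latent variance (true H² ≈ 0.8, i.e. σ²G ≈ 13 on the logit
  scale) penalized quasi-likelihood underestimates σ²G; the mean recovered
  H² at 50 strains × 50 individuals is ≈ 0.745, just outside the ±0.05
  recovery band that all other settings meet. This matches
  `MASS::glmmPQL` on the same data to within a few percent, so it is a
  property of PQL itself — the price of staying with the estimator the
  analysis tradition uses — and it is conservative: extreme heritabilities
  are shrunk toward the middle, never inflated. An integrated-likelihood
  fit would remove the bias at the cost of no longer matching PQL-based
  results.
* **Latent-scale convention.** H² values depend on the residual-variance
  convention (π²/3, log(1 + 1/λ̄)); comparisons with H² computed under a
  different convention are only meaningful within a few percentage points.
* **Tree scale.** The branch and bound is exact but exponential; it is
  intended for the ≤ ~15-taxon matrices this kind of study produces (12
  taxa with 14 characters takes about a second), not for large phylogenies.
* **AU p-values** are asymptotic in the number of characters; with fewer
  than ~10 characters the ψ–r regression rests on few, coarse BP values and
  AU should be read qualitatively.
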