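---
title: "Causal gene-regulatory-network inference with genetic instruments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal GRN inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model and its assumptions

`grniv` treats gene regulation as a linear structural equation system over
`p` genes and `q` genetic variants observed in `n` samples,

$$Y = Y\Gamma + X\Psi + \epsilon,$$

with $\Gamma$ a $p \times p$ matrix of directed regulatory effects whose
diagonal is identically zero, $\Psi$ a $q \times p$ sparse matrix of cis
genetic effects (nonzero only for variants near the gene they act on), and
$\epsilon$ Gaussian disturbances independent of $X$. The system is *not*
required to be acyclic: reciprocal regulation and feedback loops are
representable, provided $I - \Gamma$ is invertible so the reduced form
$Y = (X\Psi + \epsilon)(I - \Gamma)^{-1}$ exists.

Identification rests on the instrumental-variable argument: a cis variant
affects its own gene's expression directly, is randomized at meiosis
(independent of $\epsilon$), and affects other genes only through its
gene's expression. The per-gene limited-information model regresses each
target gene on the *genetically predicted* expression of all candidate
regulators, after projecting out the target's own cis component with the
residual-maker $H_k = I - X_{S_k}(X_{S_k}^\top X_{S_k})^{-1}X_{S_k}^\top$;
a gene with no instruments gets $H_k = I$. Inside `fit_gene()` the
projection span is augmented with an intercept column: the operator then
annihilates both the instrument columns and the constant direction, so
mean-centered responses stay centered. Without this, the centered response
retains a multiple of the (uncentered) instrument column and the target's
own cis signal leaks into the stage-2 regression — measurable as a
systematic correlation between the projected response and other genes'
predictions.

Key assumptions a user should keep in mind: effects are linear and
homogeneous across samples; instruments act only in cis (no direct
pleiotropy onto other genes); confounding between expression traits is
captured by the disturbances, which the instruments are independent of by
randomization; and a regulator can only be *detected* if it has at least
one instrument (the rank condition). The last point is why candidate
regulators default to instrumented genes (`require_iv = TRUE`), while
uninstrumented genes can still appear as targets.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `flank` | 1000 bp | cis window extension beyond the gene body |
| MAF strata | 0.05 / 0.01 | common / low-MAF / rare boundaries |
| `alpha` | 0.05 | per-candidate instrument significance gate |
| `max_ivs`, `cor_cut` | 3, 0.3 | instrument cap; pairwise absolute-correlation bound |
| `alpha0`, `n_perm` | 0.1, 1000 | aSum flip threshold; phenotype permutations |
| `isis_target_size` | `floor(n / log n)` | columns kept by screening (sure-screening scale) |
| ridge grid | 50 points, `[1e-4, 1e4] x mean(d²)` | scale-free GCV search |
| `lasso_folds`, `lasso_rule` | 10, `"1se"` | stage-2 cross-validation |
| `hwe_alpha`, `mac_cut` | 1e-4, 5 | genotype QC: HWE exact test, minor-allele count |
| missing-rate cuts | 0.10 / 0.10 | sample-wise, then variant-wise |
| `n_pcs` | 3 | genotype PCs removed before instrument discovery only |
| `B`, cutoffs | 1000-scale; here 25–100; 1.0, 0.95 | bootstrap replicates and reporting thresholds |

Two expression versions are carried through the pipeline: covariate-
adjusted expression for the transcriptome-wide stages, and additionally
PC-adjusted expression used only for instrument discovery. Removing
genotype principal components guards local association scans against
population stratification; they are deliberately *not* removed from the
expression used for network estimation, where global regulatory signal
would be lost. With very few variants (toy systems) the top PCs span the
entire genotype space and would erase all cis signal, so small fixtures
run with `n_pcs = 0`.

## The stage-2 selection rule

The adaptive LASSO uses ridge-based weights $w_j = 1/|\hat\beta_j^{ridge}|$
and k-fold cross-validation along the penalty path. We select the
*one-standard-error* penalty rather than the raw CV minimum. This was a
genuinely open design point, and the raw minimum fails a property the
method is supposed to have: with a single candidate regulator (the
two-gene system), the CV curve under the null hypothesis is flat to within
$O(\sigma^2/n)$ while its fold-to-fold noise is $O(\sigma^2/\sqrt{nk})$,
so the minimizer lands at an interior penalty — and declares a false
reverse edge — in roughly a third of null datasets. The 1-SE rule collapses
such ties toward the sparser model; empirically the forward edge is kept in
50/50 simulations and the reverse edge in 0/50, and the benchmark network
is recovered at median precision and recall of 1.0. Edge *magnitudes* are
shrunk in exchange (the two-gene effect 0.5 is estimated around 0.17);
the method's output of record is the support and its bootstrap frequency,
not the coefficient size.

# What the generator emulates — and what it does not

`simulate_network()` / `simulate_dataset()` produce: dosages drawn
variant-wise as Binomial(2, MAF) under Hardy–Weinberg proportions at
chosen MAF strata; each gene owning a disjoint 2 kb interval (10 kb
spacing) with its instruments placed inside, so cis-window scanning
exercises real coordinate geometry; random-sign regulatory and cis
effects with magnitudes uniform on configurable ranges (defaults
0.4–0.8 and 0.7–1.2, the benchmark's conditions); spectral rescaling of
$\Gamma$ to radius < 0.8 so cyclic systems stay solvable; optional
covariate effects injected *through the disturbance term* so the
structural identity $Y(I-\Gamma) = X\Psi + \epsilon$ holds exactly for
the stored draw; optional genotype missingness; and a negative-binomial
count rendering for count-level preprocessing tests.

It does **not** emulate linkage disequilibrium, haplotype phase,
admixture, trans-eQTLs, nonlinear or context-dependent regulation, or
realistic library-composition artifacts. Passing tests on this generator
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions — not robustness to LD-confounded instruments or
model misspecification on real cohorts.

Benchmark problem sizes used throughout the tests and the acceptance
script — 30 genes, 90 variants, n = 500, 10 simulation seeds, B = 50
bootstrap replicates, 1000 null datasets for test calibration — are the
package's chosen study conditions for a desk-scale, fully reproducible
benchmark.

# Numerical choices

* **Ridge + GCV** is solved through the singular-value decomposition;
  `GCV(λ) = n·RSS/(n − tr S_λ)²` with ties toward the smaller penalty,
  and penalties with `n − tr S_λ ≤ 0` excluded. The test suite
  cross-checks the curve against a dense linear solve and the minimizer
  against `MASS::lm.ridge`.
* **Weighted L1** goes through `glmnet` (`penalty.factor`), with columns
  standardized internally and coefficients returned on the original
  scale; initial estimates below 1e-10 exclude a column outright. A fixed
  `lambda` is solved exactly (no path interpolation); `lambda = 0`
  reduces to least squares, which is how the classical two-stage
  least-squares equivalence is exercised. The single-candidate case uses
  the closed-form soft-threshold path with the same CV; the path's top
  penalty is pinned to `λ_max` exactly so the null model is exactly
  representable (with `exp(log(λ_max))` the threshold misses by one ulp
  and leaks 1e-18-sized "edges").
* **Cross-validation folds** are assigned by sorted sample id, not by row
  position, making every fit invariant to row permutations and worker
  counts; all remaining randomness derives from one master seed through a
  counter scheme (seeds stay below 2³¹).
* **Hardy–Weinberg** uses the conditional exact test, summing the
  probabilities of heterozygote counts no more likely than observed, with
  a `1 + 1e-12` tie guard on the probability comparison.
* **TMM** is implemented from its published definition (30% M-trim, 5%
  A-trim, inverse-asymptotic-variance weights, upper-quartile reference,
  geometric-mean renormalization) and agrees with
  `edgeR::calcNormFactors` to 1e-10 on random count tables. Normalized
  output is `log2` of TMM-scaled, mean-library counts with a +0.5 offset.
* **Count normalization for the variance-stabilizing path** uses
  median-of-ratios size factors (medians on the *ratio* scale, matching
  the standard definition for even gene counts) with `log2(x/s + 1)`
  output. This is a deliberate substitute for a fitted mean–dispersion
  variance-stabilizing transform: downstream stages only require
  log-scale, depth-corrected expression.
* **Modularity** follows the printed formula over all ordered gene pairs
  *including* the `i = j` null term (self-edges are structurally zero).
  Retaining that term is what makes the all-in-one-community score
  exactly zero — the degree sum equals `2N`, so the null term cancels the
  edge term — and makes the score coincide with standard Newman
  modularity of the symmetrized graph, verified against `igraph` and
  against brute-force enumeration of all 4140 partitions of 8-node
  graphs. Greedy merging runs per weakly connected component (cross-
  component merges cannot raise Q), with ties broken toward the lowest
  community-id pair for cross-platform determinism.
* **Degenerate inputs**: collinear instrument columns are pruned by
  pivoted QR at 1e-10; genes with no instruments get the identity
  projection and are excluded as candidate regulators; constant dosage
  columns are skipped with a log entry; all-missing variants, all-zero
  libraries and empty post-QC matrices raise errors rather than
  propagate.

# Bootstrap and reporting conventions

Replicates resample the *adjusted* dataset (confounder adjustment sits
outside the loop) and re-run instrument discovery by default
(`refit_ivs = TRUE`), so the reported frequency reflects uncertainty in
the whole pipeline; freezing the instrument map is available for speed.
Replicate seeds derive from `(seed, b)` independently of execution order;
completed replicates can be cached as plain TSV and resumed with an
identical aggregate. Zero-frequency pairs are never materialized, so
thresholding at 0 returns exactly the pairs seen at least once.
Thresholded edge sets are nested across cutoffs by construction, and the
reported graph keeps only genes incident to at least one edge.

# Known limitations

Linear effects only; no standard errors or p-values for regulatory
effects (bootstrap frequency is the confidence currency); coefficient
magnitudes are conservative under the 1-SE rule; instruments in strong LD
with another gene's causal variant would violate the exclusion
restriction but are not simulated; full-information (joint likelihood)
estimation of the whole system is out of scope, as are reference-panel
genotype imputation, surrogate-variable batch correction, enrichment
analysis and interactive visualization.
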