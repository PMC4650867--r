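---
title: "Prioritizing condition-specific master regulators by fusing network degree ranks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing condition-specific master regulators by fusing network degree ranks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverrank)
```

## The problem

When a cell is perturbed — a drug, an oxidative stress, a viral oncogene —
a specific set of *driver* regulators reshapes the transcriptional program.
Genome-wide deletion screens can identify these drivers experimentally, but
a recurring observation is that they are hard to find computationally: the
transcription factors with the most extreme differential expression, and
the highest-degree hubs of regulatory or interaction networks, tend to be
broadly acting housekeeping regulators rather than the condition-specific
drivers. Drivers instead tend to sit *above the median but below the hubs*
in several molecular layers at once: they regulate many genes in the
condition-specific transcriptional network **and** physically interact
with many proteins.

`driverrank` operationalizes that observation. It (1) infers a
condition-specific transcriptional network from expression data,
constrained by a TF-binding prior; (2) computes each TF's degree in that
network and in a context-independent protein-interaction (PPI) network;
(3) converts the two degree distributions to ranks and fuses them into a
combined score

$$S = \frac{R_T + R_P}{2},$$

where $R_T$ is the TF's degree rank in the transcriptional network and
$R_P$ its degree rank in the PPI network (rank 1 = highest degree, so a
smaller $S$ means higher priority); and (4) evaluates ranked TF lists for
enrichment in a known driver set with ROC/AUC, rank-sum and
Kolmogorov–Smirnov tests, and top-$k$ Fisher exact overlaps.

## Network inference: penalized conditional-mutual-information parent sets

Expression is first discretized gene-by-gene into tertiles: thresholds at
the 1/3 and 2/3 empirical quantiles, a value's bin being the number of
thresholds strictly below it (ties fall into the lower bin; the convention
is order-independent). A gene's *arity* is the number of expression levels
it actually realizes; constant genes have arity 1, carry no information,
and are excluded both as regulators and as targets.

For each target gene, the candidate regulators are the TFs with a binding
site in its promoter (the prior, filtered at binding $p < 0.005$). If more
than ten candidates remain, the ten with the largest absolute Pearson
correlation with the target are kept — this cap is what makes a literal
exhaustive search feasible, since at most $2^{10}$ subsets must be scored
per gene. Self-loops are excluded: in a static network every TF trivially
predicts its own expression.

A parent set $P_1, \dots, P_m$ for target $T$ over $N$ samples is scored

$$\mathrm{score} = \sum_{i=1}^{m} \Big[\, 2N \cdot \hat I(T;P_i \mid
P_1..P_{i-1}) \;-\; \chi^2_{1-\alpha}(\mathrm{df}_i) \,\Big],
\qquad \mathrm{df}_i = (r_T - 1)(r_{P_i} - 1)\prod_{k<i} r_{P_k},$$

where $\hat I$ is the plug-in conditional mutual information in nats, so
each $2N\hat I$ term is the G statistic of a conditional-independence test
and each parent is penalized by the chi-square critical value it would
have to exceed to be significant at level $\alpha$. A parent therefore
enters the network only if it adds more dependence than expected by chance
given the parents already accepted. The empty set scores 0 and wins ties,
and remaining ties are broken toward smaller subsets, then lexicographic
identifiers, so inference is deterministic. The information terms
telescope to the joint information $\hat I(T; P_1..P_m)$ regardless of
order; with uniform arities the penalty depends only on the subset size,
making the score order-invariant. With heterogeneous arities the committed
convention is to evaluate parents in candidate order (decreasing $|r|$).

The exhaustive search enumerates subsets depth-first, sharing conditioning
prefixes, so each subset costs exactly one additional conditional-MI
evaluation; an independent naive enumerator is used in the test suite to
confirm the argmax on hundreds of random instances.

Two significance levels are used in practice: $\alpha = 0.001$ for
well-sampled datasets (tens of samples) and $\alpha = 0.05$ when only
about ten samples are available. Significance is asymptotic chi-square by
default; a seeded permutation alternative (`permutation_mi_test`) is
provided for small-sample checks, since the plug-in G statistic's
chi-square approximation degrades for sparse contingency tables.

An alternative inference route is supported for weighted-network methods
that output per-edge z-scores against a randomized control
(`panda_edge_scores`): z-scores are converted to probabilities with the
standard normal CDF and each edge scored
$(\Phi(z_{\mathrm{obs}}) - \Phi(z_{\mathrm{null}}))\cdot\Phi(z_{\mathrm{obs}})$,
retaining scores strictly above 0.8. The matching randomized control is
produced by `randomize_expression`, which permutes gene and sample
identities independently. Note the edge score is monotone in
$z_{\mathrm{obs}}$ only where $\Phi(z_{\mathrm{obs}}) \ge
\Phi(z_{\mathrm{null}})/2$ — which covers every retainable edge, but not
the far-left tail.

## Preprocessing

Standard microarray-style preprocessing is built in: genes and then
samples with a missing fraction strictly above 0.8 are removed (one pass
each, genes first; because the filter is single-pass, each gene's bound is
with respect to the original sample set), and remaining gaps are filled by
k-nearest-neighbor imputation (default $k = 10$) using Euclidean distance
over co-observed samples, averaging the neighbors' values at the missing
sample. The distance metric and $k$ are package choices — common defaults
for expression imputation — and both are configurable. Samples can be
restricted to sensitive strains by a growth-score table: strains whose
mean score over chosen conditions is strictly below −0.1 are kept.

## Rank fusion

Degree is always the number of *unique neighboring nodes* over incoming
and outgoing edges; duplicate edges and self-loops contribute nothing.
TFs with positive degree are ranked descending with average ranks on ties
(average ties are what produce fractional combined scores such as 17.75).
TFs absent from a network carry no degree information, so they are placed
at the bottom of that ranking in a *seeded* uniformly random order — the
seed is recorded, making runs reproducible while honoring the convention
that zero-degree TFs are randomly ordered at the bottom. The combined
score of TFs present in both networks is independent of that seed.

`combine_ranks` applies the same fusion to arbitrary rank sources; the
package uses it for the differential-expression baseline (per-gene Welch
$t$, ranked by ascending $p$) and its fusion with PPI degree.

## The synthetic benchmark

Real compendia (deletion-screen growth tables, binding-site maps, Y2H and
literature interactomes) are large downloads; the package instead ships a
generator whose output has the statistical structure the method assumes,
with known ground truth, so every stage is testable end to end.

* **Expression** comes from a latent discrete mechanism: each TF draws a
  level in $\{0,1,2\}$ uniformly per sample; each regulated target copies
  a randomly weighted average of its regulators' levels (thresholded back
  to three levels) with probability $1 - 0.2$, otherwise a uniform level;
  levels are emitted as Gaussians at $-2, 0, 2$ with SD $0.5$. Tertile
  binning therefore approximately recovers the latent levels, so the
  inference pipeline's assumptions hold literally and recovery is a fair
  test of the search, not of the discretization.
* **Regulatory layer**: 40 TFs and 400 targets. Eight driver TFs regulate
  15 targets each. Three non-driver "housekeeping hub" TFs regulate 18
  targets each, and the remaining non-driver edge budget (the total is
  fixed at $32 \times 3$ edges) is spread evenly over the other
  non-drivers, a few of which end with zero targets — exercising the
  random-bottom rank rule. The hubs reproduce the structure seen in real
  networks: the top of the degree distribution is *not* the drivers, so no
  single layer ranks drivers perfectly and fusion has something to
  contribute.
* **Prior**: every true edge (binding $p < 0.004$) plus, per target, five
  decoy edges passing the 0.005 cutoff (these are the false-positive
  candidates the penalized search must reject) and two chaff edges above
  the cutoff (removed by `filter_prior`).
* **PPI layer**: a preferential-attachment graph on 800 proteins
  (2 edges per new node). Driver TFs are wired onto nodes in the 0.6–0.9
  degree-quantile band — above the median, below the hubs — and the other
  TFs are placed uniformly.
* **Growth table**: 79 strains by 7 conditions with exactly 30 strains
  planted below the −0.1 sensitivity cutoff.
* 2% of expression entries are masked at random to exercise imputation.

One master seed fans out to independent per-component streams, so the
same dataset is reproduced byte-for-byte and components can be
regenerated independently. Defaults (60 samples, noise 0.2, effect sizes
above) were fixed once as a realistic desk-scale study and are not tuned.

What the generator deliberately does **not** emulate: realistic microarray
noise (probe effects, intensity-dependent variance), correlated TF
activity, post-translational regulation that decouples TF mRNA from TF
activity, or literature bias in interaction databases. Passing the
recovery tests therefore shows the algorithmic chain is correct under its
own assumptions, not that the method attains similar accuracy on real
compendia.

## Numerical choices and degenerate inputs

* $0 \log 0 = 0$ throughout; information is computed in nats internally
  and reported in bits.
* Degrees of freedom for G tests are floored at 1 so that degenerate
  (constant) variables get a defined $p$ of 1 rather than a 0-df
  reference.
* `fisher_top_k` converts a fraction to a count with `floor` by default
  (`round`/`ceiling` available); the Fisher tests are one-sided
  (enrichment) with a two-sided option for depletion questions; the odds
  ratio is the unconditional sample ratio $ad/bc$ ($\infty$ when $bc = 0$
  and $ad > 0$), not the conditional MLE that `fisher.test` reports.
* The rank-sum test is exact for small untied samples and uses the
  tie-corrected normal approximation otherwise; the KS test is two-sample,
  one-sided toward "drivers shifted to the top" (a one-sample variant was
  considered and rejected because the non-driver positions are themselves
  random).
* Strict inequalities are used exactly where the contracts state them:
  binding $p < 0.005$, growth score $< -0.1$, missing fraction $> 0.8$
  removed, edge score $> 0.8$ retained.

## Problem sizes used in the checks

The shipped checks run the full study at the generator's default size
(40 TFs, 400 targets, 60 samples) over 20 seeds — about a minute of
compute — plus 2000-replicate null calibration at $N = 200$, 100 XOR
recovery replicates at $N = 300$, and 200 random-instance comparisons of
the subset search against naive enumeration. These sizes were chosen as
the smallest at which the binomial noise on the measured rates is well
inside the asserted bounds.

## A worked run

```{r example, eval = FALSE}
d <- generate_dataset(synthetic_config(seed = 3))
res <- run_pipeline(run_config(
  expression = d$expression, prior = d$prior, ppi = d$ppi,
  drivers = d$drivers, inference = inference_config(alpha = 0.001),
  scoring_seed = 1))
print(res)
#> pipeline_result: 40 TFs, 166 inferred edges
#>   transcriptional  AUC = 0.934  Wilcoxon p = 1.33e-05
#>   ppi              AUC = 0.828  Wilcoxon p = 0.00163
#>   combined         AUC = 0.945  Wilcoxon p = 6.02e-06
#>   diff_expr        AUC = 0.496  Wilcoxon p = 0.52
#>   diff_expr_ppi    AUC = 0.719  Wilcoxon p = 0.0298
```

The fused score outranks either single layer, and the
differential-expression baseline sits at chance on this design (the
perturbation here is regulatory wiring, not a mean shift), which is
exactly the failure mode the network score is meant to address.

## Known limitations

* The penalized-score interpretation of the conditional-MI subset search
  (the exact statistic cut at $\alpha$, and the df convention under mixed
  arities) is this package's committed reading; other implementations of
  maximum-CMI parent selection differ in these details.
* The asymptotic chi-square reference is anticonservative for sparse
  tables (many conditioning strata, few samples); use the permutation
  option when $N / \prod r_z$ is small.
* Exhaustive search is exponential in the candidate cap; the cap of ten is
  a modeling decision, not merely an optimization, and raising it
  substantially is not supported.
* One-pass missing-value filtering does not re-check genes after sample
  removal (see above); with extreme missingness patterns a retained gene
  can exceed the bound over the retained samples.
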