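---
title: "Permutation inference for longitudinal mouse brain MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation inference for longitudinal mouse brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroperm)
```

## Scope

`neuroperm` implements the statistical layer of a longitudinal mouse MRI
study design: two genotypes (wild-type and knockout littermates), two
sexes, two timepoints (adolescence and adulthood), with resting-state
BOLD functional connectivity, Jacobian-based regional volumetry,
white-matter fractional anisotropy (FA), and voxel-wise maps as
outcomes. Image acquisition, registration and pre-processing are out of
scope: the package consumes ROI time courses, Jacobian/FA/label images,
and produces inference. A synthetic-data module generates all of these
inputs with known ground truth so that every estimator and test in the
package can be validated by simulation.

## The connectivity model

Each subject-session contributes a $T \times R$ matrix of ROI-averaged
BOLD time courses ($R = 36$ unilateral grey-matter regions, 18 per
hemisphere). Functional connectivity is the Pearson correlation of each
ROI pair, Fisher-z transformed:

$$z_{ij} = \operatorname{atanh}(r_{ij}), \qquad |r| \text{ clipped at } 1 - 10^{-7},$$

giving a symmetric $36 \times 36$ matrix with zero diagonal and 630
distinct edges. Graphs are formed by *proportional thresholding*: edges
are ranked by signed weight (strongest positive connections first) and
the top $\operatorname{round}(s \cdot 630)$ edges are retained at each
sparsity $s \in \{5\%, 10\%, \dots, 50\%\}$, ten graphs per subject.
Three summaries are evaluated at each sparsity: mean retained
connectivity, binary global efficiency
$E_{glob} = \frac{1}{R(R-1)} \sum_{i \ne j} 1/d_{ij}$ (disconnected
pairs contribute 0), and the average binary clustering coefficient
$C = \frac{1}{R}\sum_i 2t_i / (k_i(k_i-1))$ with $C_i = 0$ for degree
$< 2$. Each metric-versus-sparsity curve is reduced to a single
trapezoidal area under the curve (AUC) over the percent axis, and group
differences in AUC are tested by label permutation: the two-sided
p-value is $(1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(1 + N)$.

Design choices worth making explicit:

* **Signed versus absolute ranking.** "Strongest connections" is read as
  largest signed z (the reported group mean connectivity is positive);
  ranking by magnitude is available via `rank_by = "absolute"`.
* **Edge-count rounding** is half-away-from-zero, matching the common
  proportional-threshold convention; ties at the cut break by (row,
  column) lexicographic order so thresholding is deterministic and the
  retained sets are nested across the grid.
* **Binary metrics.** Global efficiency and clustering are computed on
  the binarized thresholded graph, which is what the commonly used
  implementations do when handed a thresholded matrix in this workflow.
* **Add-one permutation p-values** $(1+k)/(1+N)$ never return zero and
  have resolution $1/(N+1)$; at $N = 10\,000$ they differ from the plain
  proportion by at most $10^{-4}$.

Small a priori networks (default mode, salience, and a 20-region
anxiety network) are analysed without thresholding: mean within-network
connectivity over the network's pairs, and weighted efficiency after
min-max normalizing the subnetwork's off-diagonal entries to $[0, 1]$.
The normalization is per subject and per subnetwork, so each subject's
value is scale-free; a constant submatrix makes the normalization
degenerate and is an error. Node strength of the 20 anxiety seeds is the
mean absolute z to all 35 other regions, compared across genotypes with
a mixed ANOVA (between factor genotype, within factor region),
implemented with classical proportional-frequency sums of squares —
valid for unequal group sizes as long as every subject contributes every
region — with an optional Greenhouse-Geisser correction (off by
default, since sphericity handling is not prescribed for this design).

## Edge-wise inference and the network-based statistic

Genotype contrasts on individual edges use pooled-variance Student
t-tests (Welch is deliberately not the default, matching the declared
procedure), with Benjamini-Hochberg correction over the 630
upper-triangle p-values. The network-based statistic (NBS) thresholds
the |t| matrix at 2, finds connected components of suprathreshold edges
with a breadth-first search, retains components spanning more than one
ROI, and compares each component's *edge count* against the permutation
null of the maximal component size (labels shuffled, t matrix
recomputed). Component size in edges rather than nodes is the
convention used here because observed component sizes can exceed the
node count; node counting is available via `size = "nodes"`. Ties
between an observed component and null maxima count against the
component (a conservative reading of "exceeded").

A property of component-based inference that users should know: its
power depends strongly on the parcellation size relative to the planted
effect. At $|t| \ge 2$ with $\sim 60$ degrees of freedom, about 5% of
edges are suprathreshold under the null; on a 36-node graph that is
roughly 32 edges — beyond the percolation point, so null graphs contain
a giant component and a modest planted clique (10 edges on 5 nodes) is
masked. On a 15-node parcellation the null suprathreshold graph stays
fragmented and the same planted effect is detected essentially always.
The package's power validation therefore runs the NBS recovery
simulation at $R = 15$ while keeping edge-wise FDR validation on the
full 630-edge family, and users applying NBS to fine parcellations
should expect reduced component-level sensitivity at this threshold.

## Longitudinal change

For FA regional medians and for each graph metric at each sparsity
level, change is the within-subject difference (adulthood minus
adolescence) over subjects present at both timepoints; unmatched
subjects are dropped with a reported count. Each unit (region or
sparsity level) gets a two-sided one-sample t-test against zero, BH
corrected within the declared family (e.g. exactly the 10 sparsity
levels). Units with zero change variance are flagged and excluded from
a defined p-value rather than fabricating one.

## Voxel-wise inference: TFCE with max-statistic FWE

The threshold-free cluster enhancement of a stat map $f$ is

$$\mathrm{TFCE}(v) = \int_0^{f(v)} e(v, h)^{E}\, h^{H}\, dh,$$

where $e(v, h)$ is the voxel count of the connected component (26-
connectivity by default) containing $v$ at threshold $h$. Defaults are
$H = 2$, $E = 0.5$. The integral is discretized at 100 *midpoint*
thresholds $h_k = (k - \tfrac12)\,\mathrm{peak}/100$: midpoint sums are
second-order accurate, whereas endpoint sums miss the flat-plateau
closed form $e^{E} h^{H+1}/(H+1)$ by about 1.5% at this step count. The
negative tail is enhanced by transforming $-f$ and negating. The
implementation activates voxels in descending height order into a
union-find structure, so the cost is $O(V \cdot 26 + \text{steps} \cdot V)$
per map rather than a full relabelling per threshold.

Group inference uses the permutation distribution of the maximal
absolute TFCE score over the mask: corrected
$p(v) = (1 + \#\{\max_{perm} \ge |\mathrm{TFCE}_{obs}(v)|\})/(1 + N)$.
This is strong family-wise error control; with identical groups every
permutation ties and all corrected p-values are 1. Only the two-group
contrast is implemented — covariates and exchangeability blocks are out
of scope.

## Power

`min_detectable_d(n1, n2, alpha, power)` inverts the noncentral-t power
function of the two-sided two-sample t-test (df $n_1+n_2-2$,
noncentrality $d\sqrt{n_1 n_2/(n_1+n_2)}$) by bisection to $10^{-6}$.
At 34 subjects per group, $\alpha = 0.05$ and 80% power it returns
$d \approx 0.69$ — i.e. the design is powered for moderate effects of
about $d = 0.7$.

```{r power}
min_detectable_d(34, 34, alpha = 0.05, power = 0.80)
```

## What the synthetic-data generator emulates

`sim_config()` fixes the study conditions; the defaults are chosen once
as realistic values for medetomidine/isoflurane mouse rsfMRI and are
not tuned per analysis:

* **Cohort**: `n_per_cell` subjects per genotype-by-sex cell, each
  scanned at both timepoints; litters assigned round-robin within
  genotype so every litter mixes genotypes (the littermate-control
  design). The default `n_per_cell = 9` approximates the study scale of
  17–18 per sex per genotype split across cells.
* **Time courses**: `T = 500` samples (long enough for stable 36-region
  correlation estimates while fast at desk scale; run length is
  configurable since acquisition details live upstream) from a zero-mean
  multivariate normal with modular structure — correlation `r_within =
  0.35` inside the bundled networks, `r_between = 0.10` elsewhere,
  values typical of within- versus between-network coupling — then
  AR(1) filtering with coefficient 0.3 as the minimal model of BOLD
  temporal autocorrelation. The same filter applies to every ROI, so
  the zero-lag correlation target is preserved. Knockout sessions add
  `genotype_edge_delta` to a designated edge set (default: all pairs of
  the first module), giving a plantable ground-truth group effect;
  `genotype_edge_delta = 0` makes every downstream genotype test an
  exact null experiment, which is how the calibration suite is built.
  Targets that lose positive definiteness are repaired by eigenvalue
  flooring at $10^{-6}$ with renormalization to unit diagonal, and the
  repair is flagged.
* **Regional volumes**: log-normal per region with exact generating
  coefficient of variation (default 0.05, the observed 4–5% range), a
  4% male volume excess in adolescence only (sex differences that wash
  out by adulthood) and 10% growth into adulthood.
* **FA tables**: paired values per subject; adult FA is the subject's
  adolescent FA plus a developmental increment (default 0.03) plus
  noise (sd 0.01), except the olfactory tract, which gets a zero
  increment to emulate the early maturation of the olfactory system.
  Values are clamped to $[0,1]$.
* **Stat images**: smooth Gaussian random fields (white noise convolved
  with a Gaussian of $\sigma = 1$ voxel, rescaled to unit interior
  variance) with an optional spherical signal (radius 3 voxels) of
  stated amplitude in noise-sd units added to the knockout group; the
  mask excludes the one-voxel border where zero-padded smoothing
  attenuates the field.

What the generator does *not* emulate: physiological noise and motion,
spatial autocorrelation of ROI time courses, non-Gaussian BOLD
artefacts, registration error in Jacobians, or partial-volume effects.
Passing the simulation suite therefore demonstrates statistical
correctness of the estimators and error control under the stated
models, not robustness to every property of real data.

## Validation problem sizes

The test suite validates error control and power at desk scale, sizes
chosen as the package's own validation design: type-I error of the AUC,
NBS and TFCE/FWE permutation tests on 500 null datasets each (6 vs 6
subjects, 500 permutations, images $12^3$), checked against the 95%
binomial band around $\alpha = 0.05$; recovery of planted effects (1.5
pooled-sd edge shifts at $n = 30$/group; $5\sigma$ spheres on $16^3$
images at $n = 10$/group, 500 permutations) at the 90% detection level;
and exact-oracle agreement (all graphs on up to 6 nodes against
Floyd–Warshall and triangle enumeration, TFCE against per-threshold
relabelling and the plateau closed form, Monte-Carlo permutation
p-values against exhaustive enumeration for $n_1+n_2 \le 8$). Full-scale
analyses use 10 000 permutations; the pipeline default of 1000 is a
desk-scale compromise with p-value resolution $10^{-3}$.

## Known limitations

* The mixed ANOVA covers one between- and one within-subject factor;
  mixed-effects linear models with subject random effects are not
  implemented.
* NBS and the AUC test exchange labels freely (sexes combined), with no
  stratification by sex or litter.
* The voxel engine offers no variance smoothing and no general linear
  model beyond the two-group contrast.
* Weighted clustering and weighted global metrics on thresholded
  graphs are deliberately absent from the default path; binary metrics
  are the convention in this workflow.
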