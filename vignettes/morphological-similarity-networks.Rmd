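---
title: "Individual morphological similarity networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual morphological similarity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Group-level structural covariance networks need many subjects to estimate a
single network, so they cannot support per-patient inference. Individual
morphological networks sidestep this: within a *single* subject, every
cortical region contributes a distribution of vertex-wise values of a
morphometric index — cortical thickness (CT, mm), gyrification index (GI),
sulcal depth (SD) or fractal dimension (FD) — and two regions are called
"connected" when those distributions are statistically similar. morphnet
implements this construction end to end for the 68-region bilateral
Desikan–Killiany parcellation (any region count ≥ 3 works), together with
the graph-theoretical characterisation of the resulting networks and the
group inference machinery used to compare patient cells, for example males
versus females within a Parkinson's disease cohort with probable REM-sleep
behaviour disorder (PD-pRBD).

## The model

### From vertex values to similarity

For subject $s$ and region $i$, let $x_{si}$ be the vector of vertex values.
Its probability density $P_i$ is estimated with a Gaussian kernel:

$$\hat f_h(t) = \frac{1}{n h}\sum_{v=1}^{n} \phi\!\left(\frac{t - x_v}{h}\right),$$

with Silverman's rule-of-thumb bandwidth ($h = 0.9\,\min(\hat\sigma,
\mathrm{IQR}/1.34)\,n^{-1/5}$, `stats::bw.nrd0`). For each unordered region
pair $(i, j)$ both densities are evaluated **on one shared uniform grid** of
256 points spanning $[\min(x_i, x_j) - 3h_{\max},\ \max(x_i, x_j) +
3h_{\max}]$, where $h_{\max}$ is the larger of the two bandwidths — the
Kullback–Leibler integrand is only meaningful on a common support. The
symmetric divergence is

$$\mathrm{KLD}(P_i, P_j) = \mathrm{KL}(P_i \| P_j) + \mathrm{KL}(P_j \| P_i),$$

each term integrated by the trapezoid rule, and the edge weight is the
KLD-based similarity

$$c_{ij} = \exp(-\mathrm{KLD}(P_i, P_j)) \in (0, 1],$$

which is 1 exactly when the two densities coincide on the grid. The matrix
$C = [c_{ij}]$ with unit diagonal is the subject's morphological similarity
network.

### Sparsity thresholding

$C$ is converted to binary ($A_{ij}$) and weighted ($W_{ij}$) networks with
a *subject-specific* KLS threshold chosen so that every subject retains
exactly

$$E = \mathrm{round}\left(S \cdot \frac{n(n-1)}{2}\right)$$

edges at sparsity $S$ — identical node and edge counts across participants,
which a fixed numeric cutoff cannot guarantee. The default grid is $S \in
\{0.063, 0.073, \ldots, 0.393\}$ (34 levels, step 0.01): dense enough to
stay above the connectedness floor, sparse enough for small-world structure.
Retained entries become 1 (binary) or keep $c_{ij}$ (weighted).

### Topological attributes and AUC

At each sparsity the package evaluates global integration ($E_g$, $L_p$,
$\lambda$), global separation ($E_{loc}$, $C_p$, $\gamma$),
small-worldness ($\sigma = \gamma / \lambda$) and the nodal attributes
$N_e$ (nodal efficiency), $D_c$ (degree) and $B_c$ (betweenness). The
normalised indices divide $C_p$ and $L_p$ by their means over
degree-preserving Maslov–Sneppen rewired null networks. Each attribute's
curve over the sparsity grid is integrated by the trapezoid rule into a
threshold-free area-under-curve (AUC) summary — the quantity all downstream
inference operates on.

### Group inference and clinical correlation

Cells (e.g. PD-pRBD males vs females) are compared per attribute by a
covariate-adjusted two-sample permutation test: AUC values are first
replaced by residuals of an OLS fit on age, education and LEDD (levodopa
equivalent daily dose) pooled across both cells — a simplified
Freedman–Lane scheme — and cell labels are then shuffled. The two-tailed
p-value uses the add-one convention, $p = (1 + \#\{|T^*| \ge |T|\}) /
(n_{perm} + 1)$, so it is strictly positive and valid. Nodal attributes
share one set of shuffles across regions (preserving their dependence) and
are corrected by Benjamini–Hochberg FDR across the regions within one
(metric, attribute) family — the narrowest defensible family; global
attributes are reported with raw p-values. Clinical correlations are plain
Pearson $r$ within each (group, sex) cell with two-tailed p from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$, uncorrected at $\alpha = 0.05$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bandwidth_rule` | `"silverman"` | KDE bandwidth per region (`"sj"` optional) |
| `grid_size` | 256 | points in each pair's common density grid |
| `floor` | 1e-10 | density floor, *relative to the density peak* |
| `sparsity_grid()` | 0.063–0.393 by 0.01 | thresholding levels |
| `mode` | `"binary"` | network type fed to graph metrics |
| `n_null` | 100 | rewired nulls per level for γ, λ, σ |
| `n_perm` | 10000 | label permutations per contrast |
| `covariates` | age, education, LEDD | OLS residualisation columns |

## Numerical choices

* **Bandwidth and kernel.** Gaussian kernel with Silverman's rule: the
  standard default where nothing in the construction pins them down; both
  are configurable.
* **Density floor.** Densities are floored at $10^{-10} \times$ their peak
  before the divergence integral and renormalised. The floor is *relative*
  rather than absolute: this prevents $\log 0$ without shifting mass, and
  makes $c_{ij}$ exactly invariant under common affine rescaling
  $x \mapsto ax + b$ of the data (an absolute floor breaks that invariance
  for scale factors of a few, because the density scale changes while the
  floor does not).
* **Rounding and ties.** Edge counts use round-half-away-from-zero, a
  stated, testable convention. Ties at the KLS threshold (measure-zero for
  continuous similarities) break by ascending $(i, j)$ lexicographic order,
  so thresholding is deterministic and edge sets are nested along the grid.
* **Grid endpoint.** $0.063 + 0.01k$ never reaches 0.4 exactly; the default
  grid stops at 0.393 and `sparsity_grid(include_endpoint = TRUE)` appends
  0.4 for users who read the range as closed.
* **Disconnected graphs.** At low sparsity the graph may fragment. $L_p$
  averages over *reachable* pairs only and the fit records a per-level
  `disconnected` flag (rather than returning infinity and destroying the
  AUC); efficiency terms for unreachable pairs are 0, their natural limit.
* **Binary primary, weighted available.** Both network types are built; the
  topology analysis defaults to the binary form, the dominant convention of
  the toolbox ecosystem this follows. Weighted variants use strength
  degrees, $1/w$ Dijkstra path lengths and Onnela's geometric-mean
  clustering with weights scaled by the network maximum.
* **Small-world nulls.** $n_{null} = 100$ Maslov–Sneppen rewires with
  $100 \times |E|$ attempted swaps each; a complete graph cannot be rewired
  and returns $\gamma = \lambda = \sigma = 1$. If a network and its nulls
  are triangle-free, $\gamma$ is NaN and propagates to the AUC with a
  warning rather than being silently imputed.
* **Implementation note.** Binary shortest paths use a vectorised
  level-synchronous BFS and binary clustering counts triangles through
  $\mathrm{diag}(A^3)$ — exact combinatorics, chosen because building a
  graph object per evaluation dominated run time; weighted distances,
  betweenness (Brandes) and rewiring go through igraph. All attribute
  implementations are pinned to an exhaustive brute-force oracle
  (Floyd–Warshall plus combinatorial path counting) at $10^{-12}$ in the
  test suite.

## The synthetic cohort generator

Real inputs of this kind live in access-controlled repositories, so the
package ships a generator that emulates their *shape*: each region has a
stable vertex count (drawn once, shared by all subjects) and a Gaussian
base distribution with mean $\sim U(1.5, 3.5)$ — a cortical-thickness-like
scale in mm — and SD $\sim U(0.2, 0.5)$. Effects shift a named (group, sex)
cell's regional means in units of the region's SD and/or scale its SD;
they are applied as deterministic location-scale transforms of the base
draws, so the zero-effect cohort is bit-identical to the same seed's
effectful cohort with effects removed — which is exactly what type-I
calibration needs. Every subject×region block draws from its own RNG
substream keyed by (seed, subject, region), making output independent of
generation order. Clinical covariates are drawn at plausible scales (age
~N(62, 8) years, education ~N(14, 3) years, LEDD ~N(450, 150) mg, 0 for
controls). A score coupling generates a named score as `intercept + slope ×
AUC(attribute) + noise` in a second pass from the subject's *own* fitted
network, giving the correlation stage a known ground truth. A lognormal
base is available for robustness checks.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring parcels, hemispheric symmetry, realistic inter-metric
correlation (CT/GI/SD/FD are generated independently), metric-specific
value ranges for GI/SD/FD, or scanner/site effects. Passing tests therefore
demonstrate that the *pipeline machinery* is correct and calibrated — not
that real cortical data satisfy its assumptions.

### The designed divergence effect

For power checks the package uses a frozen "regional divergence" design:
four regions of ten in the male cell receive individual mean shifts of
+12, −12, +18 and −18 SD units. Two findings from the design phase explain
its shape. A *signed shift applied to one region set* moves some regions
toward other regions' distributions (the shift is signed, region means are
scattered), so its effect on topology is inconsistent; and *variance
inflation* makes the affected regions mutually similar — wide, flat
densities diverge little from one another — so they form their own module
instead of disconnecting. Spreading regions in opposite directions with
unchanged SD isolates them both from the core and from each other, which
fragments the male networks and reliably lowers global efficiency while
raising characteristic path length: the qualitative PD-pRBD male pattern.

## Desk-scale simulation sizes

Calibration and power studies in the test suite and acceptance script run
the full pipeline (generation → KDE/KLS → thresholding → AUC →
covariate-adjusted permutation inference) on deliberately small networks:
8–10 regions, 30–45 vertices per region, an 8-level sparsity sub-grid
(0.103–0.383, step 0.04), 128-point density grids, 30 subjects per cell and
1000 permutations, with 500 repetitions for type-I error and 50 seeds for
power. These sizes are the package's choice of a desk-scale experiment:
type-I calibration is a property of the permutation scheme, not of network
size, and the designed effect is specified at the same scale at which it
was validated. The atlas-scale configuration (68 regions, 34 levels,
10000 permutations, 100 nulls) is the default of every exported function.

## Known limitations

* KDE-based KLD is biased at small vertex counts (bandwidth smoothing
  inflates both densities' spread); the test suite tracks its convergence
  to the Gaussian closed form as samples grow. Regions with very few
  vertices will bias similarities upward.
* The residualise-then-permute scheme is approximate when covariates are
  strongly imbalanced between cells; the exact scheme under covariates is
  not identified by the reference analysis description, and alternatives
  (e.g. full Freedman–Lane) are out of scope.
* $\gamma$, $\lambda$, $\sigma$ are undefined on triangle-free or
  unrewirable graphs; at very low sparsity on few regions this produces
  NaN AUCs by design.
* Vertex values are treated as exchangeable draws within a region; real
  vertex data are spatially smooth, which effectively reduces the number of
  independent observations per region.
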