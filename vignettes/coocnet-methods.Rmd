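---
title: "Inferring microbial co-occurrence networks across environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microbial co-occurrence networks across environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocnet)
```

## The problem

Amplicon surveys summarise a microbial community as a count table: exact
sequence variants (ESVs) in rows, samples in columns, sequencing reads in
the cells. A co-occurrence network treats ESVs as vertices and draws an
edge wherever two taxa's abundances co-vary across samples more strongly
than chance allows — positive edges suggesting shared habitat preference or
cooperation, negative edges suggesting competition or niche differentiation.
When samples come from many environments, comparing the per-environment
subnetworks separates associations that recur everywhere (generalist edges)
from those tied to a single habitat (specialist edges).

Count tables of this kind are *compositional*: each sample is sequenced to
an arbitrary depth, so only relative abundances are informative, and the
fixed-sum constraint by itself induces spurious negative correlation.
Every inferential choice below exists to keep that artefact, and the large
number of tested pairs, from flooding the network with false edges.

## The inference model

For a single environment's table the pipeline
(`infer_environment_network()`) proceeds in stages:

**Association measures.** For every pair of non-constant ESVs we compute
Spearman's rank correlation $\rho$ and the Bray–Curtis similarity
$1 - \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ on relative abundances. Two
measures with different failure modes are used deliberately: an edge must
ultimately be supported by both.

**ReBoot significance.** Parametric p-values are meaningless here (ranks,
compositional coupling, unknown marginals), so each pair gets a
permutation/bootstrap comparison:

* *Permutation null*: each iteration independently shuffles the two ESVs'
  counts across samples. For Spearman the per-sample totals are then
  recomputed and relative abundances re-derived (only the pair's rows
  moved, so totals shift) — this *renormalization* step bakes the
  compositional artefact into the null instead of letting it masquerade as
  signal. Bray–Curtis permutations shuffle the relative-abundance profiles
  directly.
* *Bootstrap*: samples are resampled with replacement and the measure
  recomputed, giving the sampling distribution of the observed score.
  Resamples with fewer than three distinct samples (or a constant profile,
  for Spearman) are redrawn up to ten times.
* The p-value is the two-sided Gaussian tail of the null distribution's
  mean under a normal fitted to the bootstrap's mean and standard
  deviation. Two-sided, because both co-presence and mutual exclusion are
  of interest.

**Brown's merge and FDR.** The two per-measure p-values are dependent
(same data), so they are combined with Brown's method: the Fisher statistic
$T = -2(\ln p_1 + \ln p_2)$ is referred to a scaled $\chi^2$ whose moments
match $E = 4$, $\mathrm{Var} = 8 + 2\,\mathrm{cov}(-2\ln p_1, -2\ln p_2)$.
The covariance is estimated empirically across all candidate pairs of the
environment — a single pair offers one observation, so per-pair estimation
is impossible — and clamped to $[0, 4]$, the feasible range (at 4 the merge
returns the common p; at 0 it is exactly Fisher). Merged p-values are
Benjamini–Hochberg adjusted and edges with adjusted $p > 0.05$ discarded.

**Random-matrix-theory score threshold.** Statistical significance alone
keeps weak edges at large sample sizes, so scores below a data-driven
cutoff are discarded too. Scanning candidate thresholds (0.30–0.95 in steps
of 0.01), the $|\rho|$ matrix is thresholded, its eigenvalue spectrum
unfolded (cumulative spectral density smoothed with a monotone degree-5
polynomial), and the nearest-neighbour spacing distribution tested against
the Poisson law $e^{-s}$ versus the Wigner–Dyson GOE surmise by a
chi-square on binned spacings. Correlated noise produces GOE level
repulsion; genuine modular signal produces Poisson statistics. The smallest
threshold where the Poisson law both beats GOE and fits acceptably is
returned. Numerical choices: the spacing histogram shrinks with the number
of spacings (about five expected counts per bin, at least four bins) so
small spectra are not tested against a histogram they cannot fill;
degenerate eigenvalues are collapsed before unfolding; a matrix already
diagonal at the scan start trivially qualifies (no correlation structure at
all); if no threshold is ever testable — tiny matrices — a configurable
fallback (default 0.6) is returned with a warning flag.

**Both-measure support.** A candidate edge is retained only if (i)
$|\rho|$ reaches the RMT threshold, (ii) both measures' own BH-adjusted
p-values pass the FDR level, and (iii) the Bray–Curtis criterion holds.
Bray–Curtis similarity has no signal-free zero baseline: two independent
taxa of similar mean abundance share high similarity, two taxa of very
different abundance share low similarity, regardless of association. A
single global BC cutoff is therefore uncalibrated, and we instead compare
each pair's observed similarity with its own permutation null: positive
edges must reach the null's 95th percentile, negative (mutual-exclusion)
edges must fall at or below the complementary 5th percentile — BC
similarity cannot be negative, so exclusions manifest as abnormally *low*
similarity. This per-pair calibration is the one place the package departs
from a global score threshold for BC; `rmt_threshold()` itself accepts any
unit-diagonal score matrix should a global cutoff be preferred.

**Network deconvolution.** Transitive association (A–B and B–C strong,
hence A–C elevated) is demoted by the eigenvalue transform
$\lambda \to \lambda/(1+\lambda)$ after linearly scaling the observed
matrix so the transformed spectrum is bounded by $\beta$ (default 0.9;
largest positive eigenvalue mapped to $\beta/(1-\beta)$, the negative side
to $-\beta/(1+\beta)$). Deconvolution operates on the signed retained-score
matrix with zero diagonal. With the default $\alpha = 1$ every retained
edge is kept and annotated with its direct score; $\alpha < 1$ keeps the
top fraction of edges. The transform is applied after edge selection, so at
$\alpha = 1$ it is an annotation, not a filter — the sensitivity of results
to applying it on $|\rho|$ instead of signed scores is an open flag, and we
chose signed scores because mutual exclusions also propagate transitively.

**Merging.** Environment subnetworks merge by unioning vertices and edges
under canonical (lexicographic) unordered-pair identity. A pair retained in
$k$ environments carries $k$ records, one per environment, keeping each
environment's scores; aggregation to a single representative value is left
to reporting. Pairs with conflicting signs across environments are kept
once per sign and flagged `sign_discordant` — there is no principled way to
average a co-presence with an exclusion. Vertices left without edges are
dropped.

## Preprocessing

Filters mirror standard practice for large cross-biome tables and are
applied in a fixed order: ESVs with fewer than 25 total reads are dropped
from the full table; the table is split into per-environment matrices; and
within each environment, ESVs with overall relative abundance below
10^-5^ (0.001%) *or* prevalence below 10% of samples are removed
(OR-removal: failing either criterion drops the ESV; both thresholds keep
ties). Relative abundance is computed per environment table because the
filter is applied per environment. Both filters are idempotent. For
cross-environment comparisons of topology, each environment's table is
trimmed to a uniform 400 top-abundant ESVs × 360 randomly selected samples
(`trim_dataset()`); abundance ties at the cutoff break lexicographically
for determinism, and an environment with fewer than 360 samples raises an
explicit exclusion condition rather than being silently truncated.

## The downstream ecology layer

* **Topology** (`topology_report()`): edge count, diameter and average
  separation on the largest connected component (the component size is
  logged; the handling of disconnected graphs is a package choice), global
  transitivity, mean vertex betweenness, and fast-greedy modularity, all on
  the undirected, unweighted skeleton with negative edges included. The
  agglomeration dendrogram is cut exactly at the modularity maximum. Q is
  verified in the tests against its definitional formula. `scale_free_fit()`
  regresses log-frequency on log-degree; `abundance_degree_association()`
  returns a *signed* Spearman correlation between degree and mean relative
  abundance (a correlation, not a coefficient of determination).
* **Edge ecology** (`classify_edges()`, `omission_score()`, ...): edges in
  two or more subnetworks are generalist; single-subnetwork edges split by
  whether both endpoints appear as vertices in at least two subnetworks
  (vertex "generality" means network membership, not mere presence in the
  count table). The omission score of a generalist edge for an environment
  is the |Spearman| recomputed without that environment's samples; its
  null distribution comes from 1000 random same-sized removals, with
  p = #(random OS < group OS)/1000 — strict inequality, so ties count
  against locality — and an edge is local when OS/|original| < 1 and the
  BH-adjusted p is below 0.05. The literal "< 1" rule admits ratios
  arbitrarily close to 1; a margin argument exists but defaults to the
  literal rule. Environment similarity and hub-set similarity both use
  Jaccard distance with average-linkage clustering (the clustering
  algorithm is a package choice) and a two-group cut. Hubs are the ten
  top-degree vertices per subnetwork, ties broken lexicographically.
* **Enrichment** (`taxon_pair_overrepresentation()`): for labels A, B at a
  chosen rank, the hypergeometric urn draws the realized number of edges
  from the population of all vertex pairs, with successes the A–B pairs
  (within-taxon uses $\binom{|A|}{2}$); the upper tail is
  overrepresentation, both tails are reported, and adjustment is
  Benjamini–Yekutieli. The null is uniform edge placement conditional on
  network size; it does not condition on the degree sequence, a documented
  limitation. Mutual exclusion versus co-presence per taxon pair uses a
  binomial test with the network-wide negative-edge frequency as
  background.

## The synthetic-data generator

No public benchmark provides ground-truth microbial associations, so the
package ships a generator (`generate_dataset()`) whose defaults define the
study conditions used throughout the tests. A Gaussian copula over latent
log-abundances embeds planted pairwise correlations per environment
(nearest-positive-definite repair by eigenvalue clipping at 10^-8^,
deterministic); baseline log-abundances are log-normal (meanlog 0, sdlog
1); a per-environment presence mask implements habitat sparsity; and each
sample is drawn as a multinomial at fixed depth (default 10,000 reads), so
the data are genuinely compositional and the renormalized permutation null
is exercised for real. Monotone latent dependence is detectable by Spearman
by construction — which is the point: the generator validates the
machinery, not the biology. Planted partners receive comparable baseline
abundances (log-offset N(0, 0.25)) because pairwise association measures
are only jointly informative for taxa with overlapping abundance ranges:
Bray–Curtis similarity saturates when one taxon dwarfs the other, and a
detectable planted truth must be detectable by both measures. Hub
specifications expand into planted partner edges deterministically.

What the generator does *not* emulate: real taxonomic composition,
phylogenetic correlation, depth variation across samples, batch effects, or
environment-specific marginal shifts. Passing tests therefore demonstrate
statistical correctness of the machinery under a known monotone-dependence
model, not field performance on real surveys.

## Problem sizes and verification

The test suite verifies, among others: type-I control (no planted edges,
100 ESVs × 200 samples, ten generator seeds, 200 permutation/bootstrap
iterations — the retained-edge fraction stays within 3 binomial standard
errors of the 5% FDR level, and is typically zero because the RMT score
threshold removes weak-score survivors); parameter recovery (20 planted
edges with $|\rho_{latent}| \ge 0.8$, five of them exclusions, on a table
trimmed to 400 × 360 — precision and recall at least 0.8 and every
recovered exclusion negative); omission-score calibration (200 exchangeable
synthetic edges, p-value ECDF within the 1% Kolmogorov–Smirnov band of
uniform); deconvolution ordering on the three-vertex chain against an
eigendecomposition oracle; byte-identical edge lists for repeated runs at a
fixed seed; and a fourteen-environment replica (60 samples × 150 ESVs per
environment, 100 iterations) through the full preprocess–infer–merge–
topology–classify–enrich–hub–negative chain. Iteration counts of 100–200
(down from the 1000 used at survey scale) and these table sizes were chosen
so the whole suite runs on a laptop core; the statistical properties under
test do not depend on the larger sizes. `scripts/acceptance.R` recomputes
the same quantities from scratch (recovery at 300 ESVs, four null seeds)
and writes them as JSON.

## Known limitations

* ReBoot's Gaussian fit to the bootstrap can be optimistic for extreme
  scores where the bootstrap distribution is skewed against its boundary.
* The RMT scan needs a spectrum of at least ten distinct eigenvalues to
  test; very small matrices always take the fallback threshold.
* Brown covariance is estimated once per environment; heterogeneous
  dependence across pairs is averaged.
* Hub status is degree only; no claim of keystone-ness is made, and
  correct hub recovery from association networks is itself uncertain.
* Sign-discordant merged edges are reported, not resolved.
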