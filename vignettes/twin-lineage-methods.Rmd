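---
title: "Tracing twin clonal architecture with early embryonic mutations: models and methods"
author: "twinEEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing twin clonal architecture with early embryonic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinEEM)
```

## The biological model

During the first cell divisions of a human embryo, each daughter cell
acquires on the order of 1.2 somatic point mutations per division. These
early embryonic mutations (EEMs) are inherited by all of the cell's
descendants and therefore act as endogenous lineage barcodes: the fraction
of an individual's cells carrying a given EEM identifies how large a share
of the soma descends from the cell in which it arose. In bulk sequencing a
heterozygous mutation carried by a cell fraction $c$ appears at variant
allele fraction (VAF) $c/2$; pre-zygotic de novo variants, carried by every
cell, sit at VAF $\approx 0.5$ and serve as an internal clonality control.

Monozygotic twins arise by splitting one embryo. Write $L_1$ and $L_2$ for
the two earliest ancestral lineages whose descendants jointly compose both
co-twins' somatic tissues, and $a$ and $b$ for the fraction of Twin 1's and
Twin 2's soma derived from $L_1$ (Twin 1 is defined so that $a \ge b$).
EEMs carried by $L_1$ then sit at VAFs $(a/2,\, b/2)$ in the two twins (the
**anchor cluster**) and EEMs carried by $L_2$ at $((1-a)/2,\, (1-b)/2)$
(the **counter-anchor cluster**). Two exact identities follow for every
$(a, b)$ and are enforced by tests:

* the midpoint of the two cluster positions is $(0.25, 0.25)$;
* per twin, $2 v_\text{anchor} + 2 v_\text{counter} = 1$ — the two earliest
  lineages account for the whole soma.

Three clonal architectures span the observed space: **para-identical**
($a = 1, b = 0$; the twins descend from two disjoint early lineages),
**sub-identical** ($a = 1,\ 0 < b < 1$; Twin 1 is a clonal subset of the
embryo) and **full-identical** ($a \approx b < 1$; both twins are comparable
mixtures). Because the three patterns do not tile $(a,b)$ space, the
package emits a fourth label, `discordant`, for fits that are mixed but
strongly unequal, rather than forcing a nearest category.

## The forward simulator and its study conditions

`simulate_lineage()` grows a complete binary tree from the zygote
(generation 0) to `n_generations` (default 12, 4096 terminal cells). Every
non-root cell draws Poisson(`mutation_rate` = 1.2) new EEMs; the zygote
carries `denovo_count` = 68 heterozygous de novo variants. Mutation
positions are uniform without replacement on a 3.0 Gb virtual genome (24
chromosomes of 125 Mb), so independent zygotes essentially never collide —
dizygotic control pairs are two independent trees.

`apply_twinning()` implements the three architectures: para as complete
segregation of the two daughters of an ancestral cell; sub as a single cell
budding off at `split_generation` (default 6) against all remaining
contemporaneous cells; full as a random partition of the cells of
generation 7. Tissues are founded by bottleneck sampling of progenitor
cells among the twin's terminal cells, then read out with Poisson depth and
binomial alt counts with error $p = v(1-e) + (1-v)e/3$ (60x whole-genome,
700x deep-targeted, $e = 10^{-3}$).

Several scales are not printed in the source material and were fixed here
once, on biological plausibility:

* **Effective progenitor pools**: 128 founders for buccal epithelium and
  cord blood, 32 for umbilical cord, 8 per laser-capture placental patch
  (deliberately oligoclonal), 128 for PBMC sampling. With substantially
  smaller pools (e.g. 32) the realized tissue composition deviates from the
  founder-level truth by a binomial sd of ~0.09, which is larger than the
  category tolerance $\varepsilon$ and makes genuinely full-identical pairs
  read as discordant; 128 keeps tissue noise below the classification
  scale while still letting placental patches show oligoclonal structure.
* **Category frequencies per membrane type** default to the observed cohort
  proportions (monoamniotic pairs almost exclusively full-identical;
  diamniotic pairs dominated by sub- and para-identical), and monochorionic
  blood mixing draws the major contributor uniformly in 56–83% with a
  random major twin.
* The default cohort is 8 MCMA + 7 MCDA + 7 DCDA monozygotic pairs, one
  DCTA monozygotic triplet (two consecutive budding events, true topology
  `((T1,T2),T3)`) and 6 dizygotic pairs, each family with both parents
  (30 inherited variants exercise trio subtraction).

What the generator deliberately does not emulate: chromatin- or
replication-timing-biased mutation placement, trinucleotide signature
structure, copy-number changes, read-level artefacts, parental mosaicism,
or X-inactivation effects. Passing recovery tests therefore demonstrate
correctness of the inference under binomial read noise, Poisson mutation
accrual and bottleneck sampling — not robustness to alignment artefacts or
CNV-distorted VAFs in real data.

## Variant classification

`classify_variants()` applies trio subtraction: variants present in a
parent are inherited; parent-absent variants with VAF $\ge$ 0.3 in *every*
sibling are de novo; remaining parent-absent variants detected in at least
one sibling (alt reads $\ge$ 3 and VAF $\ge$ 0.03, chosen to keep the
binomial false-call rate negligible at 60x) are EEMs. Two consequences are
intrinsic and documented rather than patched: an EEM fully clonal in every
sibling is indistinguishable from a de novo variant, and a de novo variant
can leak into the EEM class through one unlucky low-VAF draw. The anchor
fit therefore drops EEMs clonal (VAF $\ge$ 0.4) in both twins — they carry
no lineage information either way.

## Fitting (a, b)

`detect_anchor_clusters()` clusters EEM VAF pairs by complete-linkage
agglomeration cut at diameter 0.10. Single linkage (radius 0.05) was tried
first and fails on forward-simulated data: detected EEMs form a dense
subclonal continuum along both axes, and chaining absorbs the anchor
cluster into a mega-cluster whose centroid is meaningless. A
diameter-bounded cut keeps the anchor compact (its members share the same
carrier cells, so their VAF spread is purely binomial).

The anchor is the cluster of size $\ge 2$ with maximal summed centroid VAF
among those with sum $\ge 0.5$; the counter-anchor is the cluster nearest
the point reflection of the anchor through $(0.25, 0.25)$, within tolerance
0.10. When both are present and symmetric, $(a,b)$ averages the two
estimates $(2v_1, 2v_2)$ and $(1-2u_1, 1-2u_2)$ with cluster-size weights.

Poisson sparsity forces two further rules, both consequences of
$\mu = 1.2$ leaving a generation-1 cell unmarked with probability
$e^{-1.2} \approx 0.30$:

* **Unmarked $L_1$.** A deeper cell on Twin 1's founding chain is still
  fully clonal in Twin 1, so its mutations masquerade as the anchor at
  $(0.5,\, b'/2)$ with $b' < b$. The giveaway is the broken point symmetry.
  In that case the clonal coordinate is taken from the anchor ($a = 2v_1$)
  and the co-twin coordinate from the twin-pure counter cluster with the
  largest co-twin VAF ($b = 1 - 2u_2$); if even that cluster is implausibly
  deep ($u_2 < 0.1$), the midpoint of the two available bounds is used.
* **Mutual exclusivity.** If no EEM is detected in both twins, the twins
  share no marked lineage — the para-identical definition — and the minor
  contribution is set to 0. This also resolves the genuine ambiguity
  between a para pair with an unmarked $L_2$ and a sub pair with an
  unmarked founding chain (their VAF patterns are otherwise identical).
* **Anchor absent entirely.** The counter-anchor alone identifies $(a,b)$
  via $(1-2u_1, 1-2u_2)$. It is selected as the largest-summed-VAF cluster
  below the 0.5 threshold: the true counter-anchor's sum is
  $1 - (\text{anchor sum})$, which dominates any deeper sublineage cluster.
  (A literal "maximal $(1-2v_1) + (1-2v_2)$" rule would instead select
  background clusters near the origin.)

`classify_category()` uses $\varepsilon = 0.10$ boundaries: para if
$a \ge 1-\varepsilon$ and $b \le \varepsilon$; sub if $a \ge 1-\varepsilon$
and $\varepsilon < b < 1-\varepsilon$; full if $a < 1-\varepsilon$ and
$|a-b| \le 2\varepsilon$; otherwise discordant. $\varepsilon$ is a free
parameter of the category definition, surfaced in `model_config()` and
reported with every fit.

Genetic distance is the number of EEM events detected in exactly one
co-twin; founder separation converts unique clonal mutation counts to
divisions by dividing by 1.2 (rounded, or floored for "at least"
statements). On simulated cohorts the detected-EEM count is larger than in
the real study (the bottleneck creates many detectable deep subclonal
EEMs), so simulated distances sit on a larger scale; the monoamniotic <
diamniotic ordering is preserved and is what the tests assert.

## Chimerism, multi-tissue refinement, single cells

**Blood mixing** (`estimate_mixing()`): an EEM clonal in exactly one twin's
buccal tissue (VAF $\ge 0.4$) and absent in the co-twin's ($\le 0.02$)
marks that twin's whole soma. In a shared hematopoietic pool with twin-2
fraction $m$, a source-twin-2 EEM has expected cord-blood VAF $m/2$ and a
source-twin-1 EEM $(1-m)/2$. The binomial likelihood is maximised on a
$10^{-3}$ grid with golden-section refinement (the likelihood is unimodal;
a numerical check is part of the test suite), the error floor $e/3$
prevents zero-probability degeneracy, and the 95% CI is the
profile-likelihood interval (drop 1.92). Estimates are reported per cord
sample; a pooled fit is available (`pool = TRUE`) since it is not knowable
whether the original analysis pooled.

**Multi-tissue refinement** (`multisample_refine()`): with $\ge 3$ samples,
EEMs are clustered on their VAF profile across samples (correlation
distance, average linkage, cut at 0.15 — nested lineage profiles remain
correlated at roughly 0.7, so the cut must sit well below distance 0.3;
0.15 also tolerates binomial noise at 24x patch depth). Clusters are
ordered into a lineage by containment of detection patterns and serialised
as Newick.

**Single cells** (`reconstruct_sc_phylogeny()`): the observation model per
site is locus dropout $\lambda$ (site missing), allelic dropout $\alpha$
(true het read as hom-ref) and false positive rate (0.01; not reported for
MDA, fixed here). Defaults $\alpha = 0.23$, $\lambda = 0.46$. Assignment is
greedy top-down: clades seeded with the anchor/counter-anchor marker sets
(or the two most prevalent mutually exclusive variant groups), each cell
assigned by summed log observation likelihood, score gaps below 1 log unit
labelled ambiguous, exact ties broken toward the clade with more covered
marker sites, then recursion within clades. A putative marker whose
observed co-occurrence with the opposite clade exceeds the 99th percentile
expected from false positives alone is treated as misplaced and dropped
from the top split — this is what relocates a "counter-anchor" EEM that in
truth sits downstream of $L_1$. Exhaustive perfect-phylogeny search is out
of scope; the analysis resolves $L_1$/$L_2$ and immediate sublineages, as
in the bulk model.

## Cohort statistics

The contingency and rank tests are implemented in the package (base R
equivalents serve only as oracles in the test suite). The exact 2x2 Fisher
test enumerates the hypergeometric range; the two-sided p-value follows the
probability-mass rule with $10^{-7}$ relative slack, with a
doubled-one-tail variant available because printed two-sided conventions
differ. The $r \times c$ Monte Carlo test samples tables with both margins
fixed by sequential hypergeometric fill (vectorised over draws) and uses
the add-one estimator $(1+x)/(B+1)$. The Kruskal–Wallis statistic carries
the tie correction, with Bonferroni-multiplied pairwise tests.

Calibration is checked at a table scale where discreteness does not
dominate: 3x3 tables with row totals 40 (exact-type tests on very small
margins are conservative by construction, which is a property of the data
scale, not of the implementation). At that scale the Monte Carlo test's
null rejection rate at nominal 0.05 must fall in [0.03, 0.07] over 2000
null tables, and its p-values must be uniform.

## Determinism and numerical choices

Every stochastic function takes a seed; nested stages derive child seeds
with a fixed integer map (`derive_seed()`, always below $2^{31}$), so a
cohort, a pipeline run and its written artefacts are byte-identical across
reruns with the same seed — which is also why no stage caching exists: a
rerun *is* the cache. Zero read depth yields a missing VAF, distinct from
zero, everywhere. Ties in anchor selection break toward larger clusters,
then lower Twin-1 VAF variance. Degenerate inputs (all-missing single-cell
matrices, empty informative-EEM sets, all-tied rank groups, zero-margin
contingency rows) return explicit statuses or flagged results, never silent
guesses.

## Problem sizes used by the test suite

Tests run at deliberately desk-scale sizes chosen once: lineage trees of
depth 8–13; 200 replicates for $(a,b)$ and mixing recovery at 700x; 200
dropout matrices of 80 cells; 50 seeded families for calling recovery; 10
full cohorts for the category-recovery regression; $B$ up to $10^5$ for
Monte Carlo agreement and 2000 null tables for calibration. The
`analysis/` scripts run the full 29-family cohort.

## Known limitations

* A fully clonal EEM in both twins is labelled de novo (blind spot of
  VAF-only classification).
* Sub pairs whose founding chain is entirely unmarked are indistinguishable
  from para pairs with an unmarked $L_2$; the mutual-exclusivity rule
  resolves the common cases but a residual few percent of sub pairs
  misclassify as para.
* Chimerism assumes source EEMs are fully clonal in the source twin's
  hematopoietic lineage; subclonal contamination of the informative set
  (co-twin fraction just below the 0.02 screen) biases $\hat m$ by up to a
  few percent.
* Bulk $(a,b)$ describe the sampled tissue; with finite progenitor pools
  the tissue composition itself fluctuates around the founder-level truth,
  which bounds achievable category accuracy below 100%.
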