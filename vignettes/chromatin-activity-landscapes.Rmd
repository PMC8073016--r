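---
title: "Lineage-resolved chromatin activity landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage-resolved chromatin activity landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoscape)
```

## The measurement and its model

The *C. elegans* embryo develops through an invariant cell lineage: every
cell has a reproducible name (Sulston nomenclature), division history and
fate. A single-copy fluorescent reporter driven by a ubiquitous promoter
reads out the chromatin environment of its genomic integration site —
position effects — in every lineaged cell. Imaging many transgenic strains,
each with the reporter at a different site, and aligning cells by lineage
identity yields a **chromatin activity landscape**: a cells-by-positions
matrix of reporter activity on a log2 scale.

`chromoscape` implements the full quantitative path from per-nucleus
intensity time series to that landscape and its downstream statistics,
together with a seeded generator of synthetic embryo studies so that every
stage can be exercised against a known ground truth.

## From nucleus intensities to instantaneous expression

The quantification pipeline runs in a fixed order, each step with a
specific justification:

1. **Background subtraction.** Mean pixel intensity in an annulus between
   1.2 and 2 nuclear radii around the centroid, in the nucleus' own Z
   plane, with pixels inside 1.2 radii of any neighbouring nucleus
   excluded (`annular_background()`). Net intensities are floored at 0.
2. **Depth attenuation correction.** Fluorescence dims multiplicatively
   with imaging depth. With planes numbered away from the objective and a
   centre plane *c* (default 15 of 30), the measured intensity at plane
   *i* is restored by multiplying with $(1+\alpha)^{i-c}$: deeper cells
   are boosted, shallower cells dimmed, the centre plane untouched.
   `fit_attenuation()` estimates $\alpha$ by grid search (default 0 to
   0.10 in steps of 0.002), maximising the mean Pearson correlation of
   matched-cell intensities between replicate embryos imaged in opposite
   orientations (ventral versus dorsal side near the objective), because
   the same cell then sits at mirrored depths. Only cells whose
   *uncorrected* mean intensity exceeds 7 units in both pair members enter
   the objective — attenuation is not reliably measurable in dim cells,
   and keeping the cell set fixed across the grid keeps the objective
   smooth — but the fitted correction applies to all cells. Ties resolve
   to the smallest $\alpha$ (parsimony). The published factor for this
   imaging regime is 0.054 per plane, which is also the generator default.
3. **Per-cell mean.** Frames immediately adjacent to divisions are
   unreliable (chromatin condensation, nuclear envelope breakdown), so
   `k = 1` frame at each end of every cell's series is dropped before
   averaging. Both ends are trimmed for every cell; terminal cells' final
   frames abut the end of the recording and are equally boundary-suspect.
4. **Mother subtraction.** The reporter protein is stable over
   embryogenesis while cell cycles are fast, so a cell's content mixes
   inherited and newly made reporter. The mother's last pre-division
   corrected intensity is subtracted from the daughter's mean (no
   expression is assumed during division); lineage entry points subtract
   0; negative differences are floored. Subtracting from the *mean*
   rather than frame-by-frame keeps the estimate stable when cell-cycle
   lengths differ.
5. **Cutoff and transform.** A null distribution from reporter-free
   control embryos defines the detection cutoff as its 99th percentile
   (published value 6.36, used as default when no controls are supplied).
   Values below the cutoff become 0; otherwise the cutoff is subtracted
   and the result $\log_2(x+1)$ transformed. This is the cell's
   **chromatin activity**.

## Building the landscape

Reporter expression per integration site is measured in 2–8 replicate
embryos. Per cell and site, expression is accepted only when strictly more
than 60% of the replicates in which the cell was traced show a positive
value; the untransformed values of all traced replicates (zeros included)
are then averaged and $\log_2(x+1)$ transformed; otherwise the consensus
activity is 0. Cells untraced in a replicate leave the denominator —
traced-cell sets differ slightly between embryos, and treating absence as
silence would bias the rule. A cell/site is flagged *replicate-variable*
when its expressed fraction lies strictly between 0 and 1; such positions
are excluded from the cell-distinctness test (two cells are "distinct"
when five or more positions differ in consistent on/off state).

## Divergence statistics

Chromatin divergence between two cells is the Euclidean distance between
their activity vectors across all positions. Positions unmeasured in
either cell are dropped and the squared distance rescaled by
$P/P_\mathrm{used}$ so divergences stay comparable across coverage.

* **Lineage-distance stratification.** Lineage distance is the number of
  divisions separating two cells via their lowest common ancestor. Odd
  distances compare cells of different generations, so summaries default
  to even distances only.
* **Transition points.** For a candidate mother, divergences between the
  two daughter lineages' terminal cells (inter) are compared with
  divergences within each daughter lineage (intra) by one-sided
  Mann–Whitney U tests, one per daughter. The Benjamini–Hochberg family
  is *all* tests of the run (both daughters of every candidate mother),
  matching the genome-wide character of the screen; a division is a
  transition point when both adjusted p-values fall below 0.05 and the
  mean inter-divergence exceeds each mean intra-divergence. The
  transition score is the mean over daughters of
  mean(inter)/mean(intra) — the mean-of-ratios form, pinned by a
  regression test.
* **Cell clustering.** Pairwise divergences are first normalized by the
  mean divergence of all pairs at the same lineage distance (removing the
  systematic growth of divergence with lineage distance), then rows of
  the normalized matrix are clustered agglomeratively (Euclidean metric,
  average linkage) and the tree cut at 4.5.
* **Tissue analyses.** Intra- versus inter-tissue divergences are
  compared by MWU; because intra-tissue pairs are lineally closer, a
  matched control resamples inter-tissue pairs to the intra-tissue
  lineage-distance distribution (1000 seeded draws, one inter pair per
  intra pair; the reported matched p is the median MWU p across draws,
  computed with a tie-corrected normal approximation for speed).
* **Left–right symmetric pairs.** Each bilaterally symmetric pair's
  divergence is compared with same-tissue pairs at the same lineage
  distance (the symmetric pairs themselves excluded from the pool). The
  per-pair control summary is the pool *median*: divergence distributions
  are right-skewed, so comparison against the mean would count ~65% of
  exchangeable pairs as "below control"; the median makes the null
  fraction one half, which is what the shuffled-pairing control should
  give. The paired test is a one-sided Wilcoxon signed-rank.

## Genomic co-dynamics and enrichment

Position columns are compared by the same Euclidean divergence (across
cells), and the resulting position-by-position matrix is clustered with
the *same* agglomerative core used for cells, cut at 65. Clusters with at
least two members define co-dynamic pairs, classified geometrically as
linked (< 1 Mb on one chromosome, strict), same chromosome at ≥ 1 Mb, or
different chromosomes — midpoints of the integration intervals are used.

Enrichment statistics all reduce to one hypergeometric building block
(`hypergeom_enrichment()`): observed count, uniform-draw expectation, O/E
ratio and upper-tail p. Gene-level analyses draw genes from 100-kb windows
centred on each site (closed at both ends); the default universe for
pairwise functional enrichment is the set of gene pairs arising from *any*
site pair, which is the definition consistent with the worked
4-of-5-versus-4-of-10 example (O/E 2, p 6/252). Co-dynamic cluster
enrichment in clonal tissue lineages tests each cell's active and
silenced site sets against each multi-site cluster, adjusts BH within the
cell across all cluster-by-state tests, calls a cell enriched at O/E > 1.5
and Q < 0.05, and calls a cluster for the lineage when at least half of
its cells are enriched.

Clonal tissue lineages themselves are found bottom-up: a terminal cell
scores 1 for its own tissue (dying/unclassified cells score 0 for every
tissue, which keeps the recursion defined everywhere), each progenitor
averages its two daughters *unweighted* — so an imbalanced tree gives 0.5,
not the leaf fraction 4/5, a deliberate and tested distinction — and the
most-rootward progenitors with probability > 0.85 and ≥ 3 matching
terminal cells are reported, non-nested per tissue.

Chromosome arms are the outer 20% of each chromosome; the 20% boundary
itself belongs to the centre (the arm condition is strict).

## Fate profiles and fate divergence

A progenitor's developmental fate is the tissue pattern of its terminal
descendants in lineal order (anterior/left/dorsal daughters first). Two
profiles are aligned branch by branch; when one lineage ran fewer
division rounds, the shallower side's leaf fate is replicated across the
opposing subtree, recursively. Aligned leaves score 1 for matching
tissues, and fate divergence is 1 minus the mean score. Dying and
unclassified cells are removed from both profiles first; a branch left
empty on one side only contributes no comparisons (its opposing leaves
have no partner).

## The synthetic embryo generator

`sim_config()` fixes every study condition; a seed fully determines all
output. The defaults describe one synthetic study, chosen once:

* **Tree.** Founder subtrees AB/MS/E/C/D at depths 8/5/4/5/4 plus the
  germline, giving 354 terminal cells — the scale of a 350-cell-stage
  analysis set, which the published thresholds (4.5 for cells, 65 for
  positions) presume. Division axes follow anterior/posterior at most
  rounds with a left/right round second, so bilateral lineage pairs exist
  structurally.
* **Fates.** An inherit-or-switch process (switch probability 0.5 per
  division) over four major somatic tissues, 3% programmed death, the
  germline fixed, three planted clonal lineages (intestine from E, muscle
  from D, a neuronal clone at ABala), and fates mirrored across the
  registered symmetric pair (ABpl, ABpr).
* **Activity truth.** Each co-dynamic cluster shares one activity
  *profile* (member sites deviate by per-cell jitter, SD 0.3); every
  other site has its own. A profile carries a bimodal tissue-level on/off
  pattern (on level 7, off level −2 — which clips to silent — SD 1,
  P(on) 0.6, constrained so no profile is constitutively on or off across
  tissues, as observed for real integration sites), and each planted
  switch region flips 30% of those states, so chromatin identity is
  resolved by lineage origin as well as tissue. On top: a per-profile
  brightness offset (SD 1), a heritable Gaussian random walk along tree
  edges (SD 0.8 per division) producing the monotone
  divergence-versus-lineage-distance relation, tissue convergence 0.8
  shrinking terminal cells toward their tissue centroid, additive
  heritable switch shifts (+6 log2 units at 40% of profiles) below the
  second daughters of ABa, MS and C, exact activity copies across the
  predetermined left–right pairs, and a clip at 0. A repulsion step
  guarantees that distinct profiles stay separated by at least
  2.8·sqrt(n cells) after clipping (profiles too close by chance are
  redrawn), so planted singleton sites cannot collide with clusters.
* **Measurements.** Replicates (4 per site) are the untransformed linear
  activities with 10% lognormal noise, 3% on/off dropout and 5% untraced
  cells. Imaging renders per-frame intensities as inherited content (the
  stable reporter's carry-over: the mother's final content) plus linear
  accumulation proportional to activity over 7 frames per cycle, scaled
  by a gain of 300 intensity units per unit linear activity — placing
  expressed cells well above the 6.36 detection cutoff, as for the real
  reporter — attenuated by $(1+0.054)^{-(z-15)}$ at the cell's plane
  (mirrored between VNO and DNO embryos) over a constant background of
  10 units with 10% per-frame noise. Round-trip recovery is assessed on
  the untransformed scale, where mother subtraction and the cutoff
  operate.
* **Annotations.** 3000 genes placed along six chromosomes
  (length-weighted), co-expression relations planted between genes near
  same-cluster sites (rate 0.6) over a random background, categories, and
  tissue gene sets planted near each clonal lineage's active sites.

### What the generator does and does not emulate

It reproduces the *structure* the analyses target: replicate on/off
variability, depth attenuation with mirrored orientations, reporter
inheritance, lineage-coupled drift, switch-like transitions, tissue
convergence, left–right predetermination, co-dynamic position clusters and
functionally related annotation. It does not emulate cell geometry or
movement, photobleaching, segmentation/tracking errors, cell-cycle-length
variation, or the real genome's gene annotation — so green tests show the
*methods* are correct and well calibrated at realistic scales, not that
any particular biological conclusion transfers to a given real dataset.

### Controlled experiments versus the default study

Some properties are measured in focused configurations rather than on the
full default study, because the question demands a controlled contrast:

* Transition-detector error rates use i.i.d. noise landscapes (null) and
  single planted shifts of twice the noise SD (sensitivity): on the full
  study, detection of the planted mothers is a structural consequence of
  large switch effects and says nothing about calibration.
* The left–right predetermination contrast (on: ≥ 90% of pairs below
  matched controls; off: ≈ 50%) uses a configuration without planted
  switches and with convergence 0.4, so that pairs and their
  lineage-distance-matched controls are exchangeable under the null;
  with region structure present the controls mix switch regions and are
  systematically inflated for *any* same-region pair.
* Drift monotonicity is checked on a drift-only configuration, with a 3%
  per-step slack for sampling wobble of the deepest strata.

## Numerical choices and degenerate inputs

* Ties in the attenuation grid resolve to the smallest $\alpha$; the grid
  is ascending, so `which.max` after rounding to 12 digits implements
  this deterministically.
* Cluster labels are renumbered by first appearance, so clustering is
  invariant to input order up to relabeling (tested).
* Strata with zero mean divergence make normalized values undefined
  (`NA` with a warning) rather than infinite.
* Cells whose series is entirely division-adjacent are dropped with a
  warning; a mother absent from an embryo contributes 0 to subtraction.
* An annulus fully covered by neighbours, an empty fate-comparison set
  after exclusions, and a symmetric pair without matched controls each
  return an explicit undefined result (`NA` plus warning, or an excluded
  row with a reason) instead of failing silently.
* All genomic coordinates in files are 0-based half-open (BED); interval
  midpoints are used for geometry and windows.

## Problem sizes

Tests and examples run at the default 354-cell tree with 40 integration
sites and 4 replicates per site; the full pipeline completes in seconds.
Attenuation-recovery experiments use 6 opposite-orientation embryo pairs
of ~224 matched terminal cells over 20 seeds; detector calibration uses
20-seed batches of 114-cell trees. These sizes were chosen to mirror the
scale at which the published thresholds operate while keeping every stage
quick to re-run.

## Known limitations

* The lineage-distance normalization assumes every represented distance
  stratum is populated; tiny trees can leave single-pair strata where the
  spread is undefined.
* The matched-control MWU uses a tie-corrected normal approximation
  inside the resampling loop; exact p-values are used everywhere else.
* `fit_attenuation()` requires opposite-orientation replicate pairs of
  the same integrant; embryos in other orientations are corrected but
  never inform the fit.
* The co-dynamics threshold (65) is calibrated for landscapes of a few
  hundred cells; applying it to much smaller cell sets will under-split,
  because column distances scale with the square root of the cell count.
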