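---
title: "Sampling and analysing alternative protein conformations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling and analysing alternative protein conformations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altconf)
```

## The problem

Transporters and G-protein-coupled receptors work by moving between distinct
conformations — a transporter alternates between inward-facing (IF) and
outward-facing (OF) states, a receptor between inactive and active ones.
Deep-learning structure predictors are trained to produce a single static
structure, and with a deep multiple sequence alignment (MSA) they do exactly
that: fifty predictions of the same protein come out nearly identical.

The sampling protocol implemented here perturbs the predictor's view of the
evolutionary record instead of its physics: the input MSA is randomly
subsampled to a small depth (as few as 16 sequences), recycling is reduced to
a single pass, post-prediction relaxation is skipped, and many models are
drawn per depth. Under these conditions the predictor's output distribution
spreads out and, for suitable targets, covers both experimental end states
and the path between them. The package emits complete, machine-readable run
specifications for an external ColabFold-compatible engine — inference is
never run from R — and implements the downstream ensemble analysis in full:

1. **Misfold exclusion by coclustering.** Well-folded models cluster with
   each other even across conformations; misfolded ones virtually never do.
2. **Accuracy scoring** of every model against both experimental references
   with TM-score.
3. **Per-residue flexibility**: RMSF across the aligned ensemble, compared
   with the displacement of each Cα between the two superimposed
   references.
4. **Conformational landscape**: PCA of Cα coordinates, projection of the
   experimental structures into the model landscape, and selection of the
   models at the extremes of PC1 as candidate end-state representatives.

## The run-specification protocol

`make_runspec()` encodes the protocol constants:

* one recycle, no relaxation;
* without templates, all 5 networks × 10 models; with templates, the 2
  template-capable networks × 25 models — 50 models per MSA depth either
  way;
* the cluster-count parameter is half the subsampling depth, except 512 when
  the depth is 5120 (`default_cluster_count()`);
* with templates, the template similarity cutoff drops from 10% to 1% and
  template subsampling is enabled;
* the depth ladder defaults to powers of two from 16 to 512, then 1024 and
  5120 (`depth_ladder()`). The endpoints are protocol constants; the
  intermediate rungs are this package's interpolation and can be overridden.

Subsampling (`subsample_msa()`) draws rows uniformly without replacement and
always retains the query: predicting without the query sequence is
meaningless, and the query counts toward the reported depth. No
cluster-aware stratification is attempted — the cluster count is carried as
run metadata only. Per-model seeds derive from the run seed as
`seed + ordinal`, so each of the 50 models gets an independent but fully
reproducible subsample. Identity vetting of candidate templates uses
Needleman–Wunsch global alignment (BLOSUM62, gap open 11, extend 1 — the
algorithm is fixed by the protocol, the scoring defaults are ours) with
identity defined over the full alignment length including gap columns;
alternative denominators are selectable. Identities are reported to the
user, never applied as an automatic cutoff: template choice by conformation
is a human decision (`vet_templates()` filters by user-supplied labels).

## Superposition and TM-score

`kabsch()` computes the least-squares optimal proper rotation via SVD of the
cross-covariance matrix, with the determinant correction that forbids
reflections — a mirror-image decoy can never be "fixed" by the fit.

`tm_score()` implements the template-modeling score

$$\mathrm{TM} = \frac{1}{L_\mathrm{ref}} \sum_{i=1}^{L}
\frac{1}{1 + (d_i/d_0)^2}, \qquad
d_0 = \max\!\left(0.5,\; 1.24\,(L_\mathrm{ref}-15)^{1/3} - 1.8\right)$$

maximized over rigid superpositions of the mapped Cα pairs. Residue
correspondence always comes from sequence alignment (`correspond()`), never
from a structural alignment search: every comparison in this workflow is
same-protein or near-identical homolog. Maximization follows the standard
iterative scheme — superpositions seeded from contiguous fragments (full
chain, halves, quarters; minimum seed 4), then alternation between
superposing on the inlier set and recomputing inliers under a distance
cutoff that shrinks from $d_0$ to $d_0/2$ over the first six iterations —
and reports the best score over all seeds. Ties between seeds resolve to the
first seed in deterministic order. $L_\mathrm{ref}$ defaults to the
*mapped* residue count of the reference structure; TM-score is asymmetric
in this choice, so it is recorded in every result and a `length_norm`
argument exposes the alternative normalizations.

On toys of ≤ 30 residues the iterative scheme agrees to $10^{-3}$ with a
dense random-restart direct maximization, which is how the test suite pins
it down.

## Ensemble statistics

`align_ensemble()` puts all models in one frame, by default through
iterative mean-structure alignment (superpose all on the current mean,
recompute the mean, repeat until the mean moves < $10^{-6}$ Å, cap 100
iterations). This minimizes total ensemble variance compared with any
single-model reference policy, which the tests verify numerically.

`rmsf_profile()` is the textbook definition
$\mathrm{RMSF}_i = \sqrt{\langle \lVert x_{mi} - \bar x_i \rVert^2\rangle_m}$;
for isotropic Gaussian coordinate noise of scale $\sigma$ its expectation is
$\sigma\sqrt{3}$, a closed form the tests check by simulation.
`displacement_profile()` superposes one reference onto the other on the
mapped Cα pairs and measures per-residue distances; because the fit is a
mutual least-squares optimum the profile is symmetric under swapping the
references. Residues with pLDDT ≤ 75 are removed before correlating the two
profiles (`confidence_filter()`; the boundary is inclusive, and the filter
can be disabled because one benchmark target is conventionally analysed
unfiltered).

`filter_misfolded()` builds the pairwise Cα-RMSD matrix (each pair optimally
superposed on its shared residues), clusters by average linkage, cuts the
tree at 5 Å and discards models in clusters smaller than 3. No specific
algorithm or cutoff is prescribed by the protocol for this step — "failure
to cocluster" is the criterion — so these defaults were chosen for
simplicity and determinism, are stated in every report, and can be
overridden; `1 - TM` is available as an alternative metric.

## The landscape

`fit_landscape()` performs PCA — an eigendecomposition of the coordinate
covariance across models — on the flattened, masked Cα coordinate vectors.
Loop residues are excluded by default, since their heterogeneity swamps the
collective motions of interest: the built-in mask is a coarse Cα-geometry
secondary-structure heuristic (helical d(i, i+4) and extended d(i, i+2)
signatures), and any user-supplied mask overrides it. The mask in force is
recorded in all outputs.

The landscape is fit on models only; experimental references are projected
afterwards (`project_reference()`), the conservative reading of how a
reference can "occupy an extreme position" in a model-derived space. No
re-superposition happens inside the fit — models arrive aligned, so an
exactly collinear ensemble is exactly rank one. Three conventions make
reports deterministic: components carry their largest-magnitude loading
positive; `orient_landscape()` additionally flips PC1 so the first
reference projects negative; ties in extreme-model selection
(`select_extremes()`) break lexicographically by model id.

Models excluded by the misfold filter never enter the PCA, mirroring their
exclusion from all further analysis in the workflow (`run_analysis()`).

## What the synthetic generator emulates

`make_ensemble()` stands in for the GPU experiments so that every analysis
stage is testable at desk scale. It emulates:

* two rigid end states connected by a hinge motion — an idealized
  helical-hairpin Cα trace (3.8 Å virtual bonds) whose hinge segment is an
  Ω-loop-like circular arc, rotated rigidly about the axis through its two
  anchor Cαs. That axis choice preserves every bond length exactly in both
  states; the hairpin's second arm gives the scaffold leverage far from the
  hinge axis, so the hinge motion cannot be absorbed into a global rigid
  fit. The rotation angle is solved so the maximum per-residue displacement
  between the *superimposed* states equals the requested amplitude (10 Å by
  default), matching how displacement is measured downstream;
* an ensemble distributed between the states: end-state draws sit exactly
  at interpolation parameter 0 or 1; intermediates are uniform on
  [0.05, 0.95] — the margin keeps the three labels identifiable and makes
  "the references flank the models on PC1" a well-posed property, since a
  model drawn *at* an end state straddles that reference by construction
  once noise is added. The default composition is 60% intermediates and 20%
  per end state: models spanning the range between the two conformations,
  with the end states reached by a minority, is the distribution the
  selection logic is designed for, and an end-state-dominated mixture
  degenerates the comparison between extreme-model accuracy and the
  ensemble median;
* isotropic Gaussian coordinate noise (σ = 0.5 Å by default, small against
  the 10 Å hinge);
* misfolded decoys as self-avoiding random walks with 3.8 Å steps (2 per
  ensemble by default), far from every folded model by construction;
* per-residue pLDDT as `95 − 40·(local noise magnitude / model maximum)` —
  a monotone proxy sufficient to exercise the ≤ 75 filter, with no claim to
  emulate real confidence calibration;
* A3M alignments of controllable depth, substitution rate, gap rate and
  lowercase-insertion rate (`make_msa()`).

Everything is deterministic in the seed: regenerating with the same
specification is byte-identical.

What the generator does **not** emulate: real protein geometry beyond bond
lengths, side chains, sequence–structure covariation, predictor failure
modes other than global misfolding, and realistic pLDDT calibration.
Passing tests therefore demonstrate that the analysis machinery recovers
known constructions — conformer separation, hinge modes, decoy exclusion —
not that any predictor exhibits these behaviours on real proteins.

## Worked example

```{r example, eval = FALSE}
out <- make_ensemble(fixture_spec(seed = 13))
cfg <- workflow_config(target = "demo", seed = 13)
bundle <- run_analysis(cfg, ensemble = out$ensemble,
                       ref1 = out$end_states$stateA,
                       ref2 = out$end_states$stateB,
                       out_dir = "demo_run")
bundle$outliers           # decoys excluded by coclustering
bundle$landscape_summary$variance_fractions[1]   # PC1 dominance
bundle$correlation_r2     # RMSF vs displacement
head(bundle$extremes)     # top-k PC1 model selection
```

## Numerical choices and degenerate inputs

* Kabsch requires ≥ 3 points; 1–2 mapped residues in a displacement profile
  are handled by centering alone (a single pair always gives zero).
* TM-score requires ≥ 5 mapped pairs; the inlier set never shrinks below 4.
* `subsample_msa()` at a depth beyond the available rows returns the full
  alignment unchanged; `select_extremes()` with k = 0 returns an empty
  vector; an all-filtered confidence profile warns rather than errors.
* Iterative-mean alignment converges at < $10^{-6}$ Å mean movement; the
  hinge-angle solver uses `uniroot` at $10^{-10}$ tolerance; end states are
  refused if any nonadjacent Cα pair falls below 1 Å.
* `run_analysis()` catches per-stage errors, reports them by stage name and
  retains the outputs of earlier stages; reruns with the same config and
  inputs are byte-identical.

## Problem sizes used by the tests

The suite runs on 60-residue toys with ensembles of up to 52 models (500
for the RMSF noise check, which is the cheapest statistic), 20 seeds for
the decoy-exclusion property and 100 seeds for the subsampling overlap
statistic — sizes chosen so the whole suite exercises every property in a
couple of minutes on one core while keeping the statistical checks
well-powered.

## Known limitations

* Single chains only; complexes and symmetry expansion are out of scope.
* Residue correspondence is sequence-based; remote homologs that need a
  structural alignment search are not supported.
* The landscape is Cartesian; no kernel or time-lagged embeddings.
* The secondary-structure mask is a coarse heuristic — supply an explicit
  mask for real proteins.
* The quantitative headline numbers of the original GPU-scale experiments
  (e.g. variance fractions or accuracy averages over real benchmark
  targets) are not reproducible at desk scale and are not claimed by this
  package's tests; the synthetic recovery properties above are.
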