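---
title: "Geometric binding-site rescoring: methods and design notes"
author: "SiteRescore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric binding-site rescoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SiteRescore)
```

## The problem and the model

A docking engine ranks each compound of a screening library by an energy
score over a bundle of candidate poses. For flexible, polyspecific receptors
such as the apelin receptor (APJR, a class A GPCR) that energy is often a
poor classifier: when evaluated against a library of known binders (true
positives, TPs) and property-matched decoys, the minimum docking energy can
sit at — or below — chance level. SiteRescore implements a Stage-II filter
that re-ranks docked compounds by where they bind rather than how strongly
the docking function thinks they bind.

The score of a pose against a binding-site definition $BS$ with reference
atoms $\{r_{BS,i}\}_{i=1}^{n}$ is

$$ s_{BS} \;=\; \frac{1}{n} \sum_{i=1}^{n} \min_j \,\lVert r_{BS,i} - r_{lig,j} \rVert , $$

the mean over site reference atoms of the distance to the nearest ligand
atom (Å). The outer mean runs over the site and the inner minimum over the
ligand: every part of the site must be near *some* ligand atom for the score
to be small, which rewards poses that fill the pocket and penalizes poses
that merely graze it. The transposed form (mean over ligand atoms of the
distance to the nearest site atom) is available as
`direction = "ligand-to-site"`; it scores small for a ligand that touches
the site anywhere, a laxer criterion, and is not the default.

Assumptions worth making explicit:

* reference atoms are the site residues' alpha carbons (`atomMode = "CA"`),
  so the score is insensitive to side-chain rotamers; `"all-heavy"` mode
  trades that robustness for resolution;
* hydrogens present in a pose participate by default ("every ligand atom");
  `includeHydrogens = FALSE` restricts to heavy atoms;
* the score carries no physics — no sterics, no electrostatics. It is a
  geometric filter meant to precede, not replace, free-energy rescoring.

## Scoring rules and ensemble aggregation

Per ligand, `scoreBundle()` reports `minE` (minimum docking energy over the
bundle), `avgE` (mean energy) and $s_{BS}$ per site. Under the default
`pose_rule = "min-energy-pose"` the geometric score is evaluated on the
single lowest-energy pose — the pose a docking pipeline retains for
analysis. `"best-score-pose"` instead takes the per-site minimum over all
poses (useful when the energy ranking is distrusted entirely), and
`"all-poses"` returns the full per-pose table.

For a receptor ensemble, `aggregateEnsemble()` combines per-snapshot score
tables cell-wise. How per-snapshot scores are best pooled into one
ensemble ROC is genuinely open; the default rule is `min` — a ligand is
judged by its best fit in any sampled conformation, the common
ensemble-docking choice — with `mean` and `median` available. This default
is a design decision of this package, not an established fact.

## Enrichment statistics

`rocCurve()` builds the ROC over all distinct score thresholds with tied
scores grouped at a single threshold, which makes the trapezoidal AUC equal
to the tie-corrected Mann–Whitney statistic
$P(s_{TP} < s_{decoy}) + \tfrac12 P(=)$; the test suite verifies that
identity to $10^{-12}$ against an independent pairwise-rank oracle.

Two conventions matter and are deliberate:

* **Orientation is uniform and explicit** — `lower-is-positive` for every
  score, energies and distances alike, and never auto-flipped. An
  anti-informative score is reported with AUC below 0.5 instead of being
  silently inverted; benchmark tables in this field report such values
  as-is, and auto-orientation would make ratios against them meaningless.
* **AUC ratios truncate to three decimals** (`aucRatio()`): published
  ratio tables in this area match truncation of the printed-AUC quotient,
  not rounding. Full precision is retained internally;
  `rounding = "none"` disables display truncation.

## Grid-box construction

`computeGridBox()` builds the docking search volume from a contact-residue
list: centered at the residues' mass center (standard atomic weights when
elements are known, unit masses otherwise; `massMode` forces either), with
per-axis point counts

$$ \mathrm{points} = 2\,\lceil h/\mathrm{spacing} \rceil + 1, \qquad
   h = \max(\mathrm{max} - c,\; c - \mathrm{min}) + \mathrm{padding}, $$

odd by construction (AutoDock's points = intervals + 1 convention), with a
floor of 3 per axis. Using the larger center-to-extreme distance $h$ rather
than half the min–max range guarantees that every listed atom lies inside
the box with at least `padding` of margin even when the mass center is
off-center in the residue cloud; for symmetric clouds the two definitions
coincide. Defaults are spacing 0.375 Å and padding 0 (the maximum confining
box). The bundled APJR registry (`apjrSites()`) carries the exact
17-residue contact list used for grid construction, plus BS1/BS2/BS3 and
the critical set; the per-site memberships of the latter four are
approximate — the published assignment is conveyed by figure coloring
only — and the YAML is designed to be edited.

## Interaction analysis

The pose-analysis layer is purely geometric, with every cutoff a config
default chosen from common structural-biology practice (the underlying
observations these tools support are qualitative):

| quantity | default | unit |
|---|---|---|
| covalent bond tolerance | 0.45 | Å over summed covalent radii |
| X–H bond maximum | 1.2 | Å |
| ring planarity tolerance | 0.15 | Å out-of-plane |
| pi-stack centroid cutoff | 5.5 | Å |
| parallel / T-shaped interplanar angle | ≤ 30 / ≥ 60 | degrees |
| H-bond donor–acceptor cutoff | 3.5 | Å |
| D–H⋯A minimum angle (explicit H) | 120 | degrees |
| aromatic-cluster linkage radius | 2.5 | Å |

Bonds are inferred from covalent radii; rings of size 3–7 come from the
bond graph's cycles, each with a best-fit-plane normal (SVD). Receptor
donors/acceptors come from a residue template table (backbone N donor
except proline, backbone O acceptor, side chains per amino-acid chemistry);
receptor hydrogens are not required, so receptor-donor contacts are
distance-only. Ligand typing uses elements plus inferred bonds, with no
formal-charge perception — a known simplification. Aromatic pose hot-spots
are single-linkage clusters of ring centroids, the numeric counterpart of
spotting substructure clusters by eye; no claim is made that cluster
identities on real data are reproduced, only the clustering behavior itself
is tested (on constructions with known answers).

## Samplers

`sampleChain()` provides generic Hamiltonian Monte Carlo and Langevin
dynamics over pluggable potentials — `function(q)` returning the energy and
the force. The deliberate design choice is to implement the
acceptance-rejection scheme, not a force field: proposals are short
leapfrog trajectories (default 10 MD steps, mirroring the production
protocol this scheme comes from, where samples were retained every 25,000
acceptance-rejection steps of 10 MD steps at dt = 0.002 ps), momenta are
fully refreshed from the Maxwell–Boltzmann distribution each proposal (the
refresh policy is unstated in the source protocol; full refresh is the
standard choice), and the Metropolis test uses the full Hamiltonian,
$\min(1, e^{-\Delta H/kT})$. A trajectory that diverges to a non-finite
gradient is treated as a divergent proposal and rejected, preserving
detailed balance. The Langevin sampler uses the BAOAB splitting at friction
`gamma`, targeting the same $kT$.

Thinning and burn-in follow the retained-frame convention: the chain runs
`(nSamples + burnIn) * thin` iterations, keeps every `thin`-th frame and
drops the first `burnIn` retained frames — so `burnIn = 1` drops exactly
the first frame, matching the ensemble-generation protocol the scheme
mirrors. Seeds are mandatory (no hidden global default), and runs are
bit-reproducible given seed and parameters.

The elastic-network potential (`enmPotential()`) — harmonic springs of
uniform force constant between CA pairs within 10 Å at their reference
lengths — gives a structure-shaped test potential so RMSD/RMSF pipelines
can be exercised on receptor-like objects without a force field.

Correctness is established statistically in the test suite: free-particle
and reversibility identities and $O(dt^2)$ energy error for the integrator;
exact unit acceptance on a constant potential; harmonic variance $kT/k$
within 3 standard errors (batch-means SE, since draws are correlated);
three-bin occupancies on a tilted double well against quadrature Boltzmann
factors; and 2-D anisotropic Gaussian covariance within 5% relative
Frobenius error at $10^5$ draws.

## Trajectory metrics

`rmsd()` superposes by the standard least-squares SVD construction with a
reflection guard before measuring (superposition on by default — whether
published trajectory RMSDs were fitted is often unstated, so the flag is
explicit). `rmsf()` superposes every snapshot onto the running ensemble
mean, iterated to a fixed point, which makes the result independent of
snapshot order; fluctuations are reported per residue. For isotropic
per-axis jitter $\sigma$, the expected RMSF is $\sigma\sqrt{3}$, the closed
form the recovery tests use. The least-squares fit necessarily absorbs a
small fraction ($\approx 2/n_{res}$ of the variance) of a single residue's
fluctuation; tests size their systems so this bias is well inside the
statistical tolerance.

## The synthetic benchmark and what it does (not) show

`makeToyReceptor()` builds a deterministic 7-helix bundle (196 helix
residues plus 10 acidic rim residues, CA/N/C/O/CB per residue, PHE rings
lining the pocket) with three disjoint labeled sites: BS1 inside the
pocket, BS2/BS3 on the rim above the mouth plane. `makeLibrary()` plants
each TP's minimum-energy pose as a compact atom cloud on the BS1 centroid
plus isotropic noise `tpSigma`, scatters decoy poses uniformly in the
confining grid box of all three sites (or at a shifted site;
`shift = 0` is an exact null), and draws energies N(−6, 1.5) kcal/mol
independent of label (`"anti-informative"` worsens TP energies by half an
SD, reproducing the qualitative below-chance behavior of raw docking
energies on hard benchmarks). The default study conditions — 50 TPs, 400
decoys, `tpSigma = 3` Å, 10 poses per ligand, uniform-box decoys,
uninformative energies — are the calibration the acceptance checks
prescribe, chosen once; atom counts (8–16 per ligand) and the energy
parameters are arbitrary but documented defaults.

`expectedAuc()` is the benchmark's independent oracle: it computes the AUC
of the *generated* scores by the pairwise rank statistic (naive double-loop
code paths, shared with nothing in the pipeline) with a seeded bootstrap
95% CI. The acceptance property is that the full pipeline — write files,
re-read them, resolve sites, score, label, ROC — lands inside that CI,
that the focused BS1 score out-enriches the diluted BStot union, and that
the minE CI straddles 0.5.

What passing these tests shows: the scoring, labeling and ROC machinery is
self-consistent, statistically calibrated, and recovers planted enrichment
structure through the full file-format round trip. What it does not show:
performance on real chemistry. The synthetic ligands are labeled point
clouds (optionally with planted hexagonal rings); there is no
conformational strain, no property matching between TPs and decoys, no
docking physics, and the toy receptor's geometry is idealized. Quantitative
AUCs from the synthetic benchmark therefore do not transfer to real
screens; only the qualitative ordering (site-focused score ≫ diluted
site ≫ uninformative energy) is the claim under test.

## Numerical choices and degenerate inputs

* Distances in double precision; no cutoff or neighbor lists (sites are at
  most tens of reference atoms).
* PDB/PDBQT parsing is fixed-column (x, y, z from columns 31–54) — docking
  engines emit irregular spacing, so whitespace splitting is unsafe.
  Insertion codes are rejected (residue identity is `(chain, resseq)`);
  PDBQT charge and atom-type columns are retained as metadata. The native
  JSON pose table is the normative fixture format (full precision); PDBQT
  round-trips at its printed 3 decimals. Pose-energy REMARK lines are
  matched by a configurable regex list accepting VINA-result and
  free-binding-energy dialects.
* `aucRatio()` truncation adds a $10^{-9}$ epsilon before flooring so
  quotients that are exact in decimal but one ulp low do not truncate a
  full digit down.
* Empty site definitions are legal values (set algebra may produce them)
  and only error when resolved against a structure. A residue present
  without a CA is an error, not a silent skip; a residue absent entirely
  goes to the geometry's `missing` report.
* Ties in ROC thresholds are grouped (step construction); curve endpoints
  are exactly (0,0) and (1,1).
* Grid-box point counts floor at 3 per axis, so degenerate (planar or
  single-atom) residue sets still yield a valid box.

## Problem sizes

The test suite and acceptance checks run at desk scale by design: oracle
equivalences on 1000 random instances (n ≤ 500 ligands, ≤ 25 site atoms),
the synthetic enrichment study at 450 ligands × 10 poses, HMC checks at
5×10^4–10^5 draws of 1–2-dimensional targets, and RMSF recovery at 150
residues × 1200 snapshots. These sizes were chosen so the full suite
completes in a few minutes while keeping every statistical tolerance
(3 SE bands, 5% Frobenius, CI containment) meaningful.

## Known limitations

* The geometric score ignores chemistry entirely; two poses with identical
  geometry but opposite charge complementarity score identically.
* Receptor H-bond typing is template-based and hydrogen-free; histidine
  tautomers and protonation states are not distinguished.
* `BScritical` and the BS1/BS2/BS3 memberships shipped for APJR are
  figure-derived approximations, flagged as such in the YAML.
* The samplers are not a molecular-dynamics engine: no constraints, no
  pressure coupling, no PME — by design, they exist to make the
  acceptance-rejection scheme and the ensemble pipeline testable.
* Early-enrichment metrics (BEDROC, EF@1%) and AUC confidence tests are
  out of scope; the bootstrap CI in `expectedAuc()` covers the synthetic
  oracle only.
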