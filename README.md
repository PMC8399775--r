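# SiteRescore

Stage-II rescoring toolkit for structure-based virtual screening against
GPCR-like receptors. After a docking engine has generated pose bundles for a
compound library, the expensive parts of a screening campaign (free-energy
rescoring, experimental follow-up) want a cheap, reliable filter that
re-ranks candidates better than the docking energy itself. SiteRescore
implements such a filter — a geometric binding-site fitness score — together
with everything needed to evaluate and deploy it: binding-site definitions
with set algebra, docking grid-box construction, ROC/AUC enrichment analysis
against true-positive/decoy libraries, ensemble-docking aggregation,
geometric pose-interaction analysis, generic Hamiltonian Monte Carlo and
Langevin samplers for receptor-ensemble generation at toy scale, and a
synthetic benchmark generator with independent statistical oracles.

It is aimed at structural bioinformaticians running or prototyping
virtual-screening pipelines, in particular against the apelin receptor
(APJR), whose binding-site definitions ship with the package.

## The score

For a binding site *BS* with *n* reference atoms (by default the alpha
carbon of each site residue) and a ligand pose with atoms *r*<sub>lig,j</sub>,

&nbsp;&nbsp;&nbsp;&nbsp;*s*<sub>BS</sub> = (1/*n*) Σ<sub>i</sub> min<sub>j</sub> ‖*r*<sub>BS,i</sub> − *r*<sub>lig,j</sub>‖

i.e. the mean over site reference atoms of the distance to the nearest
ligand atom, in Å. A pose nestled into the site leaves no reference atom far
from the ligand, so **lower is better** — the toolkit's uniform orientation
convention for every score, docking energies included. Enrichment of a score
against a labeled library is summarized by the trapezoidal AUC of its ROC
curve, and the gain of a rescoring function is reported as the ratio of its
AUC to that of the minimum docking energy (`minE`), truncated to three
decimals for display.

## Worked example

Generate a synthetic benchmark (a 7-helix toy receptor with a labeled
pocket; 50 true positives placed in the pocket with 3 Å of noise, 400 decoys
scattered uniformly, docking energies carrying no class signal), score it,
and measure enrichment:

```r
library(SiteRescore)

rec <- makeToyReceptor(seed = 1)
lib <- makeLibrary(rec, nTp = 50, nDecoy = 400, tpSigma = 3, seed = 7)

tab <- scoreLibrary(lib$bundles, rec$structure, rec$sites[c("BS1", "BStot")])
head(scores(tab), 3)
#>   ligand_id       snapshot pose_index_scored      minE      avgE       BS1    BStot
#> 1     tp001 toy-receptor-1                 2 -6.175433 -4.347483 10.140205 12.62878
#> 2     tp002 toy-receptor-1                 9 -8.183426 -6.275290  9.761368 12.34944
#> 3     tp003 toy-receptor-1                 2 -7.709581 -5.309689 10.316213 11.35781

rocCurve(scoreVector(tab, "BS1"), lib$manifest)
#> ROCCurve (lower-is-positive): AUC = 0.9505 over 50 TP / 400 decoys, 451 thresholds
```

The three scores line up the way a site-focused geometric filter should:
`BS1` (the pocket itself) enriches best, the diluted union of all three
sites (`BStot`) less, and the docking energy not at all:

```r
#> AUC: BS1 0.950 | BStot 0.886 | minE 0.482
```

`minE` sits at chance level because the generator draws energies
independently of the labels — rescoring by pocket geometry is what separates
binders from decoys here, with an AUC gain of
`aucRatio(0.950, 0.482)` = 1.971 over the docking energy.

A docking grid box for the bundled APJR contact residues (or any residue
list) comes from the same machinery:

```r
box <- computeGridBox(rec$structure, rec$sites$BStot, spacing = 0.375)
writeLines(gpfStanza(box))
#> npts 74 74 46
#> spacing 0.375
#> gridcenter 0.083 0.038 39.107
```

The same pipeline is scriptable from a shell through the bundled CLI
(`system.file("cli", "site-rescore", package = "SiteRescore")`), with
subcommands `simulate`, `gridbox`, `rescore`, `roc`, `analyze-poses`,
`hmc-sample` and `md-sample`.

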