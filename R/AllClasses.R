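#' @import methods
#' @importFrom stats sd quantile rnorm runif median ks.test hclust cutree dist setNames
#' @importFrom utils read.csv write.csv head
#' @importFrom graphics hist
NULL

.finite3 <- function(m) is.numeric(m) && all(is.finite(m))

#' Atomic structure: a receptor or one ensemble snapshot
#'
#' Holds one atom per row of `atoms` with residue and chain identity and
#' Cartesian coordinates in Angstrom. Extra columns produced by a dialect
#' (PDBQT partial charge, AutoDock atom type) are retained verbatim.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resseq`, `chain`, `x`, `y`, `z` (Angstrom); further columns
#'   allowed.
#' @slot label free-text snapshot identifier.
#' @exportClass Structure
setClass("Structure",
  representation(atoms = "data.frame", label = "character"),
  prototype(label = "")
)

setValidity("Structure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resseq", "chain", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms lacks columns:", paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) < 1L) return("a Structure needs at least one atom")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(!nzchar(a$element))) return("empty element symbol")
  if (anyDuplicated(a$serial)) return("duplicate atom serial numbers")
  key <- paste(a$chain, a$resseq, a$name)
  if (anyDuplicated(key))
    return(paste("duplicate (chain, resseq, atom name):", key[duplicated(key)][1L]))
  TRUE
})

#' One ligand's docked poses
#'
#' All poses share the same atoms (order and identity); each pose carries its
#' own coordinates and a docking energy in kcal/mol. Energies may be `NaN`
#' only when a permissive reader supplied them; scoring rules that need
#' energies reject `NaN`.
#'
#' @slot ligandId ligand identifier.
#' @slot coords list of m x 3 coordinate matrices (Angstrom), one per pose.
#' @slot energies numeric vector of docking energies (kcal/mol), one per pose.
#' @slot atomMeta data.frame with per-atom `name` and `element`, shared
#'   across poses.
#' @exportClass PoseBundle
setClass("PoseBundle",
  representation(ligandId = "character", coords = "list",
                 energies = "numeric", atomMeta = "data.frame")
)

setValidity("PoseBundle", function(object) {
  if (length(object@coords) < 1L) return("a PoseBundle needs at least one pose")
  if (length(object@coords) != length(object@energies))
    return("one energy per pose required")
  m <- nrow(object@coords[[1L]])
  for (k in seq_along(object@coords)) {
    ck <- object@coords[[k]]
    if (!is.matrix(ck) || ncol(ck) != 3L)
      return(sprintf("pose %d coordinates are not an m x 3 matrix", k))
    if (nrow(ck) != m)
      return(sprintf("pose %d has %d atoms; pose 1 has %d", k, nrow(ck), m))
    if (!all(is.finite(ck))) return(sprintf("pose %d has non-finite coordinates", k))
  }
  if (any(is.infinite(object@energies))) return("infinite pose energy")
  if (nrow(object@atomMeta) != m) return("atomMeta rows must match pose atom count")
  TRUE
})

#' True-positive / decoy library manifest
#'
#' Labels each ligand `TP` (a known binder, here a compound with measured
#' EC50 below the configured threshold) or `decoy` (a presumed non-binder).
#'
#' @slot entries data.frame with columns `ligand_id`, `label` and optional
#'   `ec50_nM`.
#' @slot ec50Threshold maximum EC50 (nM) a labeled TP may carry; default 1.0.
#' @exportClass LibraryManifest
setClass("LibraryManifest",
  representation(entries = "data.frame", ec50Threshold = "numeric"),
  prototype(ec50Threshold = 1.0)
)

setValidity("LibraryManifest", function(object) {
  e <- object@entries
  if (!all(c("ligand_id", "label") %in% names(e)))
    return("entries needs ligand_id and label columns")
  if (anyDuplicated(e$ligand_id))
    return(paste("duplicate ligand_id:", e$ligand_id[duplicated(e$ligand_id)][1L]))
  bad <- setdiff(unique(e$label), c("TP", "decoy"))
  if (length(bad)) return(paste("unknown label(s):", paste(bad, collapse = ", ")))
  if ("ec50_nM" %in% names(e)) {
    tp <- e$label == "TP" & !is.na(e$ec50_nM)
    if (any(e$ec50_nM[tp] >= object@ec50Threshold))
      return(sprintf("TP with ec50_nM >= threshold (%g nM)", object@ec50Threshold))
    if (any(e$ec50_nM[!is.na(e$ec50_nM)] <= 0)) return("ec50_nM must be positive")
  }
  TRUE
})

#' Named binding-site residue set
#'
#' A binding site is a set of (chain, residue number) pairs; the geometric
#' fitness score is computed against the alpha carbons of these residues.
#' Sets support union/intersection/difference via [siteAlgebra()].
#'
#' @slot name site name (e.g. "BS1").
#' @slot residues data.frame with columns `chain`, `resseq`.
#' @slot provenance free text recording where the definition came from.
#' @exportClass BindingSiteDefinition
setClass("BindingSiteDefinition",
  representation(name = "character", residues = "data.frame",
                 provenance = "character"),
  prototype(provenance = "")
)

setValidity("BindingSiteDefinition", function(object) {
  r <- object@residues
  if (!all(c("chain", "resseq") %in% names(r)))
    return("residues needs chain and resseq columns")
  if (anyDuplicated(paste(r$chain, r$resseq))) return("duplicate residues")
  if (!nzchar(object@name)) return("site name must be non-empty")
  TRUE
})

#' Reference-point geometry of a resolved binding site
#'
#' The coordinates (default: one alpha carbon per residue) a pose is scored
#' against, in definition order, plus a report of definition residues absent
#' from the structure.
#'
#' @slot siteName name of the source definition.
#' @slot coords n x 3 matrix of reference coordinates (Angstrom).
#' @slot residueOrder data.frame (`chain`, `resseq`) aligned with `coords`
#'   rows (repeated per atom under all-heavy mode).
#' @slot missing data.frame of requested residues not found in the structure.
#' @exportClass SiteGeometry
setClass("SiteGeometry",
  representation(siteName = "character", coords = "matrix",
                 residueOrder = "data.frame", missing = "data.frame")
)

setValidity("SiteGeometry", function(object) {
  if (ncol(object@coords) != 3L) return("coords must be n x 3")
  if (nrow(object@coords) < 1L) return("no reference coordinates")
  if (!all(is.finite(object@coords))) return("non-finite coordinates")
  if (nrow(object@residueOrder) != nrow(object@coords))
    return("residueOrder must align with coords rows")
  TRUE
})

#' AutoDock-style docking grid box
#'
#' An axis-aligned search volume given by its center, grid spacing and odd
#' point counts per axis (points = intervals + 1).
#'
#' @slot center 3-vector, Angstrom.
#' @slot spacing grid spacing, Angstrom.
#' @slot points integer 3-vector of per-axis point counts (odd, >= 3).
#' @slot padding margin added on each side of the residue extent, Angstrom.
#' @exportClass GridBox
setClass("GridBox",
  representation(center = "numeric", spacing = "numeric",
                 points = "integer", padding = "numeric")
)

setValidity("GridBox", function(object) {
  if (length(object@center) != 3L || !all(is.finite(object@center)))
    return("center must be a finite 3-vector")
  if (object@spacing <= 0) return("spacing must be > 0")
  if (length(object@points) != 3L) return("points must have length 3")
  if (any(object@points < 3L)) return("at least 3 points per axis")
  if (any(object@points %% 2L == 0L)) return("points must be odd")
  if (object@padding < 0) return("padding must be >= 0")
  TRUE
})

#' Per-ligand score table
#'
#' One row per ligand (and snapshot): the minimum and average docking energy
#' over the pose bundle and the geometric site score for each site
#' definition, joinable with a [LibraryManifest-class] by `ligand_id`.
#'
#' @slot scores data.frame with columns `ligand_id`, `snapshot`,
#'   `pose_index_scored`, `minE`, `avgE` and one column per site name.
#' @slot siteNames ordered character vector of site score columns.
#' @exportClass ScoreTable
setClass("ScoreTable",
  representation(scores = "data.frame", siteNames = "character")
)

setValidity("ScoreTable", function(object) {
  s <- object@scores
  need <- c("ligand_id", "snapshot", "minE", "avgE", object@siteNames)
  if (!all(need %in% names(s)))
    return(paste("scores lacks columns:", paste(setdiff(need, names(s)), collapse = ", ")))
  if (anyDuplicated(paste(s$ligand_id, s$snapshot)))
    return("duplicate (ligand_id, snapshot) rows")
  for (nm in object@siteNames)
    if (any(s[[nm]] < 0, na.rm = TRUE)) return("site scores must be >= 0")
  if (any(s$minE > s$avgE + 1e-9, na.rm = TRUE)) return("minE must be <= avgE")
  TRUE
})

#' Receiver operating characteristic curve
#'
#' TPR versus FPR over a running threshold, with the trapezoidal area under
#' the curve. Orientation is explicit and never auto-flipped: under
#' `lower-is-positive` a ligand is called positive when its score is at or
#' below the threshold.
#'
#' @slot thresholds score thresholds, ordered from most to least stringent.
#' @slot fpr,tpr arrays in \[0, 1\], starting at (0, 0), ending at (1, 1).
#' @slot auc trapezoidal area under the curve.
#' @slot orientation `"lower-is-positive"` or `"higher-is-positive"`.
#' @slot nPos,nNeg class counts.
#' @exportClass ROCCurve
setClass("ROCCurve",
  representation(thresholds = "numeric", fpr = "numeric", tpr = "numeric",
                 auc = "numeric", orientation = "character",
                 nPos = "integer", nNeg = "integer")
)

setValidity("ROCCurve", function(object) {
  if (length(object@fpr) != length(object@tpr)) return("fpr/tpr length mismatch")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    return("fpr and tpr must be monotone non-decreasing")
  n <- length(object@fpr)
  if (object@fpr[1L] != 0 || object@tpr[1L] != 0) return("curve must start at (0,0)")
  if (object@fpr[n] != 1 || object@tpr[n] != 1) return("curve must end at (1,1)")
  if (object@auc < 0 || object@auc > 1) return("auc out of [0,1]")
  if (!object@orientation %in% c("lower-is-positive", "higher-is-positive"))
    return("unknown orientation")
  TRUE
})

#' One MCMC / Langevin sampling run
#'
#' @slot samples n x d matrix of retained coordinate snapshots (row = draw).
#' @slot acceptanceRate accepted / proposed fraction (NA for Langevin).
#' @slot nAccepted,nProposals accept/reject tally behind `acceptanceRate`.
#' @slot seed the RNG seed the run was started from.
#' @slot params list: sampler, md_steps_per_proposal, dt, thin, burn_in, kT.
#' @exportClass SampleRun
setClass("SampleRun",
  representation(samples = "matrix", acceptanceRate = "numeric",
                 nAccepted = "integer", nProposals = "integer",
                 seed = "integer", params = "list")
)

setValidity("SampleRun", function(object) {
  if (nrow(object@samples) < 1L) return("no samples retained")
  if (object@nProposals > 0L) {
    r <- object@nAccepted / object@nProposals
    if (!is.na(object@acceptanceRate) && abs(r - object@acceptanceRate) > 1e-12)
      return("acceptanceRate inconsistent with tally")
  }
  TRUE
})
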