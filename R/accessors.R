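#' Accessors for SiteRescore objects
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param i pose index (for [poseCoords()]).
#' @name accessors
NULL

#' @describeIn accessors atom table of a [Structure-class].
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)

#' @describeIn accessors n x 3 coordinate matrix.
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))
#' @export
setMethod("coords", "Structure", function(x, ...) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
})
#' @export
setMethod("coords", "SiteGeometry", function(x, ...) x@coords)

#' @describeIn accessors number of atoms.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))
#' @export
setMethod("nAtoms", "PoseBundle", function(x) nrow(x@atomMeta))

#' @describeIn accessors snapshot label of a [Structure-class].
#' @export
setGeneric("structureLabel", function(x) standardGeneric("structureLabel"))
#' @export
setMethod("structureLabel", "Structure", function(x) x@label)

#' @describeIn accessors ligand identifier of a [PoseBundle-class].
#' @export
setGeneric("ligandId", function(x) standardGeneric("ligandId"))
#' @export
setMethod("ligandId", "PoseBundle", function(x) x@ligandId)

#' @describeIn accessors number of poses in a bundle.
#' @export
setGeneric("nPoses", function(x) standardGeneric("nPoses"))
#' @export
setMethod("nPoses", "PoseBundle", function(x) length(x@coords))

#' @describeIn accessors coordinates of pose `i` (m x 3, Angstrom).
#' @export
setGeneric("poseCoords", function(x, i) standardGeneric("poseCoords"))
#' @export
setMethod("poseCoords", "PoseBundle", function(x, i) x@coords[[i]])

#' @describeIn accessors per-pose docking energies (kcal/mol).
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))
#' @export
setMethod("energies", "PoseBundle", function(x) x@energies)

#' @describeIn accessors per-atom metadata shared across poses.
#' @export
setGeneric("atomMeta", function(x) standardGeneric("atomMeta"))
#' @export
setMethod("atomMeta", "PoseBundle", function(x) x@atomMeta)

#' @describeIn accessors manifest entry table.
#' @export
setGeneric("manifestEntries", function(x) standardGeneric("manifestEntries"))
#' @export
setMethod("manifestEntries", "LibraryManifest", function(x) x@entries)

#' @describeIn accessors named counts per label plus the total.
#' @export
setGeneric("labelCounts", function(x) standardGeneric("labelCounts"))
#' @export
setMethod("labelCounts", "LibraryManifest", function(x) {
  e <- x@entries
  c(TP = sum(e$label == "TP"), decoy = sum(e$label == "decoy"), total = nrow(e))
})

#' @describeIn accessors site name.
#' @export
setGeneric("siteName", function(x) standardGeneric("siteName"))
#' @export
setMethod("siteName", "BindingSiteDefinition", function(x) x@name)
#' @export
setMethod("siteName", "SiteGeometry", function(x) x@siteName)

#' @describeIn accessors residue table (`chain`, `resseq`) of a definition.
#' @export
setGeneric("siteResidues", function(x) standardGeneric("siteResidues"))
#' @export
setMethod("siteResidues", "BindingSiteDefinition", function(x) x@residues)
#' @export
setMethod("siteResidues", "SiteGeometry", function(x) unique(x@residueOrder))

#' @describeIn accessors residues requested but absent from the structure.
#' @export
setGeneric("missingResidues", function(x) standardGeneric("missingResidues"))
#' @export
setMethod("missingResidues", "SiteGeometry", function(x) x@missing)

#' @describeIn accessors grid-box center (3-vector, Angstrom).
#' @export
setGeneric("boxCenter", function(x) standardGeneric("boxCenter"))
#' @export
setMethod("boxCenter", "GridBox", function(x) x@center)

#' @describeIn accessors grid-box per-axis point counts.
#' @export
setGeneric("boxPoints", function(x) standardGeneric("boxPoints"))
#' @export
setMethod("boxPoints", "GridBox", function(x) x@points)

#' @describeIn accessors grid spacing (Angstrom).
#' @export
setGeneric("boxSpacing", function(x) standardGeneric("boxSpacing"))
#' @export
setMethod("boxSpacing", "GridBox", function(x) x@spacing)

#' @describeIn accessors physical per-axis box lengths, spacing * (points - 1).
#' @export
setGeneric("boxLengths", function(x) standardGeneric("boxLengths"))
#' @export
setMethod("boxLengths", "GridBox", function(x) x@spacing * (x@points - 1L))

#' @describeIn accessors score data.frame of a [ScoreTable-class].
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @export
setMethod("scores", "ScoreTable", function(x) x@scores)

#' @describeIn accessors ordered site score column names.
#' @export
setGeneric("siteNames", function(x) standardGeneric("siteNames"))
#' @export
setMethod("siteNames", "ScoreTable", function(x) x@siteNames)

#' @describeIn accessors area under the ROC curve.
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @export
setMethod("auc", "ROCCurve", function(x) x@auc)

#' @describeIn accessors false positive rates.
#' @export
setGeneric("fpr", function(x) standardGeneric("fpr"))
#' @export
setMethod("fpr", "ROCCurve", function(x) x@fpr)

#' @describeIn accessors true positive rates.
#' @export
setGeneric("tpr", function(x) standardGeneric("tpr"))
#' @export
setMethod("tpr", "ROCCurve", function(x) x@tpr)

#' @describeIn accessors thresholds of the ROC curve.
#' @export
setGeneric("rocThresholds", function(x) standardGeneric("rocThresholds"))
#' @export
setMethod("rocThresholds", "ROCCurve", function(x) x@thresholds)

#' @describeIn accessors retained coordinate draws (n x d matrix).
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @export
setMethod("samples", "SampleRun", function(x) x@samples)

#' @describeIn accessors fraction of proposals accepted.
#' @export
setGeneric("acceptanceRate", function(x) standardGeneric("acceptanceRate"))
#' @export
setMethod("acceptanceRate", "SampleRun", function(x) x@acceptanceRate)

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat(sprintf("Structure '%s': %d atoms, %d residues, chains %s\n",
              object@label, nrow(a),
              length(unique(paste(a$chain, a$resseq))),
              paste(unique(a$chain), collapse = ",")))
})

setMethod("show", "PoseBundle", function(object) {
  cat(sprintf("PoseBundle '%s': %d poses x %d atoms, energies [%.2f, %.2f] kcal/mol\n",
              object@ligandId, length(object@coords), nrow(object@atomMeta),
              suppressWarnings(min(object@energies, na.rm = TRUE)),
              suppressWarnings(max(object@energies, na.rm = TRUE))))
})

setMethod("show", "LibraryManifest", function(object) {
  n <- labelCounts(object)
  cat(sprintf("LibraryManifest: %d ligands (%d TP, %d decoy), TP EC50 < %g nM\n",
              n["total"], n["TP"], n["decoy"], object@ec50Threshold))
})

setMethod("show", "BindingSiteDefinition", function(object) {
  cat(sprintf("BindingSiteDefinition '%s': %d residues%s\n",
              object@name, nrow(object@residues),
              if (nzchar(object@provenance)) paste0(" (", object@provenance, ")") else ""))
})

setMethod("show", "SiteGeometry", function(object) {
  cat(sprintf("SiteGeometry '%s': %d reference atoms, %d residues missing\n",
              object@siteName, nrow(object@coords), nrow(object@missing)))
})

setMethod("show", "GridBox", function(object) {
  cat(sprintf(
    "GridBox: center (%.3f, %.3f, %.3f) A, %d x %d x %d points @ %.3f A (padding %.2f A)\n",
    object@center[1], object@center[2], object@center[3],
    object@points[1], object@points[2], object@points[3],
    object@spacing, object@padding))
})

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable: %d ligands, %d snapshot(s), sites: %s\n",
              length(unique(object@scores$ligand_id)),
              length(unique(object@scores$snapshot)),
              paste(object@siteNames, collapse = ", ")))
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve (%s): AUC = %.4f over %d TP / %d decoys, %d thresholds\n",
              object@orientation, object@auc, object@nPos, object@nNeg,
              length(object@thresholds)))
})

setMethod("show", "SampleRun", function(object) {
  cat(sprintf("SampleRun (%s): %d draws of dim %d, acceptance %.3f, seed %d\n",
              object@params$sampler %||% "?", nrow(object@samples),
              ncol(object@samples), object@acceptanceRate, object@seed))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
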