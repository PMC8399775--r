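# ROC/AUC enrichment statistics against TP/decoy labels.

#' ROC curve of a score against TP/decoy labels
#'
#' Builds the receiver operating characteristic of a per-ligand score: TPR
#' versus FPR over a running threshold, with tied scores grouped at a single
#' threshold (so the trapezoidal AUC equals the tie-corrected Mann-Whitney
#' rank statistic). Orientation is explicit and never auto-flipped; the
#' toolkit's uniform convention is `"lower-is-positive"` — for energies and
#' distance scores alike, a lower value predicts a binder — so an
#' anti-informative score is reported with its AUC below 0.5 rather than
#' silently inverted.
#'
#' @param scoreValues named numeric vector, ligand id -> score.
#' @param manifest a [LibraryManifest-class] labeling every scored ligand.
#' @param orientation `"lower-is-positive"` (default) or
#'   `"higher-is-positive"`.
#' @return a [ROCCurve-class].
#' @examples
#' man <- makeManifest(data.frame(ligand_id = c("a", "b", "c", "d"),
#'                                label = c("TP", "TP", "decoy", "decoy")))
#' auc(rocCurve(c(a = 1, b = 2, c = 3, d = 4), man))  # 1: perfect separation
#' @export
rocCurve <- function(scoreValues, manifest,
                     orientation = c("lower-is-positive", "higher-is-positive")) {
  orientation <- match.arg(orientation)
  if (is.null(names(scoreValues))) stop("scoreValues must be named by ligand id", call. = FALSE)
  bad <- names(scoreValues)[is.na(scoreValues)]
  if (length(bad))
    stop("NaN/NA scores for ligand(s): ", paste(bad, collapse = ", "), call. = FALSE)
  e <- manifestEntries(manifest)
  lab <- e$label[match(names(scoreValues), e$ligand_id)]
  if (anyNA(lab))
    stop("unlabeled ligand(s): ",
         paste(names(scoreValues)[is.na(lab)], collapse = ", "), call. = FALSE)
  nPos <- sum(lab == "TP"); nNeg <- sum(lab == "decoy")
  if (nPos < 1L || nNeg < 1L)
    stop("both classes required (", nPos, " TP, ", nNeg, " decoy)", call. = FALSE)

  key <- if (orientation == "lower-is-positive") scoreValues else -scoreValues
  o <- order(key)
  pos <- (lab == "TP")[o]
  ks <- key[o]
  grp_last <- !duplicated(ks, fromLast = TRUE)        # tie groups collapse
  tprv <- c(0, cumsum(pos)[grp_last] / nPos)
  fprv <- c(0, cumsum(!pos)[grp_last] / nNeg)
  thr <- ks[grp_last]
  if (orientation == "higher-is-positive") thr <- -thr
  thr <- c(if (orientation == "lower-is-positive") -Inf else Inf, thr)
  n <- length(fprv)
  aucv <- sum(diff(fprv) * (tprv[-1L] + tprv[-n]) / 2)
  new("ROCCurve", thresholds = unname(thr), fpr = unname(fprv), tpr = unname(tprv),
      auc = aucv, orientation = orientation,
      nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

#' AUC ratio with display truncation
#'
#' The enrichment gain of a rescoring function is reported as the ratio of
#' its AUC to a reference AUC (conventionally the minimum docking energy).
#' Under `rounding = "truncate3"` the quotient is truncated — not rounded —
#' to three decimals, the convention the published benchmark ratios follow;
#' `"none"` returns full precision.
#'
#' @param aucScore AUC of the score under evaluation.
#' @param aucReference reference AUC (> 0).
#' @param rounding `"truncate3"` or `"none"`.
#' @return the (possibly truncated) ratio.
#' @examples
#' aucRatio(0.664, 0.142)  # 4.676
#' @export
aucRatio <- function(aucScore, aucReference, rounding = c("truncate3", "none")) {
  rounding <- match.arg(rounding)
  if (!is.finite(aucReference) || aucReference <= 0)
    stop("reference AUC must be > 0", call. = FALSE)
  q <- aucScore / aucReference
  if (rounding == "none") return(q)
  # epsilon guards quotients that are exact in decimal but sit one ulp low
  floor(q * 1000 + 1e-9) / 1000
}

#' Per-class score distributions over shared bins
#'
#' Histogram densities of a score for the TP and decoy classes on a common
#' set of bin edges, normalized to integrate to 1 within each class — the
#' side-by-side view that shows whether a site score separates binders from
#' decoys before any ROC is drawn.
#'
#' @inheritParams rocCurve
#' @param nBins number of bins (>= 2).
#' @param scoreName label stored in the summary.
#' @return a list with `score_name`, `bin_edges`, `tp_density`,
#'   `decoy_density`, `n_tp`, `n_decoy`.
#' @export
classDistributions <- function(scoreValues, manifest, nBins = 30, scoreName = "score") {
  if (nBins < 2) stop("nBins must be >= 2", call. = FALSE)
  e <- manifestEntries(manifest)
  lab <- e$label[match(names(scoreValues), e$ligand_id)]
  if (anyNA(lab)) stop("unlabeled ligand(s) in scores", call. = FALSE)
  if (length(unique(lab)) < 2L) stop("both classes required", call. = FALSE)
  rng <- range(scoreValues)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  dens <- function(x) {
    h <- graphics::hist(x, breaks = edges, plot = FALSE, include.lowest = TRUE)
    h$density
  }
  list(score_name = scoreName, bin_edges = edges,
       tp_density = dens(scoreValues[lab == "TP"]),
       decoy_density = dens(scoreValues[lab == "decoy"]),
       n_tp = sum(lab == "TP"), n_decoy = sum(lab == "decoy"))
}
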