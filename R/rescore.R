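# Geometric binding-site fitness scoring and ensemble aggregation.

#' Geometric binding-site fitness score of one pose
#'
#' The score of a pose against a binding site is the mean, over the site's
#' reference atoms (by default one alpha carbon per site residue), of the
#' minimum Euclidean distance from that reference atom to any ligand atom:
#' \deqn{s_{BS} = \frac{1}{n}\sum_{i=1}^{n} \min_j \|r_{BS,i} - r_{lig,j}\|}
#' Lower is better: a pose nestled into the site leaves no reference atom
#' far from the ligand. Units are Angstrom. The `"ligand-to-site"` variant
#' averages over ligand atoms the distance to the nearest reference atom
#' instead.
#'
#' @param pose m x 3 matrix of ligand atom coordinates, Angstrom.
#' @param site a [SiteGeometry-class] (or an n x 3 matrix of reference
#'   coordinates).
#' @param direction `"site-to-ligand"` (default, the normative form) or
#'   `"ligand-to-site"`.
#' @return the score in Angstrom (scalar, >= 0).
#' @examples
#' site <- matrix(c(0, 0, 0), 1, 3)
#' scorePose(matrix(c(3, 4, 0), 1, 3), site)  # 5
#' @export
scorePose <- function(pose, site, direction = c("site-to-ligand", "ligand-to-site")) {
  direction <- match.arg(direction)
  S <- if (is(site, "SiteGeometry")) coords(site) else site
  if (!is.matrix(pose)) pose <- matrix(pose, ncol = 3L)
  if (nrow(pose) < 1L || nrow(S) < 1L) stop("empty pose or site", call. = FALSE)
  if (!all(is.finite(pose)) || !all(is.finite(S)))
    stop("non-finite coordinates", call. = FALSE)
  d2 <- outer(rowSums(S^2), rowSums(pose^2), `+`) - 2 * tcrossprod(S, pose)
  d2[d2 < 0] <- 0
  mins <- if (direction == "site-to-ligand") apply(d2, 1L, min) else apply(d2, 2L, min)
  mean(sqrt(mins))
}

#' Score a ligand's pose bundle
#'
#' Computes the energy summaries (`minE`: minimum docking energy over the
#' bundle; `avgE`: mean energy) and the geometric site score per site
#' definition. Under the default `"min-energy-pose"` rule the site scores
#' are evaluated on the single lowest-energy pose (the pose retained for
#' analysis after docking); `"best-score-pose"` takes, per site, the minimum
#' score over all poses; `"all-poses"` returns one row per pose.
#'
#' @param bundle a [PoseBundle-class].
#' @param sites list of [SiteGeometry-class] objects (named, or names taken
#'   from their `siteName`).
#' @param poseRule `"min-energy-pose"`, `"best-score-pose"` or `"all-poses"`.
#' @param direction passed to [scorePose()].
#' @param snapshot snapshot label recorded in the output.
#' @param includeHydrogens if `FALSE`, hydrogen atoms (per the bundle's atom
#'   metadata) are dropped from the ligand atom set before scoring.
#' @return a one-row data.frame (`ligand_id`, `snapshot`,
#'   `pose_index_scored`, `minE`, `avgE`, one column per site), or a
#'   per-pose data.frame under `"all-poses"`.
#' @export
scoreBundle <- function(bundle, sites,
                        poseRule = c("min-energy-pose", "best-score-pose", "all-poses"),
                        direction = c("site-to-ligand", "ligand-to-site"),
                        snapshot = "model", includeHydrogens = TRUE) {
  poseRule <- match.arg(poseRule)
  direction <- match.arg(direction)
  if (is(sites, "SiteGeometry")) sites <- list(sites)
  nm <- names(sites)
  if (is.null(nm) || any(!nzchar(nm)))
    names(sites) <- vapply(sites, siteName, "")
  en <- energies(bundle)
  keep <- rep(TRUE, nAtoms(bundle))
  if (!includeHydrogens) keep <- toupper(atomMeta(bundle)$element) != "H"
  if (!any(keep)) stop("no ligand atoms left after hydrogen exclusion", call. = FALSE)
  pose_k <- function(i) poseCoords(bundle, i)[keep, , drop = FALSE]

  if (poseRule == "all-poses") {
    rows <- lapply(seq_len(nPoses(bundle)), function(i) {
      sc <- vapply(sites, function(s) scorePose(pose_k(i), s, direction), 0)
      cbind(data.frame(ligand_id = ligandId(bundle), snapshot = snapshot,
                       pose_index = i, energy = en[i]),
            as.data.frame(as.list(sc)))
    })
    return(do.call(rbind, rows))
  }

  if (poseRule == "min-energy-pose") {
    if (anyNA(en))
      stop("NaN energies in bundle '", ligandId(bundle),
           "': cannot pick the minimum-energy pose", call. = FALSE)
    i <- which.min(en)
    sc <- vapply(sites, function(s) scorePose(pose_k(i), s, direction), 0)
    idx <- i
  } else {
    per_pose <- vapply(seq_len(nPoses(bundle)), function(i)
      vapply(sites, function(s) scorePose(pose_k(i), s, direction), 0),
      numeric(length(sites)))
    per_pose <- matrix(per_pose, nrow = length(sites))
    sc <- apply(per_pose, 1L, min)
    names(sc) <- names(sites)
    idx <- which.min(per_pose[1L, ])
  }
  minE <- if (all(is.na(en))) NA_real_ else min(en, na.rm = TRUE)
  avgE <- if (all(is.na(en))) NA_real_ else mean(en, na.rm = TRUE)
  cbind(data.frame(ligand_id = ligandId(bundle), snapshot = snapshot,
                   pose_index_scored = idx, minE = minE, avgE = avgE),
        as.data.frame(as.list(sc)))
}

#' Score a whole library against one receptor snapshot
#'
#' Resolves each site definition on the structure and applies
#' [scoreBundle()] to every ligand.
#'
#' @param bundles list of [PoseBundle-class] objects.
#' @param structure a [Structure-class] receptor snapshot.
#' @param definitions list of [BindingSiteDefinition-class] objects.
#' @param atomMode site resolution mode, see [resolveSite()].
#' @inheritParams scoreBundle
#' @return a [ScoreTable-class].
#' @export
scoreLibrary <- function(bundles, structure, definitions,
                         poseRule = c("min-energy-pose", "best-score-pose"),
                         direction = c("site-to-ligand", "ligand-to-site"),
                         atomMode = "CA",
                         snapshot = structureLabel(structure),
                         includeHydrogens = TRUE) {
  poseRule <- match.arg(poseRule)
  direction <- match.arg(direction)
  if (is(definitions, "BindingSiteDefinition")) definitions <- list(definitions)
  geoms <- lapply(definitions, function(d) resolveSite(structure, d, atomMode))
  names(geoms) <- vapply(geoms, siteName, "")
  if (!nzchar(snapshot)) snapshot <- "model"
  rows <- lapply(bundles, scoreBundle, sites = geoms, poseRule = poseRule,
                 direction = direction, snapshot = snapshot,
                 includeHydrogens = includeHydrogens)
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  new("ScoreTable", scores = df, siteNames = names(geoms))
}

#' Aggregate per-snapshot score tables over a receptor ensemble
#'
#' Combines the score tables obtained against each ensemble snapshot into a
#' single per-ligand table. Under the default `rule = "min"` a ligand is
#' judged by its best fit in any sampled receptor conformation (and the
#' `snapshot` column records the snapshot achieving the minimal `minE`);
#' `"mean"` and `"median"` average cell-wise.
#'
#' @param tables list of [ScoreTable-class] objects, one per snapshot, all
#'   over the same ligand set and site names.
#' @param rule `"min"`, `"mean"` or `"median"`.
#' @return a [ScoreTable-class] with one row per ligand.
#' @export
aggregateEnsemble <- function(tables, rule = c("min", "mean", "median")) {
  rule <- match.arg(rule)
  stopifnot(length(tables) >= 1L)
  sn <- siteNames(tables[[1L]])
  ids <- sort(unique(scores(tables[[1L]])$ligand_id))
  for (t in tables[-1L]) {
    if (!identical(siteNames(t), sn)) stop("site-name mismatch across tables", call. = FALSE)
    tids <- sort(unique(scores(t)$ligand_id))
    if (!identical(tids, ids)) {
      d <- c(setdiff(ids, tids), setdiff(tids, ids))
      stop("ligand-set mismatch across tables: ", paste(d, collapse = ", "), call. = FALSE)
    }
  }
  if (length(tables) == 1L) return(tables[[1L]])
  f <- switch(rule, min = min, mean = mean, median = stats::median)
  cols <- c("minE", "avgE", sn)
  mats <- lapply(tables, function(t) {
    s <- scores(t)
    as.matrix(s[match(ids, s$ligand_id), cols, drop = FALSE])
  })
  arr <- simplify2array(mats)                      # ligand x col x snapshot
  agg <- apply(arr, c(1L, 2L), f)
  snap_labels <- vapply(tables, function(t) scores(t)$snapshot[1L], "")
  snap <- if (rule == "min") {
    snap_labels[apply(arr[, "minE", , drop = FALSE], 1L, which.min)]
  } else rep(paste0("ensemble-", rule), length(ids))
  df <- cbind(data.frame(ligand_id = ids, snapshot = snap,
                         pose_index_scored = NA_integer_),
              as.data.frame(agg))
  rownames(df) <- NULL
  new("ScoreTable", scores = df, siteNames = sn)
}

#' Extract one score column as a named vector
#'
#' @param table a [ScoreTable-class].
#' @param column a site name, `"minE"` or `"avgE"`.
#' @return named numeric vector keyed by ligand id.
#' @export
scoreVector <- function(table, column) {
  s <- scores(table)
  if (!column %in% names(s)) stop("no such score column: ", column, call. = FALSE)
  stats::setNames(s[[column]], s$ligand_id)
}
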