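# Binding-site definitions, set algebra, site resolution, grid boxes.

.site_keys <- function(def) paste(def@residues$chain, def@residues$resseq, sep = ":")

.keys_to_residues <- function(keys) {
  if (!length(keys))
    return(data.frame(chain = character(0), resseq = integer(0)))
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(chain = vapply(parts, `[`, "", 1L),
             resseq = as.integer(vapply(parts, `[`, "", 2L)))
}

#' Create a binding-site definition
#'
#' @param name site name.
#' @param resseq integer residue numbers.
#' @param chain chain id(s), recycled along `resseq`.
#' @param provenance free text on where the residue list came from.
#' @return a [BindingSiteDefinition-class].
#' @examples
#' bindingSite("BS1", c(85, 88, 93), chain = "A")
#' @export
bindingSite <- function(name, resseq, chain = "A", provenance = "") {
  new("BindingSiteDefinition", name = name,
      residues = data.frame(chain = rep_len(as.character(chain), length(resseq)),
                            resseq = as.integer(resseq)),
      provenance = provenance)
}

#' Read binding-site definitions from YAML
#'
#' Schema: a top-level `sites:` list whose items carry `name`, `chain`,
#' `residues: [int...]` and optional `source`.
#'
#' @param path YAML path.
#' @return named list of [BindingSiteDefinition-class] objects.
#' @export
readSiteDefinitions <- function(path) {
  y <- yaml::read_yaml(path)
  items <- if (!is.null(y$sites)) y$sites else y
  defs <- lapply(items, function(s) {
    if (is.null(s$name) || is.null(s$residues))
      stop("each site needs 'name' and 'residues'", call. = FALSE)
    bindingSite(s$name, unlist(s$residues), chain = s$chain %||% "A",
                provenance = s$source %||% "")
  })
  names(defs) <- vapply(defs, siteName, "")
  if (anyDuplicated(names(defs))) stop("duplicate site names in ", path, call. = FALSE)
  defs
}

#' Bundled APJR binding-site definitions
#'
#' The apelin-receptor site registry shipped with the package: the pocket
#' interior (BS1), the two exterior acidic patches (BS2, BS3), their union
#' (BStot), the critical residue set (BScritical) and the docking contact
#' list used for grid-box construction. BS1/BS2/BS3/BScritical memberships
#' are approximate (derived from published figure coloring, see the YAML
#' `source` fields) and intended to be edited; the contact list is exact.
#'
#' @return named list of [BindingSiteDefinition-class] objects.
#' @export
apjrSites <- function() {
  defs <- readSiteDefinitions(system.file("extdata", "apjr_sites.yaml",
                                          package = "SiteRescore", mustWork = TRUE))
  defs$BStot <- siteUnion(defs$BS1, defs$BS2, defs$BS3, name = "BStot")
  defs[c("BS1", "BS2", "BS3", "BStot", "BScritical", "contacts")]
}

.site_setop <- function(op, keys, name, provenance) {
  out <- Reduce(op, keys)
  new("BindingSiteDefinition", name = name,
      residues = .keys_to_residues(sort(out)), provenance = provenance)
}

#' Set algebra on binding-site definitions
#'
#' `siteUnion()`, `siteIntersection()` and `siteDifference()` operate on the
#' residue sets; `siteAlgebra()` evaluates a small expression such as
#' `union(BS1, BS2, BS3)` or `intersection(BS1, difference(BStot, BS3))`
#' against a registry of definitions. An empty result is a legal value; it
#' only errors when later resolved against a structure.
#'
#' @param ... two or more [BindingSiteDefinition-class] objects.
#' @param name name of the resulting definition.
#' @return a [BindingSiteDefinition-class].
#' @examples
#' a <- bindingSite("A", 1:5); b <- bindingSite("B", 4:8)
#' siteResidues(siteIntersection(a, b, name = "AB"))$resseq
#' @export
siteUnion <- function(..., name = "union") {
  defs <- list(...)
  .site_setop(union, lapply(defs, .site_keys), name,
              paste("union of", paste(vapply(defs, siteName, ""), collapse = "+")))
}

#' @rdname siteUnion
#' @export
siteIntersection <- function(..., name = "intersection") {
  defs <- list(...)
  .site_setop(intersect, lapply(defs, .site_keys), name,
              paste("intersection of", paste(vapply(defs, siteName, ""), collapse = "&")))
}

#' @rdname siteUnion
#' @param x,y definitions for `siteDifference(x, y)` (residues of `x` not in `y`).
#' @export
siteDifference <- function(x, y, name = "difference") {
  .site_setop(setdiff, list(.site_keys(x), .site_keys(y)), name,
              paste("difference", siteName(x), "-", siteName(y)))
}

#' @rdname siteUnion
#' @param defs named list of registered definitions.
#' @param expression character, e.g. `"union(BS1, BS2)"`; names must be
#'   registered in `defs`.
#' @export
siteAlgebra <- function(defs, expression, name = expression) {
  expr <- str2lang(expression)
  env <- new.env(parent = emptyenv())
  assign("union", function(...) siteUnion(..., name = name), envir = env)
  assign("intersection", function(...) siteIntersection(..., name = name), envir = env)
  assign("difference", function(x, y) siteDifference(x, y, name = name), envir = env)
  check <- function(e) {
    if (is.name(e)) {
      nm <- as.character(e)
      if (!nm %in% names(defs)) stop("unknown site name: ", nm, call. = FALSE)
      assign(nm, defs[[nm]], envir = env)
    } else if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (!op %in% c("union", "intersection", "difference"))
        stop("unsupported operation: ", op, call. = FALSE)
      lapply(as.list(e)[-1L], check)
    } else stop("malformed site expression", call. = FALSE)
    invisible(NULL)
  }
  check(expr)
  out <- eval(expr, env)
  out@name <- name
  out
}

#' Resolve a binding-site definition against a structure
#'
#' Extracts the reference coordinates the geometric score uses: by default
#' the alpha carbon of each definition residue (in definition order), or all
#' heavy atoms under `atomMode = "all-heavy"`. Residues absent from the
#' structure are reported in the geometry's `missing` slot; a residue that
#' is present but lacks a CA is an error.
#'
#' @param structure a [Structure-class].
#' @param definition a [BindingSiteDefinition-class].
#' @param atomMode `"CA"` (default) or `"all-heavy"`.
#' @return a [SiteGeometry-class].
#' @export
resolveSite <- function(structure, definition, atomMode = c("CA", "all-heavy")) {
  atomMode <- match.arg(atomMode)
  res <- siteResidues(definition)
  if (nrow(res) == 0L)
    stop("definition '", siteName(definition), "' is empty", call. = FALSE)
  a <- atoms(structure)
  akey <- paste(a$chain, a$resseq)
  rows <- list(); order_out <- list(); miss <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    sel <- akey == paste(res$chain[i], res$resseq[i])
    if (!any(sel)) { miss[i] <- TRUE; next }
    sub <- a[sel, , drop = FALSE]
    if (atomMode == "CA") {
      sub <- sub[sub$name == "CA", , drop = FALSE]
      if (nrow(sub) == 0L)
        stop(sprintf("residue %s:%d has no CA atom", res$chain[i], res$resseq[i]),
             call. = FALSE)
    } else {
      sub <- sub[toupper(sub$element) != "H", , drop = FALSE]
    }
    rows[[length(rows) + 1L]] <- as.matrix(sub[, c("x", "y", "z")])
    order_out[[length(order_out) + 1L]] <-
      data.frame(chain = rep(res$chain[i], nrow(sub)),
                 resseq = rep(res$resseq[i], nrow(sub)))
  }
  if (!length(rows))
    stop("no residue of '", siteName(definition), "' resolves in the structure",
         call. = FALSE)
  cm <- do.call(rbind, rows)
  dimnames(cm) <- list(NULL, c("x", "y", "z"))
  new("SiteGeometry", siteName = siteName(definition), coords = cm,
      residueOrder = do.call(rbind, order_out),
      missing = res[miss, , drop = FALSE])
}

.ATOMIC_WEIGHTS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                     P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.90,
                     Zn = 65.38, Mg = 24.305, Fe = 55.845, Ca = 40.078, Mn = 54.938,
                     Na = 22.990)

#' Docking grid box from a contact-residue list
#'
#' Builds the maximum confining box of the listed residues: centered at
#' their mass center, with per-axis point counts chosen so the grid spans
#' the residue extent plus `padding` on each side. Points per axis are
#' `2*ceil(h/spacing) + 1` where `h` is the larger center-to-extreme
#' distance plus padding — odd by construction (AutoDock's points =
#' intervals + 1 convention) with a minimum of 3, and guaranteeing that
#' every listed atom lies inside the box with at least `padding` margin.
#'
#' @param structure a [Structure-class].
#' @param definition a [BindingSiteDefinition-class] listing contact residues.
#' @param spacing grid spacing, Angstrom (default 0.375).
#' @param padding extra margin per side, Angstrom (default 0: the confining box).
#' @param massMode `"auto"` weighs atoms by standard atomic weight when
#'   elements are known and falls back to unit masses; `"element"` and
#'   `"unit"` force either.
#' @return a [GridBox-class].
#' @examples
#' s <- makeToyReceptor(seed = 1)
#' computeGridBox(s$structure, s$sites$BS1)
#' @export
computeGridBox <- function(structure, definition, spacing = 0.375, padding = 0,
                           massMode = c("auto", "element", "unit")) {
  massMode <- match.arg(massMode)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  a <- atoms(structure)
  res <- siteResidues(definition)
  if (nrow(res) == 0L) stop("empty residue list", call. = FALSE)
  sel <- paste(a$chain, a$resseq) %in% paste(res$chain, res$resseq)
  if (!any(sel))
    stop("no atom of the residue list '", siteName(definition),
         "' found in the structure", call. = FALSE)
  sub <- a[sel, , drop = FALSE]
  w <- rep(1, nrow(sub))
  if (massMode != "unit") {
    mw <- .ATOMIC_WEIGHTS[sub$element]
    if (massMode == "element" && anyNA(mw))
      stop("unknown element(s): ", paste(unique(sub$element[is.na(mw)]), collapse = ", "),
           call. = FALSE)
    if (!anyNA(mw)) w <- unname(mw)
  }
  cm <- as.matrix(sub[, c("x", "y", "z")])
  center <- colSums(cm * w) / sum(w)
  half <- pmax(apply(cm, 2, max) - center, center - apply(cm, 2, min)) + padding
  pts <- pmax(2L * as.integer(ceiling(half / spacing - 1e-9)) + 1L, 3L)
  new("GridBox", center = unname(center), spacing = spacing,
      points = pts, padding = padding)
}

#' AutoDock GPF-style stanza for a grid box
#'
#' @param box a [GridBox-class].
#' @return character vector of `npts`/`spacing`/`gridcenter` lines.
#' @export
gpfStanza <- function(box) {
  c(sprintf("npts %d %d %d", box@points[1] - 1L, box@points[2] - 1L, box@points[3] - 1L),
    sprintf("spacing %.3f", box@spacing),
    sprintf("gridcenter %.3f %.3f %.3f", box@center[1], box@center[2], box@center[3]))
}

#' Does a grid box contain points with the required margin?
#'
#' @param box a [GridBox-class].
#' @param pts n x 3 matrix, Angstrom.
#' @param margin required margin inside each face (default: the box padding).
#' @return logical vector, one per point.
#' @export
boxContains <- function(box, pts, margin = box@padding) {
  half <- boxLengths(box) / 2
  ok <- rep(TRUE, nrow(pts))
  for (ax in 1:3)
    ok <- ok & abs(pts[, ax] - box@center[ax]) <= half[ax] - margin + 1e-9
  ok
}
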