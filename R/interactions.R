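# Geometric protein-ligand interaction analysis.
#
# Cutoffs follow common structural-biology practice and are all arguments:
# covalent tolerance 0.45 A; pi-stacking 5.5 A with <=30 deg parallel and
# >=60 deg T-shaped interplanar angles; H-bond 3.5 A heavy-atom distance with
# >=120 deg D-H...A angle when the donor hydrogen is explicit; 2.5 A
# single-linkage radius for aromatic pose clusters.

.COVALENT_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                     Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                     I = 1.39, Se = 1.20)

.ring_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2L, ctr))
  normal <- sv$v[, 3L]
  normal <- normal / sqrt(sum(normal^2))
  dev <- max(abs(sweep(xyz, 2L, ctr) %*% normal))
  list(centroid = ctr, normal = normal, max_dev = dev)
}

#' Infer covalent bonds and rings from elements and coordinates
#'
#' Two heavy atoms are bonded when their distance is at most the sum of
#' their covalent radii plus `tolerance`; a hydrogen bonds to the heavy atom
#' within `hMax`. Rings of size 3-7 are perceived from the bond graph and
#' each ring carries its centroid, best-fit-plane unit normal and maximal
#' out-of-plane deviation; a ring is flagged `planar` (aromatic candidate)
#' when that deviation is at most `planarTol`.
#'
#' @param xyz m x 3 coordinate matrix, Angstrom.
#' @param elements character vector of element symbols, one per atom.
#' @param tolerance additive covalent tolerance, Angstrom.
#' @param hMax maximal X-H bond length, Angstrom.
#' @param planarTol maximal out-of-plane deviation of a planar ring, Angstrom.
#' @return a list of class `BondGraph`: `edges` (2-column index matrix,
#'   each bond once), `rings` (list of `atoms`, `centroid`, `normal`,
#'   `max_dev`, `planar`), `elements`, `xyz`.
#' @export
inferBonds <- function(xyz, elements, tolerance = 0.45, hMax = 1.2,
                       planarTol = 0.15) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3L)
  stopifnot(nrow(xyz) == length(elements))
  r <- .COVALENT_RADII[elements]
  if (anyNA(r))
    stop("unknown element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "), call. = FALSE)
  m <- nrow(xyz)
  edges <- matrix(integer(0), ncol = 2L)
  if (m >= 2L) {
    d <- as.matrix(dist(xyz))
    cut <- outer(r, r, `+`) + tolerance
    isH <- elements == "H"
    ok <- d <= cut & upper.tri(d)
    ok[isH, isH] <- FALSE
    hpair <- outer(isH, !isH, `&`) | outer(!isH, isH, `&`)
    ok[hpair & d > hMax] <- FALSE
    edges <- which(ok, arr.ind = TRUE)
    colnames(edges) <- NULL
  }
  rings <- list()
  if (nrow(edges) >= 3L) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < m) g <- igraph::add_vertices(g, m - igraph::vcount(g))
    seen <- character(0)
    for (k in seq_len(nrow(edges))) {
      gk <- igraph::delete_edges(g, igraph::get_edge_ids(g, edges[k, ]))
      sp <- suppressWarnings(
        igraph::shortest_paths(gk, from = edges[k, 1L], to = edges[k, 2L]))
      path <- as.integer(sp$vpath[[1L]])
      if (length(path) >= 3L && length(path) <= 7L) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <- c(seen, key)
          pl <- .ring_plane(xyz[path, , drop = FALSE])
          rings[[length(rings) + 1L]] <- list(
            atoms = path, centroid = pl$centroid, normal = pl$normal,
            max_dev = pl$max_dev, planar = pl$max_dev <= planarTol)
        }
      }
    }
  }
  structure(list(edges = edges, rings = rings, elements = elements, xyz = xyz),
            class = "BondGraph")
}

.AROMATIC_RING_ATOMS <- list(
  PHE = list(benzene = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(benzene = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(imidazole = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(pyrrole = c("CG", "CD1", "NE1", "CE2", "CD2"),
             benzene = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

#' Aromatic side-chain rings of a receptor
#'
#' Collects the ring geometry (centroid, normal) of every PHE/TYR/HIS/TRP
#' side chain; tryptophan contributes its pyrrole and benzene rings
#' separately. Residues with incomplete ring atoms are skipped with a
#' warning.
#'
#' @param structure a [Structure-class].
#' @return data.frame: `chain`, `resseq`, `resname`, `ring`, centroid
#'   `cx,cy,cz`, normal `nx,ny,nz`.
#' @export
receptorAromaticRings <- function(structure) {
  a <- atoms(structure)
  out <- list()
  for (key in unique(paste(a$chain, a$resseq))) {
    sub <- a[paste(a$chain, a$resseq) == key, , drop = FALSE]
    rn <- sub$resname[1L]
    tmpl <- .AROMATIC_RING_ATOMS[[rn]]
    if (is.null(tmpl)) next
    for (ring_name in names(tmpl)) {
      idx <- match(tmpl[[ring_name]], sub$name)
      if (anyNA(idx)) {
        warning(sprintf("%s %s: incomplete %s ring atoms, skipped",
                        rn, key, ring_name), call. = FALSE)
        next
      }
      pl <- .ring_plane(as.matrix(sub[idx, c("x", "y", "z")]))
      out[[length(out) + 1L]] <- data.frame(
        chain = sub$chain[1L], resseq = sub$resseq[1L], resname = rn,
        ring = ring_name, cx = pl$centroid[1L], cy = pl$centroid[2L],
        cz = pl$centroid[3L], nx = pl$normal[1L], ny = pl$normal[2L],
        nz = pl$normal[3L])
    }
  }
  if (!length(out))
    return(data.frame(chain = character(0), resseq = integer(0),
                      resname = character(0), ring = character(0),
                      cx = numeric(0), cy = numeric(0), cz = numeric(0),
                      nx = numeric(0), ny = numeric(0), nz = numeric(0)))
  do.call(rbind, out)
}

.interplanar_angle <- function(n1, n2) {
  cosang <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi     # folded to [0, 90]
}

#' Pi-stacking contacts between ligand rings and receptor aromatics
#'
#' A ligand ring and a receptor aromatic ring are in contact when their
#' centroids are within `dMax` and the interplanar angle (folded to
#' \[0, 90\] degrees) is at most `parallelAngle` (face-to-face,
#' `pi-parallel`) or at least `tshapeAngle` (edge-to-face, `pi-tshaped`).
#' Only planar ligand rings are considered.
#'
#' @param ligandGraph a `BondGraph` from [inferBonds()] on one pose.
#' @param structure the receptor [Structure-class] (or a precomputed
#'   [receptorAromaticRings()] table).
#' @param dMax centroid-centroid cutoff, Angstrom.
#' @param parallelAngle maximal interplanar angle of a parallel stack, deg.
#' @param tshapeAngle minimal interplanar angle of a T-shaped stack, deg.
#' @return data.frame of contacts: `kind`, `ligand_ring`, `chain`,
#'   `resseq`, `resname`, `ring`, `distance`, `angle`.
#' @export
findPiStacks <- function(ligandGraph, structure, dMax = 5.5,
                         parallelAngle = 30, tshapeAngle = 60) {
  rec <- if (is.data.frame(structure)) structure else receptorAromaticRings(structure)
  empty <- data.frame(kind = character(0), ligand_ring = integer(0),
                      chain = character(0), resseq = integer(0),
                      resname = character(0), ring = character(0),
                      distance = numeric(0), angle = numeric(0))
  rings <- Filter(function(r) isTRUE(r$planar), ligandGraph$rings)
  if (!length(rings) || !nrow(rec)) return(empty)
  out <- list()
  for (li in seq_along(rings)) {
    lr <- rings[[li]]
    for (ri in seq_len(nrow(rec))) {
      d <- sqrt(sum((lr$centroid - c(rec$cx[ri], rec$cy[ri], rec$cz[ri]))^2))
      if (d > dMax) next
      ang <- .interplanar_angle(lr$normal, c(rec$nx[ri], rec$ny[ri], rec$nz[ri]))
      kind <- if (ang <= parallelAngle) "pi-parallel"
              else if (ang >= tshapeAngle) "pi-tshaped" else NA_character_
      if (is.na(kind)) next
      out[[length(out) + 1L]] <- data.frame(
        kind = kind, ligand_ring = li, chain = rec$chain[ri],
        resseq = rec$resseq[ri], resname = rec$resname[ri], ring = rec$ring[ri],
        distance = d, angle = ang)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# residue-template donor/acceptor typing; backbone N is a donor (except PRO)
# and backbone O an acceptor for every residue.
.SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"), TRP = "NE1")
.SIDECHAIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  MET = "SD")

.receptor_polar_atoms <- function(structure) {
  a <- atoms(structure)
  don <- a$name == "N" & a$resname != "PRO"
  acc <- a$name == "O"
  for (i in seq_len(nrow(a))) {
    rn <- a$resname[i]
    if (a$name[i] %in% .SIDECHAIN_DONORS[[rn]]) don[i] <- TRUE
    if (a$name[i] %in% .SIDECHAIN_ACCEPTORS[[rn]]) acc[i] <- TRUE
  }
  list(donors = a[don, , drop = FALSE], acceptors = a[acc, , drop = FALSE])
}

.angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Hydrogen-bond contacts between a ligand pose and the receptor
#'
#' Ligand donors are N/O atoms carrying at least one explicit hydrogen in
#' the bond graph; ligand acceptors are all N/O. Receptor typing comes from
#' a built-in residue template (backbone N donor except proline, backbone O
#' acceptor, side chains per amino-acid chemistry). A contact requires a
#' donor-acceptor heavy-atom distance of at most `dMax`; when the donor
#' hydrogen is explicit (the ligand side), the best D-H...A angle must also
#' reach `angleMin`. Receptor hydrogens are typically absent, so
#' receptor-donor contacts are distance-only.
#'
#' @inheritParams findPiStacks
#' @param dMax donor-acceptor heavy-atom cutoff, Angstrom.
#' @param angleMin minimal D-H...A angle when the donor H is explicit, deg.
#' @return data.frame: `kind` (`hbond`), `direction` (`ligand-donor` /
#'   `receptor-donor`), `ligand_atom`, `chain`, `resseq`, `receptor_atom`,
#'   `distance`, `angle` (NA when no explicit donor H).
#' @export
findHBonds <- function(ligandGraph, structure, dMax = 3.5, angleMin = 120) {
  pol <- .receptor_polar_atoms(structure)
  el <- ligandGraph$elements
  xyz <- ligandGraph$xyz
  edges <- ligandGraph$edges
  adjH <- lapply(seq_along(el), function(i) {
    nb <- c(edges[edges[, 1L] == i, 2L], edges[edges[, 2L] == i, 1L])
    nb[el[nb] == "H"]
  })
  lig_polar <- which(el %in% c("N", "O"))
  out <- list()
  add <- function(direction, lig_atom, rec_row, d, ang) {
    out[[length(out) + 1L]] <<- data.frame(
      kind = "hbond", direction = direction, ligand_atom = lig_atom,
      chain = rec_row$chain, resseq = rec_row$resseq,
      receptor_atom = rec_row$name, distance = d, angle = ang)
  }
  for (i in lig_polar) {
    hs <- adjH[[i]]
    # ligand as donor (needs an explicit H) against receptor acceptors
    if (length(hs)) {
      for (j in seq_len(nrow(pol$acceptors))) {
        acc <- pol$acceptors[j, ]
        av <- c(acc$x, acc$y, acc$z)
        d <- sqrt(sum((xyz[i, ] - av)^2))
        if (d > dMax) next
        ang <- max(vapply(hs, function(h) .angle_deg(xyz[i, ], xyz[h, ], av), 0))
        if (ang < angleMin) next
        add("ligand-donor", i, acc, d, ang)
      }
    }
    # ligand as acceptor against receptor donors (no explicit receptor H)
    for (j in seq_len(nrow(pol$donors))) {
      don <- pol$donors[j, ]
      d <- sqrt(sum((xyz[i, ] - c(don$x, don$y, don$z))^2))
      if (d > dMax) next
      add("receptor-donor", i, don, d, NA_real_)
    }
  }
  if (!length(out))
    return(data.frame(kind = character(0), direction = character(0),
                      ligand_atom = integer(0), chain = character(0),
                      resseq = integer(0), receptor_atom = character(0),
                      distance = numeric(0), angle = numeric(0)))
  do.call(rbind, out)
}

#' Single-linkage clustering of aromatic ring centroids
#'
#' Clusters ring centroids collected across ligands and poses at the given
#' radius (single linkage: clusters merge whenever any two members come
#' within `radius`), the numeric counterpart of spotting aromatic
#' substructure hot-spots in a pose bundle by eye.
#'
#' @param centroids data.frame with columns `x`, `y`, `z` plus any member
#'   identity columns (e.g. `ligand_id`, `pose_index`, `ring`).
#' @param radius merge radius, Angstrom.
#' @return list with `assignments` (the input plus a `cluster` column;
#'   cluster 1 is the largest) and `clusters` (per-cluster size and mean
#'   centroid).
#' @export
clusterRingCentroids <- function(centroids, radius = 2.5) {
  if (nrow(centroids) == 0L)
    return(list(assignments = cbind(centroids, cluster = integer(0)),
                clusters = data.frame(cluster = integer(0), size = integer(0),
                                      cx = numeric(0), cy = numeric(0), cz = numeric(0))))
  xyz <- as.matrix(centroids[, c("x", "y", "z")])
  cl <- if (nrow(xyz) == 1L) 1L else {
    cutree(hclust(dist(xyz), method = "single"), h = radius)
  }
  sizes <- sort(table(cl), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- unname(remap[as.character(cl)])
  cdf <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    sel <- cl == k
    data.frame(cluster = k, size = sum(sel), cx = mean(xyz[sel, 1L]),
               cy = mean(xyz[sel, 2L]), cz = mean(xyz[sel, 3L]))
  }))
  list(assignments = cbind(centroids, cluster = cl), clusters = cdf)
}

#' Per-residue contact frequency over a library
#'
#' Fraction of ligands making at least one contact of each kind with each
#' receptor residue, split by TP/decoy label.
#'
#' @param contactsByLigand named list, ligand id -> contact data.frame (as
#'   returned by [findHBonds()] / [findPiStacks()]; pi tables are keyed by
#'   `kind`, `chain`, `resseq` like the H-bond table).
#' @param manifest a [LibraryManifest-class].
#' @return data.frame: `chain`, `resseq`, `kind`, `frac_all`, `frac_tp`,
#'   `frac_decoy`.
#' @export
contactFrequency <- function(contactsByLigand, manifest) {
  e <- manifestEntries(manifest)
  ids <- names(contactsByLigand)
  lab <- e$label[match(ids, e$ligand_id)]
  if (anyNA(lab)) stop("unlabeled ligand(s) in contact list", call. = FALSE)
  seen <- list()
  for (i in seq_along(ids)) {
    cdf <- contactsByLigand[[i]]
    if (is.null(cdf) || nrow(cdf) == 0L) next
    u <- unique(cdf[, c("chain", "resseq", "kind")])
    u$ligand_id <- ids[i]
    seen[[length(seen) + 1L]] <- u
  }
  if (!length(seen))
    return(data.frame(chain = character(0), resseq = integer(0),
                      kind = character(0), frac_all = numeric(0),
                      frac_tp = numeric(0), frac_decoy = numeric(0)))
  all_u <- do.call(rbind, seen)
  keys <- unique(all_u[, c("chain", "resseq", "kind")])
  n_tp <- sum(lab == "TP"); n_dec <- sum(lab == "decoy")
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- all_u$chain == keys$chain[k] & all_u$resseq == keys$resseq[k] &
      all_u$kind == keys$kind[k]
    who <- unique(all_u$ligand_id[sel])
    wlab <- lab[match(who, ids)]
    data.frame(chain = keys$chain[k], resseq = keys$resseq[k], kind = keys$kind[k],
               frac_all = length(who) / length(ids),
               frac_tp = if (n_tp) sum(wlab == "TP") / n_tp else NA_real_,
               frac_decoy = if (n_dec) sum(wlab == "decoy") / n_dec else NA_real_)
  })
  out <- do.call(rbind, rows)
  out[order(out$resseq, out$kind), ]
}
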