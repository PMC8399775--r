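# Synthetic benchmark generator: a toy 7-helix receptor with labeled binding
# sites, ligand pose bundles with known placement, and independent oracles
# for the enrichment results the pipeline should recover.
#
# Ligand "molecules" are labeled point clouds with element tags (and optional
# planted hexagonal rings so the interaction detectors have substrate); no
# chemical validity is claimed — the geometric score and the detectors
# consume geometry only.

.unit <- function(v) v / sqrt(sum(v^2))

.hexagon <- function(center, normal, radius = 1.39) {
  n <- .unit(normal)
  ref <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(pracma_cross(n, ref)); v <- pracma_cross(n, u)
  t(vapply(0:5, function(k) {
    th <- k * pi / 3
    center + radius * (cos(th) * u + sin(th) * v)
  }, numeric(3)))
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Build the toy 7-helix receptor and its binding-site registry
#'
#' Constructs a deterministic (given `seed`) GPCR-like fold: seven idealized
#' CA-trace helices on a circle enclosing a central pocket, backbone N/C/O
#' and a CB dummy per residue, aromatic side-chain rings (PHE/TRP) lining
#' the pocket so the interaction detectors have receptor rings, and acidic
#' rim residues above the pocket mouth. Three disjoint labeled sites ship
#' with it: `BS1` (pocket interior), `BS2` and `BS3` (rim patches outside
#' the mouth plane), plus their union `BStot`.
#'
#' @param seed integer; a small coordinate jitter (sigma 0.15 A) makes
#'   distinct seeds give distinct receptors while the same seed reproduces
#'   coordinates exactly.
#' @return list: `structure` ([Structure-class]), `sites` (named list of
#'   [BindingSiteDefinition-class]: BS1, BS2, BS3, BStot), `params`
#'   (`mouth_z`, `bundle_radius`, `bs1_centroid`).
#' @export
makeToyReceptor <- function(seed = 1) {
  set.seed(as.integer(seed))
  nHelix <- 7L; nRes <- 28L; R <- 11; rise <- 1.5; caR <- 2.3
  rows <- list(); serial <- 0L
  aromatic_rows <- c(23L, 25L)
  add <- function(name, element, resname, resseq, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = element, resname = resname,
      resseq = resseq, chain = "A", x = xyz[1L], y = xyz[2L], z = xyz[3L])
  }
  for (h in 0:(nHelix - 1L)) {
    th <- 2 * pi * h / nHelix
    axis <- c(R * cos(th), R * sin(th), 0)
    for (r in 1:nRes) {
      resseq <- h * nRes + r
      phase <- (100 * r) * pi / 180 + th
      radial <- c(cos(phase), sin(phase), 0)
      ca <- axis + caR * radial + c(0, 0, rise * r)
      tangent <- c(-sin(phase), cos(phase), 0)
      inward <- .unit(-ca * c(1, 1, 0))            # toward the bundle axis
      aromatic <- r %in% aromatic_rows && sum(inward * radial) > 0
      resname <- if (aromatic) "PHE" else "ALA"
      add("N", "N", resname, resseq, ca - 0.8 * tangent - c(0, 0, 0.6))
      add("CA", "C", resname, resseq, ca)
      add("C", "C", resname, resseq, ca + 0.9 * tangent + c(0, 0, 0.5))
      add("O", "O", resname, resseq, ca + 1.2 * tangent + c(0, 0, 1.4))
      add("CB", "C", resname, resseq, ca + 1.5 * inward)
      if (aromatic) {
        ringc <- ca + 3.4 * inward
        hx <- .hexagon(ringc, normal = tangent)
        ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
        for (k in 1:6) add(ring_names[k], "C", resname, resseq, hx[k, ])
      }
    }
  }
  mouth_z <- rise * nRes                           # top of the helices
  # acidic rim residues above the mouth plane: BS2 one side, BS3 the other
  rimR <- 13; rim_z <- mouth_z + 4
  rim_start <- nHelix * nRes
  for (k in 1:10) {
    resseq <- rim_start + k
    th <- pi * (k - 0.5) / 5                       # k<=5 one half, k>5 other
    pos <- c(rimR * cos(th), rimR * sin(th), rim_z)
    resname <- if (k %% 2L) "GLU" else "ASP"
    add("N", "N", resname, resseq, pos + c(-0.8, 0, -0.5))
    add("CA", "C", resname, resseq, pos)
    add("C", "C", resname, resseq, pos + c(0.9, 0, 0.4))
    add("O", "O", resname, resseq, pos + c(1.2, 0, 1.4))
    add("CB", "C", resname, resseq, pos + c(0, 0.9, 1.2))
  }
  df <- do.call(rbind, rows)
  jit <- matrix(stats::rnorm(3L * nrow(df), 0, 0.15), ncol = 3L)
  df$x <- df$x + jit[, 1L]; df$y <- df$y + jit[, 2L]; df$z <- df$z + jit[, 3L]
  structure_ <- new("Structure", atoms = df, label = sprintf("toy-receptor-%d", seed))

  bs1_res <- as.integer(outer(c(23L, 25L), (0:(nHelix - 1L)) * nRes, `+`))
  sites <- list(
    BS1 = bindingSite("BS1", sort(bs1_res), provenance = "toy pocket interior"),
    BS2 = bindingSite("BS2", rim_start + 1:5, provenance = "toy rim patch"),
    BS3 = bindingSite("BS3", rim_start + 6:10, provenance = "toy rim patch"))
  sites$BStot <- siteUnion(sites$BS1, sites$BS2, sites$BS3, name = "BStot")
  bs1_geo <- resolveSite(structure_, sites$BS1)
  list(structure = structure_, sites = sites,
       params = list(mouth_z = mouth_z, bundle_radius = R + caR,
                     bs1_centroid = colMeans(coords(bs1_geo))))
}

# independent oracles, deliberately naive: plain double loops / pairwise
# comparisons, never the vectorized pipeline code they validate
.naive_sbs <- function(site_xyz, lig_xyz) {
  tot <- 0
  for (i in seq_len(nrow(site_xyz))) {
    best <- Inf
    for (j in seq_len(nrow(lig_xyz))) {
      d <- sqrt(sum((site_xyz[i, ] - lig_xyz[j, ])^2))
      if (d < best) best <- d
    }
    tot <- tot + best
  }
  tot / nrow(site_xyz)
}

.rank_auc <- function(pos, neg, lowerIsPositive = TRUE) {
  if (!lowerIsPositive) { pos <- -pos; neg <- -neg }
  cmp <- outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

#' Generate a synthetic TP/decoy docking library
#'
#' Emulates the structure of a screening benchmark in which true positives
#' preferentially occupy one binding site while decoys do not, and docking
#' energies carry no class signal. Each true positive's minimum-energy pose
#' is a compact atom cloud centered on the BS1 centroid plus isotropic
#' Gaussian noise of scale `tpSigma`; its remaining poses, and all decoy
#' poses, are placed per `decoyModel`: `"uniform-box"` scatters them
#' uniformly in the confining grid box of all three sites, `"shifted-site"`
#' centers them on the BS1 centroid displaced by `shift` Angstrom (shift 0
#' is the null construction with indistinguishable classes). Energies are
#' N(-6, 1.5) kcal/mol independent of label under `"uninformative"`;
#' `"anti-informative"` worsens TP energies by half a standard deviation,
#' reproducing the qualitative finding that the raw docking energy can rank
#' binders below decoys.
#'
#' @param receptor result of [makeToyReceptor()].
#' @param nTp,nDecoy class sizes.
#' @param tpSigma Gaussian placement noise of the planted TP pose, Angstrom.
#' @param decoyModel `"uniform-box"` or `"shifted-site"`.
#' @param energyModel `"uninformative"` or `"anti-informative"`.
#' @param posesPerLigand poses per bundle.
#' @param atomsPerLigand inclusive range the per-ligand atom count is drawn
#'   from.
#' @param withRings plant a planar hexagonal carbon ring in every ligand so
#'   interaction analysis has aromatic substrate.
#' @param shift displacement (Angstrom) of the `"shifted-site"` decoy center.
#' @param seed integer seed; the full library is deterministic given it.
#' @return list: `bundles` (named list of [PoseBundle-class]), `manifest`
#'   ([LibraryManifest-class]), `groundTruth` (list with `table` — per
#'   ligand label, planted pose index, oracle BS1 score of the min-energy
#'   pose, minE — and `params`).
#' @export
makeLibrary <- function(receptor, nTp = 50L, nDecoy = 400L, tpSigma = 3,
                        decoyModel = c("uniform-box", "shifted-site"),
                        energyModel = c("uninformative", "anti-informative"),
                        posesPerLigand = 10L, atomsPerLigand = c(8L, 16L),
                        withRings = FALSE, shift = 8, seed = 1) {
  decoyModel <- match.arg(decoyModel)
  energyModel <- match.arg(energyModel)
  stopifnot(nTp >= 1L, nDecoy >= 1L, tpSigma > 0, posesPerLigand >= 1L)
  set.seed(as.integer(seed))
  box <- computeGridBox(receptor$structure, receptor$sites$BStot,
                        spacing = 0.375, padding = 2)
  half <- boxLengths(box) / 2
  bs1c <- receptor$params$bs1_centroid
  bs1_xyz <- coords(resolveSite(receptor$structure, receptor$sites$BS1))
  ids <- c(sprintf("tp%03d", seq_len(nTp)), sprintf("dec%04d", seq_len(nDecoy)))
  labels <- c(rep("TP", nTp), rep("decoy", nDecoy))

  rand_center <- function() {
    if (decoyModel == "uniform-box")
      boxCenter(box) + stats::runif(3L, -1, 1) * half
    else
      bs1c + c(shift, 0, 0) + stats::rnorm(3L, 0, tpSigma)
  }
  cloud <- function(center, m, ring) {
    pts <- sweep(matrix(stats::rnorm(3L * m, 0, 1.2), ncol = 3L), 2L, center, `+`)
    if (ring) {
      hx <- .hexagon(center, normal = .unit(stats::rnorm(3L)))
      pts <- rbind(pts, hx)
    }
    pts
  }

  bundles <- vector("list", length(ids)); names(bundles) <- ids
  gt <- vector("list", length(ids))
  for (g in seq_along(ids)) {
    m <- sample(atomsPerLigand[1L]:atomsPerLigand[2L], 1L)
    el <- sample(c("C", "N", "O"), m, replace = TRUE, prob = c(0.7, 0.15, 0.15))
    if (withRings) el <- c(el, rep("C", 6L))
    en <- stats::rnorm(posesPerLigand, -6, 1.5)
    if (energyModel == "anti-informative" && labels[g] == "TP") en <- en + 0.75
    planted <- NA_integer_
    coords_l <- vector("list", posesPerLigand)
    if (labels[g] == "TP") {
      planted <- which.min(en)
      for (p in seq_len(posesPerLigand)) {
        ctr <- if (p == planted) bs1c + stats::rnorm(3L, 0, tpSigma) else rand_center()
        coords_l[[p]] <- cloud(ctr, m, withRings)
      }
    } else {
      for (p in seq_len(posesPerLigand)) coords_l[[p]] <- cloud(rand_center(), m, withRings)
    }
    meta <- data.frame(name = sprintf("%s%d", el, seq_along(el)), element = el)
    bundles[[g]] <- new("PoseBundle", ligandId = ids[g], coords = coords_l,
                        energies = en, atomMeta = meta)
    imin <- which.min(en)
    gt[[g]] <- data.frame(
      ligand_id = ids[g], label = labels[g], planted_pose = planted,
      minE = min(en),
      bs1_score = .naive_sbs(bs1_xyz, coords_l[[imin]]))
  }
  ec50 <- ifelse(labels == "TP", round(10^stats::runif(length(ids), -2, -0.05), 4),
                 NA_real_)
  manifest <- makeManifest(data.frame(ligand_id = ids, label = labels,
                                      ec50_nM = ec50))
  list(bundles = bundles, manifest = manifest,
       groundTruth = list(
         table = do.call(rbind, gt),
         params = list(n_tp = nTp, n_decoy = nDecoy, tp_sigma = tpSigma,
                       decoy_model = decoyModel, energy_model = energyModel,
                       poses_per_ligand = posesPerLigand, shift = shift,
                       seed = seed)))
}

#' Expected AUC oracle for a generated library
#'
#' Computes, from the generator's own ground-truth record and independently
#' of the scoring pipeline, the empirical AUC of the true generated scores
#' by the pairwise rank statistic (probability a TP scores below a decoy,
#' ties counted half), with a seeded bootstrap 95% confidence interval.
#'
#' @param groundTruth the `groundTruth` element of [makeLibrary()]'s result.
#' @param score `"bs1"` (oracle geometric score) or `"minE"`.
#' @param nBoot bootstrap replicates.
#' @param seed bootstrap seed.
#' @return list `auc`, `ci` (2-vector), `n_pos`, `n_neg`.
#' @export
expectedAuc <- function(groundTruth, score = c("bs1", "minE"), nBoot = 2000L,
                        seed = 1) {
  score <- match.arg(score)
  tab <- groundTruth$table
  if (is.null(tab)) stop("ground-truth record has no table", call. = FALSE)
  col <- if (score == "bs1") "bs1_score" else "minE"
  pos <- tab[[col]][tab$label == "TP"]
  neg <- tab[[col]][tab$label == "decoy"]
  point <- .rank_auc(pos, neg)
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(nBoot), function(b)
    .rank_auc(sample(pos, replace = TRUE), sample(neg, replace = TRUE)), 0)
  list(auc = point,
       ci = unname(stats::quantile(boot, c(0.025, 0.975))),
       n_pos = length(pos), n_neg = length(neg))
}

#' Write a generated library to disk
#'
#' Writes the receptor as PDB, one JSON pose table per ligand under
#' `poses/`, the manifest CSV and the ground truth JSON — the plain-text
#' fixture layout every reader in the toolkit consumes.
#'
#' @param receptor result of [makeToyReceptor()].
#' @param library result of [makeLibrary()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeLibrary <- function(receptor, library, dir) {
  dir.create(file.path(dir, "poses"), recursive = TRUE, showWarnings = FALSE)
  writeStructure(receptor$structure, file.path(dir, "receptor.pdb"))
  for (b in library$bundles)
    writePoseBundle(b, file.path(dir, "poses", paste0(ligandId(b), ".json")))
  writeManifest(library$manifest, file.path(dir, "manifest.csv"))
  jsonlite::write_json(
    list(table = library$groundTruth$table, params = library$groundTruth$params),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null", dataframe = "rows")
  invisible(dir)
}
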