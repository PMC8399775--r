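test_that("bond inference recovers benzene connectivity, planarity and normals", {
  hx <- hexagon_xyz(normal = c(0, 0, 1))
  g <- inferBonds(hx, rep("C", 6))
  expect_equal(nrow(g$edges), 6L)
  expect_length(g$rings, 1L)
  expect_true(g$rings[[1]]$planar)
  expect_equal(abs(sum(g$rings[[1]]$normal * c(0, 0, 1))), 1, tolerance = 1e-9)
  expect_equal(unname(g$rings[[1]]$centroid), c(0, 0, 0), tolerance = 1e-9)

  far <- inferBonds(matrix(c(0, 0, 0, 5, 0, 0), ncol = 3, byrow = TRUE), c("C", "C"))
  expect_equal(nrow(far$edges), 0L)
  expect_length(far$rings, 0L)
  expect_error(inferBonds(hx, rep("Xx", 6)), "unknown element")
})

test_that("a cyclohexane chair is perceived as a ring but flagged non-planar", {
  chair <- t(sapply(0:5, function(k)
    c(1.47 * cos(k * pi / 3), 1.47 * sin(k * pi / 3), 0.25 * (-1)^k)))
  g <- inferBonds(chair, rep("C", 6))
  expect_length(g$rings, 1L)
  expect_false(g$rings[[1]]$planar)
  expect_gt(g$rings[[1]]$max_dev, 0.15)
})

test_that("hydrogens bond only to a heavy atom within the X-H cutoff", {
  xyz <- matrix(c(0, 0, 0,   1.0, 0, 0,   3, 0, 0), ncol = 3, byrow = TRUE)
  g <- inferBonds(xyz, c("N", "H", "H"))
  expect_equal(nrow(g$edges), 1L)             # only the 1.0 A N-H pair
  expect_setequal(as.integer(g$edges[1, ]), c(1L, 2L))
})

test_that("pi-stacking detection classifies parallel and T-shaped ring pairs", {
  rec_ring <- hexagon_xyz(center = c(0, 0, 0), normal = c(0, 0, 1))
  rec <- phe_structure(rec_ring)

  lig_par <- inferBonds(hexagon_xyz(center = c(0, 0, 3.8), normal = c(0, 0, 1)),
                        rep("C", 6))
  hits <- findPiStacks(lig_par, rec)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$kind, "pi-parallel")
  expect_equal(hits$distance, 3.8, tolerance = 1e-6)
  expect_equal(hits$resseq, 10L)

  lig_far <- inferBonds(hexagon_xyz(center = c(0, 0, 8), normal = c(0, 0, 1)),
                        rep("C", 6))
  expect_equal(nrow(findPiStacks(lig_far, rec)), 0L)

  lig_perp <- inferBonds(hexagon_xyz(center = c(0, 0, 5), normal = c(1, 0, 0)),
                         rep("C", 6))
  t_hit <- findPiStacks(lig_perp, rec)
  expect_equal(t_hit$kind, "pi-tshaped")
  expect_equal(t_hit$angle, 90, tolerance = 1e-6)

  # a receptor aromatic with missing ring atoms is skipped with a warning
  broken <- rec
  broken@atoms <- broken@atoms[broken@atoms$name != "CZ", ]
  expect_warning(rings <- receptorAromaticRings(broken), "incomplete")
  expect_equal(nrow(rings), 0L)
})

test_that("hydrogen-bond geometry gates on distance and D-H...A angle", {
  # receptor backbone O acceptor at origin; ligand N donor with H pointing at it
  rec <- new("Structure", atoms = data.frame(
    serial = 1:2, name = c("CA", "O"), element = c("C", "O"), resname = "ALA",
    resseq = 7L, chain = "A", x = c(2, 0), y = c(5, 0), z = c(0, 0)))
  lig_colinear <- inferBonds(
    matrix(c(0, 0, 2.9,   0, 0, 1.9), ncol = 3, byrow = TRUE), c("N", "H"))
  hb <- findHBonds(lig_colinear, rec)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$direction, "ligand-donor")
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)

  lig_far <- inferBonds(
    matrix(c(0, 0, 4.2,   0, 0, 3.2), ncol = 3, byrow = TRUE), c("N", "H"))
  expect_equal(nrow(findHBonds(lig_far, rec)), 0L)

  # same distance but the hydrogen points sideways: D-H...A = 90 degrees
  lig_bent <- inferBonds(
    matrix(c(0, 0, 2.9,   1.0, 0, 2.9), ncol = 3, byrow = TRUE), c("N", "H"))
  expect_equal(nrow(findHBonds(lig_bent, rec)), 0L)

  # receptor-side donors are distance-only (no explicit receptor hydrogens)
  rec_don <- new("Structure", atoms = data.frame(
    serial = 1:2, name = c("CA", "NZ"), element = c("C", "N"), resname = "LYS",
    resseq = 8L, chain = "A", x = c(5, 0), y = c(5, 0), z = c(0, 3.0)))
  lig_acc <- inferBonds(matrix(c(0, 0, 0), 1, 3), "O")
  hb2 <- findHBonds(lig_acc, rec_don)
  expect_equal(hb2$direction, "receptor-donor")
  expect_true(is.na(hb2$angle))
})

test_that("interaction detectors are invariant under joint rigid transforms", {
  set.seed(33)
  rec_ring <- hexagon_xyz(center = c(1, 2, 0), normal = c(0, 0, 1))
  rec <- phe_structure(rec_ring)
  lig_xyz <- rbind(hexagon_xyz(center = c(1, 2, 4.0), normal = c(0.2, 0, 1)),
                   c(1, 2, 6.5), c(1, 2, 7.5))
  lig_el <- c(rep("C", 6), "N", "H")
  base_pi <- findPiStacks(inferBonds(lig_xyz, lig_el), rec)
  base_hb <- findHBonds(inferBonds(lig_xyz, lig_el), rec)
  for (rep in 1:10) {
    R <- random_rotation(); t <- rnorm(3, sd = 30)
    xf <- function(m) sweep(m %*% t(R), 2, t, `+`)
    rec2 <- rec
    rec2@atoms[, c("x", "y", "z")] <- xf(as.matrix(rec@atoms[, c("x", "y", "z")]))
    g2 <- inferBonds(xf(lig_xyz), lig_el)
    pi2 <- findPiStacks(g2, rec2)
    hb2 <- findHBonds(g2, rec2)
    expect_equal(pi2$kind, base_pi$kind)
    expect_equal(pi2$distance, base_pi$distance, tolerance = 1e-9)
    expect_equal(pi2$angle, base_pi$angle, tolerance = 1e-6)
    expect_equal(hb2$distance, base_hb$distance, tolerance = 1e-9)
  }
})

test_that("centroid clustering merges blobs, respects limits and radius monotonicity", {
  set.seed(44)
  blob <- function(center, n) data.frame(
    ligand_id = "L", pose_index = seq_len(n), ring = 1L,
    x = rnorm(n, center[1], 0.3), y = rnorm(n, center[2], 0.3),
    z = rnorm(n, center[3], 0.3))
  two <- rbind(blob(c(0, 0, 0), 20), blob(c(10, 0, 0), 20))
  cl <- clusterRingCentroids(two, radius = 2.5)
  expect_equal(nrow(cl$clusters), 2L)
  expect_equal(sort(cl$clusters$size), c(20L, 20L))

  single <- clusterRingCentroids(two[1, ], radius = 2.5)
  expect_equal(nrow(single$clusters), 1L)
  expect_equal(single$clusters$size, 1L)

  all_one <- clusterRingCentroids(two, radius = 1e6)
  expect_equal(nrow(all_one$clusters), 1L)
  expect_equal(all_one$clusters$size, 40L)

  # growing the radius never increases the cluster count
  pts <- data.frame(x = rnorm(60, sd = 4), y = rnorm(60, sd = 4), z = rnorm(60, sd = 4))
  radii <- c(0.5, 1, 2, 4, 8)
  counts <- sapply(radii, function(r) nrow(clusterRingCentroids(pts, r)$clusters))
  expect_true(all(diff(counts) <= 0))
})

test_that("contact frequencies count ligands once per residue/kind and recover a planted rate", {
  man <- makeManifest(data.frame(ligand_id = sprintf("L%03d", 1:10),
                                 label = rep(c("TP", "decoy"), 5)))
  hb_row <- function(resseq) data.frame(
    kind = "hbond", direction = "ligand-donor", ligand_atom = 1L, chain = "A",
    resseq = resseq, receptor_atom = "O", distance = 2.9, angle = 150)
  contacts <- setNames(lapply(1:10, function(i) rbind(hb_row(264L), hb_row(264L))),
                       sprintf("L%03d", 1:10))
  freq <- contactFrequency(contacts, man)
  expect_equal(freq$frac_all[freq$resseq == 264], 1.0)   # duplicates count once

  # a residue nobody contacts never appears; planted 60% rate is recovered
  set.seed(55)
  n <- 200
  man2 <- makeManifest(data.frame(ligand_id = sprintf("M%03d", 1:n),
                                  label = rep("TP", n)))
  hit <- runif(n) < 0.6
  contacts2 <- setNames(lapply(seq_len(n), function(i)
    if (hit[i]) hb_row(5L) else hb_row(9L)[0, ]), sprintf("M%03d", 1:n))
  freq2 <- contactFrequency(contacts2, man2)
  se3 <- 3 * sqrt(0.6 * 0.4 / n)
  expect_lt(abs(freq2$frac_all[freq2$resseq == 5] - 0.6), se3)
  expect_false(9L %in% freq2$resseq)
})

test_that("the toy receptor provides complete aromatic rings for stacking analysis", {
  r <- makeToyReceptor(seed = 2)
  rings <- receptorAromaticRings(r$structure)
  expect_gt(nrow(rings), 3)
  expect_true(all(rings$resname == "PHE"))
  nrm <- sqrt(rings$nx^2 + rings$ny^2 + rings$nz^2)
  expect_equal(nrm, rep(1, nrow(rings)), tolerance = 1e-9)
})
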