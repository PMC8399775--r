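# Independent oracles used across the suite. Deliberately naive code paths
# (double loops, pairwise comparisons) so they share nothing with the
# vectorized implementations they validate.

brute_sbs <- function(site_xyz, lig_xyz, direction = "site-to-ligand") {
  if (direction == "ligand-to-site") {
    tmp <- site_xyz; site_xyz <- lig_xyz; lig_xyz <- tmp
  }
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

# tie-corrected Mann-Whitney AUC: P(pos < neg) + 0.5 P(pos == neg)
mw_auc <- function(pos, neg, lower_is_positive = TRUE) {
  if (!lower_is_positive) { pos <- -pos; neg <- -neg }
  mean(outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b)))
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# fixed-column ATOM line for handcrafted fixtures
atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                      element = "", extra = "") {
  base <- sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                  serial, name, resname, chain, resseq, x, y, z)
  if (nzchar(extra)) paste0(base, extra)
  else if (nzchar(element)) sprintf("%s          %2s", base, element)
  else base
}

# minimal CA-only structure from a residue -> coords map
ca_structure <- function(xyz, resseq = seq_len(nrow(xyz)), chain = "A",
                         label = "toy") {
  new("Structure",
      atoms = data.frame(serial = seq_len(nrow(xyz)), name = "CA",
                         element = "C", resname = "ALA", resseq = resseq,
                         chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
      label = label)
}

# regular hexagon with C-C 1.39 A in the plane through `center` with `normal`
hexagon_xyz <- function(center = c(0, 0, 0), normal = c(0, 0, 1), radius = 1.39) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(n[2] * ref[3] - n[3] * ref[2], n[3] * ref[1] - n[1] * ref[3],
         n[1] * ref[2] - n[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  t(sapply(0:5, function(k) center + radius * (cos(k * pi / 3) * u + sin(k * pi / 3) * v)))
}

# one-PHE receptor whose side-chain ring is the given hexagon
phe_structure <- function(ring_xyz, resseq = 10L) {
  nm <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  atoms <- data.frame(serial = 1:8, name = c("N", "CA", nm),
                      element = c("N", "C", rep("C", 6)), resname = "PHE",
                      resseq = resseq, chain = "A",
                      x = c(ring_xyz[1, 1] + 8, ring_xyz[1, 1] + 6, ring_xyz[, 1]),
                      y = c(ring_xyz[1, 2], ring_xyz[1, 2], ring_xyz[, 2]),
                      z = c(ring_xyz[1, 3], ring_xyz[1, 3], ring_xyz[, 3]))
  new("Structure", atoms = atoms, label = "phe")
}

# batch-means standard error of the mean of a correlated series
batch_se <- function(x, n_batch = 50) {
  n <- length(x)
  bs <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  sd(means) / sqrt(n_batch)
}
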