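test_that("leapfrog integrates a free particle exactly and is time-reversible", {
  const_pot <- function(q) list(energy = 0, force = rep(0, length(q)))
  out <- leapfrog(q = 0, p = 2 * 0.5, masses = 2, potential = const_pot,
                  nSteps = 7, dt = 0.3)
  expect_equal(out$q, 0.5 * 7 * 0.3, tolerance = 1e-14)   # q = v * n * dt

  set.seed(1)
  pot <- harmonicPotential(1)
  q0 <- rnorm(3); p0 <- rnorm(3)
  fwd <- leapfrog(q0, p0, 1, pot, nSteps = 10, dt = 0.05)
  back <- leapfrog(fwd$q, -fwd$p, 1, pot, nSteps = 10, dt = 0.05)
  expect_lt(max(abs(back$q - q0)), 1e-10)
  expect_lt(max(abs(back$p + p0)), 1e-10)
})

test_that("leapfrog energy error scales as dt^2 (Richardson check)", {
  pot <- harmonicPotential(1)
  H <- function(q, p) pot(q)$energy + p^2 / 2
  err_at <- function(dt) {
    out <- leapfrog(1, 0, 1, pot, nSteps = round(2 / dt), dt = dt)
    abs(H(out$q, out$p) - H(1, 0))
  }
  e1 <- err_at(0.08); e2 <- err_at(0.04)
  expect_gt(e1 / e2, 2.5)   # ~4x reduction when halving dt
  expect_lt(e1 / e2, 6)
})

test_that("leapfrog energy error stays bounded with no drift over long harmonic runs", {
  pot <- harmonicPotential(1)
  q <- 1; p <- 0
  h0 <- pot(q)$energy + p^2 / 2
  errs <- numeric(100)
  for (k in 1:100) {
    out <- leapfrog(q, p, 1, pot, nSteps = 1000, dt = 0.01)
    q <- out$q; p <- out$p
    errs[k] <- abs(pot(q)$energy + p^2 / 2 - h0)
  }
  expect_lt(max(errs), 1e-4)   # bounded, oscillatory, 1e5 total steps
  expect_lt(mean(errs[76:100]), max(errs[1:25]) + 1e-6)  # no secular growth
})

test_that("HMC accepts every proposal on a constant potential and rejects under huge steps", {
  const_pot <- function(q) list(energy = 3.5, force = rep(0, length(q)))
  run <- sampleChain(0, const_pot, nSamples = 500, dt = 0.5, mdSteps = 10, seed = 4)
  expect_identical(acceptanceRate(run), 1)     # dH = 0 exactly

  blow <- sampleChain(0.1, harmonicPotential(1), nSamples = 1000, dt = 10,
                      mdSteps = 10, seed = 5)
  expect_lt(acceptanceRate(blow), 0.05)
})

test_that("a gross leapfrog step size drives the Hamiltonian error up, not the sampler into error", {
  st <- hmcStep(0.3, harmonicPotential(1), masses = 1, kT = 1, mdSteps = 10, dt = 10)
  expect_true(is.finite(st$dH))
})

test_that("HMC samples the harmonic Boltzmann distribution (variance kT/k)", {
  run <- sampleChain(0, harmonicPotential(1), nSamples = 20000, dt = 0.15,
                     mdSteps = 10, kT = 1, seed = 6)
  x <- samples(run)[, 1]
  se <- batch_se((x - mean(x))^2)
  expect_lt(abs(var(x) - 1), 3 * se)
  expect_gt(acceptanceRate(run), 0.9)
})

test_that("thinning and burn-in follow the retained-frame convention", {
  pot <- harmonicPotential(1)
  a <- sampleChain(0, pot, nSamples = 6, thin = 3, burnIn = 0, dt = 0.1, seed = 9)
  b <- sampleChain(0, pot, nSamples = 5, thin = 3, burnIn = 1, dt = 0.1, seed = 9)
  # burnIn = 1 drops exactly the first retained frame of the same stream
  expect_equal(samples(b), samples(a)[-1, , drop = FALSE])
  expect_equal(nrow(samples(a)), 6L)

  c5 <- sampleChain(0, pot, nSamples = 5, thin = 1, burnIn = 0, dt = 0.1, seed = 10)
  expect_equal(nrow(samples(c5)), 5L)
})

test_that("sampler output is bit-reproducible given seed and parameters", {
  pot <- doubleWellPotential(1, 1)
  r1 <- sampleChain(0.5, pot, nSamples = 200, dt = 0.2, seed = 11)
  r2 <- sampleChain(0.5, pot, nSamples = 200, dt = 0.2, seed = 11)
  expect_identical(samples(r1), samples(r2))
  l1 <- sampleChain(0.5, pot, sampler = "langevin-md", nSamples = 200, dt = 0.05,
                    gamma = 2, seed = 12)
  l2 <- sampleChain(0.5, pot, sampler = "langevin-md", nSamples = 200, dt = 0.05,
                    gamma = 2, seed = 12)
  expect_identical(samples(l1), samples(l2))
  expect_error(sampleChain(0, pot, nSamples = 5, dt = 0.1), "seed")
})

test_that("HMC occupancies on a tilted double well match Boltzmann factors", {
  a <- 2; b <- 1; c <- 0.6; kT <- 1
  pot <- function(q) list(energy = a * (q^2 - b^2)^2 + c * q,
                          force = -4 * a * q * (q^2 - b^2) - c)
  # independent Boltzmann occupancies by quadrature over three bins
  Z <- function(lo, hi) integrate(function(q) exp(-(a * (q^2 - b^2)^2 + c * q) / kT),
                                  lo, hi)$value
  tot <- Z(-4, 4)
  p_ref <- c(Z(-4, -0.5), Z(-0.5, 0.5), Z(0.5, 4)) / tot
  run <- sampleChain(-1, pot, nSamples = 40000, dt = 0.08, mdSteps = 10,
                     kT = kT, seed = 13)
  x <- samples(run)[, 1]
  bins <- cbind(x < -0.5, abs(x) <= 0.5, x > 0.5)
  for (k in 1:3) {
    se <- batch_se(as.numeric(bins[, k]))
    expect_lt(abs(mean(bins[, k]) - p_ref[k]), 3 * se)
  }
})

test_that("both samplers recover an anisotropic Gaussian covariance", {
  S <- matrix(c(2, 0.8, 0.8, 1), 2)
  hmc <- sampleChain(c(0, 0), gaussianPotential(S), nSamples = 20000, dt = 0.3,
                     mdSteps = 10, seed = 14)
  expect_lt(norm(cov(samples(hmc)) - S, "F") / norm(S, "F"), 0.08)
  lan <- sampleChain(c(0, 0), gaussianPotential(S), sampler = "langevin-md",
                     nSamples = 40000, dt = 0.08, gamma = 1, seed = 15)
  expect_lt(norm(cov(samples(lan)) - S, "F") / norm(S, "F"), 0.08)
})

test_that("the elastic-network potential is at its minimum on the reference structure", {
  r <- makeToyReceptor(seed = 4)
  pot <- enmPotential(r$structure, cutoff = 10, kSpring = 1)
  q0 <- attr(pot, "q0")
  expect_equal(pot(q0)$energy, 0)
  expect_equal(max(abs(pot(q0)$force)), 0, tolerance = 1e-9)
  set.seed(16)
  dq <- rnorm(length(q0), 0, 0.05)
  expect_gt(pot(q0 + dq)$energy, 0)
  # numerical gradient check at a displaced point
  qa <- q0 + dq
  idx <- sample(length(q0), 5)
  for (i in idx) {
    h <- 1e-6
    qp <- qa; qp[i] <- qp[i] + h
    qm <- qa; qm[i] <- qm[i] - h
    num <- -(pot(qp)$energy - pot(qm)$energy) / (2 * h)
    expect_equal(pot(qa)$force[i], num, tolerance = 1e-5)
  }
})

test_that("RMSD is zero on identity, invariant to rigid motion, and symmetric", {
  r <- makeToyReceptor(seed = 5)
  s <- r$structure
  expect_equal(rmsd(s, s), 0)
  R <- random_rotation(); t <- c(4, -7, 11)
  rot <- s
  rot@atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(s@atoms[, c("x", "y", "z")]) %*% t(R), 2, t, `+`)
  expect_lt(rmsd(rot, s), 1e-9)
  expect_gt(rmsd(rot, s, superpose = FALSE), 1)

  set.seed(17)
  jig <- s
  jig@atoms[, c("x", "y", "z")] <- as.matrix(s@atoms[, c("x", "y", "z")]) +
    rnorm(3 * nAtoms(s), 0, 0.4)
  expect_lt(abs(rmsd(jig, s) - rmsd(s, jig)), 1e-9)
})

test_that("superposed RMSD matches an independent fitting implementation", {
  set.seed(18)
  P <- matrix(rnorm(12, sd = 3), 4, 3)
  Q <- P %*% t(random_rotation()) + rnorm(12, sd = 0.8)
  ours <- rmsd(P, Q, superpose = TRUE)
  fit <- suppressWarnings(   # bio3d notes it is fitting on all positions
    bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P))))
  ref <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - Q)^2)))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("RMSD selection mismatches name the first diverging residue", {
  a <- ca_structure(matrix(rnorm(15), 5, 3), resseq = 1:5)
  b <- ca_structure(matrix(rnorm(12), 4, 3), resseq = c(1:3, 9))
  expect_error(rmsd(a, b), "divergence")
})

test_that("RMSF recovers planted isotropic jitter and ignores snapshot order", {
  set.seed(19)
  n_res <- 50; n_snap <- 1500; sigma <- 0.5
  base <- matrix(rnorm(n_res * 3, sd = 12), n_res, 3)
  ens <- lapply(seq_len(n_snap), function(k) {
    xyz <- base
    xyz[7, ] <- xyz[7, ] + rnorm(3, 0, sigma)
    ca_structure(xyz, resseq = seq_len(n_res))
  })
  # frozen ensemble first: all-zero fluctuation
  frozen <- rmsf(rep(list(ca_structure(base, resseq = seq_len(n_res))), 3))
  expect_equal(frozen$rmsf, rep(0, n_res), tolerance = 1e-12)

  out <- rmsf(ens)
  target <- sigma * sqrt(3)
  se3 <- 3 * target / sqrt(2 * 3 * n_snap)
  expect_lt(abs(out$rmsf[out$resseq == 7] - target), se3 + 0.02)
  expect_lt(max(out$rmsf[out$resseq != 7]), 0.05)

  perm <- rmsf(ens[sample(n_snap)])
  expect_equal(perm$rmsf, out$rmsf, tolerance = 1e-9)
  expect_error(rmsf(ens[1]), "at least two")
})

test_that("the trajectory RMSD series is zero at the reference and grows with jitter", {
  set.seed(20)
  base <- matrix(rnorm(30, sd = 8), 10, 3)
  ens <- lapply(c(0, 0.2, 0.6), function(s)
    ca_structure(base + rnorm(30, 0, s), resseq = 1:10))
  ser <- rmsdSeries(ens, ens[[1]], atomMode = "CA")
  expect_equal(ser$rmsd[1], 0, tolerance = 1e-9)
  expect_true(all(diff(ser$rmsd) > 0))
})
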