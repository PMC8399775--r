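# Generic Hamiltonian Monte Carlo / Langevin samplers over pluggable
# potentials, plus trajectory metrics (RMSD, RMSF).
#
# A potential is a function(q) returning list(energy = U(q), force = -grad U(q))
# in consistent model units. The samplers are deliberately generic: the
# acceptance-rejection scheme (short leapfrog trajectory proposals, full
# momentum refresh, Metropolis test on the total Hamiltonian) is the reusable
# computation; production force fields are out of scope.

#' Toy and structure-shaped potentials
#'
#' Factories returning potential closures for the samplers: an isotropic
#' harmonic well, a symmetric double well (per coordinate), a centered
#' multivariate Gaussian with a given covariance, and an elastic-network
#' model built from a structure (harmonic springs of uniform force constant
#' between CA pairs within a cutoff, at their reference lengths).
#'
#' @param k force constant (energy / length^2; `kSpring` for the network).
#' @param a,b double-well parameters: `U(q) = a * sum((q^2 - b^2)^2)`, with
#'   minima at plus/minus `b` and barrier height `a * b^4` per coordinate.
#' @param sigma covariance matrix of the target Gaussian.
#' @param structure a [Structure-class]; springs connect its CA atoms.
#' @param cutoff spring cutoff distance, Angstrom.
#' @param kSpring uniform spring constant.
#' @return `function(q) -> list(energy, force)`; the elastic-network factory
#'   also attaches attributes `q0` (flattened reference coordinates) and
#'   `n_atoms`.
#' @name potentials
NULL

#' @rdname potentials
#' @export
harmonicPotential <- function(k = 1) {
  force(k)
  function(q) list(energy = 0.5 * sum(k * q^2), force = -k * q)
}

#' @rdname potentials
#' @export
doubleWellPotential <- function(a = 1, b = 1) {
  force(a); force(b)
  function(q) list(energy = a * sum((q^2 - b^2)^2),
                   force = -4 * a * q * (q^2 - b^2))
}

#' @rdname potentials
#' @export
gaussianPotential <- function(sigma) {
  P <- solve(sigma)
  function(q) {
    g <- as.vector(P %*% q)
    list(energy = 0.5 * sum(q * g), force = -g)
  }
}

#' @rdname potentials
#' @export
enmPotential <- function(structure, cutoff = 10, kSpring = 1) {
  a <- atoms(structure)
  ca <- a[a$name == "CA", , drop = FALSE]
  if (nrow(ca) < 2L) stop("need at least two CA atoms", call. = FALSE)
  x0 <- as.matrix(ca[, c("x", "y", "z")])
  d0 <- as.matrix(dist(x0))
  pair <- which(d0 <= cutoff & upper.tri(d0), arr.ind = TRUE)
  if (nrow(pair) == 0L) stop("no CA pair within the cutoff", call. = FALSE)
  r0 <- d0[pair]
  i1 <- pair[, 1L]; i2 <- pair[, 2L]
  n <- nrow(x0)
  pot <- function(q) {
    x <- matrix(q, ncol = 3L, byrow = FALSE)
    dv <- x[i1, , drop = FALSE] - x[i2, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    stretch <- d - r0
    f <- matrix(0, n, 3L)
    fpair <- -kSpring * stretch / pmax(d, 1e-12) * dv
    for (ax in 1:3) {
      f[, ax] <- f[, ax] + tapply_add(fpair[, ax], i1, n) - tapply_add(fpair[, ax], i2, n)
    }
    list(energy = 0.5 * kSpring * sum(stretch^2), force = as.vector(f))
  }
  attr(pot, "q0") <- as.vector(x0)
  attr(pot, "n_atoms") <- n
  pot
}

tapply_add <- function(v, idx, n) {
  out <- numeric(n)
  s <- rowsum(v, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Leapfrog integration of Hamiltonian dynamics
#'
#' Standard kick-drift-kick (velocity Verlet) integration of
#' `n_steps` steps of size `dt` under the given potential: time-reversible
#' and volume-preserving, which is what makes it a valid HMC proposal.
#'
#' @param q,p coordinate and momentum vectors.
#' @param masses positive vector (recycled along `q`).
#' @param potential a `function(q) -> list(energy, force)`.
#' @param nSteps number of integration steps (>= 1).
#' @param dt step size (> 0).
#' @return list `q`, `p`, `energy` (potential energy at the final point).
#' @export
leapfrog <- function(q, p, masses, potential, nSteps, dt) {
  stopifnot(nSteps >= 1L, dt > 0)
  m <- rep_len(masses, length(q))
  ev <- potential(q)
  if (!all(is.finite(ev$force)))
    stop("non-finite gradient at q = (", paste(signif(q, 4), collapse = ", "), ")",
         call. = FALSE)
  f <- ev$force
  for (s in seq_len(nSteps)) {
    p <- p + (dt / 2) * f
    q <- q + dt * p / m
    ev <- potential(q)
    if (!all(is.finite(ev$force)))
      stop("non-finite gradient at q = (", paste(signif(q, 4), collapse = ", "), ")",
           call. = FALSE)
    f <- ev$force
    p <- p + (dt / 2) * f
  }
  list(q = q, p = p, energy = ev$energy)
}

#' One Hamiltonian Monte Carlo step
#'
#' Draws fresh momenta from the Maxwell-Boltzmann distribution at `kT`,
#' integrates a short leapfrog trajectory (`mdSteps` steps of `dt`) and
#' accepts the endpoint with probability `min(1, exp(-dH/kT))` where `dH`
#' is the change in the total Hamiltonian. On rejection the coordinates are
#' unchanged. Uses the session RNG; seed it (or use [sampleChain()], which
#' requires a seed) for reproducibility.
#'
#' @inheritParams leapfrog
#' @param kT thermal energy (> 0).
#' @param mdSteps leapfrog steps per proposal (default 10).
#' @return list `q`, `accepted` (logical), `energy` (potential at `q`),
#'   `dH`.
#' @export
hmcStep <- function(q, potential, masses = 1, kT = 1, mdSteps = 10L, dt = 0.01) {
  m <- rep_len(masses, length(q))
  p <- stats::rnorm(length(q), 0, sqrt(m * kT))
  e0 <- potential(q)$energy
  h0 <- e0 + sum(p^2 / (2 * m))
  # a trajectory that diverges to a non-finite gradient is a divergent
  # proposal: treated as dH = +Inf and rejected (detailed balance preserved)
  prop <- tryCatch(leapfrog(q, p, m, potential, mdSteps, dt),
                   error = function(e) {
                     if (grepl("non-finite gradient", conditionMessage(e))) NULL
                     else stop(e)
                   })
  dH <- if (is.null(prop)) Inf
        else prop$energy + sum(prop$p^2 / (2 * m)) - h0
  if (!is.finite(dH) && !is.null(prop)) dH <- Inf
  accepted <- log(stats::runif(1)) < -dH / kT
  if (accepted) list(q = prop$q, accepted = TRUE, energy = prop$energy, dH = dH)
  else list(q = q, accepted = FALSE, energy = e0, dH = dH)
}

.langevin_step <- function(q, p, masses, potential, dt, gamma, kT, f) {
  # BAOAB splitting: half kick, half drift, OU refresh, half drift, half kick
  m <- masses
  p <- p + (dt / 2) * f
  q <- q + (dt / 2) * p / m
  c1 <- exp(-gamma * dt)
  p <- c1 * p + sqrt(kT * m * (1 - c1^2)) * stats::rnorm(length(p))
  q <- q + (dt / 2) * p / m
  ev <- potential(q)
  p <- p + (dt / 2) * ev$force
  list(q = q, p = p, f = ev$force, energy = ev$energy)
}

#' Sample a potential with HMC or Langevin dynamics
#'
#' Runs `(nSamples + burnIn) * thin` sampler iterations, retains every
#' `thin`-th frame and drops the first `burnIn` retained frames — mirroring
#' the convention of drawing a structure every fixed number of
#' acceptance-rejection steps and discarding the first frame as burn-in.
#' `"hmc"` iterations are [hmcStep()] proposals; `"langevin-md"` iterations
#' are BAOAB-discretized Langevin dynamics steps at friction `gamma`
#' targeting the same `kT`.
#'
#' @inheritParams hmcStep
#' @param q0 initial coordinate vector.
#' @param sampler `"hmc"` or `"langevin-md"`.
#' @param nSamples retained draws after burn-in (>= 1).
#' @param thin iterations between retained frames (>= 1).
#' @param burnIn retained frames dropped from the front.
#' @param gamma Langevin friction (1/time).
#' @param seed mandatory integer seed; there is no hidden default so every
#'   run is reproducible by construction.
#' @return a [SampleRun-class].
#' @examples
#' run <- sampleChain(0, harmonicPotential(), nSamples = 200, dt = 0.2, seed = 1)
#' acceptanceRate(run)
#' @export
sampleChain <- function(q0, potential, sampler = c("hmc", "langevin-md"),
                        nSamples, thin = 1L, burnIn = 0L, dt = 0.01,
                        mdSteps = 10L, kT = 1, masses = 1, gamma = 1, seed) {
  sampler <- match.arg(sampler)
  if (missing(seed)) stop("an explicit integer seed is required", call. = FALSE)
  stopifnot(nSamples >= 1L, thin >= 1L, burnIn >= 0L, kT > 0)
  set.seed(as.integer(seed))
  m <- rep_len(masses, length(q0))
  nKeep <- nSamples + burnIn
  total <- nKeep * thin
  keep <- matrix(NA_real_, nKeep, length(q0))
  q <- q0
  nAcc <- 0L; nProp <- 0L
  if (sampler == "hmc") {
    row <- 0L
    for (it in seq_len(total)) {
      st <- hmcStep(q, potential, m, kT, mdSteps, dt)
      q <- st$q
      nProp <- nProp + 1L
      if (st$accepted) nAcc <- nAcc + 1L
      if (it %% thin == 0L) { row <- row + 1L; keep[row, ] <- q }
    }
    rate <- nAcc / nProp
  } else {
    p <- stats::rnorm(length(q0), 0, sqrt(m * kT))
    f <- potential(q)$force
    row <- 0L
    for (it in seq_len(total)) {
      st <- .langevin_step(q, p, m, potential, dt, gamma, kT, f)
      q <- st$q; p <- st$p; f <- st$f
      if (it %% thin == 0L) { row <- row + 1L; keep[row, ] <- q }
    }
    rate <- NA_real_
  }
  if (burnIn > 0L) keep <- keep[-seq_len(burnIn), , drop = FALSE]
  new("SampleRun", samples = keep, acceptanceRate = rate,
      nAccepted = nAcc, nProposals = nProp, seed = as.integer(seed),
      params = list(sampler = sampler, md_steps_per_proposal = mdSteps,
                    dt = dt, thin = thin, burn_in = burnIn, kT = kT,
                    gamma = if (sampler == "langevin-md") gamma else NA_real_))
}

# least-squares superposition (SVD with reflection guard): rotation + shift
# carrying `mobile` onto `ref`
.kabsch <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2L, cm); Q <- sweep(ref, 2L, cr)
  sv <- svd(crossprod(P, Q))
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, shift = cr, center = cm)
}

.apply_fit <- function(xyz, fit) {
  sweep(sweep(xyz, 2L, fit$center) %*% t(fit$R), 2L, fit$shift, `+`)
}

.selection_coords <- function(structure, selection = NULL, atomMode = "CA") {
  if (is.null(selection)) {
    a <- atoms(structure)
    if (atomMode == "CA") a <- a[a$name == "CA", , drop = FALSE]
    else a <- a[toupper(a$element) != "H", , drop = FALSE]
    list(xyz = as.matrix(a[, c("x", "y", "z")]),
         residues = data.frame(chain = a$chain, resseq = a$resseq))
  } else {
    g <- resolveSite(structure, selection, atomMode = atomMode)
    list(xyz = coords(g), residues = g@residueOrder)
  }
}

#' Root-mean-square deviation between two structures
#'
#' RMSD over a selection (all CA atoms by default, or a binding-site
#' definition), after an optional least-squares superposition of the mobile
#' selection onto the reference (SVD construction with reflection guard).
#' Also accepts two raw n x 3 coordinate matrices.
#'
#' @param mobile,reference [Structure-class] objects (or n x 3 matrices).
#' @param selection optional [BindingSiteDefinition-class] restricting the
#'   compared atoms.
#' @param atomMode `"CA"` or `"all-heavy"`.
#' @param superpose fit before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(mobile, reference, selection = NULL, atomMode = "CA",
                 superpose = TRUE) {
  if (is.matrix(mobile) && is.matrix(reference)) {
    P <- mobile; Q <- reference
  } else {
    sm <- .selection_coords(mobile, selection, atomMode)
    sr <- .selection_coords(reference, selection, atomMode)
    P <- sm$xyz; Q <- sr$xyz
    if (nrow(P) != nrow(Q)) {
      km <- paste(sm$residues$chain, sm$residues$resseq)
      kr <- paste(sr$residues$chain, sr$residues$resseq)
      first <- c(setdiff(km, kr), setdiff(kr, km))[1L]
      stop(sprintf("selection resolves to %d vs %d atoms (first divergence: %s)",
                   nrow(P), nrow(Q), first), call. = FALSE)
    }
  }
  if (nrow(P) != nrow(Q)) stop("atom-count mismatch", call. = FALSE)
  if (superpose) P <- .apply_fit(P, .kabsch(P, Q))
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Per-residue root-mean-square fluctuation over an ensemble
#'
#' Superposes every snapshot onto the first on the selection (least-squares
#' fit), then reports, per residue, the RMS deviation of its selected atoms
#' from their ensemble-mean positions.
#'
#' @param ensemble list of [Structure-class] snapshots (>= 2).
#' @inheritParams rmsd
#' @return data.frame `chain`, `resseq`, `rmsf` (Angstrom).
#' @export
rmsf <- function(ensemble, selection = NULL, atomMode = "CA") {
  if (length(ensemble) < 2L)
    stop("RMSF needs at least two snapshots", call. = FALSE)
  sels <- lapply(ensemble, .selection_coords, selection = selection,
                 atomMode = atomMode)
  nref <- nrow(sels[[1L]]$xyz)
  for (k in seq_along(sels))
    if (nrow(sels[[k]]$xyz) != nref)
      stop(sprintf("snapshot %d resolves to %d atoms; snapshot 1 has %d",
                   k, nrow(sels[[k]]$xyz), nref), call. = FALSE)
  # iterated fit-to-mean: superpose on the first snapshot, then re-fit every
  # snapshot onto the running ensemble mean until it stabilizes, so the
  # result does not depend on which snapshot happened to come first
  ref <- sels[[1L]]$xyz
  fitted <- lapply(sels, function(s) .apply_fit(s$xyz, .kabsch(s$xyz, ref)))
  mu <- Reduce(`+`, fitted) / length(fitted)
  for (it in seq_len(50L)) {
    fitted <- lapply(fitted, function(x) .apply_fit(x, .kabsch(x, mu)))
    mu_new <- Reduce(`+`, fitted) / length(fitted)
    if (max(abs(mu_new - mu)) < 1e-10) { mu <- mu_new; break }
    mu <- mu_new
  }
  arr <- simplify2array(fitted)                      # atom x 3 x snapshot
  msf <- rowMeans(apply(arr, 3L, function(x) rowSums((x - mu)^2)))
  res <- sels[[1L]]$residues
  key <- paste(res$chain, res$resseq)
  out <- do.call(rbind, lapply(unique(key), function(k) {
    sel <- key == k
    data.frame(chain = res$chain[sel][1L], resseq = res$resseq[sel][1L],
               rmsf = sqrt(mean(msf[sel])))
  }))
  rownames(out) <- NULL
  out
}

#' Binding-site RMSD along a trajectory
#'
#' Convenience wrapper: RMSD of every snapshot against a fixed reference
#' over a selection — the per-frame series used to judge how far an
#' ensemble drifts from its starting structure.
#'
#' @param ensemble list of [Structure-class] snapshots.
#' @inheritParams rmsd
#' @return data.frame `frame`, `rmsd`.
#' @export
rmsdSeries <- function(ensemble, reference, selection = NULL,
                       atomMode = "all-heavy", superpose = TRUE) {
  data.frame(frame = seq_along(ensemble),
             rmsd = vapply(ensemble, rmsd, 0, reference = reference,
                           selection = selection, atomMode = atomMode,
                           superpose = superpose))
}
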