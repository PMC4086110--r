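# Deterministic toy structures and an independent geometry oracle: every
# other module is testable without external data.

#' Two-atom test system
#'
#' Two single-atom residues on chains A and B, separated by `d` angstrom
#' along the x-axis, with explicitly set van der Waals radii.  Substrate
#' for the analytic spherical-cap oracle: with expanded radii
#' `R1 = r1 + waterRadius` and `R2 = r2 + waterRadius`, the directed
#' contact area on sphere 1 is the cap `2 * pi * R1 * (R1 - x1)` with
#' `x1 = (d^2 + R1^2 - R2^2) / (2 d)` (zero when the expanded spheres are
#' disjoint).
#'
#' @param r1,r2 van der Waals radii in angstrom (> 0).
#' @param d center distance in angstrom (> 0).
#' @return a [Structure-class] of two `OTHER` residues.
#' @export
makeTwoAtomSystem <- function(r1, r2, d) {
  if (r1 <= 0 || r2 <= 0) stop("radii must be positive")
  if (d <= 0) stop("center distance must be positive")
  atoms <- data.frame(
    chain = c("A", "B"), resSeq = c(1L, 1L), icode = "",
    resName = "LIG", atomName = c("X1", "X2"), element = "X",
    x = c(0, d), y = 0, z = 0, vdw = c(r1, r2),
    altLoc = "", occupancy = 1, stringsAsFactors = FALSE)
  .newStructure(atoms, "protein")
}

#' Spherical-cap contact area for a two-atom system
#'
#' Closed-form directed contact area on the first atom's contact sphere
#' (see [makeTwoAtomSystem()]); the independent oracle for the sampling
#' engine.
#'
#' @inheritParams makeTwoAtomSystem
#' @param waterRadius water probe radius in angstrom.
#' @return area in square angstroms.
#' @export
sphericalCapArea <- function(r1, r2, d, waterRadius = 1.4) {
  R1 <- r1 + waterRadius
  R2 <- r2 + waterRadius
  if (d >= R1 + R2) return(0)
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  h <- min(R1 - x1, 2 * R1)  # cap height, clipped if sphere 1 is engulfed
  if (h <= 0) return(0)
  2 * pi * R1 * h
}

#' Idealized extended poly-alanine peptide
#'
#' An `n`-residue ALA chain (atoms N, CA, C, O, CB) with idealized
#' covalent geometry along an extended axis: adjacent C--N distances are
#' about 1.33 angstrom, so the peptide-bond covalent-contact exclusion is
#' exercised.  A small seeded jitter (within 0.05 angstrom per
#' coordinate) makes distinct seeds give distinct but bit-reproducible
#' structures.
#'
#' @param n residue count (>= 2).
#' @param seed RNG seed.
#' @return a protein [Structure-class] with radii assigned.
#' @export
makeToyPeptide <- function(n, seed = 1) {
  if (n < 2) stop("a toy peptide needs at least 2 residues")
  n <- as.integer(n)
  per <- 4.312  # N-CA 1.458 + CA-C 1.525 + C-N' 1.329
  one <- function(k) {
    x0 <- per * (k - 1L)
    data.frame(
      chain = "A", resSeq = k, icode = "", resName = "ALA",
      atomName = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = x0 + c(0, 1.458, 2.983, 2.983, 1.458),
      y = c(0, 0, 0, 1.23, -1.53),
      z = 0, vdw = NA_real_, altLoc = "", occupancy = 1,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, lapply(seq_len(n), one))
  jitter <- .withSeed(seed, matrix(stats::runif(3L * nrow(atoms), -0.05, 0.05),
                                   ncol = 3L))
  atoms$x <- atoms$x + jitter[, 1L]
  atoms$y <- atoms$y + jitter[, 2L]
  atoms$z <- atoms$z + jitter[, 3L]
  assignRadii(.newStructure(atoms, "protein"))
}

#' Idealized two-chain nucleic acid ladder
#'
#' A toy duplex of `nPairs` A:U pairs on chains A and B with simplified
#' planar base proxies: each residue has minimal backbone atoms (P, O3',
#' C1') and a planar six-membered base ring (N1, C2, N3, C4, C5, C6).
#' Within a chain, consecutive bases are parallel planes displaced 3.4
#' angstrom along the shared normal (stacking-true geometry); the paired
#' bases across chains are coplanar side by side (stacking-false,
#' Watson-Crick-like geometry).  Adjacent O3'--P pairs exercise the
#' phosphodiester covalent-contact exclusion.
#'
#' @param nPairs number of base pairs (>= 2).
#' @param seed RNG seed for the small coordinate jitter (within 0.01
#'   angstrom).
#' @return a nucleic-acid [Structure-class] with radii assigned.
#' @export
makeToyDuplex <- function(nPairs, seed = 1) {
  if (nPairs < 2) stop("a toy duplex needs at least 2 base pairs")
  nPairs <- as.integer(nPairs)
  hex <- function(cx, cz) {
    ang <- (0:5) * pi / 3
    data.frame(atomName = c("N1", "C2", "N3", "C4", "C5", "C6"),
               element = c("N", "C", "N", "C", "C", "C"),
               x = cx + 1.4 * cos(ang), y = 1.4 * sin(ang), z = cz,
               stringsAsFactors = FALSE)
  }
  one <- function(chain, cx, bx, k) {
    z <- 3.4 * (k - 1L)
    base <- hex(cx, z)
    bb <- data.frame(atomName = c("P", "O3'", "C1'"),
                     element = c("P", "O", "C"),
                     x = bx, y = c(0, 0.4, 1.0), z = z + c(0, 1.8, 0.6),
                     stringsAsFactors = FALSE)
    out <- rbind(base, bb)
    out$chain <- chain
    out$resSeq <- k
    out$icode <- ""
    out$resName <- if (chain == "A") "A" else "U"
    out$vdw <- NA_real_
    out$altLoc <- ""
    out$occupancy <- 1
    out
  }
  rows <- c(lapply(seq_len(nPairs), function(k) one("A", 0, -3.5, k)),
            lapply(seq_len(nPairs), function(k) one("B", 6.5, 10, k)))
  atoms <- do.call(rbind, rows)
  jitter <- .withSeed(seed, matrix(stats::runif(3L * nrow(atoms), -0.01, 0.01),
                                   ncol = 3L))
  atoms$x <- atoms$x + jitter[, 1L]
  atoms$y <- atoms$y + jitter[, 2L]
  atoms$z <- atoms$z + jitter[, 3L]
  assignRadii(.newStructure(atoms, "nucleic"))
}

#' Randomly displace every atom
#'
#' Adds an independent uniform displacement in `[-magnitude, magnitude]`
#' per coordinate to every atom, preserving all identifiers, names and
#' radii; deterministic per seed.  The standard model generator for
#' score-degradation experiments.
#'
#' @param structure a [Structure-class].
#' @param magnitude displacement bound in angstrom (>= 0).
#' @param seed RNG seed.
#' @return the perturbed [Structure-class].
#' @export
perturbStructure <- function(structure, magnitude, seed = 1) {
  if (magnitude < 0) stop("magnitude must be >= 0")
  a <- structure@atoms
  if (nrow(a) == 0L || magnitude == 0) return(structure)
  d <- .withSeed(seed, matrix(stats::runif(3L * nrow(a), -magnitude, magnitude),
                              ncol = 3L))
  a$x <- a$x + d[, 1L]
  a$y <- a$y + d[, 2L]
  a$z <- a$z + d[, 3L]
  structure@atoms <- a
  structure
}

#' Independent high-density contact-area oracle
#'
#' Reference implementation of the contact-sphere partition used only for
#' cross-validation: every sample point on every atom's contact sphere is
#' tested against all other atoms (no neighbour pruning, full distance
#' matrix, independent assignment code path) at a very high sampling
#' density.
#'
#' @param structure a [Structure-class] with radii assigned.
#' @param denseN sample points per sphere (default 200000).
#' @param waterRadius water probe radius in angstrom.
#' @return data.frame of directed atom contacts as in
#'   [computeAtomContacts()].
#' @export
bruteForceContactOracle <- function(structure, denseN = 200000,
                                    waterRadius = 1.4) {
  a <- structure@atoms
  n <- nrow(a)
  if (n == 0L)
    return(data.frame(src = integer(0), snk = integer(0), area = numeric(0)))
  xyz <- cbind(a$x, a$y, a$z)
  R <- a$vdw + waterRadius
  dirs <- fibonacciSphereDirections(denseN)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    P <- sweep(dirs * R[i], 2L, xyz[i, ], "+")
    W <- matrix(Inf, nrow = denseN, ncol = n)
    for (j in seq_len(n)) {
      if (j == i) next
      dj <- sqrt((P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
                   (P[, 3] - xyz[j, 3])^2)
      w <- dj - a$vdw[j]
      w[dj > R[j]] <- Inf
      W[, j] <- w
    }
    idx <- max.col(-W, ties.method = "first")
    idx[!is.finite(W[cbind(seq_len(denseN), idx)])] <- NA_integer_
    quantum <- 4 * pi * R[i]^2 / denseN
    counts <- table(idx, useNA = "always")
    snk <- suppressWarnings(as.integer(names(counts)))
    out[[i]] <- data.frame(src = i, snk = snk,
                           area = as.numeric(counts) * quantum)
  }
  res <- do.call(rbind, out)
  res <- res[res$area > 0 | is.na(res$snk), , drop = FALSE]
  rownames(res) <- NULL
  res
}
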