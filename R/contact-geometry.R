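#' Deterministic near-uniform directions on the unit sphere
#'
#' Fibonacci (golden-angle) spiral lattice: `n` unit vectors spread
#' near-uniformly over the sphere, each carrying an equal quadrature
#' weight of `4 * pi / n` steradians.  Deterministic for fixed `n`.
#'
#' @param n number of directions (>= 1).
#' @return an `n x 3` matrix of unit vectors.
#' @export
fibonacciSphereDirections <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Compute directed interatomic contact areas
#'
#' For every atom a contact sphere of radius `vdw + waterRadius` is
#' sampled with a deterministic spherical lattice, and each surface point
#' is assigned to the neighbouring atom that minimises the additively
#' weighted distance `d(p, c_j) - r_j` among all atoms whose own expanded
#' sphere contains the point (the condition that a water probe cannot fit
#' between the two atoms); points claimed by no neighbour are solvent.
#' This is a quadrature of the Voronoi-style partition of the contact
#' sphere into interatomic contact areas and solvent-accessible area:
#' point counts scaled by `4 * pi * R^2 / n` give areas in square
#' angstroms, and per atom the areas sum to the full sphere area exactly.
#'
#' @param structure a [Structure-class] with radii assigned.
#' @param waterRadius water probe radius in angstrom (default 1.4).
#' @param samplingDensity sample points per sphere (default 2000).
#' @param directions optional precomputed direction matrix (e.g. a rotated
#'   lattice); overrides `samplingDensity`.
#' @return data.frame of directed atom contacts: `src` (atom row index),
#'   `snk` (atom row index, or `NA` for solvent), `area`.
#' @seealso [aggregateResidueContacts()], [bruteForceContactOracle()]
#' @export
computeAtomContacts <- function(structure, waterRadius = 1.4,
                                samplingDensity = 2000, directions = NULL) {
  a <- structure@atoms
  n <- nrow(a)
  if (n == 0L)
    return(data.frame(src = integer(0), snk = integer(0), area = numeric(0)))
  if (anyNA(a$vdw)) stop("radii must be assigned before computing contacts")
  xyz <- cbind(a$x, a$y, a$z)
  if (anyDuplicated(xyz))
    stop("two atoms share identical coordinates: degenerate tessellation")
  if (is.null(directions)) directions <- fibonacciSphereDirections(samplingDensity)
  m <- nrow(directions)
  R <- a$vdw + waterRadius
  out <- vector("list", n)
  for (i in seq_len(n)) {
    di <- sqrt((xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
                 (xyz[, 3] - xyz[i, 3])^2)
    cand <- which(di < R[i] + R & seq_len(n) != i)
    px <- xyz[i, 1] + R[i] * directions[, 1]
    py <- xyz[i, 2] + R[i] * directions[, 2]
    pz <- xyz[i, 3] + R[i] * directions[, 3]
    assign <- rep(NA_integer_, m)
    if (length(cand)) {
      best <- rep(Inf, m)
      for (j in cand) {  # ascending order + strict '<' breaks ties to lowest index
        dj <- sqrt((px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 + (pz - xyz[j, 3])^2)
        w <- dj - a$vdw[j]
        take <- dj <= R[j] & w < best
        if (any(take)) {
          assign[take] <- j
          best[take] <- w[take]
        }
      }
    }
    quantum <- 4 * pi * R[i]^2 / m
    counts <- table(assign, useNA = "always")
    snk <- suppressWarnings(as.integer(names(counts)))
    out[[i]] <- data.frame(src = i, snk = snk,
                           area = as.numeric(counts) * quantum)
  }
  res <- do.call(rbind, out)
  res <- res[res$area > 0 | is.na(res$snk), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify a base-base contact as stacking or non-stacking
#'
#' Fits least-squares planes through the base ring atoms of two
#' nucleotides and classifies the pair geometrically: stacking requires
#' the two base-plane normals to be within `normalAngleMax` degrees of
#' each other and the inter-centroid vector to be within
#' `offsetAngleMax` degrees of at least one normal (face-to-face
#' geometry); coplanar side-by-side pairing (Watson-Crick-like) fails the
#' second condition.
#'
#' @param structure a [Structure-class].
#' @param src,snk residue keys of two nucleotides (see [residueKeys()]).
#' @param normalAngleMax,offsetAngleMax thresholds in degrees (defaults
#'   30 and 40).
#' @return `TRUE` for stacking, `FALSE` otherwise.
#' @export
classifyStacking <- function(structure, src, snk,
                             normalAngleMax = 30, offsetAngleMax = 40) {
  a <- structure@atoms
  ring <- function(key) {
    sel <- a$resKey == key & a$moiety == "NUCLEOTIDE" &
      a$atomName %in% .BASE_RING
    cbind(a$x[sel], a$y[sel], a$z[sel])
  }
  p1 <- ring(src)
  p2 <- ring(snk)
  if (nrow(p1) < 3L || nrow(p2) < 3L)
    stop("stacking classification needs >= 3 base ring atoms per nucleotide")
  planeNormal <- function(p) {
    p <- sweep(p, 2, colMeans(p))
    svd(p)$v[, 3L]
  }
  n1 <- planeNormal(p1)
  n2 <- planeNormal(p2)
  acute <- function(u, v) {
    cosang <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
    acos(pmin(1, cosang)) * 180 / pi
  }
  if (acute(n1, n2) > normalAngleMax) return(FALSE)
  cen <- colMeans(p2) - colMeans(p1)
  min(acute(cen, n1), acute(cen, n2)) <= offsetAngleMax
}

#' Aggregate atom contacts into a residue-level contact inventory
#'
#' Sums directed atom-level contact areas into directed residue-residue
#' contacts, keyed by the atom-subset class on both sides (main
#' chain/backbone vs side chain/base).  Contacts within a residue are
#' discarded, and so are the interatomic contacts corresponding to the
#' covalent bond between sequence-adjacent residues of the same chain
#' (the C--N peptide bond for amino acids, the O3'--P phosphodiester bond
#' for nucleotides).  Solvent areas are retained per residue.  Base-base
#' pairs of nucleotides are annotated with the stacking flag from
#' [classifyStacking()].
#'
#' @param structure a [Structure-class] with radii assigned.
#' @param atomContacts output of [computeAtomContacts()].
#' @param waterRadius,samplingDensity metadata recorded in the inventory.
#' @return a [ContactInventory-class].
#' @export
aggregateResidueContacts <- function(structure, atomContacts,
                                     waterRadius = 1.4,
                                     samplingDensity = 2000) {
  a <- structure@atoms
  ac <- atomContacts
  src <- a$resKey[ac$src]
  snk <- ifelse(is.na(ac$snk), "solvent", a$resKey[ac$snk])
  keep <- src != snk  # drops intra-residue contacts; solvent rows survive
  ac <- ac[keep, , drop = FALSE]
  src <- src[keep]
  snk <- snk[keep]
  # covalent-bond exclusion: C(i)-N(i+1) / O3'(i)-P(i+1) on adjacent
  # residues of the same chain, in file order
  if (nrow(ac)) {
    excl <- rep(FALSE, nrow(ac))
    solv <- is.na(ac$snk)
    rk <- unique(a$resKey)
    pos <- match(src, rk)
    posSnk <- rep(NA_integer_, nrow(ac))
    posSnk[!solv] <- match(snk[!solv], rk)
    adj <- !solv & abs(pos - posSnk) == 1L &
      a$chain[ac$src] == a$chain[ifelse(solv, ac$src, ac$snk)]
    if (any(adj)) {
      i <- which(adj)
      first <- ifelse(pos[i] < posSnk[i], ac$src[i], ac$snk[i])
      second <- ifelse(pos[i] < posSnk[i], ac$snk[i], ac$src[i])
      pep <- a$moiety[first] == "AMINO_ACID" & a$moiety[second] == "AMINO_ACID" &
        a$atomName[first] == "C" & a$atomName[second] == "N"
      nuc <- a$moiety[first] == "NUCLEOTIDE" & a$moiety[second] == "NUCLEOTIDE" &
        a$atomName[first] == "O3'" & a$atomName[second] == "P"
      excl[i[pep | nuc]] <- TRUE
    }
    ac <- ac[!excl, , drop = FALSE]
    src <- src[!excl]
    snk <- snk[!excl]
  }
  solv <- is.na(ac$snk)
  df <- data.frame(
    src = src,
    snk = snk,
    srcChain = a$chain[ac$src],
    snkChain = ifelse(solv, NA_character_, a$chain[ac$snk]),
    srcSubset = a$subset[ac$src],
    snkSubset = ifelse(solv, NA_character_, a$subset[ac$snk]),
    area = ac$area,
    stringsAsFactors = FALSE)
  grp <- paste(df$src, df$snk, df$srcSubset, df$snkSubset, sep = "\r")
  agg <- rowsum(df$area, grp)
  first <- !duplicated(grp)
  cc <- df[first, , drop = FALSE]
  cc$area <- agg[match(grp[first], rownames(agg)), 1L]
  cc$stacking <- NA
  # stacking annotation for nucleotide base-base pairs
  isnt <- structure@atoms$moiety == "NUCLEOTIDE"
  ntKeys <- unique(structure@atoms$resKey[isnt])
  bb <- cc$snk != "solvent" & cc$src %in% ntKeys & cc$snk %in% ntKeys
  if (any(bb)) {
    pairs <- unique(cc[bb, c("src", "snk")])
    flag <- mapply(function(s, k) {
      tryCatch(classifyStacking(structure, s, k), error = function(e) NA)
    }, pairs$src, pairs$snk)
    hit <- match(paste(cc$src, cc$snk), paste(pairs$src, pairs$snk))
    cc$stacking[bb] <- flag[hit[bb]]
  }
  rownames(cc) <- NULL
  new("ContactInventory", structure = structure,
      contacts = cc[, c("src", "snk", "srcChain", "snkChain",
                        "srcSubset", "snkSubset", "stacking", "area")],
      waterRadius = waterRadius, samplingDensity = samplingDensity)
}

#' Compute the contact inventory of a structure
#'
#' Convenience wrapper chaining [computeAtomContacts()] and
#' [aggregateResidueContacts()].
#'
#' @inheritParams computeAtomContacts
#' @return a [ContactInventory-class].
#' @export
computeContactInventory <- function(structure, waterRadius = 1.4,
                                    samplingDensity = 2000,
                                    directions = NULL) {
  ac <- computeAtomContacts(structure, waterRadius, samplingDensity, directions)
  aggregateResidueContacts(structure, ac, waterRadius,
                           if (is.null(directions)) samplingDensity
                           else nrow(directions))
}

#' Applicable CAD-score variants for a molecule type
#'
#' Proteins and complexes use the six subset variants (A-A, A-M, A-S,
#' M-M, M-S, S-S); nucleic acids additionally split S-S (base-base) into
#' stacking and non-stacking contacts.
#'
#' @param moleculeType `"protein"`, `"nucleic"` or `"complex"`.
#' @return character vector of variant names.
#' @export
applicableVariants <- function(moleculeType) {
  base <- .VARIANTS[1:6]
  if (identical(moleculeType, "nucleic")) .VARIANTS else base
}

# does a contact row with subsets (s1, s2) and stacking flag belong to a variant?
.variantMask <- function(s1, s2, stacking, variant) {
  if (variant == "A-A") return(rep(TRUE, length(s1)))
  inset <- function(s, set) !is.na(s) & s %in% set
  A <- c("MAIN", "SIDE")
  pair <- switch(variant,
                 "A-M" = list(A, "MAIN"),
                 "A-S" = list(A, "SIDE"),
                 "M-M" = list("MAIN", "MAIN"),
                 "M-S" = list("MAIN", "SIDE"),
                 "S-S" = ,
                 "S-S-stacking" = ,
                 "S-S-non-stacking" = list("SIDE", "SIDE"),
                 stop("unknown variant: ", variant))
  m <- (inset(s1, pair[[1]]) & inset(s2, pair[[2]])) |
    (inset(s1, pair[[2]]) & inset(s2, pair[[1]]))
  if (variant == "S-S-stacking") m <- m & !is.na(stacking) & stacking
  if (variant == "S-S-non-stacking") m <- m & !is.na(stacking) & !stacking
  m
}

#' Directed residue-pair areas for one variant
#'
#' Sums the inventory's subset-resolved contact rows into directed
#' residue-pair areas for a single CAD-score variant.  Solvent rows are
#' excluded.  Querying a pair absent from the result means its contact
#' area is 0.
#'
#' @param inventory a [ContactInventory-class].
#' @param variant variant name (see [applicableVariants()]).
#' @return data.frame: src, snk, srcChain, snkChain, area (> 0 rows only).
#' @export
variantAreas <- function(inventory, variant) {
  cc <- inventory@contacts
  cc <- cc[cc$snk != "solvent", , drop = FALSE]
  m <- .variantMask(cc$srcSubset, cc$snkSubset, cc$stacking, variant)
  cc <- cc[m, , drop = FALSE]
  if (!nrow(cc))
    return(data.frame(src = character(0), snk = character(0),
                      srcChain = character(0), snkChain = character(0),
                      area = numeric(0), stringsAsFactors = FALSE))
  grp <- paste(cc$src, cc$snk, sep = "\r")
  agg <- rowsum(cc$area, grp)
  first <- !duplicated(grp)
  out <- cc[first, c("src", "snk", "srcChain", "snkChain"), drop = FALSE]
  out$area <- agg[match(grp[first], rownames(agg)), 1L]
  out <- out[out$area > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a contact inventory to TSV
#'
#' Flat text export of the residue-level contact areas: source chain,
#' residue number, insertion code, sink residue (or `"solvent"`), subset
#' classes, stacking flag and area.
#'
#' @param inventory a [ContactInventory-class].
#' @param file output path.
#' @return the written data.frame, invisibly.
#' @export
writeContactInventory <- function(inventory, file) {
  cc <- inventory@contacts
  s <- .splitKey(cc$src)
  out <- data.frame(source_chain = s$chain, source_resseq = s$resSeq,
                    source_icode = s$icode, sink = cc$snk,
                    source_subset = cc$srcSubset, sink_subset = cc$snkSubset,
                    stacking = cc$stacking, area = cc$area,
                    stringsAsFactors = FALSE)
  .writeTsv(out, file)
  invisible(out)
}
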