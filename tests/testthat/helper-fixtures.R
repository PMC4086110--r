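# PDB text fixtures built in code, plus heavy-atom name inventories used by
# the subset-classification tests.

pdbLine <- function(serial, name, resName, chain, resSeq, x, y, z,
                    element, record = "ATOM", altLoc = "", icode = "",
                    occ = 1, b = 0) {
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, altLoc, resName, chain, resSeq, icode,
          x, y, z, occ, b, formatC(element, width = 2))
}

# minimal 3-residue peptide: GLY-ALA-SER backbones on a line
triPeptidePdb <- function() {
  res <- list(list("GLY", c("N", "CA", "C", "O")),
              list("ALA", c("N", "CA", "C", "O", "CB")),
              list("SER", c("N", "CA", "C", "O", "CB", "OG")))
  lines <- character(0)
  serial <- 0L
  for (k in seq_along(res)) {
    nm <- res[[k]][[2]]
    for (j in seq_along(nm)) {
      serial <- serial + 1L
      lines <- c(lines, pdbLine(serial, nm[j], res[[k]][[1]], "A", k,
                                4 * (k - 1) + j, 0.5 * j, 0,
                                substr(nm[j], 1, 1)))
    }
  }
  c(lines, "END")
}

# standard heavy-atom inventories (side chains beyond CB), by residue name
aaSideAtoms <- list(
  ALA = c("CB"), ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"), ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"), GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"), GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"), MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"), SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2"))

ntBaseAtoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"),
  DA = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  DG = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  DC = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  DT = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"))

rnaBackbone <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                 "O3'", "C2'", "O2'", "C1'")

# structure with arbitrary atoms placed far apart (no contacts implied)
looseStructure <- function(specs, moleculeType = "protein") {
  rows <- lapply(seq_along(specs), function(k) {
    s <- specs[[k]]
    data.frame(chain = s$chain, resSeq = s$resSeq,
               icode = if (is.null(s$icode)) "" else s$icode,
               resName = s$resName, atomName = s$atoms,
               element = s$elements,
               x = s$x, y = s$y, z = s$z, vdw = NA_real_,
               altLoc = "", occupancy = 1, stringsAsFactors = FALSE)
  })
  assignRadii(cadscorer:::.newStructure(do.call(rbind, rows), moleculeType))
}

# random small synthetic inventory pair (target, model areas) for algebraic
# tests that need no geometry
randomContactSet <- function(nPairs, seed) {
  set.seed(seed)
  keys <- paste0("A|", 1:max(4, ceiling(sqrt(nPairs) + 1)), "|")
  pairs <- t(combn(keys, 2))
  pairs <- rbind(pairs, pairs[, 2:1])
  pick <- sample(nrow(pairs), min(nPairs, nrow(pairs)))
  data.frame(src = pairs[pick, 1], snk = pairs[pick, 2],
             target = runif(length(pick), 0.01, 40),
             model = pmax(0, runif(length(pick), -5, 60)),
             stringsAsFactors = FALSE)
}

rotationMatrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

rigidTransform <- function(structure, rot, shift = c(0, 0, 0)) {
  a <- atoms(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  structure@atoms <- a
  structure
}
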