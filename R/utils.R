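# Internal helpers shared across modules.

.AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

.NUCLEOTIDES <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")

.WATERS <- c("HOH", "WAT", "DOD")

# main-chain atom names (amino acids) and backbone atom names (nucleotides)
.AA_MAIN <- c("N", "CA", "C", "O", "OXT")
.NT_MAIN <- c("P", "OP1", "OP2", "OP3", "O5'", "C5'", "C4'", "O4'",
              "C3'", "O3'", "C2'", "O2'", "C1'")

# heteroring atoms used for base-plane fitting in the stacking classifier
.BASE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")

.resKey <- function(chain, resSeq, icode) paste(chain, resSeq, icode, sep = "|")

.splitKey <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(chain = vapply(parts, `[`, "", 1L),
             resSeq = as.integer(vapply(parts, `[`, "", 2L)),
             icode = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
             stringsAsFactors = FALSE)
}

.moiety <- function(resName) {
  ifelse(resName %in% .AMINO_ACIDS, "AMINO_ACID",
         ifelse(resName %in% .NUCLEOTIDES, "NUCLEOTIDE", "OTHER"))
}

.subsetOf <- function(moiety, atomName) {
  ifelse(moiety == "AMINO_ACID", ifelse(atomName %in% .AA_MAIN, "MAIN", "SIDE"),
         ifelse(moiety == "NUCLEOTIDE",
                ifelse(atomName %in% .NT_MAIN, "MAIN", "SIDE"),
                NA_character_))
}

# evaluate expr under a fixed RNG seed, restoring global RNG state after
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# construct a Structure from a raw atom table, deriving moiety/subset/resKey
.newStructure <- function(atoms, moleculeType) {
  if (nrow(atoms)) {
    atoms$moiety <- .moiety(atoms$resName)
    atoms$subset <- .subsetOf(atoms$moiety, atoms$atomName)
    atoms$resKey <- .resKey(atoms$chain, atoms$resSeq, atoms$icode)
  } else {
    atoms$moiety <- character(0)
    atoms$subset <- character(0)
    atoms$resKey <- character(0)
  }
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms[, .ATOM_COLUMNS], moleculeType = moleculeType)
}

.writeTsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}
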