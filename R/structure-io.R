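#' Read a PDB file into a Structure
#'
#' Thin convenience wrapper: [parsePdb()] followed by [assignRadii()].
#'
#' @param file path to a PDB-format file.
#' @param moleculeType `"protein"`, `"nucleic"` or `"complex"`.
#' @param ... passed on to [assignRadii()].
#' @return a [Structure-class].
#' @export
readStructure <- function(file, moleculeType = c("protein", "nucleic", "complex"),
                          ...) {
  moleculeType <- match.arg(moleculeType)
  assignRadii(parsePdb(readLines(file, warn = FALSE), moleculeType), ...)
}

#' Parse PDB-format text
#'
#' Reads ATOM/HETATM records of the fixed-column PDB format into a
#' [Structure-class].  Only heavy atoms are stored (hydrogens and
#' deuteriums are discarded), water residues (HOH, WAT, DOD) are dropped,
#' only the first MODEL of a multi-model file is kept, and alternate
#' locations other than blank or `'A'` are discarded.  Residues are
#' classified as amino acid, nucleotide or other by residue-name lookup;
#' unknown residue names are retained as `OTHER` with a warning.  Van der
#' Waals radii are left unassigned; call [assignRadii()].
#'
#' @param text PDB content: a character vector of lines, or one string.
#' @param moleculeType `"protein"`, `"nucleic"` or `"complex"`.
#' @return a [Structure-class].
#' @seealso [readStructure()], [writePdbWithBfactors()]
#' @export
parsePdb <- function(text, moleculeType = c("protein", "nucleic", "complex")) {
  moleculeType <- match.arg(moleculeType)
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  rec <- substr(text, 1, 6)
  # keep only the first MODEL block, if any
  endm <- which(rec == "ENDMDL")
  if (length(endm)) text <- text[seq_len(endm[1] - 1L)]
  rec <- substr(text, 1, 6)
  lines <- text[rec %in% c("ATOM  ", "HETATM")]
  if (!length(lines)) stop("no ATOM/HETATM records found in PDB input")
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  lines <- pad(lines, 80)
  fld <- function(a, b) trimws(substr(lines, a, b))
  atomName <- fld(13, 16)
  altLoc <- fld(17, 17)
  resName <- fld(18, 20)
  element <- fld(77, 78)
  # derive element from the atom name when columns 77-78 are blank
  noel <- element == ""
  if (any(noel)) {
    guess <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", atomName[noel])))
    element[noel] <- substr(guess, 1, 1)
    two <- guess %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA", "SE")
    # CA in an ATOM record is an alpha carbon, not calcium
    isatom <- substr(lines[noel], 1, 6) == "ATOM  "
    element[noel][two & !isatom] <- guess[two & !isatom]
  }
  element <- toupper(element)
  keep <- !(element %in% c("H", "D")) &
    !(resName %in% .WATERS) &
    (altLoc %in% c("", "A"))
  if (!any(keep)) stop("no heavy atoms left after filtering PDB input")
  atoms <- data.frame(
    chain = fld(22, 22)[keep],
    resSeq = as.integer(fld(23, 26)[keep]),
    icode = fld(27, 27)[keep],
    resName = resName[keep],
    atomName = atomName[keep],
    element = element[keep],
    x = as.numeric(fld(31, 38)[keep]),
    y = as.numeric(fld(39, 46)[keep]),
    z = as.numeric(fld(47, 54)[keep]),
    vdw = NA_real_,
    altLoc = altLoc[keep],
    occupancy = suppressWarnings(as.numeric(fld(55, 60)[keep])),
    stringsAsFactors = FALSE)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  unknown <- setdiff(unique(atoms$resName),
                     c(.AMINO_ACIDS, .NUCLEOTIDES))
  if (length(unknown))
    warning("unknown residue name(s) retained as OTHER: ",
            paste(unknown, collapse = ", "))
  .newStructure(atoms, moleculeType)
}

#' Van der Waals radius table
#'
#' The bundled per-element radius table (angstrom) used by
#' [assignRadii()]: C 1.70, N 1.55, O 1.52, P 1.80, S 1.80; any element
#' absent from the table falls back to the 1.80 angstrom default.  The
#' table is stored as a plain TSV under `inst/extdata/vdw_radii.tsv` and
#' can be overridden per call.
#'
#' @return named numeric vector of radii by element symbol.
#' @export
vdwRadiusTable <- function() {
  f <- system.file("extdata", "vdw_radii.tsv", package = "cadscorer",
                   mustWork = TRUE)
  tab <- utils::read.delim(f, stringsAsFactors = FALSE)
  structure(tab$radius, names = tab$element)
}

#' Assign van der Waals radii
#'
#' Annotates every atom with its van der Waals radius from a per-element
#' table.  Elements missing from the table get the default radius with a
#' warning.
#'
#' @param structure a [Structure-class].
#' @param table named numeric vector of radii by element; defaults to
#'   [vdwRadiusTable()].
#' @param default fallback radius in angstrom for unlisted elements.
#' @return the structure with `vdw` filled in.
#' @export
assignRadii <- function(structure, table = vdwRadiusTable(), default = 1.8) {
  a <- structure@atoms
  if (nrow(a) == 0L) return(structure)
  r <- unname(table[a$element])
  if (anyNA(r)) {
    warning("element(s) without tabulated radius, using default ",
            default, " A: ",
            paste(unique(a$element[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- default
  }
  a$vdw <- r
  structure@atoms <- a
  validObject(structure)
  structure
}

#' Check target/model correspondence
#'
#' Verifies that residue numbering, chain naming and (by default) the
#' residue sequence of a model are consistent with the target.  Residues
#' are matched by chain + residue number + insertion code.  Residues
#' present in only one structure are reported as notes and ignored for
#' scoring; a residue-name disagreement at a shared identifier is a
#' sequence mismatch, which makes the verdict negative unless
#' `allowSeqMismatch = TRUE` (useful e.g. for native structure vs point
#' mutant).  Having no shared residues at all is a fatal error.
#'
#' @param target,model [Structure-class] objects.
#' @param allowSeqMismatch tolerate residue-name mismatches at shared ids.
#' @return a [ConsistencyReport-class].
#' @export
checkConsistency <- function(target, model, allowSeqMismatch = FALSE) {
  tres <- unique(target@atoms[, c("resKey", "resName")])
  mres <- unique(model@atoms[, c("resKey", "resName")])
  if (anyDuplicated(tres$resKey) || anyDuplicated(mres$resKey)) {
    dup <- c(tres$resKey[duplicated(tres$resKey)],
             mres$resKey[duplicated(mres$resKey)])
    return(new("ConsistencyReport", ok = FALSE, shared = character(0),
               mismatches = data.frame(resKey = character(0),
                                       targetRes = character(0),
                                       modelRes = character(0)),
               errors = paste("duplicated residue identifier:", unique(dup)),
               notes = character(0)))
  }
  shared <- intersect(tres$resKey, mres$resKey)
  errors <- character(0)
  notes <- character(0)
  if (!length(shared))
    errors <- c(errors,
                "no residues shared between target and model (chain naming or numbering mismatch)")
  tonly <- setdiff(tres$resKey, mres$resKey)
  monly <- setdiff(mres$resKey, tres$resKey)
  if (length(tonly))
    notes <- c(notes, paste0(length(tonly),
                             " target residue(s) absent from the model (their contacts count as fully lost): ",
                             paste(utils::head(tonly, 5), collapse = ", "),
                             if (length(tonly) > 5) ", ..." else ""))
  if (length(monly))
    notes <- c(notes, paste0(length(monly),
                             " model residue(s) absent from the target (ignored for scoring): ",
                             paste(utils::head(monly, 5), collapse = ", "),
                             if (length(monly) > 5) ", ..." else ""))
  tn <- structure(tres$resName, names = tres$resKey)
  mn <- structure(mres$resName, names = mres$resKey)
  dif <- shared[tn[shared] != mn[shared]]
  mismatches <- data.frame(resKey = dif, targetRes = unname(tn[dif]),
                           modelRes = unname(mn[dif]),
                           stringsAsFactors = FALSE)
  ok <- length(errors) == 0L && (nrow(mismatches) == 0L || allowSeqMismatch)
  new("ConsistencyReport", ok = ok, shared = shared, mismatches = mismatches,
      errors = errors, notes = notes)
}

#' Write a structure as PDB with per-residue B-factors
#'
#' Encodes per-residue values (typically normalized local errors in [0,1])
#' into the B-factor column: every atom of a residue carries the residue's
#' value scaled by 100 (so 0.25 prints as 25.00).  Residues missing from
#' the mapping get the worst value 1.0.  The output round-trips through
#' [parsePdb()] with identical identifiers and coordinates.
#'
#' @param structure a [Structure-class].
#' @param values named numeric vector in [0,1], names are residue keys
#'   (`residueKeys(structure)`).
#' @param file optional path; when given the text is also written there.
#' @return PDB-format text as a character vector of lines (invisibly when
#'   `file` is given).
#' @export
writePdbWithBfactors <- function(structure, values = numeric(0), file = NULL) {
  a <- structure@atoms
  if (length(values)) {
    if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
      stop("per-residue values must be finite and within [0,1]")
  }
  out <- "REMARK   B-factor column encodes per-residue values scaled by 100"
  if (nrow(a)) {
    v <- rep(1, nrow(a))
    hit <- match(a$resKey, names(values))
    v[!is.na(hit)] <- values[hit[!is.na(hit)]]
    name4 <- ifelse(nchar(a$atomName) >= 4L, substr(a$atomName, 1, 4),
                    sprintf(" %-3s", a$atomName))
    lines <- sprintf(
      "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(a$moiety == "OTHER", "HETATM", "ATOM"),
      seq_len(nrow(a)), name4, a$altLoc, a$resName, a$chain, a$resSeq,
      a$icode, a$x, a$y, a$z, a$occupancy, v * 100,
      formatC(a$element, width = 2))
    out <- c(out, lines)
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
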