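#' @import methods
NULL

.ATOM_COLUMNS <- c("chain", "resSeq", "icode", "resName", "atomName",
                   "element", "x", "y", "z", "vdw", "altLoc", "occupancy",
                   "moiety", "subset", "resKey")

.VARIANTS <- c("A-A", "A-M", "A-S", "M-M", "M-S", "S-S",
               "S-S-stacking", "S-S-non-stacking")

.MOLECULE_TYPES <- c("protein", "nucleic", "complex")

#' Macromolecular structure
#'
#' Ordered collection of heavy atoms grouped into residues and chains, with
#' van der Waals radii and atom-subset labels (main chain / side chain for
#' amino acids, backbone / base for nucleotides).  Created by [parsePdb()],
#' [readStructure()] or the synthetic generators ([makeToyPeptide()],
#' [makeToyDuplex()], [makeTwoAtomSystem()]).
#'
#' @slot atoms data.frame with one row per heavy atom: chain, resSeq, icode,
#'   resName, atomName, element, x, y, z (angstrom), vdw (angstrom), altLoc,
#'   occupancy, moiety (`"AMINO_ACID"`, `"NUCLEOTIDE"` or `"OTHER"`),
#'   subset (`"MAIN"`, `"SIDE"` or `NA` for OTHER residues) and resKey
#'   (internal residue identifier `"chain|resSeq|icode"`).
#' @slot moleculeType `"protein"`, `"nucleic"` or `"complex"`.
#'
#' @exportClass Structure
setClass("Structure",
         representation(atoms = "data.frame", moleculeType = "character"))

setValidity("Structure", function(object) {
  msgs <- character(0)
  if (!all(.ATOM_COLUMNS %in% names(object@atoms)))
    msgs <- c(msgs, paste("atoms must have columns:",
                          paste(.ATOM_COLUMNS, collapse = ", ")))
  if (length(object@moleculeType) != 1L ||
      !object@moleculeType %in% .MOLECULE_TYPES)
    msgs <- c(msgs, "moleculeType must be one of 'protein', 'nucleic', 'complex'")
  if (nrow(object@atoms) > 0L) {
    if (any(object@atoms$element %in% c("H", "D")))
      msgs <- c(msgs, "hydrogen/deuterium atoms must not be stored")
    if (any(!is.na(object@atoms$vdw) & object@atoms$vdw <= 0))
      msgs <- c(msgs, "assigned vdw radii must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' Residue-level contact inventory
#'
#' All directed residue-level contact areas of one structure, produced by
#' [aggregateResidueContacts()] (or the convenience wrapper
#' [computeContactInventory()]).  Each row of `contacts` is a directed
#' contribution: source residue, sink residue (or the literal `"solvent"`),
#' the atom-subset classes on both sides, an optional base-stacking flag,
#' and the contact area in square angstroms.  Query per-variant areas with
#' [variantAreas()]; a pair absent from the inventory has area 0.
#'
#' @slot structure the [Structure-class] the inventory was computed from.
#' @slot contacts data.frame: src, snk, srcChain, snkChain, srcSubset,
#'   snkSubset, stacking (logical, `NA` unless both residues are
#'   nucleotides), area.
#' @slot waterRadius water probe radius used (angstrom).
#' @slot samplingDensity sample points per contact sphere.
#'
#' @exportClass ContactInventory
setClass("ContactInventory",
         representation(structure = "Structure", contacts = "data.frame",
                        waterRadius = "numeric", samplingDensity = "numeric"))

setValidity("ContactInventory", function(object) {
  msgs <- character(0)
  need <- c("src", "snk", "srcChain", "snkChain", "srcSubset", "snkSubset",
            "stacking", "area")
  if (!all(need %in% names(object@contacts)))
    msgs <- c(msgs, paste("contacts must have columns:",
                          paste(need, collapse = ", ")))
  else {
    if (any(object@contacts$area < 0)) msgs <- c(msgs, "areas must be >= 0")
    bad <- object@contacts$src == object@contacts$snk
    if (any(bad)) msgs <- c(msgs, "self-contacts are not allowed")
  }
  if (object@waterRadius < 0) msgs <- c(msgs, "waterRadius must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Per-variant score report
#'
#' Result of scoring one model against one target for a single CAD-score
#' variant: the global score and per-residue local error profile (raw delta
#' in square angstroms and normalized epsilon in [0,1], each smoothed with
#' sequence windows w = 0..3).  A variant whose reference contact set is
#' empty carries status `"undefined"` and an `NA` score.
#'
#' @slot variant one of `"A-A"`, `"A-M"`, `"A-S"`, `"M-M"`, `"M-S"`,
#'   `"S-S"`, `"S-S-stacking"`, `"S-S-non-stacking"`.
#' @slot status `"ok"` or `"undefined"`.
#' @slot globalScore numeric in [0,1], `NA` when undefined.
#' @slot profile data.frame with one row per target residue: chain, resSeq,
#'   icode, resKey, analyzed, delta, targetSum, epsilon, and smoothed
#'   columns delta_w0..delta_w3, epsilon_w0..epsilon_w3.
#' @slot nContacts number of directed pairs in the reference set G.
#'
#' @exportClass ScoreReport
setClass("ScoreReport",
         representation(variant = "character", status = "character",
                        globalScore = "numeric", profile = "data.frame",
                        nContacts = "integer"))

setValidity("ScoreReport", function(object) {
  msgs <- character(0)
  if (!object@variant %in% .VARIANTS)
    msgs <- c(msgs, "unknown variant")
  if (!object@status %in% c("ok", "undefined"))
    msgs <- c(msgs, "status must be 'ok' or 'undefined'")
  gs <- object@globalScore
  if (object@status == "ok" &&
      (length(gs) != 1L || is.na(gs) || gs < 0 || gs > 1))
    msgs <- c(msgs, "globalScore must lie in [0,1] when status is 'ok'")
  if (length(msgs)) msgs else TRUE
})

#' Two-group residue selection
#'
#' A parsed selection that defines which residue--residue contacts form the
#' reference set G: the whole structure, the inter-chain interface
#' (optionally extended with intra-chain contacts among interface
#' residues), or a custom pair of residue groups parsed from a selection
#' string such as `"(A1-A9,A21-A90)(B1-B90)"` (see [parseSelection()]).
#'
#' @slot mode `"whole"`, `"interface"`, `"interface-plus-intra"` or
#'   `"custom"`.
#' @slot group1,group2 data.frames (chain, from, to); `NA` endpoints select
#'   the whole chain.  Empty for the implicit modes.
#'
#' @exportClass SelectionSpec
setClass("SelectionSpec",
         representation(mode = "character", group1 = "data.frame",
                        group2 = "data.frame"))

setValidity("SelectionSpec", function(object) {
  ok <- c("whole", "interface", "interface-plus-intra", "custom")
  if (length(object@mode) != 1L || !object@mode %in% ok)
    return("mode must be one of 'whole', 'interface', 'interface-plus-intra', 'custom'")
  if (object@mode == "custom" &&
      (nrow(object@group1) == 0L || nrow(object@group2) == 0L))
    return("custom selections need two non-empty residue groups")
  TRUE
})

#' Target/model correspondence report
#'
#' Diagnostic result of [checkConsistency()]: residues are matched by
#' chain, residue number and insertion code; residue-name disagreements at
#' shared identifiers are mismatches (tolerated only when requested), and
#' structural problems that break the correspondence are fatal errors.
#' Residues present in only one structure are non-fatal notes: they are
#' ignored for scoring (a residue missing from the model simply loses all
#' its contacts).
#'
#' @slot ok logical verdict.
#' @slot shared residue keys present in both structures.
#' @slot mismatches data.frame (resKey, targetRes, modelRes).
#' @slot errors fatal diagnostics (character).
#' @slot notes non-fatal diagnostics (character).
#'
#' @exportClass ConsistencyReport
setClass("ConsistencyReport",
         representation(ok = "logical", shared = "character",
                        mismatches = "data.frame", errors = "character",
                        notes = "character"))

#' Full comparison result
#'
#' Result of [cadScore()]: one [ScoreReport-class] per applicable variant,
#' together with the two contact inventories, the selection and the
#' consistency report.
#'
#' @slot reports named list of [ScoreReport-class] objects.
#' @slot targetInventory,modelInventory the two [ContactInventory-class]
#'   objects.
#' @slot selection the [SelectionSpec-class] used.
#' @slot consistency the [ConsistencyReport-class].
#'
#' @exportClass CadScoreResult
setClass("CadScoreResult",
         representation(reports = "list", targetInventory = "ContactInventory",
                        modelInventory = "ContactInventory",
                        selection = "SelectionSpec",
                        consistency = "ConsistencyReport"))
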