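#' Accessors for structure and result objects
#'
#' `atoms()` returns the per-atom table of a [Structure-class];
#' `moleculeType()` its declared molecule type; `residueKeys()` the ordered
#' unique residue identifiers (`"chain|resSeq|icode"`); `nResidues()` their
#' count.  `contacts()` returns the contact table of a
#' [ContactInventory-class].  `reports()` returns the per-variant
#' [ScoreReport-class] list of a [CadScoreResult-class]; `globalScore()`
#' the global score of a report (or a named vector across a result's
#' variants); `profile()` the per-residue error profile.
#'
#' @param x object to access.
#' @return See details above.
#' @name accessors
#' @rdname accessors
#' @aliases atoms moleculeType residueKeys nResidues contacts reports
#'   globalScore profile
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("moleculeType", function(x) standardGeneric("moleculeType"))

#' @rdname accessors
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' @rdname accessors
#' @export
setGeneric("reports", function(x) standardGeneric("reports"))

#' @rdname accessors
#' @export
setGeneric("globalScore", function(x) standardGeneric("globalScore"))

#' @rdname accessors
#' @export
setGeneric("profile", function(x) standardGeneric("profile"))

#' @rdname accessors
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("moleculeType", "Structure", function(x) x@moleculeType)

#' @rdname accessors
#' @export
setMethod("residueKeys", "Structure", function(x) unique(x@atoms$resKey))

#' @rdname accessors
#' @export
setMethod("nResidues", "Structure", function(x) length(residueKeys(x)))

#' @rdname accessors
#' @export
setMethod("contacts", "ContactInventory", function(x) x@contacts)

#' @rdname accessors
#' @export
setMethod("reports", "CadScoreResult", function(x) x@reports)

#' @rdname accessors
#' @export
setMethod("globalScore", "ScoreReport", function(x) x@globalScore)

#' @rdname accessors
#' @export
setMethod("globalScore", "CadScoreResult", function(x)
  vapply(x@reports, function(r) r@globalScore, numeric(1)))

#' @rdname accessors
#' @export
setMethod("profile", "ScoreReport", function(x) x@profile)

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure (", object@moleculeType, "): ",
      length(unique(a$chain)), " chain(s), ",
      length(unique(a$resKey)), " residue(s), ",
      nrow(a), " heavy atom(s)\n", sep = "")
  if (nrow(a)) {
    ch <- split(a$resKey, a$chain)
    for (nm in names(ch))
      cat("  chain ", nm, ": ", length(unique(ch[[nm]])), " residue(s)\n",
          sep = "")
  }
})

setMethod("show", "ContactInventory", function(object) {
  cc <- object@contacts
  inter <- cc[cc$snk != "solvent", , drop = FALSE]
  cat("ContactInventory: ", nrow(inter), " directed residue contact row(s), ",
      sum(cc$snk == "solvent"), " solvent row(s)\n",
      "  water probe ", object@waterRadius, " A, ",
      object@samplingDensity, " sample points per sphere\n", sep = "")
})

setMethod("show", "ScoreReport", function(object) {
  cat("ScoreReport [", object@variant, "]: ", sep = "")
  if (object@status == "undefined") {
    cat("undefined (empty reference contact set)\n")
  } else {
    cat(sprintf("global score %.4f over %d directed contact(s)\n",
                object@globalScore, object@nContacts))
  }
})

setMethod("show", "CadScoreResult", function(object) {
  cat("CadScoreResult (mode: ", object@selection@mode, ")\n", sep = "")
  for (r in object@reports) {
    cat("  ", format(r@variant, width = 17), " ",
        if (r@status == "undefined") "n/a"
        else sprintf("%.4f", r@globalScore), "\n", sep = "")
  }
})

setMethod("show", "ConsistencyReport", function(object) {
  cat("ConsistencyReport: ", if (object@ok) "OK" else "NOT OK",
      " (", length(object@shared), " shared residue(s), ",
      nrow(object@mismatches), " sequence mismatch(es), ",
      length(object@errors), " error(s))\n", sep = "")
  for (e in object@errors) cat("  error: ", e, "\n", sep = "")
  for (n in object@notes) cat("  note: ", n, "\n", sep = "")
})

setMethod("show", "SelectionSpec", function(object) {
  cat("SelectionSpec: mode ", object@mode, "\n", sep = "")
  if (object@mode == "custom") {
    fmt <- function(g) paste(ifelse(is.na(g$from), g$chain,
                                    paste0(g$chain, g$from, "-", g$chain, g$to)),
                             collapse = ",")
    cat("  group1: ", fmt(object@group1), "\n  group2: ", fmt(object@group2),
        "\n", sep = "")
  }
})
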