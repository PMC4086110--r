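#' Attach model areas to a reference contact set
#'
#' Looks up each directed pair of the reference set G in the model
#' inventory under the same variant; pairs absent from the model read as
#' area 0.
#'
#' @param G reference set from [buildReferenceSet()] (columns src, snk,
#'   target).
#' @param modelInventory the model's [ContactInventory-class].
#' @param variant variant name.
#' @return `G` with a `model` column added.
#' @export
attachModelAreas <- function(G, modelInventory, variant) {
  mv <- variantAreas(modelInventory, variant)
  hit <- match(paste(G$src, G$snk, sep = "\r"),
               paste(mv$src, mv$snk, sep = "\r"))
  G$model <- ifelse(is.na(hit), 0, mv$area[hit])
  G
}

.boundedDiff <- function(target, model) pmin(abs(target - model), target)

#' Global CAD-score
#'
#' The Contact Area Difference score over a reference contact set G drawn
#' from the target:
#' `1 - sum(min(|T - M|, T)) / sum(T)` over the directed pairs of G.
#' Bounding each per-pair difference by the target area keeps the score
#' within [0,1]: a score of 1 means identical contacts, 0 means every
#' target contact is entirely lost (or overshot by at least its own
#' area).  An empty G leaves the score undefined and raises an error of
#' class `"cadscorer_undefined_score"`.
#'
#' @param G data.frame with columns `target` and `model` (see
#'   [buildReferenceSet()] and [attachModelAreas()]).
#' @return numeric score in [0,1].
#' @export
globalCadScore <- function(G) {
  if (!nrow(G))
    stop(structure(class = c("cadscorer_undefined_score", "error", "condition"),
                   list(message = "reference contact set is empty: score undefined",
                        call = sys.call(-1))))
  1 - sum(.boundedDiff(G$target, G$model)) / sum(G$target)
}

#' Raw per-residue local errors
#'
#' For every source residue i, the sum of bounded contact-area
#' differences over its outgoing pairs in G:
#' `delta(i) = sum_j min(|T_ij - M_ij|, T_ij)`, in square angstroms.
#' Residues with no outgoing pair in G get `delta = 0` and are flagged as
#' not analyzed.
#'
#' @inheritParams globalCadScore
#' @param residues residue keys to report on (default: all source
#'   residues occurring in G).
#' @return data.frame: resKey, delta, targetSum (`sum_j T_ij`), analyzed.
#' @export
localErrorsRaw <- function(G, residues = NULL) {
  if (is.null(residues)) residues <- unique(G$src)
  d <- rowsum(.boundedDiff(G$target, G$model), G$src)
  ts <- rowsum(G$target, G$src)
  hit <- match(residues, rownames(d))
  out <- data.frame(resKey = residues,
                    delta = ifelse(is.na(hit), 0, d[hit, 1L]),
                    targetSum = ifelse(is.na(hit), 0, ts[hit, 1L]),
                    stringsAsFactors = FALSE)
  out$analyzed <- out$targetSum > 0
  out
}

#' Normalized per-residue local errors
#'
#' Divides each raw local error by the residue's total target contact
#' area: `epsilon(i) = delta(i) / sum_j T_ij`, in [0,1].  Residues with
#' zero target contact sum are not analyzed and get `NA`.
#'
#' @param raw output of [localErrorsRaw()].
#' @return `raw` with an `epsilon` column added.
#' @export
localErrorsNormalized <- function(raw) {
  raw$epsilon <- ifelse(raw$analyzed, raw$delta / raw$targetSum, NA_real_)
  raw
}

#' Smooth local errors along the sequence
#'
#' Sequence-window smoothing of per-residue errors with `w` residues on
#' each side: the smoothed raw error is the window mean of `delta`, and
#' the smoothed normalized error is the window's ratio of sums,
#' `sum(delta) / sum(targetSum)` (not a mean of per-residue ratios).
#' Windows never cross chain boundaries; at chain termini the window
#' truncates to the residues that exist and denominators use the actual
#' residue count and actual area sums.  Residues that are not analyzed
#' are excluded from the sums and receive `NA`.
#'
#' @param delta,targetSum numeric vectors in residue sequence order.
#' @param chain chain identifier per residue (defines boundaries).
#' @param w non-negative window half-width (0 returns the input values).
#' @param analyzed logical per residue; defaults to `targetSum > 0`.
#' @return list with vectors `delta_w` and `epsilon_w`.
#' @export
smoothErrors <- function(delta, targetSum, chain, w, analyzed = targetSum > 0) {
  if (length(w) != 1L || is.na(w) || w < 0)
    stop("w must be a non-negative integer")
  w <- as.integer(w)
  n <- length(delta)
  dw <- rep(NA_real_, n)
  ew <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!analyzed[i]) next
    win <- max(1L, i - w):min(n, i + w)
    win <- win[chain[win] == chain[i] & analyzed[win]]
    dw[i] <- mean(delta[win])
    ew[i] <- sum(delta[win]) / sum(targetSum[win])
  }
  list(delta_w = dw, epsilon_w = ew)
}

#' Per-residue error profile
#'
#' Computes the full local error profile of a scored contact set over the
#' target structure's residues: raw and normalized errors plus their
#' smoothed versions at windows w = 0, 1, 2, 3.
#'
#' @inheritParams globalCadScore
#' @param structure the target [Structure-class] (defines residue order
#'   and chain boundaries).
#' @return data.frame with one row per target residue.
#' @export
residueProfile <- function(G, structure) {
  keys <- residueKeys(structure)
  ids <- .splitKey(keys)
  raw <- localErrorsNormalized(localErrorsRaw(G, residues = keys))
  out <- data.frame(chain = ids$chain, resSeq = ids$resSeq, icode = ids$icode,
                    resKey = keys, analyzed = raw$analyzed,
                    delta = raw$delta, targetSum = raw$targetSum,
                    epsilon = raw$epsilon, stringsAsFactors = FALSE)
  for (w in 0:3) {
    sm <- smoothErrors(out$delta, out$targetSum, out$chain, w, out$analyzed)
    out[[paste0("delta_w", w)]] <- sm$delta_w
    out[[paste0("epsilon_w", w)]] <- sm$epsilon_w
  }
  out
}

.emptyProfile <- function(structure) {
  keys <- residueKeys(structure)
  ids <- .splitKey(keys)
  out <- data.frame(chain = ids$chain, resSeq = ids$resSeq, icode = ids$icode,
                    resKey = keys, analyzed = rep(FALSE, length(keys)),
                    delta = NA_real_, targetSum = 0, epsilon = NA_real_,
                    stringsAsFactors = FALSE)
  for (w in 0:3) {
    out[[paste0("delta_w", w)]] <- NA_real_
    out[[paste0("epsilon_w", w)]] <- NA_real_
  }
  out
}

#' Score one variant
#'
#' Builds the reference set for one variant under a selection, attaches
#' model areas and evaluates the global score and the local error
#' profile.  An empty reference set yields a report with status
#' `"undefined"` rather than an error.
#'
#' @param targetInventory,modelInventory [ContactInventory-class] objects.
#' @param variant variant name.
#' @param selection a [SelectionSpec-class] (default: whole structure).
#' @return a [ScoreReport-class].
#' @export
scoreVariant <- function(targetInventory, modelInventory, variant,
                         selection = wholeSelection()) {
  G <- buildReferenceSet(targetInventory, selection, variant)
  st <- targetInventory@structure
  if (!nrow(G))
    return(new("ScoreReport", variant = variant, status = "undefined",
               globalScore = NA_real_, profile = .emptyProfile(st),
               nContacts = 0L))
  G <- attachModelAreas(G, modelInventory, variant)
  new("ScoreReport", variant = variant, status = "ok",
      globalScore = globalCadScore(G), profile = residueProfile(G, st),
      nContacts = nrow(G))
}

#' Score all applicable variants
#'
#' One [ScoreReport-class] per variant applicable to the target's
#' molecule type (six subset variants for proteins and complexes, eight
#' for nucleic acids including the stacking split of base-base
#' contacts).  Variants with an empty reference set are reported as
#' undefined, not omitted.
#'
#' @inheritParams scoreVariant
#' @param variants optional subset of variant names.
#' @return named list of [ScoreReport-class] objects.
#' @export
scoreAllVariants <- function(targetInventory, modelInventory,
                             selection = wholeSelection(), variants = NULL) {
  if (is.null(variants))
    variants <- applicableVariants(targetInventory@structure@moleculeType)
  out <- lapply(variants, function(v)
    scoreVariant(targetInventory, modelInventory, v, selection))
  names(out) <- variants
  out
}

#' Compare a model structure against a target
#'
#' End-to-end CAD-score evaluation: verifies target/model correspondence,
#' computes both contact inventories, builds the reference contact set
#' under the requested evaluation mode, and scores every applicable
#' variant globally and per residue.
#'
#' @param target,model [Structure-class] objects with radii assigned (the
#'   first argument defines the reference contact set G; the score is
#'   deliberately asymmetric).
#' @param selection a [SelectionSpec-class]: [wholeSelection()] (default),
#'   [interfaceSelection()] or [parseSelection()].
#' @param variants optional subset of variant names.
#' @param waterRadius water probe radius in angstrom.
#' @param samplingDensity sample points per contact sphere.
#' @param allowSeqMismatch tolerate residue-name mismatches (see
#'   [checkConsistency()]).
#' @return a [CadScoreResult-class].
#' @examples
#' t <- makeToyPeptide(10, seed = 1)
#' m <- perturbStructure(t, magnitude = 0.5, seed = 2)
#' res <- cadScore(t, m, samplingDensity = 500)
#' globalScore(res)
#' @export
cadScore <- function(target, model, selection = wholeSelection(),
                     variants = NULL, waterRadius = 1.4,
                     samplingDensity = 2000, allowSeqMismatch = FALSE) {
  cons <- checkConsistency(target, model, allowSeqMismatch)
  if (!cons@ok)
    stop("target/model consistency check failed:\n  ",
         paste(c(cons@errors,
                 if (nrow(cons@mismatches))
                   paste0("sequence mismatch at ", cons@mismatches$resKey, ": ",
                          cons@mismatches$targetRes, " vs ",
                          cons@mismatches$modelRes)),
               collapse = "\n  "))
  tin <- computeContactInventory(target, waterRadius, samplingDensity)
  min_ <- computeContactInventory(model, waterRadius, samplingDensity)
  new("CadScoreResult",
      reports = scoreAllVariants(tin, min_, selection, variants),
      targetInventory = tin, modelInventory = min_,
      selection = selection, consistency = cons)
}
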