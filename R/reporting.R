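#' Blue-white-red error color ramp
#'
#' Maps values in [0,1] to the local-error gradient: pure blue at 0
#' (good agreement), white at 0.5, pure red at 1 (poor agreement), with
#' linear interpolation in each half.  `NA` (not analyzed) maps to grey.
#'
#' @param values numeric vector in [0,1] (or `NA`).
#' @return numeric matrix with columns r, g, b in [0,1].
#' @export
errorColorRamp <- function(values) {
  v <- pmin(1, pmax(0, values))
  lo <- pmin(v, 0.5) * 2         # 0..1 over the blue->white half
  hi <- (pmax(v, 0.5) - 0.5) * 2 # 0..1 over the white->red half
  col <- cbind(r = lo, g = lo * (1 - hi) + (1 - lo) * 0, b = 1 - hi)
  col[, "g"] <- pmin(lo, 1 - hi)
  col[is.na(values), ] <- 0.5
  col
}

#' Sortable table of global scores
#'
#' One row per model.  The summary view has the `A-A`, `A-S` and `S-S`
#' columns (plus the stacking split for nucleic acids); `full = TRUE`
#' emits every computed variant, suitable for the flat-text export.
#' Undefined variants render as `"n/a"`.  Rows are plain data, sortable
#' by the caller on any column.
#'
#' @param results named list of [CadScoreResult-class] objects (names are
#'   model labels) or a single result.
#' @param full include all variants instead of the summary columns.
#' @param file optional TSV output path.
#' @return data.frame of formatted scores (model column first).
#' @export
renderGlobalTable <- function(results, full = FALSE, file = NULL) {
  if (is(results, "CadScoreResult")) results <- list(model = results)
  stopifnot(length(results) >= 1L)
  allv <- unique(unlist(lapply(results, function(r) names(r@reports))))
  cols <- if (full) allv
  else intersect(c("A-A", "A-S", "S-S", "S-S-stacking", "S-S-non-stacking"),
                 allv)
  rows <- lapply(names(results), function(nm) {
    rep <- results[[nm]]@reports
    vals <- vapply(cols, function(v) {
      if (!v %in% names(rep) || rep[[v]]@status == "undefined") "n/a"
      else sprintf("%.4f", rep[[v]]@globalScore)
    }, "")
    c(model = nm, vals)
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!is.null(file)) .writeTsv(out, file)
  out
}

.writeRaster <- function(rgb, file, cellSize = 8) {
  img <- array(0, dim = c(dim(rgb)[1] * cellSize, dim(rgb)[2] * cellSize, 3))
  for (k in 1:3)
    img[, , k] <- rgb[rep(seq_len(dim(rgb)[1]), each = cellSize),
                      rep(seq_len(dim(rgb)[2]), each = cellSize), k]
  png::writePNG(img, file)
}

#' Render a local-error profile
#'
#' One color cell per residue in sequence order, black separator columns
#' between chains.  Normalized errors use the fixed blue-white-red ramp
#' over [0,1]; raw errors are min-max scaled over the analyzed residues
#' before coloring.  Exact numeric values are available via
#' [writeProfileTable()].
#'
#' @param report a [ScoreReport-class].
#' @param w smoothing window (0, 1, 2 or 3).
#' @param raw render the raw (square-angstrom) errors instead of the
#'   normalized ones.
#' @param file optional PNG output path.
#' @param cellSize pixels per residue cell.
#' @return invisibly, a list with `values` and the `colors` matrix
#'   (one row of cells).
#' @export
renderProfile <- function(report, w = 0, raw = FALSE, file = NULL,
                          cellSize = 8) {
  stopifnot(w %in% 0:3)
  p <- report@profile
  vals <- p[[paste0(if (raw) "delta_w" else "epsilon_w", w)]]
  shown <- vals
  if (raw && !all(is.na(shown))) {
    rng <- range(shown, na.rm = TRUE)
    shown <- if (diff(rng) > 0) (shown - rng[1]) / diff(rng)
    else ifelse(is.na(shown), NA_real_, 0)
  }
  col <- errorColorRamp(shown)
  # black separator cells between chains
  newchain <- which(p$chain[-1] != p$chain[-nrow(p)])
  cells <- matrix(NA_real_, nrow = nrow(p) + length(newchain), ncol = 3)
  at <- seq_len(nrow(p)) + findInterval(seq_len(nrow(p)) - 1L, newchain)
  cells[at, ] <- col
  cells[-at, ] <- 0
  rgb <- array(0, dim = c(1, nrow(cells), 3))
  rgb[1, , ] <- cells
  if (!is.null(file)) .writeRaster(rgb, file, cellSize)
  invisible(list(values = vals, colors = col))
}

#' Write the per-residue profile values as TSV
#'
#' Plain-text twin of the profile images: residue identifiers, raw and
#' normalized errors at windows 0-3.
#'
#' @param report a [ScoreReport-class].
#' @param file output path.
#' @return the written data.frame, invisibly.
#' @export
writeProfileTable <- function(report, file) {
  .writeTsv(report@profile, file)
  invisible(report@profile)
}

#' Superimposed target/model contact map
#'
#' Square matrix over the analyzed residues in sequence order.  Cells
#' with no contact in either structure are black; otherwise the red and
#' green channels are proportional to the target and model contact areas
#' (scaled so the larger one has full intensity), so target-only
#' contacts are pure red, model-only pure green, and equal areas yellow.
#' Directed pairs fill both sides of the diagonal.
#'
#' @param targetInventory,modelInventory [ContactInventory-class] objects.
#' @param G reference set from [buildReferenceSet()] (defines the
#'   analyzed residues and the target areas).
#' @param variant variant used to look up model areas.
#' @param file optional PNG output path.
#' @param tsv optional path for the machine-readable table (i, j, T, M).
#' @param cellSize pixels per matrix cell.
#' @return invisibly, a list with the pair table and the color array.
#' @export
renderContactMap <- function(targetInventory, modelInventory, G,
                             variant = "A-A", file = NULL, tsv = NULL,
                             cellSize = 4) {
  resOrder <- residueKeys(targetInventory@structure)
  analyzed <- resOrder[resOrder %in% unique(c(G$src, G$snk))]
  mv <- variantAreas(modelInventory, variant)
  mv <- mv[mv$src %in% analyzed & mv$snk %in% analyzed, , drop = FALSE]
  key <- function(s, k) paste(s, k, sep = "\r")
  tk <- key(G$src, G$snk)
  mk <- key(mv$src, mv$snk)
  allk <- union(tk, mk)
  pairs <- data.frame(
    src = sub("\r.*$", "", allk), snk = sub("^.*\r", "", allk),
    target = ifelse(is.na(match(allk, tk)), 0, G$target[match(allk, tk)]),
    model = ifelse(is.na(match(allk, mk)), 0, mv$area[match(allk, mk)]),
    stringsAsFactors = FALSE)
  n <- length(analyzed)
  img <- array(0, dim = c(n, n, 3))
  i <- match(pairs$src, analyzed)
  j <- match(pairs$snk, analyzed)
  mx <- pmax(pairs$target, pairs$model)
  img[cbind(i, j, 1L)] <- pairs$target / mx
  img[cbind(i, j, 2L)] <- pairs$model / mx
  if (!is.null(file)) {
    big <- array(0, dim = c(n * cellSize, n * cellSize, 3))
    idx <- rep(seq_len(n), each = cellSize)
    for (k in 1:3) big[, , k] <- img[idx, idx, k]
    png::writePNG(big, file)
  }
  if (!is.null(tsv)) {
    s <- .splitKey(pairs$src)
    k2 <- .splitKey(pairs$snk)
    .writeTsv(data.frame(i = paste0(s$chain, s$resSeq, s$icode),
                         j = paste0(k2$chain, k2$resSeq, k2$icode),
                         target_area = pairs$target, model_area = pairs$model),
              tsv)
  }
  invisible(list(pairs = pairs, image = img, residues = analyzed))
}

#' Write the combined contacts file
#'
#' One row per directed pair of the reference set G: residue identifiers,
#' target and model areas and the bounded per-pair difference
#' `min(|T - M|, T)`; a totals row reproduces the global score.  An empty
#' reference set writes a header plus an `undefined` marker.
#'
#' @param G reference set with model areas attached (see
#'   [attachModelAreas()]), or a [ScoreReport-class]-compatible pair
#'   table with columns src, snk, target, model.
#' @param file output path.
#' @return the global score recomputed from the written rows (`NA` when
#'   undefined), invisibly.
#' @export
writeCombinedContacts <- function(G, file) {
  header <- "source\tsink\ttarget_area\tmodel_area\tbounded_difference"
  if (!nrow(G)) {
    writeLines(c(header, "# undefined: empty reference contact set"), file)
    return(invisible(NA_real_))
  }
  bd <- .boundedDiff(G$target, G$model)
  rows <- sprintf("%s\t%s\t%.9f\t%.9f\t%.9f", G$src, G$snk, G$target,
                  G$model, bd)
  score <- 1 - sum(bd) / sum(G$target)
  foot <- c(sprintf("TOTAL\t\t%.9f\t%.9f\t%.9f", sum(G$target), sum(G$model),
                    sum(bd)),
            sprintf("# global score: %.9f", score))
  writeLines(c(header, rows, foot), file)
  invisible(score)
}

#' Read back a combined contacts file and recompute the score
#'
#' @param file path written by [writeCombinedContacts()].
#' @return the recomputed global score (`NA` if the file is marked
#'   undefined).
#' @export
recomputeScoreFromCombined <- function(file) {
  lines <- readLines(file)
  if (any(grepl("^# undefined", lines))) return(NA_real_)
  body <- lines[-1]
  body <- body[!startsWith(body, "#") & !startsWith(body, "TOTAL")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  target <- vapply(parts, function(p) as.numeric(p[3]), 0)
  bd <- vapply(parts, function(p) as.numeric(p[5]), 0)
  1 - sum(bd) / sum(target)
}
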