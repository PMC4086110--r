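#' Built-in evaluation modes
#'
#' `wholeSelection()` selects every residue-residue contact in the target.
#' `interfaceSelection()` restricts the reference set to contacts between
#' residues of different chains; with `includeIntra = TRUE` it is extended
#' by same-chain contacts where both residues are interface residues (a
#' residue is an interface residue iff it has at least one inter-chain
#' contact with positive target area) -- the interface residue set itself
#' is identical in both cases, only the contact reference sets differ.
#'
#' @param includeIntra extend the interface set with intra-chain contacts
#'   among interface residues.
#' @return a [SelectionSpec-class].
#' @export
wholeSelection <- function() {
  g <- data.frame(chain = character(0), from = integer(0), to = integer(0))
  new("SelectionSpec", mode = "whole", group1 = g, group2 = g)
}

#' @rdname wholeSelection
#' @export
interfaceSelection <- function(includeIntra = FALSE) {
  g <- data.frame(chain = character(0), from = integer(0), to = integer(0))
  new("SelectionSpec",
      mode = if (includeIntra) "interface-plus-intra" else "interface",
      group1 = g, group2 = g)
}

#' Parse a custom selection string
#'
#' Parses the two-group selection notation: two parenthesized
#' comma-separated lists of items, each item either a bare chain name
#' (`"A"`), a residue range (`"A1-A9"`, endpoints inclusive and on the
#' same chain) or a single residue (`"A5"`, equivalent to `"A5-A5"`).
#' Examples: `"(A)(B)"` -- contacts between chains A and B;
#' `"(A,B)(C)"` -- contacts of chains A and B with C; `"(A)(A)"` --
#' contacts within chain A; `"(A1-A9,A21-A90)(B1-B90)"` -- contacts
#' between two explicit residue groups.  Parsing is case-sensitive;
#' malformed input raises an error naming the offending position.
#'
#' @param text the selection string.
#' @return a [SelectionSpec-class] with mode `"custom"`.
#' @export
parseSelection <- function(text) {
  if (length(text) != 1L || !nzchar(text))
    stop("selection string must be a single non-empty string")
  m <- regmatches(text, regexec("^\\(([^()]*)\\)\\(([^()]*)\\)$", text))[[1]]
  if (length(m) != 3L)
    stop("malformed selection '", text,
         "': expected two parenthesized groups like (A)(B)")
  parseGroup <- function(s, which) {
    items <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    items <- items[nzchar(items)]
    if (!length(items))
      stop("empty group ", which, " in selection '", text, "'")
    rows <- lapply(seq_along(items), function(k) {
      it <- items[k]
      where <- paste0("group ", which, ", item ", k, " ('", it, "')")
      if (grepl("^[A-Za-z]+$", it))
        return(data.frame(chain = it, from = NA_integer_, to = NA_integer_,
                          stringsAsFactors = FALSE))
      mm <- regmatches(it, regexec("^([A-Za-z]+)([0-9]+)(-([A-Za-z]+)([0-9]+))?$",
                                   it))[[1]]
      if (!length(mm))
        stop("cannot parse selection item at ", where)
      ch1 <- mm[2]
      from <- as.integer(mm[3])
      if (mm[4] == "") {
        to <- from
      } else {
        if (mm[5] != ch1)
          stop("range endpoints on different chains at ", where)
        to <- as.integer(mm[6])
        if (to < from)
          stop("reversed residue range at ", where)
      }
      data.frame(chain = ch1, from = from, to = to, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  new("SelectionSpec", mode = "custom",
      group1 = parseGroup(m[2], 1L), group2 = parseGroup(m[3], 2L))
}

# resolve a group (chain / residue-range rows) to residue keys of a structure
.resolveGroup <- function(group, structure) {
  a <- unique(structure@atoms[, c("chain", "resSeq", "resKey")])
  sel <- rep(FALSE, nrow(a))
  for (k in seq_len(nrow(group))) {
    g <- group[k, ]
    if (is.na(g$from)) sel <- sel | a$chain == g$chain
    else sel <- sel | (a$chain == g$chain & a$resSeq >= g$from & a$resSeq <= g$to)
  }
  unique(a$resKey[sel])
}

#' Build the reference contact set G
#'
#' Restricts the target's directed residue-pair areas for one variant to
#' the contacts selected by the evaluation mode: every pair (whole
#' structure), inter-chain pairs only (interface), interface pairs plus
#' same-chain pairs between interface residues (interface-plus-intra), or
#' pairs with one residue in each group of a custom selection (evaluated
#' symmetrically; `"(A)(A)"` selects the pairs within chain A).  Group
#' membership is resolved against the target structure.  A custom group
#' that matches no residue is an error; a selection that matches residues
#' but yields no contacts returns an empty set, which downstream scoring
#' reports as an undefined score.
#'
#' @param targetInventory the target's [ContactInventory-class].
#' @param selection a [SelectionSpec-class].
#' @param variant variant name.
#' @return data.frame of directed pairs: src, snk, target (area, > 0).
#' @export
buildReferenceSet <- function(targetInventory, selection = wholeSelection(),
                              variant = "A-A") {
  tv <- variantAreas(targetInventory, variant)
  keep <- switch(selection@mode,
    "whole" = rep(TRUE, nrow(tv)),
    "interface" = tv$srcChain != tv$snkChain,
    "interface-plus-intra" = {
      inter <- tv$srcChain != tv$snkChain
      ifres <- unique(c(tv$src[inter], tv$snk[inter]))
      inter | (tv$src %in% ifres & tv$snk %in% ifres)
    },
    "custom" = {
      g1 <- .resolveGroup(selection@group1, targetInventory@structure)
      g2 <- .resolveGroup(selection@group2, targetInventory@structure)
      if (!length(g1)) stop("selection group 1 matches no residue in the target")
      if (!length(g2)) stop("selection group 2 matches no residue in the target")
      (tv$src %in% g1 & tv$snk %in% g2) | (tv$src %in% g2 & tv$snk %in% g1)
    },
    stop("unknown selection mode: ", selection@mode))
  out <- tv[keep, c("src", "snk"), drop = FALSE]
  out$target <- tv$area[keep]
  rownames(out) <- NULL
  out
}

#' Interface residues of a reference set
#'
#' Residues carrying at least one inter-chain contact with positive
#' target area within a reference set.
#'
#' @param G output of [buildReferenceSet()].
#' @return character vector of residue keys.
#' @export
interfaceResidues <- function(G) {
  ids <- .splitKey(G$src)
  jds <- .splitKey(G$snk)
  inter <- ids$chain != jds$chain
  sort(unique(c(G$src[inter], G$snk[inter])))
}
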