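#' Place a cap hydrogen along a severed bond
#'
#' The hydrogen replacing removed atom j sits on the severed bond vector at
#' X_i + rho (X_j - X_i) with rho = (r_i + r_H) / (r_i + r_j): the cap bond
#' is the anchor's full bond scaled by the expected single-bond length
#' ratio. Removing a hydrogen gives rho = 1 and the cap coincides with X_j.
#'
#' @param anchor numeric length-3 position of the retained atom i, Angstrom.
#' @param removed numeric length-3 position of the removed atom j.
#' @param anchorElement,removedElement element symbols of i and j.
#' @param table covalent radii.
#' @return numeric length-3 cap position, Angstrom.
#' @examples
#' placeCap(c(0, 0, 0), c(1.54, 0, 0), "C", "C")  # C-H cap at 1.084 A
#' @export
placeCap <- function(anchor, removed, anchorElement, removedElement,
                     table = corderoRadii()) {
  anchor <- as.numeric(anchor); removed <- as.numeric(removed)
  if (sqrt(sum((removed - anchor)^2)) < 1e-8)
    stop("geometry error: anchor and removed atoms coincide")
  ri <- covalentRadius(anchorElement, table)
  rj <- covalentRadius(removedElement, table)
  rH <- covalentRadius("H", table)
  rho <- (ri + rH) / (ri + rj)
  anchor + rho * (removed - anchor)
}

# severed bonds (i kept, j removed) for one connected component of groups
.componentSeveredBonds <- function(graph, component) {
  out <- NULL
  for (key in names(graph@severedAtoms)) {
    ab <- as.integer(strsplit(key, "-", fixed = TRUE)[[1L]])
    inA <- ab[1L] %in% component; inB <- ab[2L] %in% component
    if (inA == inB) next
    pairs <- graph@severedAtoms[[key]]
    if (inA) out <- rbind(out, pairs)          # keep i, remove j
    else out <- rbind(out, pairs[, c(2L, 1L), drop = FALSE])
  }
  out
}

#' Realize a fragment as a capped molecule
#'
#' Collects the real atoms of the fragment's groups and adds one hydrogen
#' link atom per severed bond of each component (bonds leaving the
#' component's group set). Real atoms keep their original order; caps come
#' last. Components of nonbonded complexes are capped independently, which
#' coincides with capping against the whole fragment since components are
#' never adjacent.
#'
#' @param fragment a \linkS4class{SignedFragment}.
#' @param graph a \linkS4class{GroupGraph}.
#' @param table covalent radii.
#' @return a \linkS4class{CappedFragment}.
#' @examples
#' gg <- groupMolecule(generateLinearAlkane(7))
#' plan <- bondedPlan(gg, 3)
#' f234 <- fragments(plan, "bonded")[[5]]
#' elementFormula(realizeFragment(f234, gg)@elements)  # propane, C3H8
#' @export
realizeFragment <- function(fragment, graph, table = corderoRadii()) {
  stopifnot(is(fragment, "SignedFragment"), is(graph, "GroupGraph"))
  mol <- graph@molecule
  real <- sort(unlist(lapply(graph@groups[fragment@groups], function(g)
    c(g$heavy, g$hydrogens))))
  groupOfAtom <- integer(nAtoms(mol))
  for (g in fragment@groups)
    groupOfAtom[c(graph@groups[[g]]$heavy, graph@groups[[g]]$hydrogens)] <- g
  capAnchor <- integer(0); capReplaced <- integer(0)
  capXYZ <- NULL
  for (component in fragment@components) {
    sb <- .componentSeveredBonds(graph, component)
    for (r in seq_len(NROW(sb))) {
      i <- sb[r, 1L]; j <- sb[r, 2L]
      capAnchor <- c(capAnchor, i); capReplaced <- c(capReplaced, j)
      capXYZ <- rbind(capXYZ,
                      placeCap(mol@coords[i, ], mol@coords[j, ],
                               mol@elements[i], mol@elements[j], table))
    }
  }
  nc <- length(capAnchor)
  coords <- rbind(mol@coords[real, , drop = FALSE], capXYZ)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  new("CappedFragment",
      elements = c(mol@elements[real], rep("H", nc)),
      coords = coords,
      realAtoms = as.integer(real),
      realGroups = groupOfAtom[real],
      capAnchor = capAnchor, capReplaced = capReplaced,
      fragment = fragment)
}

#' Signed cap-hydrogen balance of a plan
#'
#' Sum over bonded fragments of coefficient times cap count. Chemical
#' balance requires the hydrogens added to +1 fragments to equal those
#' added to -1 fragments, so the result is 0 for every valid plan; a
#' nonzero value is raised as an error.
#'
#' @param plan a \linkS4class{FragmentationPlan}.
#' @param strict error on nonzero balance (default TRUE).
#' @return signed integer (0 for valid plans).
#' @export
capBalance <- function(plan, strict = TRUE) {
  stopifnot(is(plan, "FragmentationPlan"))
  total <- 0L
  for (f in plan@bonded) {
    sb <- .componentSeveredBonds(plan@graph, f@groups)
    total <- total + f@coefficient * NROW(sb)
  }
  if (strict && total != 0L)
    stop("plan invariant violated: signed cap balance is ", total,
         " (must be 0)")
  total
}

#' Per-fragment signed cap counts
#'
#' @param plan a \linkS4class{FragmentationPlan}.
#' @return data.frame with fragment key, coefficient and cap count for the
#'   bonded plan.
#' @export
capCountTable <- function(plan) {
  data.frame(
    fragment = vapply(plan@bonded, structureKey, ""),
    coefficient = vapply(plan@bonded, function(f) f@coefficient, 1L),
    caps = vapply(plan@bonded, function(f)
      NROW(.componentSeveredBonds(plan@graph, f@groups)), 1L),
    stringsAsFactors = FALSE)
}

#' Canonical structure key of a fragment or group set
#'
#' Groups within a component joined by \code{"+"}, components joined by
#' \code{"|"}: bonded \{2,3,4\} is \code{"2+3+4"}, the dimer of groups 1
#' and 5 is \code{"1|5"}, the 3BC of group 1 against edge \{4,5\} is
#' \code{"1|4+5"}. Distinct capped structures have distinct keys, so the
#' key doubles as the deduplication handle for monomer energies.
#'
#' @param x a \linkS4class{SignedFragment} or list of integer vectors
#'   (component partition).
#' @return character key.
#' @export
structureKey <- function(x) {
  comps <- if (is(x, "SignedFragment")) x@components else x
  paste(vapply(comps, function(s) paste(sort(s), collapse = "+"), ""),
        collapse = "|")
}
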