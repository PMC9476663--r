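#' Bond-perception tolerances constructor
#'
#' Defaults (deltaSB = 0.40, deltaDB = 0.05, deltaTB = 0.20 Angstrom) are
#' calibrated against textbook bond lengths with the Cordero radii: C-C
#' 1.54 A reads as single, aromatic C-C ~1.39 A and ethene 1.33 A as double,
#' acetylene 1.20 A as triple.
#'
#' @param deltaSB single-bond slack, Angstrom.
#' @param deltaDB double-bond tightening, Angstrom.
#' @param deltaTB triple-bond tightening, Angstrom.
#' @param deltaNB nonbonded cutoff, Angstrom (carried for configuration unity).
#' @return a \linkS4class{BondTolerances}.
#' @export
bondTolerances <- function(deltaSB = 0.40, deltaDB = 0.05,
                           deltaTB = 0.20, deltaNB = Inf) {
  new("BondTolerances", deltaSB = deltaSB, deltaDB = deltaDB,
      deltaTB = deltaTB, deltaNB = deltaNB)
}

#' Perceive bond orders from interatomic distances
#'
#' For atoms i, j at distance R with covalent radii r_i, r_j the bond order
#' is 1 if R < r_i + r_j + deltaSB, overwritten to 2 if
#' R < r_i + r_j - deltaDB and to 3 if R < r_i + r_j - deltaTB; otherwise 0.
#'
#' @param molecule a \linkS4class{Molecule}.
#' @param table named covalent-radius vector ([corderoRadii()] by default).
#' @param tol a \linkS4class{BondTolerances}.
#' @return symmetric integer matrix of bond orders in 0..3, zero diagonal.
#' @examples
#' eth <- Molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)))
#' perceiveBonds(eth)[1, 2]  # 1
#' @export
perceiveBonds <- function(molecule, table = corderoRadii(),
                          tol = bondTolerances()) {
  stopifnot(is(molecule, "Molecule"), is(tol, "BondTolerances"))
  n <- nAtoms(molecule)
  r <- covalentRadius(molecule@elements, table)
  R <- as.matrix(stats::dist(molecule@coords))
  if (n > 1L && min(R[upper.tri(R)]) < 0.1)
    stop("geometry error: atom pair closer than 0.1 Angstrom")
  rsum <- outer(r, r, "+")
  B <- matrix(0L, n, n)
  B[R < rsum + tol@deltaSB] <- 1L
  B[R < rsum - tol@deltaDB] <- 2L
  B[R < rsum - tol@deltaTB] <- 3L
  diag(B) <- 0L
  hh <- which(molecule@elements == "H")
  if (length(hh)) {
    deg <- rowSums(B[hh, , drop = FALSE] > 0L)
    if (any(deg > 1L))
      warning("hydrogen atom(s) ", paste(hh[deg > 1L], collapse = ", "),
              " bonded to more than one atom")
  }
  B
}

#' Partition atoms into fragmentation groups
#'
#' Heavy atoms are grouped as the connected components of the heavy-atom
#' graph restricted to bonds of order >= 2 (so every singly-bonded heavy
#' atom forms its own group, and e.g. an aromatic ring merges into one
#' group). Each hydrogen joins the group of a heavy atom it bonds to
#' (nearest on ties, then lowest atom index). Group ids follow first
#' occurrence of each group's lowest-index heavy atom.
#'
#' @param molecule a \linkS4class{Molecule}.
#' @param bonds bond-order matrix from [perceiveBonds()].
#' @return list of groups, each \code{list(heavy =, hydrogens =)} of 1-based
#'   atom indices.
#' @export
assignGroups <- function(molecule, bonds) {
  stopifnot(is(molecule, "Molecule"), nrow(bonds) == nAtoms(molecule))
  el <- molecule@elements
  heavy <- which(el != "H")
  if (!length(heavy))
    stop("assignment error: molecule has no heavy atoms")
  Bh <- (bonds[heavy, heavy, drop = FALSE] >= 2L) * 1L
  gh <- igraph::graph_from_adjacency_matrix(Bh, mode = "undirected")
  comp <- igraph::components(gh)$membership
  # relabel components by first occurrence of their lowest-index heavy atom
  ids <- match(comp, unique(comp))
  ng <- max(ids)
  groups <- lapply(seq_len(ng), function(g)
    list(heavy = heavy[ids == g], hydrogens = integer(0)))
  groupOfAtom <- integer(nAtoms(molecule))
  groupOfAtom[heavy] <- ids
  for (h in which(el == "H")) {
    nb <- which(bonds[h, ] >= 1L & el != "H")
    if (!length(nb))
      stop("assignment error: hydrogen atom ", h,
           " is bonded to no heavy atom")
    d <- sqrt(rowSums((molecule@coords[nb, , drop = FALSE] -
                       matrix(molecule@coords[h, ], length(nb), 3L,
                              byrow = TRUE))^2))
    pick <- nb[order(d, nb)][1L]
    g <- groupOfAtom[pick]
    groups[[g]]$hydrogens <- c(groups[[g]]$hydrogens, h)
  }
  iso <- which(vapply(groups, function(g)
    length(g$heavy) == 1L && all(bonds[g$heavy, ] == 0L), TRUE))
  if (length(iso))
    warning("group(s) ", paste(iso, collapse = ", "),
            " contain an unbonded heavy atom")
  groups
}

#' Build the group connectivity graph
#'
#' Two groups are adjacent when an order-1 bond joins a heavy atom of one to
#' a heavy atom of the other; those atom pairs are the severable bonds that
#' hydrogen caps will replace. The per-group cap count is the number of
#' severed bonds the group presents when isolated.
#'
#' @param molecule a \linkS4class{Molecule}.
#' @param bonds bond-order matrix from [perceiveBonds()].
#' @param groups group list from [assignGroups()].
#' @return a \linkS4class{GroupGraph}.
#' @export
buildGroupGraph <- function(molecule, bonds, groups) {
  ng <- length(groups)
  groupOfAtom <- integer(nAtoms(molecule))
  for (g in seq_len(ng))
    groupOfAtom[c(groups[[g]]$heavy, groups[[g]]$hydrogens)] <- g
  A <- matrix(0L, ng, ng)
  severed <- list()
  el <- molecule@elements
  idx <- which(bonds == 1L & upper.tri(bonds), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    if (el[i] == "H" || el[j] == "H") next
    a <- groupOfAtom[i]; b <- groupOfAtom[j]
    if (a == b) next
    if (a > b) { tmp <- a; a <- b; b <- tmp; tmp <- i; i <- j; j <- tmp }
    A[a, b] <- A[b, a] <- 1L
    key <- paste0(a, "-", b)
    severed[[key]] <- rbind(severed[[key]],
                            matrix(c(i, j), 1L, 2L,
                                   dimnames = list(NULL, c("i", "j"))))
  }
  caps <- integer(ng)
  for (key in names(severed)) {
    ab <- as.integer(strsplit(key, "-", fixed = TRUE)[[1L]])
    caps[ab[1L]] <- caps[ab[1L]] + nrow(severed[[key]])
    caps[ab[2L]] <- caps[ab[2L]] + nrow(severed[[key]])
  }
  # adjacency counts edges once per pair; cap counts include bond multiplicity
  new("GroupGraph", molecule = molecule, groups = groups, adjacency = A,
      severedAtoms = severed, capsPerGroup = caps)
}

#' Group a molecule in one call
#'
#' Convenience wrapper: [perceiveBonds()], [assignGroups()],
#' [buildGroupGraph()].
#'
#' @inheritParams perceiveBonds
#' @return a \linkS4class{GroupGraph}.
#' @export
groupMolecule <- function(molecule, table = corderoRadii(),
                          tol = bondTolerances()) {
  bonds <- perceiveBonds(molecule, table, tol)
  buildGroupGraph(molecule, bonds, assignGroups(molecule, bonds))
}

#' Bonded domain of a group
#'
#' The groups directly connected to \code{g} (excluding \code{g}).
#'
#' @param graph a \linkS4class{GroupGraph}.
#' @param g group id.
#' @return integer vector of group ids.
#' @export
bondedDomain <- function(graph, g) {
  stopifnot(is(graph, "GroupGraph"), g >= 1L, g <= nGroups(graph))
  which(graph@adjacency[g, ] == 1L)
}

#' Nonbonded domain of a group
#'
#' Groups that are neither \code{g} nor adjacent to it and pass the
#' nonbonded cutoff (closest-atom distance for DBE, minimum
#' distance-to-radius-sum ratio for DCRR).
#'
#' @param graph a \linkS4class{GroupGraph}.
#' @param g group id.
#' @param settings an \linkS4class{NBSettings}.
#' @param table covalent radii (used by DCRR).
#' @return integer vector of group ids.
#' @export
nonbondedDomain <- function(graph, g, settings = nbSettings(),
                            table = corderoRadii()) {
  stopifnot(is(graph, "GroupGraph"), is(settings, "NBSettings"))
  cand <- setdiff(which(graph@adjacency[g, ] == 0L), g)
  keep <- vapply(cand, function(b)
    nbWithinCutoff(graph, g, b, settings, table), TRUE)
  cand[keep]
}

# shared cutoff predicate for a group pair
nbWithinCutoff <- function(graph, a, b, settings, table = corderoRadii()) {
  if (settings@mode == "dbe")
    minGroupDistance(graph, a, b) <= settings@deltaNB
  else
    dcrrRatio(graph, a, b, table) <= settings@dcrrThreshold
}
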