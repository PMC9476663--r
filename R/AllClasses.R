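#' @import methods
NULL

#' Molecule: elements plus Cartesian coordinates
#'
#' Ordered collection of atoms: an element symbol and a Cartesian position
#' (Angstrom) per atom. Atom indices are the 1-based row order of the input.
#'
#' @slot elements character vector of element symbols, one per atom.
#' @slot coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @slot name label for the molecule (XYZ comment line or generator spec).
#' @slot provenance source path or generator description.
#'
#' @exportClass Molecule
setClass("Molecule",
  representation(
    elements   = "character",
    coords     = "matrix",
    name       = "character",
    provenance = "character"
  ),
  prototype(name = "", provenance = "")
)

setValidity("Molecule", function(object) {
  n <- length(object@elements)
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    return("coords must be a numeric matrix with 3 columns")
  if (nrow(object@coords) != n)
    return("coords must have one row per element")
  if (n == 0L)
    return("molecule has no atoms")
  if (any(!is.finite(object@coords)))
    return("coordinates must be finite")
  unknown <- setdiff(unique(object@elements), names(corderoRadii()))
  if (length(unknown))
    return(paste0("element(s) without a tabulated covalent radius: ",
                  paste(unknown, collapse = ", ")))
  if (n > 1L) {
    dmin <- min(stats::dist(object@coords))
    if (dmin < 0.1)
      return(sprintf(
        "degenerate geometry: atom pair at %.4f Angstrom (< 0.1)", dmin))
  }
  TRUE
})

#' Bond-perception tolerances
#'
#' Distance slacks (Angstrom) applied to covalent-radius sums when assigning
#' bond orders, plus the nonbonded cutoff carried alongside for configuration
#' unity. An atom pair at distance R with radii r_i, r_j receives order 1 if
#' R < r_i + r_j + deltaSB, tightened to 2 if R < r_i + r_j - deltaDB and to
#' 3 if R < r_i + r_j - deltaTB.
#'
#' @slot deltaSB single-bond slack, Angstrom (> 0).
#' @slot deltaDB double-bond tightening, Angstrom (>= 0).
#' @slot deltaTB triple-bond tightening, Angstrom (> deltaDB).
#' @slot deltaNB nonbonded cutoff, Angstrom.
#'
#' @exportClass BondTolerances
setClass("BondTolerances",
  representation(deltaSB = "numeric", deltaDB = "numeric",
                 deltaTB = "numeric", deltaNB = "numeric"),
  prototype(deltaSB = 0.40, deltaDB = 0.05, deltaTB = 0.20, deltaNB = Inf)
)

setValidity("BondTolerances", function(object) {
  if (object@deltaSB <= 0) return("deltaSB must be positive")
  if (object@deltaDB < 0) return("deltaDB must be non-negative")
  if (object@deltaTB <= object@deltaDB)
    return("deltaTB must exceed deltaDB")
  if (object@deltaNB < 0) return("deltaNB must be non-negative")
  TRUE
})

#' Group graph: the group-level connectivity of a molecule
#'
#' Groups are the elementary fragmentation units: maximal sets of heavy atoms
#' joined by bonds of order >= 2, plus the hydrogens bonded to them. The
#' group graph records which groups are joined by (severable) single bonds,
#' which atom pairs realize those bonds, and how many hydrogen caps each
#' group needs when isolated.
#'
#' @slot molecule the parent \linkS4class{Molecule}.
#' @slot groups list, one entry per group: \code{list(heavy=, hydrogens=)}
#'   with 1-based atom indices.
#' @slot adjacency symmetric 0/1 integer matrix over groups.
#' @slot severedAtoms named list; for each adjacent pair \code{"a-b"}
#'   (a < b), an integer matrix with columns \code{i} (atom in a) and
#'   \code{j} (atom in b), one row per severable bond.
#' @slot capsPerGroup integer vector: incident severed-bond count per group.
#'
#' @exportClass GroupGraph
setClass("GroupGraph",
  representation(
    molecule     = "Molecule",
    groups       = "list",
    adjacency    = "matrix",
    severedAtoms = "list",
    capsPerGroup = "integer"
  )
)

setValidity("GroupGraph", function(object) {
  ng <- length(object@groups)
  A <- object@adjacency
  if (!all(dim(A) == c(ng, ng))) return("adjacency dimension mismatch")
  if (any(A != t(A))) return("adjacency must be symmetric")
  if (any(diag(A) != 0)) return("adjacency diagonal must be zero")
  members <- unlist(lapply(object@groups, function(g) c(g$heavy, g$hydrogens)))
  natom <- length(object@molecule@elements)
  if (length(members) != natom || anyDuplicated(members) > 0L ||
      !setequal(members, seq_len(natom)))
    return("groups must partition the atom set")
  if (any(vapply(object@groups, function(g) length(g$heavy), 1L) == 0L))
    return("every group must contain a heavy atom")
  if (length(object@capsPerGroup) != ng)
    return("capsPerGroup length mismatch")
  if (sum(object@capsPerGroup) != sum(A))
    return("cap counts must sum to twice the edge count")
  TRUE
})

#' Signed fragment: a set of groups with an integer coefficient
#'
#' A term of the fragment expansion. Bonded fragments are connected sets of
#' groups; nonbonded fragments are complexes whose \code{components} slot
#' partitions the groups into the separately-capped units (the single group
#' and/or multi-group fragments brought into spatial contact).
#'
#' @slot groups sorted integer vector of group ids.
#' @slot coefficient signed integer weight in the energy sum.
#' @slot kind \code{"bonded"} or \code{"nonbonded"}.
#' @slot components list of integer vectors partitioning \code{groups};
#'   bonded fragments have a single component.
#'
#' @exportClass SignedFragment
setClass("SignedFragment",
  representation(groups = "integer", coefficient = "integer",
                 kind = "character", components = "list")
)

setValidity("SignedFragment", function(object) {
  if (length(object@groups) == 0L) return("fragment has no groups")
  if (is.unsorted(object@groups, strictly = TRUE))
    return("groups must be strictly sorted")
  if (!object@kind %in% c("bonded", "nonbonded"))
    return("kind must be 'bonded' or 'nonbonded'")
  comp <- sort(unlist(object@components))
  if (!identical(as.integer(comp), object@groups))
    return("components must partition the fragment's groups")
  TRUE
})

#' Nonbonded fragmentation settings
#'
#' Level 1 builds dimers of capped groups; level 2 builds three-body
#' complexes (a group against a two-group bonded fragment) with dimer
#' renormalization. The cutoff is either distance-based elimination (DBE:
#' keep a pair if its closest-atom separation is at most \code{deltaNB}
#' Angstrom) or the dimensionless distance-to-covalent-radii ratio (DCRR:
#' keep if min over atom pairs of R_ij / (r_i + r_j) is at most
#' \code{dcrrThreshold}).
#'
#' @slot level integer, 1 or 2.
#' @slot mode \code{"dbe"} or \code{"dcrr"}.
#' @slot deltaNB DBE threshold, Angstrom.
#' @slot dcrrThreshold DCRR threshold, dimensionless.
#'
#' @exportClass NBSettings
setClass("NBSettings",
  representation(level = "integer", mode = "character",
                 deltaNB = "numeric", dcrrThreshold = "numeric"),
  prototype(level = 1L, mode = "dbe", deltaNB = Inf, dcrrThreshold = Inf)
)

setValidity("NBSettings", function(object) {
  if (!object@level %in% c(1L, 2L)) return("level must be 1 or 2")
  if (!object@mode %in% c("dbe", "dcrr"))
    return("mode must be 'dbe' or 'dcrr'")
  if (object@deltaNB < 0 || object@dcrrThreshold < 0)
    return("thresholds must be non-negative")
  TRUE
})

#' Fragmentation plan
#'
#' The full signed fragment expansion of a molecule at bonded level m and
#' nonbonded level n, together with the group graph it was derived from.
#'
#' @slot levelBonded bonded level m (main fragments have m + 1 groups).
#' @slot levelNonbonded nonbonded level n (0 = none, 1 = dimers, 2 = 3BCs).
#' @slot bonded list of bonded \linkS4class{SignedFragment}s, canonical
#'   order (size descending, then lexicographic group ids).
#' @slot nonbonded list of nonbonded \linkS4class{SignedFragment}s.
#' @slot graph the \linkS4class{GroupGraph}.
#'
#' @exportClass FragmentationPlan
setClass("FragmentationPlan",
  representation(levelBonded = "integer", levelNonbonded = "integer",
                 bonded = "list", nonbonded = "list", graph = "GroupGraph")
)

setValidity("FragmentationPlan", function(object) {
  keys <- vapply(object@bonded, function(f) paste(f@groups, collapse = "+"), "")
  if (anyDuplicated(keys)) return("duplicate bonded fragment group sets")
  co <- vapply(c(object@bonded, object@nonbonded),
               function(f) f@coefficient, 1L)
  if (any(co == 0L)) return("finalized plans must not carry zero coefficients")
  TRUE
})

#' Capped fragment: a realized sub-molecule
#'
#' The physical structure submitted to an energy backend: the real atoms of
#' the fragment's groups plus one hydrogen link atom per severed bond, placed
#' along the missing bond vector at a covalent-radius-scaled distance.
#'
#' @slot elements element symbols, real atoms first (original order), caps last.
#' @slot coords coordinates matching \code{elements}, Angstrom.
#' @slot realAtoms original molecule indices of the real atoms.
#' @slot realGroups group id of each real atom.
#' @slot capAnchor for each cap, the original index of the retained atom i.
#' @slot capReplaced for each cap, the original index of the removed atom j.
#' @slot fragment the \linkS4class{SignedFragment} this realizes.
#'
#' @exportClass CappedFragment
setClass("CappedFragment",
  representation(
    elements = "character", coords = "matrix",
    realAtoms = "integer", realGroups = "integer",
    capAnchor = "integer", capReplaced = "integer",
    fragment = "SignedFragment"
  )
)

setValidity("CappedFragment", function(object) {
  nr <- length(object@realAtoms)
  nc <- length(object@capAnchor)
  if (length(object@elements) != nr + nc)
    return("element count must equal real atoms plus caps")
  if (nrow(object@coords) != nr + nc) return("coords dimension mismatch")
  if (nc && any(object@elements[(nr + 1L):(nr + nc)] != "H"))
    return("cap atoms must be hydrogen")
  if (length(object@realGroups) != nr)
    return("realGroups must annotate every real atom")
  TRUE
})

#' Energy ledger
#'
#' Assembled fragment energies: the bonded sum E_b = sum f_i E(F_i), the
#' nonbonded sum E_nb over signed complex (interaction) energies, and their
#' total, with the per-fragment signed contributions retained for audit.
#'
#' @slot Eb bonded energy, hartree.
#' @slot Enb nonbonded energy, hartree.
#' @slot Etotal E_b + E_nb, hartree.
#' @slot contributions data.frame: fragment id, kind, coefficient, structure
#'   key(s), energy and signed contribution per fragment.
#'
#' @exportClass EnergyLedger
setClass("EnergyLedger",
  representation(Eb = "numeric", Enb = "numeric", Etotal = "numeric",
                 contributions = "data.frame")
)

setValidity("EnergyLedger", function(object) {
  if (!is.finite(object@Etotal)) return("energies must be finite")
  if (abs(object@Etotal - (object@Eb + object@Enb)) > 1e-9)
    return("Etotal must equal Eb + Enb")
  TRUE
})
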