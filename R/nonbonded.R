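#' Nonbonded settings constructor
#'
#' @param level nonbonded level: 1 (dimers of capped groups) or 2
#'   (three-body complexes with dimer renormalization).
#' @param mode cutoff scheme: \code{"dbe"} (distance-based elimination) or
#'   \code{"dcrr"} (distance-to-covalent-radii ratio).
#' @param deltaNB DBE threshold, Angstrom; \code{Inf} disables the cutoff.
#' @param dcrrThreshold DCRR threshold, dimensionless.
#' @return an \linkS4class{NBSettings}.
#' @export
nbSettings <- function(level = 1L, mode = c("dbe", "dcrr"),
                       deltaNB = Inf, dcrrThreshold = Inf) {
  new("NBSettings", level = as.integer(level), mode = match.arg(mode),
      deltaNB = deltaNB, dcrrThreshold = dcrrThreshold)
}

# coordinates of the real atoms of a set of groups
.groupCoords <- function(graph, gset) {
  idx <- unlist(lapply(graph@groups[gset], function(g)
    c(g$heavy, g$hydrogens)))
  list(idx = idx, xyz = graph@molecule@coords[idx, , drop = FALSE])
}

#' Minimum interatomic distance between two group sets
#'
#' Closest-atom separation over the real atoms (caps excluded) of two
#' disjoint sets of groups; the quantity the DBE cutoff thresholds.
#'
#' @param graph a \linkS4class{GroupGraph}.
#' @param a,b group ids (or vectors of ids); must be disjoint.
#' @return distance, Angstrom.
#' @export
minGroupDistance <- function(graph, a, b) {
  stopifnot(is(graph, "GroupGraph"), !any(a %in% b))
  pa <- .groupCoords(graph, a)$xyz
  pb <- .groupCoords(graph, b)$xyz
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  sqrt(max(min(d2), 0))
}

#' Distance-to-covalent-radii ratio between two group sets
#'
#' min over atom pairs (i in a, j in b) of R_ij / (r_i + r_j). For two
#' carbons 6.0 Angstrom apart this is 6.0 / 1.52 = 3.95, so a 6 Angstrom
#' DBE cutoff on carbon corresponds to a DCRR threshold near 4.
#'
#' @param graph a \linkS4class{GroupGraph}.
#' @param a,b group ids (or vectors of ids); must be disjoint.
#' @param table covalent radii.
#' @return dimensionless ratio.
#' @export
dcrrRatio <- function(graph, a, b, table = corderoRadii()) {
  stopifnot(is(graph, "GroupGraph"), !any(a %in% b))
  ca <- .groupCoords(graph, a)
  cb <- .groupCoords(graph, b)
  ra <- covalentRadius(graph@molecule@elements[ca$idx], table)
  rb <- covalentRadius(graph@molecule@elements[cb$idx], table)
  d2 <- outer(rowSums(ca$xyz^2), rowSums(cb$xyz^2), "+") -
    2 * ca$xyz %*% t(cb$xyz)
  min(sqrt(pmax(d2, 0)) / outer(ra, rb, "+"))
}

# does any bonded fragment of the plan contain all of `gset`?
.coveredByBonded <- function(plan, gset) {
  for (f in plan@bonded) if (all(gset %in% f@groups)) return(TRUE)
  FALSE
}

#' Allowed nonbonded group pairs
#'
#' Pairs of groups that never appear together in a bonded fragment of the
#' plan and whose separation passes the nonbonded cutoff. These are the
#' two-body interactions the bonded expansion does not already include.
#'
#' @param plan a \linkS4class{FragmentationPlan} (bonded part finalized).
#' @param settings an \linkS4class{NBSettings}.
#' @param table covalent radii (DCRR mode).
#' @return integer matrix with columns \code{a}, \code{b} (a < b).
#' @export
allowedPairs <- function(plan, settings = nbSettings(),
                         table = corderoRadii()) {
  stopifnot(is(plan, "FragmentationPlan"))
  graph <- plan@graph
  ng <- nGroups(graph)
  out <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("a", "b")))
  if (ng < 2L) return(out)
  for (a in seq_len(ng - 1L)) for (b in (a + 1L):ng) {
    if (.coveredByBonded(plan, c(a, b))) next
    if (!nbWithinCutoff(graph, a, b, settings, table)) next
    out <- rbind(out, c(a, b))
  }
  out
}

.nbFragment <- function(components, coefficient) {
  groups <- sort(as.integer(unlist(components)))
  new("SignedFragment", groups = groups,
      coefficient = as.integer(coefficient), kind = "nonbonded",
      components = lapply(components, function(x) sort(as.integer(x))))
}

#' Level-1 nonbonded fragments: dimers of capped groups
#'
#' One dimer per allowed pair, coefficient +1, the two capped groups as
#' components.
#'
#' @inheritParams allowedPairs
#' @return list of nonbonded \linkS4class{SignedFragment}s.
#' @export
nbLevel1 <- function(plan, settings = nbSettings(), table = corderoRadii()) {
  prs <- allowedPairs(plan, settings, table)
  lapply(seq_len(nrow(prs)), function(k)
    .nbFragment(list(prs[k, 1L], prs[k, 2L]), 1L))
}

#' Level-2 nonbonded fragments: three-body complexes with dimer
#' renormalization
#'
#' Builds one three-body complex (3BC) per pairing of a group g with a
#' two-group bonded fragment \{j, k\} (a group-graph edge) such that the
#' three groups never co-occur in a bonded fragment and g is within the
#' nonbonded cutoff of \{j, k\}. Each 3BC's interaction energy covers the
#' pairs (g, j) and (g, k); dimer fragments are then appended with
#' coefficient target - count for every such pair, where the target is 1
#' for allowed in-range pairs and 0 otherwise, so the signed pair coverage
#' of the nonbonded plan equals the allowed-pair indicator exactly.
#' Allowed pairs touched by no 3BC fall back to +1 dimers.
#'
#' @inheritParams allowedPairs
#' @return list of nonbonded \linkS4class{SignedFragment}s (3BCs first,
#'   then dimers).
#' @export
nbLevel2 <- function(plan, settings = nbSettings(), table = corderoRadii()) {
  graph <- plan@graph
  ng <- nGroups(graph)
  A <- graph@adjacency
  edges <- which(A == 1L & upper.tri(A), arr.ind = TRUE)
  tbc <- list()
  count <- matrix(0L, ng, ng)
  for (g in seq_len(ng)) {
    for (e in seq_len(nrow(edges))) {
      j <- edges[e, 1L]; k <- edges[e, 2L]
      if (g == j || g == k) next
      if (.coveredByBonded(plan, c(g, j, k))) next
      if (!nbWithinCutoff(graph, g, c(j, k), settings, table)) next
      tbc[[length(tbc) + 1L]] <- .nbFragment(list(g, c(j, k)), 1L)
      for (b in c(j, k)) {
        a1 <- min(g, b); b1 <- max(g, b)
        count[a1, b1] <- count[a1, b1] + 1L
      }
    }
  }
  target <- matrix(0L, ng, ng)
  prs <- allowedPairs(plan, settings, table)
  for (r in seq_len(nrow(prs))) target[prs[r, 1L], prs[r, 2L]] <- 1L
  dimers <- list()
  need <- which(target != count & upper.tri(target), arr.ind = TRUE)
  for (r in seq_len(nrow(need))) {
    a <- need[r, 1L]; b <- need[r, 2L]
    dimers[[length(dimers) + 1L]] <-
      .nbFragment(list(a, b), target[a, b] - count[a, b])
  }
  c(tbc, dimers)
}

#' Build a complete LSSMF(m, n) fragmentation plan
#'
#' Bonded expansion at level m plus the nonbonded plan at level n.
#'
#' @param graph a \linkS4class{GroupGraph} from [groupMolecule()].
#' @param m bonded level.
#' @param settings an \linkS4class{NBSettings}; its \code{level} slot picks
#'   dimers (1) or three-body complexes (2). \code{NULL} skips nonbonded
#'   fragments entirely.
#' @param table covalent radii.
#' @return a \linkS4class{FragmentationPlan}.
#' @examples
#' gg <- groupMolecule(generateLinearAlkane(7))
#' plan <- fragmentationPlan(gg, m = 3, settings = nbSettings(level = 1))
#' length(fragments(plan, "nonbonded"))  # 6 dimers
#' @export
fragmentationPlan <- function(graph, m, settings = nbSettings(),
                              table = corderoRadii()) {
  plan <- bondedPlan(graph, m)
  if (is.null(settings)) return(plan)
  stopifnot(is(settings, "NBSettings"))
  nb <- if (settings@level == 1L) nbLevel1(plan, settings, table)
        else nbLevel2(plan, settings, table)
  new("FragmentationPlan", levelBonded = plan@levelBonded,
      levelNonbonded = settings@level, bonded = plan@bonded,
      nonbonded = nb, graph = graph)
}

#' Signed nonbonded pair coverage
#'
#' For auditing: the signed number of times each group pair (a, b) is
#' covered by the nonbonded plan, counting for each complex the pairs that
#' span two different components (internal component pairs are subtracted
#' away with the component energies).
#'
#' @param plan a \linkS4class{FragmentationPlan}.
#' @return symmetric integer matrix over groups.
#' @export
nbPairCoverage <- function(plan) {
  ng <- nGroups(plan@graph)
  cov <- matrix(0L, ng, ng)
  for (f in plan@nonbonded) {
    comps <- f@components
    nc <- length(comps)
    if (nc < 2L) next
    for (x in seq_len(nc - 1L)) for (y in (x + 1L):nc) {
      for (a in comps[[x]]) for (b in comps[[y]]) {
        cov[a, b] <- cov[a, b] + f@coefficient
        cov[b, a] <- cov[a, b]
      }
    }
  }
  cov
}
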