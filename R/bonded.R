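# ---- internal graph helpers ------------------------------------------------

# igraph view of the group graph (vertices = group ids)
.groupIgraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph@adjacency, mode = "undirected")
}

# is the induced subgraph on `set` connected?
.isConnectedSet <- function(adjacency, set) {
  k <- length(set)
  if (k <= 1L) return(TRUE)
  sub <- adjacency[set, set, drop = FALSE]
  seen <- logical(k)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    nb <- which(sub[v, ] == 1L & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

# connected components of the induced subgraph on `set`
.connectedParts <- function(adjacency, set) {
  parts <- list()
  left <- set
  while (length(left)) {
    comp <- left[1L]
    repeat {
      grow <- setdiff(
        left[colSums(adjacency[comp, left, drop = FALSE] == 1L) > 0L], comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    parts[[length(parts) + 1L]] <- sort(comp)
    left <- setdiff(left, comp)
  }
  parts
}

.setKey <- function(set) paste(sort(set), collapse = "+")

# ---- operations ------------------------------------------------------------

#' Union of bonded domains around a seed group
#'
#' The two-hop neighborhood used as the candidate pool when enumerating
#' main fragments: BD(g) together with the bonded domains of every member
#' of BD(g), excluding the seed itself. On alkanes (max group degree 4)
#' this pool holds at most 16 groups.
#'
#' @param graph a \linkS4class{GroupGraph}.
#' @param g seed group id.
#' @return integer vector of group ids (seed excluded).
#' @export
unionBondedDomain <- function(graph, g) {
  bd <- bondedDomain(graph, g)
  setdiff(sort(unique(c(bd, unlist(lapply(bd, bondedDomain,
                                          graph = graph))))), g)
}

#' Enumerate main bonded fragments
#'
#' All distinct connected sets of m + 1 groups. Enumeration grows connected
#' sets from every seed group inside a graph-distance ball of radius
#' ceiling(m / 2) (the radius of a tree on m + 1 vertices, so every
#' connected set is reached from one of its central groups); the result
#' equals exhaustive enumeration of connected induced subsets. A molecule
#' with at most m + 1 groups yields the single whole-molecule set.
#'
#' @param graph a \linkS4class{GroupGraph}.
#' @param m bonded level (main fragments carry m + 1 groups).
#' @return list of sorted integer vectors (group id sets), canonical order.
#' @export
enumerateMainFragments <- function(graph, m) {
  stopifnot(is(graph, "GroupGraph"), m >= 1L)
  ng <- nGroups(graph)
  size <- m + 1L
  if (ng <= size) return(list(seq_len(ng)))
  A <- graph@adjacency
  ig <- .groupIgraph(graph)
  radius <- ceiling(m / 2)
  found <- new.env(parent = emptyenv())
  out <- list()
  for (seed in seq_len(ng)) {
    ball <- as.integer(
      igraph::ego(ig, order = radius, nodes = seed)[[1L]])
    grow <- function(set) {
      if (length(set) == size) {
        key <- .setKey(set)
        if (is.null(found[[key]])) {
          found[[key]] <- TRUE
          out[[length(out) + 1L]] <<- sort(set)
        }
        return(invisible())
      }
      nb <- setdiff(
        ball[colSums(A[set, ball, drop = FALSE] == 1L) > 0L], set)
      for (v in nb) grow(c(set, v))
      invisible()
    }
    grow(seed)
  }
  out[order(vapply(out, .setKey, ""))]
}

#' Derive renormalization coefficients by inclusion-exclusion
#'
#' Main fragments enter with coefficient +1. The plan is closed under
#' pairwise intersection (disconnected intersections are split into
#' connected components); derived sets are processed in decreasing size and
#' each set S receives c(S) = 1 - sum of c(T) over plan sets T strictly
#' containing S, so that every group and every group pair covered by a main
#' fragment nets exactly once (chemical balance). Zero coefficients are
#' dropped.
#'
#' @param mains list of group id sets from [enumerateMainFragments()].
#' @param graph a \linkS4class{GroupGraph}.
#' @return list of bonded \linkS4class{SignedFragment}s, canonical order
#'   (size descending, then lexicographic group ids).
#' @export
deriveCoefficients <- function(mains, graph) {
  if (!length(mains)) stop("no main fragments supplied")
  A <- graph@adjacency
  keys <- vapply(mains, .setKey, "")
  if (anyDuplicated(keys)) stop("main fragments must be deduplicated")
  mains <- lapply(mains, function(s) sort(as.integer(s)))

  # closure under pairwise intersection, splitting disconnected sets
  closure <- list()
  closKeys <- character(0)
  pool <- mains
  repeat {
    all_sets <- c(mains, closure)
    fresh <- list()
    nall <- length(all_sets)
    for (a in seq_len(nall - 1L)) for (b in (a + 1L):nall) {
      inter <- intersect(all_sets[[a]], all_sets[[b]])
      if (!length(inter)) next
      for (part in .connectedParts(A, inter)) {
        key <- .setKey(part)
        if (!(key %in% keys) && !(key %in% closKeys)) {
          closKeys <- c(closKeys, key)
          fresh[[length(fresh) + 1L]] <- part
        }
      }
    }
    if (!length(fresh)) break
    closure <- c(closure, fresh)
  }

  # top-down coefficient assignment over the closure
  planSets <- mains
  planCoef <- rep(1L, length(mains))
  if (length(closure)) {
    closure <- closure[order(-lengths(closure),
                             vapply(closure, .setKey, ""))]
    for (S in closure) {
      covered <- vapply(seq_along(planSets), function(k)
        all(S %in% planSets[[k]]) && length(planSets[[k]]) > length(S),
        TRUE)
      co <- 1L - sum(planCoef[covered])
      planSets[[length(planSets) + 1L]] <- S
      planCoef <- c(planCoef, as.integer(co))
    }
  }
  keep <- planCoef != 0L
  planSets <- planSets[keep]; planCoef <- planCoef[keep]
  ord <- order(-lengths(planSets), vapply(planSets, .setKey, ""))
  mapply(function(s, co)
    new("SignedFragment", groups = as.integer(s), coefficient = co,
        kind = "bonded", components = list(as.integer(s))),
    planSets[ord], planCoef[ord], SIMPLIFY = FALSE)
}

#' Build the bonded part of a fragmentation plan
#'
#' @param graph a \linkS4class{GroupGraph}.
#' @param m bonded level (1..6 validated; higher allowed with a warning).
#' @return a \linkS4class{FragmentationPlan} with an empty nonbonded slot.
#' @examples
#' hept <- groupMolecule(generateLinearAlkane(7))
#' plan <- bondedPlan(hept, m = 3)
#' table(lengths(lapply(fragments(plan, "bonded"), function(f) f@groups)))
#' @export
bondedPlan <- function(graph, m) {
  stopifnot(is(graph, "GroupGraph"))
  m <- as.integer(m)
  if (m < 1L) stop("bonded level m must be >= 1")
  if (m > 6L)
    warning("bonded level ", m, " is outside the validated range 1..6")
  mains <- enumerateMainFragments(graph, m)
  bonded <- deriveCoefficients(mains, graph)
  new("FragmentationPlan", levelBonded = m, levelNonbonded = 0L,
      bonded = bonded, nonbonded = list(), graph = graph)
}

#' Chemical-balance report for a plan
#'
#' Audits the three balance identities of a signed bonded expansion: every
#' group nets once, every group pair inside some main fragment nets once
#' (others zero), and the signed cap-hydrogen count nets zero.
#'
#' @param plan a \linkS4class{FragmentationPlan}.
#' @return list with \code{groupCoverage} (integer vector over groups),
#'   \code{pairCoverage} (matrix), \code{capBalance} (integer) and
#'   \code{ok} (logical).
#' @export
balanceReport <- function(plan) {
  stopifnot(is(plan, "FragmentationPlan"))
  ng <- nGroups(plan@graph)
  gcov <- integer(ng)
  pcov <- matrix(0L, ng, ng)
  inMain <- matrix(FALSE, ng, ng)
  for (f in plan@bonded) {
    gcov[f@groups] <- gcov[f@groups] + f@coefficient
    pr <- f@groups
    if (length(pr) > 1L) {
      cmb <- utils::combn(pr, 2L)
      for (k in seq_len(ncol(cmb))) {
        a <- cmb[1L, k]; b <- cmb[2L, k]
        pcov[a, b] <- pcov[a, b] + f@coefficient
        pcov[b, a] <- pcov[a, b]
        # every plan fragment is a subset of a main, so membership in any
        # plan fragment marks the pair as main-covered
        inMain[a, b] <- inMain[b, a] <- TRUE
      }
    }
  }
  cb <- capBalance(plan)
  ok <- all(gcov == 1L) && cb == 0L &&
    all(pcov[inMain] == 1L) && all(pcov[!inMain] == 0L)
  list(groupCoverage = gcov, pairCoverage = pcov, capBalance = cb, ok = ok)
}
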