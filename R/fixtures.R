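#' Alkane skeleton specification
#'
#' Describes an acyclic alkane by its carbon tree (parent list) and the
#' idealized geometry parameters used to realize it: C-C 1.54 Angstrom,
#' C-H 1.09 Angstrom, tetrahedral angles, and an all-anti arrangement of
#' every chain (each new carbon is placed anti-periplanar to its
#' great-grandparent). An optional seeded Gaussian jitter (sigma <= 0.01
#' Angstrom) supports robustness tests; it is off by default.
#'
#' @param parents integer vector; \code{parents[1]} is 0 (root) and
#'   \code{parents[k] < k} names the parent carbon of carbon k. Max degree 4.
#' @param ccBond,chBond bond lengths, Angstrom.
#' @param jitterSD Gaussian jitter standard deviation, Angstrom (<= 0.01).
#' @param seed integer seed for the jitter.
#' @return list of class \code{"AlkaneSpec"}.
#' @export
alkaneSpec <- function(parents, ccBond = 1.54, chBond = 1.09,
                       jitterSD = 0, seed = 1L) {
  parents <- as.integer(parents)
  n <- length(parents)
  stopifnot(n >= 1L, parents[1L] == 0L)
  if (n > 1L && any(parents[-1L] >= seq_len(n)[-1L] | parents[-1L] < 1L))
    stop("parents must be topologically ordered: parents[k] in 1..(k-1)")
  deg <- tabulate(parents[-1L], nbins = n) +
    c(0L, rep(1L, n - 1L))[seq_len(n)]
  if (any(deg > 4L)) stop("carbon degree exceeds 4")
  if (jitterSD > 0.01) stop("jitterSD must not exceed 0.01 Angstrom")
  structure(list(parents = parents, ccBond = ccBond, chBond = chBond,
                 jitterSD = jitterSD, seed = as.integer(seed)),
            class = "AlkaneSpec")
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# The three tetrahedral slot directions of a carbon whose bond to its parent
# points along -back. The frame's twist phi0 is chosen on a 5-degree grid to
# minimize steric crowding (sum over slot tips of inverse-square distances
# to already-placed atoms). phi0 = 0 aligns the first slot anti-periplanar
# to `anti` (the parent-to-grandparent bond); for unbranched runs the
# staggered optimum is exactly phi0 = 0, so chains come out all-anti.
.tetraSlots <- function(center, back, anti, tipLen, others) {
  thet <- acos(-1 / 3)
  ref <- NULL
  if (!is.null(anti)) {
    w <- anti - sum(anti * back) * back
    if (sqrt(sum(w^2)) > 1e-8) ref <- -w
  }
  if (is.null(ref)) {
    r <- if (abs(back[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    ref <- r - sum(r * back) * back
  }
  e1 <- ref / sqrt(sum(ref^2))
  e2 <- .cross3(back, e1)
  dirs <- function(phi0) lapply(phi0 + c(0, 2 * pi / 3, 4 * pi / 3),
    function(phi) cos(thet) * back +
      sin(thet) * (cos(phi) * e1 + sin(phi) * e2))
  if (is.null(others) || nrow(others) == 0L) return(dirs(0))
  bestPhi <- 0; bestScore <- Inf
  for (phi0 in seq(0, 2 * pi / 3 - 1e-9, by = 5 * pi / 180)) {
    sc <- sum(vapply(dirs(phi0), function(s) {
      tip <- center + tipLen * s
      sum(1 / rowSums((others - matrix(tip, nrow(others), 3L,
                                       byrow = TRUE))^2))
    }, 0.0))
    if (sc < bestScore - 1e-9) { bestScore <- sc; bestPhi <- phi0 }
  }
  dirs(bestPhi)
}

#' Generate an idealized alkane geometry from a skeleton
#'
#' Carbons are placed breadth-first with ideal tetrahedral geometry; each
#' chain continuation takes the slot anti-periplanar to the grandparent
#' bond, so unbranched runs come out all-anti (planar zigzag). Hydrogens
#' fill the remaining tetrahedral slots. Deterministic for a fixed spec.
#'
#' @param spec an [alkaneSpec()] (or bare parent vector).
#' @param name molecule label.
#' @return a \linkS4class{Molecule} with carbons first (skeleton order),
#'   then hydrogens.
#' @examples
#' dmp <- generateBranchedAlkane(alkaneSpec(c(0, 1, 2, 3, 4, 2, 4)),
#'                               name = "2,4-dimethylpentane")
#' nAtoms(dmp)  # 23
#' @export
generateBranchedAlkane <- function(spec, name = "alkane") {
  if (!inherits(spec, "AlkaneSpec")) spec <- alkaneSpec(spec)
  parents <- spec$parents
  n <- length(parents)
  pos <- matrix(0, n, 3L)
  # per-carbon bond-direction slots, built lazily at first use so the
  # twist-angle search can see everything already placed; consumed as
  # children and hydrogens claim them
  slots <- vector("list", n)
  backs <- vector("list", n)
  antis <- vector("list", n)
  built <- logical(n)
  s0 <- 1 / sqrt(3)
  slots[[1L]] <- list(c(s0, s0, s0), c(s0, -s0, -s0),
                      c(-s0, s0, -s0), c(-s0, -s0, s0))
  built[1L] <- TRUE
  ensureFrame <- function(p, placed) {
    if (built[p]) return(invisible())
    slots[[p]] <<- .tetraSlots(pos[p, ], backs[[p]], antis[[p]],
                               spec$ccBond, placed)
    built[p] <<- TRUE
    invisible()
  }
  for (k in seq_len(n)[-1L]) {
    p <- parents[k]
    placed <- pos[seq_len(k - 1L), , drop = FALSE]
    ensureFrame(p, placed)
    # among the parent's free slots, take the least crowded one (rounded so
    # exact symmetric ties fall back to stored order, whose first slot is
    # the all-anti continuation)
    ref <- pos[setdiff(seq_len(k - 1L), p), , drop = FALSE]
    score <- vapply(slots[[p]], function(s) {
      if (nrow(ref) == 0L) return(0)
      cand <- pos[p, ] + spec$ccBond * s
      round(sum(1 / rowSums((ref -
        matrix(cand, nrow(ref), 3L, byrow = TRUE))^2)), 9L)
    }, 0.0)
    pick <- which.min(score)
    u <- slots[[p]][[pick]]
    slots[[p]] <- slots[[p]][-pick]
    pos[k, ] <- pos[p, ] + spec$ccBond * u
    backs[[k]] <- -u
    gp <- parents[p]
    antis[k] <- list(if (gp >= 1L) {
      w <- pos[gp, ] - pos[p, ]
      w / sqrt(sum(w^2))
    } else NULL)
  }
  # hydrogens fill the remaining slots; leaf-carbon frames (still unbuilt)
  # are twist-optimized here against carbons and hydrogens placed so far
  hx <- NULL
  for (k in seq_len(n)) {
    if (!built[k]) {
      others <- rbind(pos[-k, , drop = FALSE], hx)
      slots[[k]] <- .tetraSlots(pos[k, ], backs[[k]], antis[[k]],
                                spec$chBond, others)
      built[k] <- TRUE
    }
    for (s in slots[[k]]) hx <- rbind(hx, pos[k, ] + spec$chBond * s)
  }
  coords <- rbind(pos, hx)
  el <- c(rep("C", n), rep("H", nrow(coords) - n))
  if (spec$jitterSD > 0) {
    set.seed(spec$seed)
    coords <- coords + matrix(stats::rnorm(length(coords), 0,
                                           spec$jitterSD),
                              nrow(coords), 3L)
  }
  if (nrow(coords) > 1L && min(stats::dist(coords)) < 0.9)
    stop("generated geometry has an atom pair closer than 0.9 Angstrom")
  Molecule(el, coords, name = name,
           provenance = paste0("alkaneSpec(parents=c(",
                               paste(parents, collapse = ","), "))"))
}

#' Generate a linear alkane C_n H_{2n+2}
#'
#' All-anti extended backbone with idealized tetrahedral geometry;
#' deterministic for fixed arguments. Always 3n + 2 atoms.
#'
#' @param n carbon count (>= 1).
#' @param ccBond,chBond bond lengths, Angstrom.
#' @param jitterSD,seed optional seeded Gaussian jitter (off by default).
#' @return a \linkS4class{Molecule}.
#' @examples
#' nAtoms(generateLinearAlkane(7))  # 23
#' @export
generateLinearAlkane <- function(n, ccBond = 1.54, chBond = 1.09,
                                 jitterSD = 0, seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("carbon count must be >= 1")
  parents <- c(0L, seq_len(n - 1L))[seq_len(n)]
  generateBranchedAlkane(
    alkaneSpec(parents, ccBond, chBond, jitterSD, seed),
    name = sprintf("n-C%dH%d (linear alkane)", n, 2L * n + 2L))
}

#' 2,4-dimethylpentane fixture
#'
#' Pentane backbone (carbons 1-5) with methyl branches on carbons 2 and 4;
#' the canonical branched test molecule (7 groups forming a tree).
#'
#' @inheritParams generateLinearAlkane
#' @return a \linkS4class{Molecule} (C7H16, 23 atoms).
#' @export
generate24DMP <- function(jitterSD = 0, seed = 1L) {
  generateBranchedAlkane(
    alkaneSpec(c(0L, 1L, 2L, 3L, 4L, 2L, 4L), jitterSD = jitterSD,
               seed = seed),
    name = "2,4-dimethylpentane")
}

#' Tetra-tert-butylmethane-like fixture (17 carbons)
#'
#' A central carbon bearing four tert-butyl branches: the maximally
#' branched acyclic alkane skeleton, whose central group realizes the
#' largest possible union of bonded domains (16 groups) at level 3. The
#' real molecule is severely strained (experimentally stretched central
#' bonds and distorted angles); the fixture idealizes that strain as a
#' uniformly stretched C-C bond of 1.66 Angstrom so that tetrahedral
#' angles can be kept while no nonbonded contact drops into bonding range.
#'
#' @param ccBond C-C bond length, Angstrom (stretched default, see above).
#' @inheritParams generateLinearAlkane
#' @return a \linkS4class{Molecule} (C17H36).
#' @export
generateMaxBranchedAlkane <- function(ccBond = 1.66, chBond = 1.09,
                                      jitterSD = 0, seed = 1L) {
  parents <- c(0L, 1L, 1L, 1L, 1L,
               rep(2:5, each = 3L))
  generateBranchedAlkane(
    alkaneSpec(parents, ccBond = ccBond, chBond = chBond,
               jitterSD = jitterSD, seed = seed),
    name = "tetra-tert-butylmethane (idealized)")
}
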