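#' Hartree to kcal/mol conversion factor
#' @export
HARTREE_TO_KCAL <- 627.509

#' Toy energy model parameters
#'
#' A transparent additive energy model used to validate the fragmentation
#' pipeline in closed loop: per-element atomic energies epsilon(e), an
#' optional group-pair potential V evaluated on the real atoms of each
#' group pair, and an optional three-body term W over group triples. Cap
#' hydrogens contribute epsilon("H") only, so the model exposes exactly
#' the cancellations the chemical-balance identities promise.
#'
#' @param epsilon named numeric vector of per-element energies, hartree.
#'   Elements absent from the vector default to \code{fill}.
#' @param pair NULL or \code{function(xyzA, xyzB)} over the real-atom
#'   coordinate matrices of two groups, returning hartree.
#' @param threeBody NULL or \code{function(xyzA, xyzB, xyzC)} over three
#'   groups' real-atom coordinates.
#' @param fill default per-element energy for unlisted elements.
#' @return list of class \code{"toyParams"}.
#' @examples
#' p <- toyParams(pair = function(a, b) {
#'   d <- sqrt(sum((colMeans(a) - colMeans(b))^2))
#'   -0.002 * exp(-d / 2)
#' })
#' @export
toyParams <- function(epsilon = c(C = -37.8, H = -0.5),
                      pair = NULL, threeBody = NULL, fill = -1.0) {
  stopifnot(is.numeric(epsilon),
            is.null(pair) || is.function(pair),
            is.null(threeBody) || is.function(threeBody))
  structure(list(epsilon = epsilon, pair = pair, threeBody = threeBody,
                 fill = fill),
            class = "toyParams")
}

.epsOf <- function(el, params) {
  e <- params$epsilon[el]
  e[is.na(e)] <- params$fill
  sum(e)
}

# group id -> real-atom coordinate matrix, for toy potentials
.toyGroupSplit <- function(elements, coords, groupIds) {
  ids <- sort(unique(groupIds))
  lapply(ids, function(g) coords[groupIds == g, , drop = FALSE])
}

.toyBody <- function(elements, coords, groupIds, params) {
  # collect terms and sum() once: R accumulates in extended precision, which
  # keeps the signed fragment cancellations well below 1e-10 hartree
  terms <- .epsOf(elements, params)
  xs <- .toyGroupSplit(elements, coords, groupIds)
  n <- length(xs)
  if (!is.null(params$pair) && n > 1L)
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
      terms <- c(terms, params$pair(xs[[a]], xs[[b]]))
  if (!is.null(params$threeBody) && n > 2L)
    for (a in seq_len(n - 2L)) for (b in (a + 1L):(n - 1L))
      for (cc in (b + 1L):n)
        terms <- c(terms, params$threeBody(xs[[a]], xs[[b]], xs[[cc]]))
  sum(terms)
}

#' Toy energy of a molecule or capped fragment
#'
#' Sum of per-element energies over all atoms (cap hydrogens count as
#' ordinary hydrogens in the epsilon sum only) plus the group-pair
#' potential over distinct pairs of groups present, evaluated on real
#' atoms, plus any three-body term over group triples.
#'
#' @param x a \linkS4class{CappedFragment}, or a \linkS4class{Molecule}
#'   (with \code{graph} supplied for its group structure).
#' @param params a [toyParams()] object.
#' @param graph a \linkS4class{GroupGraph}; required when \code{x} is a
#'   Molecule.
#' @return energy in hartree.
#' @export
toyEnergy <- function(x, params = toyParams(), graph = NULL) {
  stopifnot(inherits(params, "toyParams"))
  if (is(x, "CappedFragment")) {
    nReal <- length(x@realAtoms)
    capE <- .epsOf(x@elements[seq_len(length(x@elements)) > nReal], params)
    .toyBody(x@elements[seq_len(nReal)],
             x@coords[seq_len(nReal), , drop = FALSE],
             x@realGroups, params) + capE
  } else if (is(x, "Molecule")) {
    if (is.null(graph))
      stop("toyEnergy for a Molecule needs its GroupGraph")
    groupOfAtom <- integer(nAtoms(x))
    for (g in seq_len(nGroups(graph)))
      groupOfAtom[c(graph@groups[[g]]$heavy,
                    graph@groups[[g]]$hydrogens)] <- g
    .toyBody(x@elements, x@coords, groupOfAtom, params)
  } else stop("toyEnergy expects a CappedFragment or Molecule")
}

#' Distinct capped structures a plan requires
#'
#' Bonded fragments contribute one structure each; nonbonded fragments
#' contribute their complex plus each capped component. Structures are
#' deduplicated by [structureKey()] (shared monomers appear once).
#'
#' @param plan a \linkS4class{FragmentationPlan}.
#' @return named list: structure key -> component partition (list of
#'   integer vectors).
#' @export
requiredStructures <- function(plan) {
  out <- list()
  add <- function(components) {
    key <- structureKey(components)
    if (is.null(out[[key]])) out[[key]] <<- components
  }
  for (f in plan@bonded) add(f@components)
  for (f in plan@nonbonded) {
    add(f@components)
    for (comp in f@components) add(list(comp))
  }
  out[order(names(out))]
}

#' Realize one required structure
#'
#' @param plan a \linkS4class{FragmentationPlan}.
#' @param components component partition (list of integer group vectors).
#' @param table covalent radii.
#' @return a \linkS4class{CappedFragment} (coefficient slot is a dummy +1).
#' @export
realizeStructure <- function(plan, components, table = corderoRadii()) {
  kind <- if (length(components) > 1L) "nonbonded" else "bonded"
  proxy <- new("SignedFragment",
               groups = sort(as.integer(unlist(components))),
               coefficient = 1L, kind = kind,
               components = lapply(components, function(s)
                 sort(as.integer(s))))
  realizeFragment(proxy, plan@graph, table)
}

#' Evaluate all required structures with the toy backend
#'
#' @param plan a \linkS4class{FragmentationPlan}.
#' @param params a [toyParams()] object.
#' @param table covalent radii.
#' @return named numeric vector: structure key -> energy (hartree).
#' @export
computeToyEnergies <- function(plan, params = toyParams(),
                               table = corderoRadii()) {
  req <- requiredStructures(plan)
  vapply(req, function(components)
    toyEnergy(realizeStructure(plan, components, table), params),
    0.0)
}

#' Assemble the total energy from per-structure energies
#'
#' E_b is the signed sum of bonded fragment energies. E_nb sums, for each
#' nonbonded complex, the coefficient times either the interaction energy
#' (complex minus its capped components; default, so far-separated
#' complexes contribute nothing) or the raw complex energy
#' (\code{nbEnergy = "raw"}). E_total = E_b + E_nb.
#'
#' @param plan a \linkS4class{FragmentationPlan}.
#' @param energies named numeric vector keyed by [structureKey()]
#'   (e.g. from [computeToyEnergies()] or [readEnergies()]).
#' @param nbEnergy \code{"interaction"} or \code{"raw"}.
#' @return an \linkS4class{EnergyLedger}.
#' @export
assembleEnergy <- function(plan, energies,
                           nbEnergy = c("interaction", "raw")) {
  nbEnergy <- match.arg(nbEnergy)
  stopifnot(is(plan, "FragmentationPlan"), is.numeric(energies))
  if (anyDuplicated(names(energies)))
    stop("duplicate energy records: ",
         paste(unique(names(energies)[duplicated(names(energies))]),
               collapse = ", "))
  getE <- function(key) {
    if (is.na(match(key, names(energies))))
      stop("missing energy record for structure '", key, "'")
    energies[[key]]
  }
  rows <- list()
  for (idx in seq_along(plan@bonded)) {
    f <- plan@bonded[[idx]]
    key <- structureKey(f)
    e <- getE(key)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("b%03d", idx), kind = "bonded",
      coefficient = f@coefficient, structure = key, energy = e,
      contribution = f@coefficient * e, stringsAsFactors = FALSE)
  }
  for (idx in seq_along(plan@nonbonded)) {
    f <- plan@nonbonded[[idx]]
    key <- structureKey(f)
    e <- getE(key)
    if (nbEnergy == "interaction")
      for (comp in f@components)
        e <- e - getE(structureKey(list(comp)))
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("nb%03d", idx), kind = "nonbonded",
      coefficient = f@coefficient, structure = key, energy = e,
      contribution = f@coefficient * e, stringsAsFactors = FALSE)
  }
  contrib <- do.call(rbind, rows)
  # sum() accumulates in extended precision: essential for the large signed
  # cancellations between overlapping fragments
  Eb <- sum(contrib$contribution[contrib$kind == "bonded"])
  Enb <- sum(contrib$contribution[contrib$kind == "nonbonded"])
  new("EnergyLedger", Eb = Eb, Enb = Enb, Etotal = Eb + Enb,
      contributions = contrib)
}

#' Emit per-fragment geometry jobs
#'
#' Writes one XYZ file per distinct capped structure (monomers
#' deduplicated) plus a tab-separated manifest mapping each fragment to its
#' structure file, coefficient, kind and component structure files. Output
#' is deterministic: fixed ordering and a fixed coordinate format, so a
#' rerun is byte-identical.
#'
#' @param plan a \linkS4class{FragmentationPlan}.
#' @param outDir output directory (created if missing).
#' @param table covalent radii.
#' @return invisibly, a list with \code{manifest} (path) and
#'   \code{structures} (named vector key -> file).
#' @export
emitJobs <- function(plan, outDir, table = corderoRadii()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  req <- requiredStructures(plan)
  files <- character(0)
  for (key in names(req)) {
    capped <- realizeStructure(plan, req[[key]], table)
    fn <- paste0("frag_", gsub("\\|", "_", gsub("\\+", "-", key)), ".xyz")
    writeXYZ(Molecule(capped@elements, capped@coords, name = key),
             file.path(outDir, fn))
    files[[key]] <- fn
  }
  allFrags <- c(plan@bonded, plan@nonbonded)
  man <- data.frame(
    id = c(sprintf("b%03d", seq_along(plan@bonded)),
           if (length(plan@nonbonded))
             sprintf("nb%03d", seq_along(plan@nonbonded))),
    kind = vapply(allFrags, function(f) f@kind, ""),
    coefficient = vapply(allFrags, function(f) f@coefficient, 1L),
    groups = vapply(allFrags, function(f)
      paste(f@groups, collapse = ","), ""),
    structure = vapply(allFrags, structureKey, ""),
    structure_file = vapply(allFrags, function(f)
      files[[structureKey(f)]], ""),
    component_files = vapply(allFrags, function(f)
      paste(vapply(f@components, function(comp)
        files[[structureKey(list(comp))]] %||% "", ""),
        collapse = ";"), ""),
    stringsAsFactors = FALSE)
  manifestPath <- file.path(outDir, "manifest.tsv")
  utils::write.table(man, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(manifest = manifestPath, structures = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read per-structure energies from delimited text
#'
#' Expects a tab- or whitespace-separated file with a header naming at
#' least the columns \code{structure} and \code{energy} (hartree), as an
#' external engine would produce for the emitted jobs.
#'
#' @param path input path.
#' @return named numeric vector: structure key -> energy.
#' @export
readEnergies <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE)
  if (!all(c("structure", "energy") %in% names(df)))
    stop("energy file must have 'structure' and 'energy' columns")
  if (anyDuplicated(df$structure)) {
    dup <- unique(df$structure[duplicated(df$structure)])
    agg <- tapply(df$energy, df$structure, function(v)
      max(v) - min(v))
    if (any(agg[dup] > 1e-12))
      stop("conflicting duplicate energy records for: ",
           paste(dup[agg[dup] > 1e-12], collapse = ", "))
    df <- df[!duplicated(df$structure), ]
  }
  stats::setNames(df$energy, df$structure)
}
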