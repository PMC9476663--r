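#' @rdname Molecule-class
#' @param object a Molecule (or other container with atoms)
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))

#' @rdname Molecule-class
#' @export
setGeneric("atomElements", function(object) standardGeneric("atomElements"))

#' @rdname Molecule-class
#' @export
setGeneric("atomCoords", function(object) standardGeneric("atomCoords"))

#' @rdname Molecule-class
#' @export
setGeneric("moleculeName", function(object) standardGeneric("moleculeName"))

#' @rdname GroupGraph-class
#' @param object a GroupGraph (or plan holding one)
#' @export
setGeneric("nGroups", function(object) standardGeneric("nGroups"))

#' @rdname GroupGraph-class
#' @export
setGeneric("groupMembers", function(object) standardGeneric("groupMembers"))

#' @rdname GroupGraph-class
#' @export
setGeneric("adjacencyMatrix", function(object)
  standardGeneric("adjacencyMatrix"))

#' @rdname GroupGraph-class
#' @export
setGeneric("capCounts", function(object) standardGeneric("capCounts"))

#' @rdname FragmentationPlan-class
#' @param object a FragmentationPlan
#' @param kind "bonded", "nonbonded" or "all"
#' @export
setGeneric("fragments", function(object, kind = "all")
  standardGeneric("fragments"))

#' @rdname FragmentationPlan-class
#' @export
setGeneric("fragmentCoefficients", function(object, kind = "all")
  standardGeneric("fragmentCoefficients"))

setMethod("nAtoms", "Molecule", function(object) length(object@elements))
setMethod("atomElements", "Molecule", function(object) object@elements)
setMethod("atomCoords", "Molecule", function(object) object@coords)
setMethod("moleculeName", "Molecule", function(object) object@name)

setMethod("nGroups", "GroupGraph", function(object) length(object@groups))
setMethod("groupMembers", "GroupGraph", function(object)
  lapply(object@groups, function(g) sort(c(g$heavy, g$hydrogens))))
setMethod("adjacencyMatrix", "GroupGraph", function(object) object@adjacency)
setMethod("capCounts", "GroupGraph", function(object) object@capsPerGroup)
setMethod("nGroups", "FragmentationPlan", function(object)
  nGroups(object@graph))

setMethod("fragments", "FragmentationPlan", function(object, kind = "all") {
  kind <- match.arg(kind, c("all", "bonded", "nonbonded"))
  switch(kind,
    bonded    = object@bonded,
    nonbonded = object@nonbonded,
    all       = c(object@bonded, object@nonbonded))
})

setMethod("fragmentCoefficients", "FragmentationPlan",
  function(object, kind = "all") {
    fr <- fragments(object, kind)
    stats::setNames(vapply(fr, function(f) f@coefficient, 1L),
                    vapply(fr, structureKey, ""))
  })
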