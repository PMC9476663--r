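setMethod("show", "Molecule", function(object) {
  cat("Molecule:", moleculeName(object), "\n")
  cat(" ", nAtoms(object), "atoms,",
      elementFormula(object@elements), "\n")
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "GroupGraph", function(object) {
  ng <- nGroups(object)
  cat("GroupGraph:", ng, "groups,",
      sum(object@adjacency) / 2L, "edges\n")
  show_n <- min(ng, 10L)
  for (g in seq_len(show_n)) {
    mem <- object@groups[[g]]
    cat(sprintf("  G%-3d %-8s caps=%d  neighbors: %s\n", g,
                elementFormula(object@molecule@elements[
                  c(mem$heavy, mem$hydrogens)]),
                object@capsPerGroup[g],
                paste(bondedDomain(object, g), collapse = " ")))
  }
  if (ng > show_n) cat("  ... and", ng - show_n, "more groups\n")
})

setMethod("show", "SignedFragment", function(object) {
  cat(sprintf("SignedFragment (%s): %+d x [%s]\n", object@kind,
              object@coefficient, structureKey(object)))
})

setMethod("show", "FragmentationPlan", function(object) {
  sizes <- table(lengths(lapply(object@bonded, function(f) f@groups)))
  cat(sprintf("FragmentationPlan LSSMF(%d, %d)\n", object@levelBonded,
              object@levelNonbonded))
  cat("  bonded:", paste(rev(sprintf("%sF%s", sizes, names(sizes))),
                         collapse = " + "), "\n")
  cat("  nonbonded:", length(object@nonbonded), "fragment(s)\n")
})

setMethod("show", "CappedFragment", function(object) {
  cat(sprintf("CappedFragment [%s]: %s (%d real atoms + %d caps)\n",
              structureKey(object@fragment),
              elementFormula(object@elements),
              length(object@realAtoms), length(object@capAnchor)))
})

setMethod("show", "EnergyLedger", function(object) {
  cat("EnergyLedger (hartree):\n")
  cat(sprintf("  E_b     = %16.8f\n", object@Eb))
  cat(sprintf("  E_nb    = %16.8f\n", object@Enb))
  cat(sprintf("  E_total = %16.8f  (%.4f kcal/mol)\n", object@Etotal,
              object@Etotal * HARTREE_TO_KCAL))
  cat("  fragments:", nrow(object@contributions), "\n")
})

setMethod("show", "NBSettings", function(object) {
  cat(sprintf("NBSettings: level %d, mode %s, deltaNB = %s A, DCRR <= %s\n",
              object@level, object@mode, format(object@deltaNB),
              format(object@dcrrThreshold)))
})

setMethod("show", "BondTolerances", function(object) {
  cat(sprintf(
    "BondTolerances (A): sb +%.2f, db -%.2f, tb -%.2f; nb cutoff %s\n",
    object@deltaSB, object@deltaDB, object@deltaTB,
    format(object@deltaNB)))
})
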