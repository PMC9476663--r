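test_that("minimum group distance is symmetric and matches geometry", {
  gg <- groupMolecule(generateLinearAlkane(10))
  d15 <- minGroupDistance(gg, 1, 5)
  expect_equal(d15, minGroupDistance(gg, 5, 1))
  # independent check: brute force over the two groups' atoms
  mem <- groupMembers(gg)
  xyz <- atomCoords(gg@molecule)
  brute <- min(as.matrix(stats::dist(xyz))[mem[[1]], mem[[5]]])
  expect_equal(d15, brute, tolerance = 1e-12)
  expect_error(minGroupDistance(gg, 3, 3))
})

test_that("DCRR ratio reproduces the radius-sum arithmetic", {
  bareCarbons <- function(d) {
    two <- Molecule(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)))
    bonds <- perceiveBonds(two)
    # two isolated carbons are flagged as unbonded singleton groups
    expect_warning(groups <- assignGroups(two, bonds), "unbonded")
    buildGroupGraph(two, bonds, groups)
  }
  gg <- bareCarbons(6)
  expect_equal(dcrrRatio(gg, 1, 2), 6 / 1.52, tolerance = 1e-12)
  expect_equal(dcrrRatio(gg, 1, 2), dcrrRatio(gg, 2, 1))
  gg2 <- bareCarbons(3.04)
  expect_equal(dcrrRatio(gg2, 1, 2), 2.0, tolerance = 1e-12)
})

test_that("DBE and DCRR agree on carbon-only systems at matched thresholds", {
  gg <- groupMolecule(generateLinearAlkane(14))
  plan <- bondedPlan(gg, 3)
  for (delta in c(4, 6, 9)) {
    # carbon-carbon contacts scale by r_C + r_C = 1.52; but closest contacts
    # involve hydrogens, so match via explicit pair agreement instead of a
    # single rescale: kept sets must coincide when thresholds are per-pair
    dbe <- allowedPairs(plan, nbSettings(mode = "dbe", deltaNB = delta))
    # reference: filter the no-cutoff pairs by the DBE rule directly
    all_p <- allowedPairs(plan, nbSettings(deltaNB = Inf))
    keep <- vapply(seq_len(nrow(all_p)), function(r)
      minGroupDistance(gg, all_p[r, 1], all_p[r, 2]) <= delta, TRUE)
    expect_equal(unname(dbe), unname(all_p[keep, , drop = FALSE]))
  }
  # carbon-only geometry: strip hydrogens, then DCRR = DBE / 1.52 exactly
  mol <- gg@molecule
  cOnly <- Molecule(rep("C", 14),
                    atomCoords(mol)[atomElements(mol) == "C", ])
  b <- perceiveBonds(cOnly)
  ggc <- buildGroupGraph(cOnly, b, assignGroups(cOnly, b))
  planc <- bondedPlan(ggc, 3)
  for (delta in c(5, 8)) {
    dbe <- allowedPairs(planc, nbSettings(mode = "dbe", deltaNB = delta))
    dcrr <- allowedPairs(planc, nbSettings(mode = "dcrr",
                                           dcrrThreshold = delta / 1.52))
    expect_equal(dbe, dcrr)
  }
})

test_that("heptane level 3 allows exactly the six distant pairs", {
  plan <- bondedPlan(heptaneGraph(), 3)
  prs <- allowedPairs(plan, nbSettings(deltaNB = Inf))
  got <- apply(prs, 1L, paste, collapse = "-")
  expect_setequal(got, c("1-5", "1-6", "1-7", "2-6", "2-7", "3-7"))
  nb <- nbLevel1(plan, nbSettings(deltaNB = Inf))
  expect_length(nb, 6L)
  expect_true(all(vapply(nb, function(f) f@coefficient, 1L) == 1L))
  expect_true(all(vapply(nb, function(f) length(f@components), 1L) == 2L))
})

test_that("a bonded level covering the molecule leaves no nonbonded pairs", {
  plan <- bondedPlan(groupMolecule(generateLinearAlkane(5)), 5)
  expect_equal(nrow(allowedPairs(plan, nbSettings(deltaNB = Inf))), 0L)
  expect_length(nbLevel1(plan, nbSettings()), 0L)
  expect_length(nbLevel2(plan, nbSettings()), 0L)
})

test_that("signed pair coverage equals the allowed-pair indicator at both levels", {
  cases <- list(
    list(gg = heptaneGraph(), m = 3, set = nbSettings(deltaNB = Inf)),
    list(gg = groupMolecule(generateLinearAlkane(12)), m = 2,
         set = nbSettings(deltaNB = Inf)),
    list(gg = groupMolecule(generateLinearAlkane(12)), m = 3,
         set = nbSettings(deltaNB = 6)),
    list(gg = dmpGraph(), m = 2, set = nbSettings(deltaNB = Inf)),
    list(gg = groupMolecule(generateMaxBranchedAlkane()), m = 3,
         set = nbSettings(deltaNB = Inf)))
  for (cs in cases) for (lev in 1:2) {
    st <- nbSettings(lev, cs$set@mode, cs$set@deltaNB, cs$set@dcrrThreshold)
    plan <- fragmentationPlan(cs$gg, cs$m, st)
    cov <- nbPairCoverage(plan)
    want <- matrix(0L, nGroups(cs$gg), nGroups(cs$gg))
    prs <- allowedPairs(plan, st)
    for (r in seq_len(nrow(prs))) {
      want[prs[r, 1], prs[r, 2]] <- 1L
      want[prs[r, 2], prs[r, 1]] <- 1L
    }
    expect_identical(cov, want)
  }
})

test_that("level-2 plans carry only nonzero-coefficient fragments", {
  plan <- fragmentationPlan(heptaneGraph(), 3, nbSettings(level = 2))
  expect_true(all(vapply(fragments(plan, "nonbonded"),
                         function(f) f@coefficient, 1L) != 0L))
})

test_that("nonbonded counts scale quadratically without a cutoff and
           linearly with one", {
  counts <- sapply(c(10, 20, 40), function(n) {
    plan <- bondedPlan(groupMolecule(generateLinearAlkane(n)), 3)
    c(free = length(nbLevel1(plan, nbSettings(deltaNB = Inf))),
      cut = length(nbLevel1(plan, nbSettings(deltaNB = 10))))
  })
  # no cutoff: exactly (n-3)(n-4)/2 pairs on an n-group chain at level 3
  expect_equal(unname(counts["free", ]), c(21, 136, 666))
  # cutoff: constant per-carbon slope (linear); without: slope keeps growing
  slope <- function(v, ns) diff(v) / diff(ns)
  sCut <- slope(counts["cut", ], c(10, 20, 40))
  sFree <- slope(counts["free", ], c(10, 20, 40))
  expect_lt(sCut[2] / sCut[1], 1.2)
  expect_gt(sFree[2] / sFree[1], 1.8)
  expect_lt(counts["cut", 3] / counts["cut", 2], 2.5)
})

test_that("a cutoff strictly reduces the level-2 fragment count on a long chain", {
  plan <- bondedPlan(groupMolecule(generateLinearAlkane(30)), 3)
  free <- length(nbLevel2(plan, nbSettings(level = 2, deltaNB = Inf)))
  cut <- length(nbLevel2(plan, nbSettings(level = 2, deltaNB = 8)))
  expect_lt(cut, free)
  expect_gt(cut, 0L)
})
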