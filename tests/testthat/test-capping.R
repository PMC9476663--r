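test_that("cap placement follows the covalent-radius length ratio", {
  # severed C-C at 1.54 A: rho = (0.76+0.31)/(0.76+0.76), cap C-H 1.084 A
  cap <- placeCap(c(0, 0, 0), c(1.54, 0, 0), "C", "C")
  expect_equal(cap, c(1.54 * 1.07 / 1.52, 0, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(cap^2)), 1.084, tolerance = 1e-3)
  # removing a hydrogen: rho = 1, cap coincides with the removed atom
  capH <- placeCap(c(0, 0, 0), c(0, 1.09, 0), "C", "H")
  expect_equal(capH, c(0, 1.09, 0), tolerance = 1e-12)
  # collinearity and interiority for rho < 1
  anchor <- c(1, 2, 3); removed <- c(2.2, 0.5, 3.9)
  capCN <- placeCap(anchor, removed, "C", "N")
  v1 <- capCN - anchor; v2 <- removed - anchor
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  expect_equal(cosang, 1, tolerance = 1e-12)
  expect_lt(sqrt(sum(v1^2)), sqrt(sum(v2^2)))
  expect_error(placeCap(anchor, anchor, "C", "C"), "coincide")
})

test_that("capped realizations have the expected stoichiometry", {
  gg <- heptaneGraph()
  plan <- bondedPlan(gg, 3)
  fr <- fragments(plan, "bonded")
  keys <- vapply(fr, structureKey, "")
  # interior three-group fragment -> propane; four-group -> butane
  expect_equal(elementFormula(
    realizeFragment(fr[[match("2+3+4", keys)]], gg)@elements), "C3H8")
  expect_equal(elementFormula(
    realizeFragment(fr[[match("2+3+4+5", keys)]], gg)@elements), "C4H10")
  # an interior group alone caps to methane
  lone <- new("SignedFragment", groups = 4L, coefficient = 1L,
              kind = "bonded", components = list(4L))
  expect_equal(elementFormula(realizeFragment(lone, gg)@elements), "CH4")
  # nonbonded dimer of interior groups: two methanes
  dim45 <- new("SignedFragment", groups = c(3L, 5L), coefficient = 1L,
               kind = "nonbonded", components = list(3L, 5L))
  cp <- realizeFragment(dim45, gg)
  expect_equal(elementFormula(cp@elements), "C2H8")
  expect_equal(length(cp@capAnchor), 4L)
})

test_that("whole-molecule fragments need no caps", {
  gg <- heptaneGraph()
  whole <- new("SignedFragment", groups = 1:7, coefficient = 1L,
               kind = "bonded", components = list(1:7))
  cp <- realizeFragment(whole, gg)
  expect_length(cp@capAnchor, 0L)
  expect_equal(elementFormula(cp@elements),
               elementFormula(atomElements(gg@molecule)))
})

test_that("signed cap balance nets to zero with the expected split", {
  hp <- bondedPlan(heptaneGraph(), 3)
  ct <- capCountTable(hp)
  signed <- ct$coefficient * ct$caps
  expect_equal(sum(signed[ct$coefficient > 0]), 6L)
  expect_equal(sum(signed[ct$coefficient < 0]), -6L)
  expect_equal(capBalance(hp), 0L)

  dp <- bondedPlan(dmpGraph(), 3)
  ct <- capCountTable(dp)
  sizes <- lengths(strsplit(ct$fragment, "+", fixed = TRUE))
  signed <- ct$coefficient * ct$caps
  expect_equal(sum(signed[sizes == 4]), 14L)
  expect_equal(sum(signed[sizes == 3]), -20L)
  expect_equal(sum(signed[sizes == 2]), 6L)
  expect_equal(capBalance(dp), 0L)

  # single whole-molecule fragment
  expect_equal(capBalance(bondedPlan(groupMolecule(
    generateLinearAlkane(3)), 3)), 0L)
})

test_that("signed element composition of the bonded plan reproduces the molecule", {
  for (gg in list(heptaneGraph(), dmpGraph())) for (m in 1:3) {
    plan <- bondedPlan(gg, m)
    tot <- integer(0)
    for (f in fragments(plan, "bonded")) {
      el <- table(realizeFragment(f, gg)@elements)
      for (e in names(el)) {
        tot[e] <- (if (is.na(tot[e])) 0L else tot[e]) +
          f@coefficient * el[[e]]
      }
    }
    want <- table(atomElements(gg@molecule))
    expect_equal(tot[sort(names(tot))],
                 setNames(as.integer(want), names(want))[sort(names(tot))])
  }
})

test_that("emitted jobs are deterministic and the manifest covers the plan", {
  plan <- fragmentationPlan(heptaneGraph(), 3, nbSettings(level = 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  j1 <- emitJobs(plan, d1)
  j2 <- emitJobs(plan, d2)
  man <- read.delim(j1$manifest, stringsAsFactors = FALSE)
  expect_equal(nrow(man), length(fragments(plan)))
  expect_equal(sum(man$kind == "bonded"), 7L)
  expect_equal(sum(man$kind == "nonbonded"), 6L)
  # byte-identical rerun
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # every referenced structure file exists
  expect_true(all(file.exists(file.path(d1, man$structure_file))))
})

test_that("energy ingestion round-trips through the delimited format", {
  plan <- fragmentationPlan(heptaneGraph(), 3, nbSettings(level = 1))
  en <- computeToyEnergies(plan, toyParams(pair = centroidPair))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(structure = names(en), energy = en),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  en2 <- readEnergies(f)
  expect_equal(en2[names(en)], setNames(en, names(en)), tolerance = 1e-12)
  l1 <- assembleEnergy(plan, en)
  l2 <- assembleEnergy(plan, en2)
  expect_equal(l1@Etotal, l2@Etotal, tolerance = 1e-12)
})

test_that("missing and conflicting records are reported by structure", {
  plan <- bondedPlan(heptaneGraph(), 3)
  en <- computeToyEnergies(plan)
  expect_error(assembleEnergy(plan, en[-1]),
               paste0("missing energy record for structure '",
                      names(en)[1], "'"), fixed = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(structure = c(names(en), names(en)[1]),
                   energy = c(en, en[[1]] + 1))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readEnergies(f), "conflicting duplicate")
})
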