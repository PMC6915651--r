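mboI <- defaultEnzymes()$MboI

test_that("species profiling clusters records into pattern variants", {
  recs <- Biostrings::DNAStringSet(c(a1 = "AAAGATCTTTTTTTTT",
                                     a2 = "AAAGATCTTTTTTTTT",
                                     b1 = "AAAGATCTTTTTTTTT"))
  panel <- ReferencePanel(recs, species = c("A", "A", "B"))
  params <- gelParams(minBand = 1)
  profs <- profileSpecies(panel, mboI, params)
  expect_length(profs, 2)
  expect_identical(vapply(profs, variantCount, integer(1)), c(1L, 1L))
  expect_true(patternsMatch(profileVariants(profs[[1]])[[1]],
                            profileVariants(profs[[2]])[[1]]))
  expect_identical(profs[[1]]@supportIds[[1]], c("a1", "a2"))

  # a planted site gain yields a second intraspecific variant
  sim <- makePanel(seed = 5, nSpecies = 2, nPerSpecies = 2, length = 500,
                   intraspecificRate = 0)
  seqs <- as.character(sim$panel)
  variant <- makeCladeVariant(seqs[1], mboI, "add-site", seed = 2)
  recs2 <- Biostrings::DNAStringSet(c(seqs, x = variant))
  panel2 <- ReferencePanel(recs2, species = c(panelSpecies(sim$panel),
                                              panelSpecies(sim$panel)[1]))
  profs2 <- profileSpecies(panel2, mboI)
  counts <- vapply(profs2, variantCount, integer(1))
  names(counts) <- vapply(profs2, profileSpeciesName, character(1))
  expect_identical(counts[[panelSpecies(sim$panel)[1]]], 2L)
})

test_that("variant count never exceeds the number of records per species", {
  for (seed in 1:5) {
    sim <- makePanel(seed = seed, nSpecies = 3, nPerSpecies = 4,
                     length = 600, intraspecificRate = 0.01)
    profs <- profileSpecies(sim$panel, mboI)
    for (p in profs) {
      expect_lte(variantCount(p),
                 sum(panelSpecies(sim$panel) == profileSpeciesName(p)))
    }
  }
})

test_that("enzyme evaluation flags colliding species and is order-invariant", {
  same <- Biostrings::DNAStringSet(c(a = "AAAGATCTTTTT", b = "AAAGATCTTTTT"))
  collide <- ReferencePanel(same, species = c("A", "B"))
  rep1 <- evaluateEnzyme(profileSpecies(collide, mboI, gelParams(minBand = 1)))
  expect_false(discriminatesAll(rep1))

  sim <- makePanel(seed = 9, nSpecies = 4, nPerSpecies = 2, length = 650,
                   intraspecificRate = 0)
  profs <- profileSpecies(sim$panel, mboI)
  rep2 <- evaluateEnzyme(profs)
  expect_true(discriminatesAll(rep2))
  expect_false(rep2@flagged)
  # permutation invariance of the species order
  repPerm <- evaluateEnzyme(profs[c(3, 1, 4, 2)])
  sp <- rownames(distinguishablePairs(rep2))
  expect_identical(distinguishablePairs(repPerm)[sp, sp],
                   distinguishablePairs(rep2))
  expect_identical(discriminatesAll(repPerm), discriminatesAll(rep2))

  single <- evaluateEnzyme(profs[1])
  expect_true(discriminatesAll(single))
  expect_true(single@flagged)
})

test_that("the planted enzyme is selected first on synthetic panels", {
  for (seed in c(3, 14, 27)) {
    sim <- makePanel(seed = seed, nSpecies = 5, nPerSpecies = 2,
                     length = 700, intraspecificRate = 0)
    sel <- selectEnzymes(sim$panel, defaultEnzymes())
    expect_identical(reportEnzyme(sel$reports[[1]]), "MboI")
    expect_true(discriminatesAll(sel$reports[[1]]))
    expect_true(solutionFeasible(sel$solution))
    expect_identical(solutionEnzymes(sel$solution), "MboI")
    # decoys cannot discriminate: they cut nothing, so only amplicon
    # length separates species
    for (r in sel$reports[-1]) {
      expect_identical(sum(variantCounts(r)), 5L)
    }
  }
})

test_that("greedy enzyme-set cover matches the exhaustive minimum", {
  fx <- setCoverFixture()
  sel <- selectEnzymes(fx$panel, fx$enzymes)
  expect_false(discriminatesAll(sel$reports[[1]]))
  expect_true(solutionFeasible(sel$solution))
  expect_identical(solutionEnzymes(sel$solution), c("e2", "e1"))
  expect_identical(length(solutionEnzymes(sel$solution)),
                   as.integer(exhaustiveMinCover(fx$panel, fx$enzymes)))

  # single-enzyme panels also agree with exhaustive search
  sim <- makePanel(seed = 21, nSpecies = 3, nPerSpecies = 1, length = 600,
                   intraspecificRate = 0)
  sel2 <- selectEnzymes(sim$panel, defaultEnzymes())
  expect_identical(length(solutionEnzymes(sel2$solution)),
                   as.integer(exhaustiveMinCover(sim$panel,
                                                 defaultEnzymes())))

  # unresolvable pair: identical sequences for two species
  same <- Biostrings::DNAStringSet(c(a = strrep("ACT", 100),
                                     b = strrep("ACT", 100)))
  sel3 <- selectEnzymes(ReferencePanel(same, species = c("A", "B")),
                        defaultEnzymes())
  expect_false(solutionFeasible(sel3$solution))
  expect_match(sel3$solution@diagnostic, "infeasible")
})

test_that("sample assignment calls species, ambiguity and non-matches", {
  profs <- profilesFromPatterns(
    c("A", "B", "B"),
    list(c(510), c(400, 110), c(400, 150)))
  hit <- assignSample(c(512), profs)
  expect_identical(hit$call, "A")
  expect_identical(hit$score, 1)
  hit2 <- assignSample(c(398, 112), profs)
  expect_identical(hit2$call, "B")
  expect_identical(hit2$variant, 1L)
  expect_identical(assignSample(c(999), profs)$call, "unassigned")

  # two species sharing a pattern are ambiguous at full match
  shared <- profilesFromPatterns(c("A", "B"), list(c(300), c(302)))
  expect_identical(assignSample(c(301), shared)$call, "ambiguous")

  # sub-threshold partial matches can be rescued by lowering the threshold
  part <- assignSample(c(400), profs, threshold = 0.6)
  expect_identical(part$call, "B")
  expect_lt(part$score, 1)

  # sequences are digested before matching
  sim <- makePanel(seed = 2, nSpecies = 3, nPerSpecies = 2, length = 600,
                   intraspecificRate = 0)
  sprofs <- profileSpecies(sim$panel, mboI)
  for (k in seq_along(sim$panel)) {
    a <- assignSample(as.character(sim$panel)[k], sprofs, mboI)
    expect_identical(a$call, panelSpecies(sim$panel)[k])
    expect_identical(a$score, 1)
  }
  expect_error(assignSample(c(400), list()), "empty")
  expect_error(assignSample(as.character(sim$panel)[1], sprofs),
               "requires 'enzyme'")
})
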