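mboI <- defaultEnzymes()$MboI

test_that("panel generation is deterministic and reproducible from the seed", {
  simA <- makePanel(seed = 8, nSpecies = 3, nPerSpecies = 3, length = 600)
  simB <- makePanel(seed = 8, nSpecies = 3, nPerSpecies = 3, length = 600)
  expect_identical(writeFastaRecords(simA$panel),
                   writeFastaRecords(simB$panel))
  expect_identical(writeTruthJSON(simA$truth), writeTruthJSON(simB$truth))
  simC <- makePanel(seed = 9, nSpecies = 3, nPerSpecies = 3, length = 600)
  expect_false(identical(as.character(simA$panel),
                         as.character(simC$panel)))
})

test_that("digesting generated records reproduces the planted truth exactly", {
  sim <- makePanel(seed = 4, nSpecies = 4, nPerSpecies = 3, length = 650,
                   intraspecificRate = 0.005)
  species <- panelSpecies(sim$panel)
  seqs <- as.character(sim$panel)
  for (k in seq_along(seqs)) {
    sp <- species[k]
    expect_identical(digestSequence(seqs[k], mboI),
                     sim$truth$expectedFragments[[sp]])
    expect_identical(cutPositions(findSites(seqs[k], mboI)),
                     sim$truth$cutPositions[[sp]])
  }
  # expected species patterns are pairwise non-matching by construction
  pats <- sim$truth$expectedPatterns
  for (i in seq_along(pats)) {
    for (j in seq_along(pats)) {
      expect_identical(patternsMatch(pats[[i]], pats[[j]]), i == j)
    }
  }
})

test_that("decoy enzymes never cut generated sequences", {
  sim <- makePanel(seed = 16, nSpecies = 3, nPerSpecies = 2, length = 600,
                   intraspecificRate = 0.01)
  decoys <- defaultEnzymes()[setdiff(names(defaultEnzymes()), "MboI")]
  for (s in as.character(sim$panel)) {
    for (enz in decoys) {
      scan <- findSites(s, enz)
      expect_length(cutPositions(scan), 0)
      expect_length(candidatePositions(scan), 0)
    }
  }
})

test_that("intraspecific rate zero gives identical within-species copies", {
  sim <- makePanel(seed = 6, nSpecies = 2, nPerSpecies = 4, length = 500,
                   intraspecificRate = 0)
  seqs <- split(as.character(sim$panel), panelSpecies(sim$panel))
  for (s in seqs) expect_identical(length(unique(s)), 1L)

  simMut <- makePanel(seed = 6, nSpecies = 2, nPerSpecies = 4,
                      length = 500, intraspecificRate = 0.02)
  seqsMut <- split(as.character(simMut$panel), panelSpecies(simMut$panel))
  expect_gt(max(vapply(seqsMut, function(s) length(unique(s)), integer(1))),
            1L)
})

test_that("infeasible layouts fail with a diagnostic instead of looping", {
  expect_error(makePanel(seed = 1, nSpecies = 40, nPerSpecies = 1,
                         length = 300, maxAttempts = 150),
               "too short")
})

test_that("clade variants gain or lose exactly one site without resizing", {
  sim <- makePanel(seed = 12, nSpecies = 2, nPerSpecies = 1, length = 600,
                   intraspecificRate = 0)
  src <- unname(as.character(sim$panel)[1])
  nCuts <- length(cutPositions(findSites(src, mboI)))

  added <- makeCladeVariant(src, mboI, "add-site", seed = 3)
  expect_identical(nchar(added), nchar(src))
  expect_identical(length(digestSequence(added, mboI)),
                   length(digestSequence(src, mboI)) + 1L)
  expect_false(patternsMatch(makePattern(digestSequence(added, mboI)),
                             makePattern(digestSequence(src, mboI))))

  if (nCuts > 0) {
    removed <- makeCladeVariant(src, mboI, "remove-site", seed = 3)
    expect_identical(nchar(removed), nchar(src))
    expect_identical(length(cutPositions(findSites(removed, mboI))),
                     nCuts - 1L)
  }

  siteless <- strrep("ACT", 150)
  expect_error(makeCladeVariant(siteless, mboI, "remove-site", seed = 1),
               "at least one existing")
})
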