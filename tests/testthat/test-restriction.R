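mboI <- parseEnzyme("MboI", "^GATC")
hinfI <- parseEnzyme("HinfI", "G^ANTC")
hindIII <- parseEnzyme("HindIII", "A^AGCTT")

test_that("caret notation parses into pattern and cut offset", {
  expect_identical(enzymePattern(mboI), "GATC")
  expect_identical(enzymeCutOffset(mboI), 0L)
  expect_identical(enzymePattern(hinfI), "GANTC")
  expect_identical(enzymeCutOffset(hinfI), 1L)
  expect_error(parseEnzyme("bad", "GATC"), "cut marker")
  expect_error(parseEnzyme("bad", "G^AT^C"), "cut marker")
  expect_error(parseEnzyme("bad", "G^AFC"), "non-IUPAC")
  five <- defaultEnzymes()
  expect_identical(names(five),
                   c("HpaII", "HinfI", "MboI", "RsaI", "HindIII"))
  expect_identical(enzymePattern(five$RsaI), "GTAC")
  expect_identical(enzymeCutOffset(five$RsaI), 2L)
})

test_that("site scanning handles exact, ambiguous and bottom-strand matches", {
  expect_identical(cutPositions(findSites("GATCGATC", mboI)), c(0L, 4L))
  expect_identical(cutPositions(findSites("GAATC", hinfI)), 1L)
  # pattern longer than sequence: empty scan, not an error
  scan <- findSites("ACGT", hindIII)
  expect_length(cutPositions(scan), 0)
  expect_length(candidatePositions(scan), 0)
  # sequence-side ambiguity is conservative: N can complete a site but is
  # reported as a candidate, not a cut
  scan <- findSites("AAGATNAA", mboI)
  expect_identical(cutPositions(scan), integer(0))
  expect_identical(candidatePositions(scan), 2L)
  # sequence R inside pattern-set positions is a confirmed match when its
  # set is contained in the pattern code's set (R subset of N)
  expect_identical(cutPositions(findSites("GARTC", hinfI)), 1L)
  # overlapping matches all count
  aa <- parseEnzyme("toy", "^AA")
  expect_identical(cutPositions(findSites("AAAA", aa)), c(0L, 1L, 2L))
  # bottom-strand-only match maps through L - cutOffset
  gga <- parseEnzyme("asym", "^GGA")
  expect_identical(cutPositions(findSites("AATCCAA", gga)), 5L)
  expect_identical(cutPositions(findSites("AATCCAA", gga,
                                          bothStrands = FALSE)),
                   integer(0))
})

test_that("both-strand scanning equals top-strand scanning for palindromic sites", {
  set.seed(11)
  for (enz in defaultEnzymes()) {
    expect_identical(revComp(enzymePattern(enz)), enzymePattern(enz))
    for (i in 1:10) {
      s <- randomDNA(sample(50:200, 1))
      expect_identical(cutPositions(findSites(s, enz)),
                       cutPositions(findSites(s, enz, bothStrands = FALSE)))
    }
  }
})

test_that("scanner agrees with the brute-force IUPAC-expansion oracle", {
  set.seed(23)
  for (i in 1:25) {
    s <- randomDNA(sample(20:120, 1))
    for (enz in defaultEnzymes()) expectScanEqualsOracle(s, enz)
  }
  for (i in 1:15) {
    s <- randomAmbiguousDNA(sample(20:80, 1), nAmbig = 4)
    for (enz in defaultEnzymes()) expectScanEqualsOracle(s, enz)
  }
  # ambiguity on both sides, non-palindromic pattern
  wob <- parseEnzyme("wobble", "R^GAY")
  for (i in 1:15) {
    s <- randomAmbiguousDNA(sample(20:60, 1), nAmbig = 3)
    expectScanEqualsOracle(s, wob)
  }
})

test_that("digestion produces ordered fragments that conserve length", {
  expect_identical(digestSequence("AAAGATCTT", mboI), c(3L, 6L))
  expect_identical(digestSequence("AAAA", mboI), 4L)
  expect_identical(digestSequence("GATCGATC", mboI), c(4L, 4L))
  expect_identical(digestSequence("TTGACTCTT", hinfI), c(3L, 6L))
  set.seed(31)
  for (i in 1:40) {
    s <- randomAmbiguousDNA(sample(30:300, 1), nAmbig = 2)
    for (enz in defaultEnzymes()) {
      frags <- digestSequence(s, enz)
      expect_identical(sum(frags), nchar(s))
      expect_true(all(frags > 0))
      if (!length(cutPositions(findSites(s, enz)))) {
        expect_identical(frags, nchar(s))
      }
    }
  }
})

test_that("digesting the reverse complement reverses centred-cut fragments", {
  # exact fragment-list reversal needs the cut centred in the site
  # (RsaI GT^AC); off-centre cuts shift boundaries by the overhang
  rsaI <- defaultEnzymes()$RsaI
  set.seed(37)
  for (i in 1:15) {
    s <- randomDNA(250)
    expect_identical(digestSequence(revComp(s), rsaI),
                     rev(digestSequence(s, rsaI)))
  }
})

test_that("digest tables hold one row per record and enzyme", {
  recs <- Biostrings::DNAStringSet(c(r1 = "AAAGATCTT", r2 = "AAAA"))
  tab <- digestRecords(recs, list(mboI, hinfI))
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$fragment_sizes[tab$record_id == "r1" &
                                      tab$enzyme == "MboI"], "3,6")
  expect_identical(tab$n_sites[tab$record_id == "r2" &
                               tab$enzyme == "MboI"], 0L)
})

test_that("in silico PCR recovers the primer-to-primer amplicon", {
  set.seed(41)
  fwd <- "ACGTACGTACGTACGTAA"
  rev <- "TTGCATGCATGCATGCAT"
  core <- randomDNA(20)
  template <- paste0(fwd, core, revComp(rev))
  pp <- primerPair(fwd, rev)
  res <- insilicoPCR(template, pp)
  expect_identical(res$status, "ok")
  expect_identical(nchar(res$amplicon), nchar(fwd) + 20L + nchar(rev))
  expect_identical(res$amplicon, template)

  # tails are carried verbatim
  tailed <- primerPair(fwd, rev, forwardTail = strrep("T", 18),
                       reverseTail = strrep("A", 18))
  expect_identical(nchar(insilicoPCR(template, tailed)$amplicon),
                   nchar(template) + 36L)

  # missing reverse primer site
  expect_identical(insilicoPCR(paste0(fwd, core), pp)$status, "no-product")

  # mismatch tolerance: 2 mismatches anneal, 3 do not
  mut <- template
  for (p in c(2, 5)) substr(mut, p, p) <- "T"
  expect_identical(insilicoPCR(mut, pp)$status, "ok")
  substr(mut, 8, 8) <- "C"
  expect_identical(insilicoPCR(mut, pp)$status, "no-product")

  # flanking context does not change the product
  framed <- paste0(randomDNA(30), template, randomDNA(30))
  expect_identical(insilicoPCR(framed, pp)$amplicon, template)
})
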