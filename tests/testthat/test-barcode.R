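test_that("coding screen uses the vertebrate mitochondrial code", {
  expect_true(codingPass(checkCoding("ATGGCTGCT")))
  expect_identical(bestFrame(checkCoding("ATGGCTGCT")), 0L)
  # TGA is tryptophan in mitochondria but a stop in the standard code:
  # build a long frame-0 coding sequence rich in TGA codons, whose shifted
  # frames contain stops under either code
  set.seed(83)
  codons <- sample(mitoSenseCodons(), 180, replace = TRUE)
  codons[seq(10, 170, by = 20)] <- "TGA"
  tgaRich <- paste(codons, collapse = "")
  expect_true(codingPass(checkCoding(tgaRich)))
  expect_identical(bestFrame(checkCoding(tgaRich)), 0L)
  expect_false(codingPass(checkCoding(tgaRich, geneticCode = "1")))
  # AGA is a vertebrate-mitochondrial stop (coding under the standard code)
  agaBroken <- tgaRich
  substr(agaBroken, 301, 303) <- "AGA"
  expect_false(codingPass(checkCoding(agaBroken)))
  # a terminal stop codon is not premature
  expect_true(codingPass(checkCoding("ATGGCTAGA")))
  expect_error(checkCoding("AT"), "shorter than one codon")
})

test_that("short sequences are flagged as possible NUMTs", {
  set.seed(3)
  shortSeq <- randomDNA(450)
  expect_true(lengthFlagged(checkCoding(shortSeq)))
  expect_false(lengthFlagged(checkCoding(randomDNA(652))))
  expect_true(lengthFlagged(checkCoding(randomDNA(652),
                                        numtLengthThreshold = 700)))
})

test_that("codon-wise coding sequences pass; stop insertions fail all frames", {
  set.seed(19)
  sense <- mitoSenseCodons()
  stops <- mitoStopCodons()
  for (i in 1:15) {
    nCodons <- sample(50:220, 1)
    seqStr <- paste(sample(sense, nCodons, replace = TRUE), collapse = "")
    chk <- checkCoding(seqStr)
    expect_true(codingPass(chk))
    expect_identical(bestFrame(chk), 0L)
    expect_identical(nchar(checkProtein(chk)), nCodons)
    # plant one stop mid-frame in each of the three forward frames, in
    # disjoint codon regions so the plants cannot overwrite one another
    broken <- seqStr
    anchors <- c(10, 20, 30)
    for (frame in 0:2) {
      at <- 3 * anchors[frame + 1] + frame
      substr(broken, at + 1, at + 3) <- sample(stops, 1)
    }
    expect_false(codingPass(checkCoding(broken)))
  }
})

test_that("six-frame search rescues reverse-complemented input", {
  set.seed(29)
  seqStr <- paste(sample(mitoSenseCodons(), 120, replace = TRUE),
                  collapse = "")
  rc <- revComp(seqStr)
  expect_true(codingPass(checkCoding(rc, allFrames = TRUE)))
  expect_gte(bestFrame(checkCoding(rc, allFrames = TRUE)), 0L)
})

test_that("qc tables summarise verdicts per record", {
  set.seed(59)
  good <- paste(sample(mitoSenseCodons(), 210, replace = TRUE),
                collapse = "")
  bad <- paste0(substr(good, 1, 300), "AGA", substr(good, 304, 630))
  recs <- Biostrings::DNAStringSet(c(ok = good, numt = bad))
  tab <- qcRecords(recs)
  expect_identical(tab$verdict, c("pass", "fail"))
  expect_identical(tab$record_id, c("ok", "numt"))
  expect_false(any(tab$length_flag[1]))
})

test_that("best-match identification scores identity over aligned columns", {
  set.seed(47)
  refA <- randomDNA(652)
  refB <- refA
  for (p in c(11, 101, 303, 440, 551)) {
    substr(refB, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(refA, p, p))[1]
  }
  refs <- Biostrings::DNAStringSet(c(accA = refA, accB = refB))
  S4Vectors::mcols(refs) <- S4Vectors::DataFrame(
    species = c("Prionace glauca", "Mustelus mustelus"))

  exact <- bestMatch(refA, refs, "q0")
  expect_identical(identityPct(exact), 100)
  expect_identical(hitSubject(exact), "accA")
  expect_identical(exact@alignedColumns, 652L)

  # one substitution over 652 columns: 651/652 -> 99.85
  q1 <- refA
  substr(q1, 300, 300) <- setdiff(c("A", "C", "G", "T"),
                                  substr(refA, 300, 300))[1]
  hit <- bestMatch(q1, refs)
  expect_identical(identityPct(hit), 99.85)
  expect_identical(hitSpecies(hit), "Prionace glauca")

  # a query equidistant from nothing: nearer reference wins
  expect_identical(hitSubject(bestMatch(refB, refs)), "accB")

  # truncated query still aligns over its own length (free end gaps)
  hit3 <- bestMatch(substr(refA, 51, 450), refs)
  expect_identical(identityPct(hit3), 100)
  expect_identical(hit3@alignedColumns, 400L)

  expect_error(bestMatch(refA, Biostrings::DNAStringSet()), "length")
})

test_that("mislabeling rates and substitution tallies recompute from counts", {
  surv <- utils::read.delim(
    system.file("extdata", "market_survey.tsv", package = "coiRFLP"),
    stringsAsFactors = FALSE)
  rep <- mislabelingReport(surv)
  per <- mislabelingPerGroup(rep)
  expect_identical(per$percent[per$group == "2018"], 15.0)
  expect_identical(per$mismatched[per$group == "2018"], 3L)
  expect_identical(per$percent[per$group == "2010"], 6.7)
  expect_identical(per$percent[per$group == "reference"], 0)
  expect_identical(rep@total, 45L)
  subs <- mislabelingSubstitutions(rep)
  expect_identical(subs$count[subs$matched == "Prionace glauca"], 2L)
  expect_identical(sum(subs$count), 4L)

  # name normalisation: case and whitespace differences are not mismatches
  df <- data.frame(id = "s", declared = " xiphias  GLADIUS ",
                   matched = "Xiphias gladius")
  expect_identical(mislabelingReport(df)@mismatched, 0L)

  clean <- data.frame(id = c("a", "b"), declared = "X", matched = "X")
  expect_identical(mislabelingPerGroup(mislabelingReport(clean))$percent, 0)

  empty <- mislabelingReport(data.frame())
  expect_identical(empty@total, 0L)
  expect_identical(nrow(mislabelingPerGroup(empty)), 0L)
})
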