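# Hand-built fixtures constructed in code at test time.

# Backbone over {A,C} only: cannot contain GGCC or TTAA, so those two
# artificial enzymes cut exactly where we plant them.
acBackbone <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
}

plantMotif <- function(sequence, motif, at0) {
  # at0 = 0-based start of the motif
  paste0(substr(sequence, 1L, at0),
         motif,
         substr(sequence, at0 + nchar(motif) + 1L, nchar(sequence)))
}

# A three-species panel in which no single enzyme separates every pair:
#   e1 (^GGCC) separates A from B only (C carries both e1 patterns as
#   intraspecific variants), e2 (^TTAA) separates C from both A and B.
# The unique minimal cover is {e2, e1}.
setCoverFixture <- function() {
  e1 <- parseEnzyme("e1", "^GGCC")
  e2 <- parseEnzyme("e2", "^TTAA")
  n <- 420L
  bbA <- acBackbone(n, seed = 101)
  bbB <- acBackbone(n, seed = 102)
  bbC <- acBackbone(n, seed = 103)
  seqA <- plantMotif(bbA, "GGCC", 200L)           # e1: [200, 220]
  seqB <- bbB                                     # e1: [420]
  seqC1 <- plantMotif(bbC, "TTAA", 150L)          # e1: [420], e2: [150, 270]
  seqC2 <- plantMotif(seqC1, "GGCC", 205L)        # e1: [205, 215]
  recs <- Biostrings::DNAStringSet(c(a1 = seqA, b1 = seqB,
                                     c1 = seqC1, c2 = seqC2))
  panel <- ReferencePanel(recs, species = c("A", "B", "C", "C"))
  list(panel = panel, enzymes = list(e1 = e1, e2 = e2))
}

# exhaustive minimal cover size over all non-empty enzyme subsets
exhaustiveMinCover <- function(panel, enzymes, params = gelParams()) {
  species <- panelSpeciesNames(panel)
  allPairs <- apply(combn(sort(species), 2L), 2L, paste, collapse = "|")
  coverOf <- lapply(enzymes, function(e) {
    m <- distinguishablePairs(evaluateEnzyme(profileSpecies(panel, e,
                                                            params)))
    idx <- which(upper.tri(m) & m, arr.ind = TRUE)
    if (!nrow(idx)) return(character(0L))
    vapply(seq_len(nrow(idx)), function(k)
      paste(sort(c(rownames(m)[idx[k, 1L]], colnames(m)[idx[k, 2L]])),
            collapse = "|"), character(1L))
  })
  best <- Inf
  for (size in seq_along(enzymes)) {
    for (subset in asplit(combn(length(enzymes), size), 2L)) {
      if (setequal(intersect(unique(unlist(coverOf[subset])), allPairs),
                   allPairs)) {
        best <- min(best, size)
      }
    }
    if (is.finite(best)) break
  }
  best
}

# profiles built from the observed reference gel patterns shipped with the
# package (one row per species variant)
referenceGelProfiles <- function(params = gelParams()) {
  tab <- utils::read.delim(
    system.file("extdata", "reference_band_patterns.tsv",
                package = "coiRFLP"), stringsAsFactors = FALSE)
  profilesFromPatterns(tab$species,
                       lapply(strsplit(tab$bands, ","), as.numeric),
                       enzyme = "MboI", params = params,
                       ids = tab$sample_id)
}

# non-stop codons of the vertebrate mitochondrial code, for building
# guaranteed-coding sequences codon-wise
mitoSenseCodons <- function() {
  code <- Biostrings::getGeneticCode("2")
  names(code)[code != "*"]
}

mitoStopCodons <- function() {
  code <- Biostrings::getGeneticCode("2")
  names(code)[code == "*"]
}
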