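# Restriction enzyme modelling and in silico digestion. Coordinates are
# 0-based and half-open: "cut at position p" means the phosphodiester bond
# between residues p-1 and p is cleaved, so fragment lengths are plain
# differences of cut coordinates.

#' Parse a restriction enzyme from caret notation
#'
#' Caret notation writes the recognition site with a single `^` marking the
#' top-strand cut, e.g. `"^GATC"` (MboI, cut before the site) or `"G^ANTC"`
#' (HinfI, cut after the first base).
#'
#' @param name Enzyme name.
#' @param site Recognition site in caret notation; exactly one `^`.
#' @return A [RestrictionEnzyme-class].
#' @examples
#' parseEnzyme("MboI", "^GATC")
#' parseEnzyme("HinfI", "G^ANTC")
#' @export
parseEnzyme <- function(name, site) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(site), length(site) == 1L)
  ncuts <- lengths(regmatches(site, gregexpr("^", site, fixed = TRUE)))
  if (ncuts != 1L) {
    stop("recognition site '", site, "' must contain exactly one '^' ",
         "cut marker (found ", ncuts, ")", call. = FALSE)
  }
  offset <- as.integer(regexpr("^", site, fixed = TRUE)) - 1L
  pattern <- toupper(sub("^", "", site, fixed = TRUE))
  if (!.validIupac(pattern)) {
    stop("recognition pattern '", pattern, "' contains non-IUPAC characters",
         call. = FALSE)
  }
  methods::new("RestrictionEnzyme", name = name, pattern = pattern,
               cutOffset = offset)
}

#' Enzyme accessors
#' @param enzyme A [RestrictionEnzyme-class].
#' @return `enzymeName()`/`enzymePattern()`: a string; `enzymeCutOffset()`:
#'   an integer.
#' @export
enzymeName <- function(enzyme) enzyme@name

#' @rdname enzymeName
#' @export
enzymePattern <- function(enzyme) enzyme@pattern

#' @rdname enzymeName
#' @export
enzymeCutOffset <- function(enzyme) enzyme@cutOffset

setMethod("show", "RestrictionEnzyme", function(object) {
  p <- object@pattern
  cat(sprintf("RestrictionEnzyme %s: %s^%s\n", object@name,
              substr(p, 1L, object@cutOffset),
              substr(p, object@cutOffset + 1L, nchar(p))))
})

#' Load a restriction enzyme table
#'
#' Reads a TSV with columns `name` and `site` (caret notation) into a named
#' list of [RestrictionEnzyme-class] objects. `defaultEnzymes()` loads the
#' table shipped with the package: the five enzymes commonly screened for
#' COI-barcode RFLP of fish (HpaII `C^CGG`, HinfI `G^ANTC`, MboI `^GATC`,
#' RsaI `GT^AC`, HindIII `A^AGCTT`), all with palindromic sites.
#'
#' @param path Path to the enzyme TSV.
#' @return A named list of enzymes, in table order.
#' @examples
#' names(defaultEnzymes())
#' @export
readEnzymeTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "site") %in% colnames(tab))) {
    stop("enzyme table needs columns 'name' and 'site'", call. = FALSE)
  }
  enzymes <- mapply(parseEnzyme, tab$name, tab$site, SIMPLIFY = FALSE)
  names(enzymes) <- tab$name
  enzymes
}

#' @rdname readEnzymeTable
#' @export
defaultEnzymes <- function() {
  readEnzymeTable(system.file("extdata", "enzymes.tsv",
                              package = "coiRFLP", mustWork = TRUE))
}

# Confirmed / candidate window starts (0-based) for one pattern against one
# sequence. Subset rule: the sequence base's IUPAC set must be contained in
# the pattern code's set for a confirmed match; a bare non-empty
# intersection at any position demotes the window to candidate.
.scanWindows <- function(seqBits, patBits) {
  L <- length(patBits)
  n <- length(seqBits) - L + 1L
  if (n < 1L) return(list(confirmed = integer(0L), candidate = integer(0L)))
  confirmed <- rep(TRUE, n)
  possible <- rep(TRUE, n)
  for (j in seq_len(L)) {
    sb <- seqBits[j:(j + n - 1L)]
    pb <- patBits[j]
    both <- bitwAnd(sb, pb)
    possible <- possible & both > 0L
    confirmed <- confirmed & both == sb
  }
  list(confirmed = which(confirmed) - 1L,
       candidate = which(possible & !confirmed) - 1L)
}

#' Scan a sequence for restriction sites
#'
#' Finds all recognition-site matches of an enzyme on a linear,
#' double-stranded sequence and reports the implied 0-based cut
#' coordinates. Matching is IUPAC-aware on both sides: a sequence position
#' matches a pattern position when the sequence base's set of possible
#' bases is a subset of the pattern code's set (confirmed); windows whose
#' match merely survives on a non-empty intersection (ambiguity in the
#' sequence, e.g. an `N`) are reported separately as candidates and are
#' never cut by [digestSequence()]. With `bothStrands = TRUE` (default)
#' the bottom strand is scanned too: a bottom-strand site in the top-strand
#' window `[i, i+L)` cuts at `i + (L - cutOffset)`. For palindromic sites
#' both passes find the same cuts. Overlapping matches all count; a pattern
#' longer than the sequence yields an empty scan.
#'
#' @param sequence DNA string over the IUPAC alphabet.
#' @param enzyme A [RestrictionEnzyme-class].
#' @param bothStrands Scan the bottom strand as well (default `TRUE`).
#' @return A [SiteScan-class].
#' @examples
#' mboI <- parseEnzyme("MboI", "^GATC")
#' cutPositions(findSites("GATCGATC", mboI))     # 0, 4
#' candidatePositions(findSites("AAGATNAA", mboI))  # N could complete GATC
#' @export
findSites <- function(sequence, enzyme, bothStrands = TRUE) {
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  seqBits <- .seqBits(sequence)
  L <- nchar(enzyme@pattern)
  patBits <- .seqBits(enzyme@pattern, what = "pattern")
  top <- .scanWindows(seqBits, patBits)
  cuts <- top$confirmed + enzyme@cutOffset
  cand <- top$candidate + enzyme@cutOffset
  if (bothStrands) {
    rcBits <- .seqBits(revComp(enzyme@pattern), what = "pattern")
    bot <- .scanWindows(seqBits, rcBits)
    # a window matching on both strands (palindromic site) is one physical
    # site and contributes only its top-strand cut; the bottom-strand cut
    # mapping applies to bottom-only matches
    botOnly <- setdiff(bot$confirmed, top$confirmed)
    cuts <- c(cuts, botOnly + (L - enzyme@cutOffset))
    botCand <- setdiff(bot$candidate, c(top$confirmed, top$candidate))
    cand <- c(cand, botCand + (L - enzyme@cutOffset))
  }
  cuts <- sort(unique(cuts))
  cand <- sort(unique(setdiff(cand, cuts)))
  methods::new("SiteScan", cutPositions = as.integer(cuts),
               candidatePositions = as.integer(cand))
}

#' SiteScan accessors
#' @param scan A [SiteScan-class].
#' @return Sorted integer vectors of 0-based cut coordinates.
#' @export
cutPositions <- function(scan) scan@cutPositions

#' @rdname cutPositions
#' @export
candidatePositions <- function(scan) scan@candidatePositions

setMethod("show", "SiteScan", function(object) {
  cat("SiteScan:", length(object@cutPositions), "confirmed cut(s)",
      if (length(object@candidatePositions))
        paste0("(+", length(object@candidatePositions), " candidate)"),
      "\n")
})

#' Digest a linear sequence in silico
#'
#' Cuts the sequence at every confirmed restriction site (candidate sites
#' arising from sequence ambiguity are deliberately not cut) and returns
#' the fragment lengths in sequence order. Zero-length fragments (cuts at
#' the very ends) are dropped; fragment lengths always sum to the sequence
#' length.
#'
#' @param sequence DNA string over the IUPAC alphabet.
#' @param enzyme A [RestrictionEnzyme-class].
#' @param bothStrands Passed to [findSites()].
#' @return Integer vector of fragment lengths (bp), 5' to 3'.
#' @examples
#' mboI <- parseEnzyme("MboI", "^GATC")
#' digestSequence("AAAGATCTT", mboI)  # 3, 6
#' digestSequence("AAAA", mboI)       # 4 (no site)
#' @export
digestSequence <- function(sequence, enzyme, bothStrands = TRUE) {
  len <- nchar(sequence)
  cuts <- cutPositions(findSites(sequence, enzyme, bothStrands))
  bounds <- sort(unique(c(0L, cuts, len)))
  frags <- diff(bounds)
  as.integer(frags[frags > 0L])
}

#' Digest every record of a collection
#'
#' Applies [digestSequence()] to each record for one or more enzymes and
#' tabulates the results in the package's digest-table layout
#' (`record_id`, `enzyme`, `n_sites`, `fragment_sizes` comma-joined in
#' sequence order), suitable for TSV export.
#'
#' @param records A named `DNAStringSet` (or [ReferencePanel-class]).
#' @param enzymes A [RestrictionEnzyme-class] or list of them.
#' @return A `data.frame`, one row per record x enzyme.
#' @export
digestRecords <- function(records, enzymes) {
  stopifnot(is(records, "DNAStringSet"))
  if (is(enzymes, "RestrictionEnzyme")) enzymes <- list(enzymes)
  seqs <- as.character(records)
  rows <- list()
  for (enz in enzymes) {
    for (k in seq_along(seqs)) {
      frags <- digestSequence(seqs[k], enz)
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = names(seqs)[k], enzyme = enz@name,
        n_sites = length(frags) - 1L,
        fragment_sizes = paste(frags, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Construct a primer pair
#'
#' @param forward,reverse Primer sequences, 5'->3' on their own strands.
#' @param forwardTail,reverseTail Optional tails (e.g. M13) carried into
#'   the amplicon verbatim.
#' @param maxMismatch Mismatches tolerated per primer (default 2; no
#'   indels). Degenerate fish-barcoding primers routinely tolerate a
#'   couple of template mismatches.
#' @return A [PrimerPair-class].
#' @export
primerPair <- function(forward, reverse, forwardTail = "",
                       reverseTail = "", maxMismatch = 2L) {
  methods::new("PrimerPair", forward = toupper(forward),
               reverse = toupper(reverse),
               forwardTail = toupper(forwardTail),
               reverseTail = toupper(reverseTail),
               maxMismatch = as.integer(maxMismatch))
}

# Window starts (1-based) where the primer anneals with <= maxMismatch
# mismatching positions; a mismatch is a position whose IUPAC sets do not
# intersect.
.primerMatches <- function(seqBits, primerBits, maxMismatch) {
  L <- length(primerBits)
  n <- length(seqBits) - L + 1L
  if (n < 1L) return(integer(0L))
  mm <- rep(0L, n)
  for (j in seq_len(L)) {
    sb <- seqBits[j:(j + n - 1L)]
    mm <- mm + as.integer(bitwAnd(sb, primerBits[j]) == 0L)
  }
  which(mm <= maxMismatch)
}

#' Extract an in silico PCR amplicon
#'
#' Locates the leftmost forward-primer annealing site and the rightmost
#' downstream annealing site of the reverse complement of the reverse
#' primer on the top strand (each tolerating up to `maxMismatch`
#' IUPAC-aware mismatches, no indels). The amplicon spans both primer
#' footprints inclusively; tails are prepended/appended verbatim, mirroring
#' what tailed-primer PCR products look like on a gel (~100 bp larger than
#' the trimmed barcode).
#'
#' @param template DNA string or a single-record `DNAStringSet` element.
#' @param primers A [PrimerPair-class].
#' @return A list with elements `status` (`"ok"` or `"no-product"`),
#'   `amplicon` (string or `NA`), and `reason` (diagnostic for failures).
#' @export
insilicoPCR <- function(template, primers) {
  stopifnot(is(primers, "PrimerPair"))
  if (is(template, "DNAStringSet")) template <- as.character(template)[1L]
  if (is(template, "DNAString")) template <- as.character(template)
  seqBits <- .seqBits(template, what = "template")
  fwBits <- .seqBits(primers@forward, what = "forward primer")
  rvSeq <- revComp(primers@reverse)
  rvBits <- .seqBits(rvSeq, what = "reverse primer")
  noProd <- function(reason) list(status = "no-product", amplicon = NA_character_,
                                  reason = reason)
  fHits <- .primerMatches(seqBits, fwBits, primers@maxMismatch)
  if (!length(fHits)) return(noProd("forward primer does not anneal"))
  f <- fHits[1L]
  fEnd <- f + length(fwBits) - 1L
  rHits <- .primerMatches(seqBits, rvBits, primers@maxMismatch)
  rHits <- rHits[rHits + length(rvBits) - 1L > fEnd]
  if (!length(rHits)) return(noProd("reverse primer does not anneal downstream"))
  r <- rHits[length(rHits)]
  if (r <= fEnd) return(noProd("primer footprints overlap"))
  rEnd <- r + length(rvBits) - 1L
  core <- substr(template, f, rEnd)
  list(status = "ok",
       amplicon = paste0(primers@forwardTail, core, primers@reverseTail),
       reason = NA_character_)
}
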