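# S4 class definitions for the RFLP toolkit. Accessors live next to the
# module code that owns each class; validity methods enforce the container
# invariants so downstream code can assume well-formed objects.

#' RestrictionEnzyme class
#'
#' A restriction endonuclease modelled as a named IUPAC recognition pattern
#' plus the top-strand cut offset (0 = cut before the first pattern base,
#' `nchar(pattern)` = cut after the last). All enzymes used for COI-barcode
#' RFLP in this package have palindromic sites, so the top-strand cut
#' coordinate determines the double-stranded fragment lengths exactly.
#'
#' @slot name Enzyme name, e.g. `"MboI"`.
#' @slot pattern IUPAC recognition pattern, e.g. `"GATC"`, `"GANTC"`.
#' @slot cutOffset Integer cut position within the pattern, in
#'   `[0, nchar(pattern)]`.
#' @seealso [parseEnzyme()], [findSites()], [digestSequence()]
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", pattern = "character",
                 cutOffset = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@pattern) != 1L || nchar(object@pattern) < 2L)
      msg <- c(msg, "'pattern' must have length >= 2")
    else if (!.validIupac(object@pattern))
      msg <- c(msg, "'pattern' contains non-IUPAC characters")
    if (length(object@cutOffset) != 1L || is.na(object@cutOffset) ||
        object@cutOffset < 0L || object@cutOffset > nchar(object@pattern))
      msg <- c(msg, "'cutOffset' must lie in [0, nchar(pattern)]")
    if (is.null(msg)) TRUE else msg
  })

#' SiteScan class
#'
#' Result of scanning one sequence for one enzyme. `cutPositions` holds
#' 0-based cut coordinates (the cut falls immediately before that index)
#' supported unambiguously by the sequence; `candidatePositions` holds cuts
#' whose recognition-site match relies on ambiguity codes in the sequence
#' (the IUPAC set of a sequence base intersects, but is not contained in,
#' the pattern code's set). The two lists are disjoint.
#'
#' @slot cutPositions Sorted unique integer cut coordinates (confirmed).
#' @slot candidatePositions Sorted unique integer cut coordinates that are
#'   only possible, not certain, given sequence ambiguity.
#' @export
setClass("SiteScan",
  representation(cutPositions = "integer", candidatePositions = "integer"),
  validity = function(object) {
    if (is.unsorted(object@cutPositions, strictly = TRUE) ||
        is.unsorted(object@candidatePositions, strictly = TRUE))
      return("positions must be sorted and unique")
    if (length(intersect(object@cutPositions, object@candidatePositions)))
      return("confirmed and candidate positions must be disjoint")
    TRUE
  })

#' PrimerPair class
#'
#' A PCR primer pair for in silico amplicon extraction. Primers are written
#' 5'->3' on their own strand (forward on the top strand, reverse on the
#' bottom strand, as in primer order sheets). Optional sequencing tails
#' (e.g. M13) are carried verbatim into the amplicon.
#'
#' @slot forward,reverse IUPAC primer sequences, 5'->3'.
#' @slot forwardTail,reverseTail Tail sequences prepended/appended to the
#'   amplicon (may be empty strings).
#' @slot maxMismatch Maximum number of primer-template mismatches tolerated
#'   per primer (no indels).
#' @export
setClass("PrimerPair",
  representation(forward = "character", reverse = "character",
                 forwardTail = "character", reverseTail = "character",
                 maxMismatch = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!nzchar(object@forward) || !nzchar(object@reverse))
      msg <- c(msg, "primers must be non-empty")
    if (!.validIupac(object@forward) || !.validIupac(object@reverse))
      msg <- c(msg, "primers must be IUPAC DNA")
    if (object@maxMismatch < 0L)
      msg <- c(msg, "'maxMismatch' must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' GelParams class
#'
#' Parameters of the virtual agarose gel: the minimum fragment size that
#' produces a visible band, the relative size tolerance within which two
#' fragments comigrate (and within which two observed bands are considered
#' the same size), and an optional upper size cap.
#'
#' @slot minBand Minimum visible band size in bp (default 100).
#' @slot tolerance Relative size tolerance as a fraction of the larger band
#'   (default 0.10).
#' @slot maxBand Optional maximum band size in bp (`NA` = no cap).
#' @seealso [gelParams()], [makePattern()]
#' @export
setClass("GelParams",
  representation(minBand = "numeric", tolerance = "numeric",
                 maxBand = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@minBand) != 1L || is.na(object@minBand) ||
        object@minBand < 0)
      msg <- c(msg, "'minBand' must be a single value >= 0")
    if (length(object@tolerance) != 1L || is.na(object@tolerance) ||
        object@tolerance < 0 || object@tolerance >= 1)
      msg <- c(msg, "'tolerance' must lie in [0, 1)")
    if (length(object@maxBand) != 1L ||
        (!is.na(object@maxBand) && object@maxBand < object@minBand))
      msg <- c(msg, "'maxBand' must be NA or >= minBand")
    if (is.null(msg)) TRUE else msg
  })

#' GelPattern class
#'
#' The visible band pattern of one digested sample: band sizes after
#' minimum-size filtering and comigration merging, sorted largest first,
#' each with the number of comigrating fragments it absorbed. Multiplicity
#' is informational only; band matching ignores it because band intensity
#' cannot be read reliably from a gel.
#'
#' @slot sizes Strictly decreasing band sizes (bp), all `>= minBand`.
#' @slot counts Fragment multiplicities per band (each `>= 1`).
#' @slot params The [GelParams-class] the pattern was built with.
#' @seealso [makePattern()], [patternsMatch()], [patternDistance()]
#' @export
setClass("GelPattern",
  representation(sizes = "numeric", counts = "integer", params = "GelParams"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sizes) != length(object@counts))
      msg <- c(msg, "'sizes' and 'counts' must have equal length")
    if (length(object@sizes)) {
      if (is.unsorted(rev(object@sizes), strictly = TRUE))
        msg <- c(msg, "'sizes' must be strictly decreasing")
      if (any(object@sizes < object@params@minBand))
        msg <- c(msg, "all band sizes must be >= minBand")
      if (any(object@counts < 1L))
        msg <- c(msg, "all multiplicities must be >= 1")
    }
    if (is.null(msg)) TRUE else msg
  })

#' ReferencePanel class
#'
#' A species-labelled reference library of COI barcodes: a
#' [Biostrings::DNAStringSet] whose element metadata carries a `species`
#' column (and optionally `group`). Record ids (names) are unique
#' panel-wide.
#'
#' @seealso [ReferencePanel()], [profileSpecies()], [selectEnzymes()]
#' @export
setClass("ReferencePanel", contains = "DNAStringSet",
  validity = function(object) {
    msg <- NULL
    ids <- names(object)
    if (length(object) < 1L)
      msg <- c(msg, "panel must contain at least one record")
    if (is.null(ids) || any(!nzchar(ids)))
      msg <- c(msg, "all records must be named")
    else if (anyDuplicated(ids))
      msg <- c(msg, "record ids must be unique panel-wide")
    sp <- S4Vectors::mcols(object)[["species"]]
    if (is.null(sp) || any(is.na(sp)) || any(!nzchar(sp)))
      msg <- c(msg, "every record needs a non-empty 'species' label")
    if (is.null(msg)) TRUE else msg
  })

#' SpeciesProfile class
#'
#' Per-species digestion profile for one enzyme: the distinct gel-pattern
#' variants observed across the species' reference records (intraspecific
#' clades can produce more than one), each with the ids of the records
#' supporting it.
#'
#' @slot species Species name.
#' @slot enzyme Enzyme name the profile was built with.
#' @slot variants List of [GelPattern-class] objects, pairwise non-matching.
#' @slot supportIds List (parallel to `variants`) of record id vectors.
#' @slot params The shared [GelParams-class].
#' @seealso [profileSpecies()], [assignSample()]
#' @export
setClass("SpeciesProfile",
  representation(species = "character", enzyme = "character",
                 variants = "list", supportIds = "list",
                 params = "GelParams"),
  validity = function(object) {
    msg <- NULL
    if (length(object@variants) != length(object@supportIds))
      msg <- c(msg, "'variants' and 'supportIds' must be parallel")
    if (!all(vapply(object@variants, is, logical(1L), "GelPattern")))
      msg <- c(msg, "'variants' must contain GelPattern objects")
    if (is.null(msg)) TRUE else msg
  })

#' DiscriminationReport class
#'
#' Verdict on one enzyme against a reference panel: the species profiles,
#' the pairwise distinguishability matrix (a pair is distinguishable iff no
#' gel-pattern variant of one species matches any variant of the other),
#' whether the enzyme separates every species pair simultaneously, and the
#' intraspecific variant count per species.
#'
#' @slot enzyme Enzyme name.
#' @slot profiles List of [SpeciesProfile-class], one per species.
#' @slot distinguishable Symmetric logical matrix over species.
#' @slot discriminatesAll `TRUE` iff every off-diagonal entry is `TRUE`.
#' @slot variantCounts Named integer vector of variants per species.
#' @slot flagged `TRUE` when fewer than two species were supplied (the
#'   verdict is then vacuous).
#' @seealso [evaluateEnzyme()], [selectEnzymes()]
#' @export
setClass("DiscriminationReport",
  representation(enzyme = "character", profiles = "list",
                 distinguishable = "matrix", discriminatesAll = "logical",
                 variantCounts = "integer", flagged = "logical"))

#' EnzymePanelSolution class
#'
#' A (near-)minimal set of enzymes whose digests jointly separate every
#' species pair of a panel, found by greedy set cover when no single enzyme
#' suffices.
#'
#' @slot enzymes Chosen enzyme names, in selection order.
#' @slot coveredPairs Named list: for each chosen enzyme, the `"A|B"` keys
#'   of the species pairs it distinguishes.
#' @slot feasible `FALSE` when some pair cannot be covered by any enzyme.
#' @slot diagnostic Human-readable note (why infeasible, if so).
#' @export
setClass("EnzymePanelSolution",
  representation(enzymes = "character", coveredPairs = "list",
                 feasible = "logical", diagnostic = "character"))

#' TranslationCheck class
#'
#' Open-reading-frame screen of one barcode: the forward frame with the
#' fewest internal stop codons under the chosen genetic code, its
#' translation, and a length flag marking sequences shorter than the NUMT
#' screening threshold.
#'
#' @slot id Record id.
#' @slot bestFrame Frame offset 0/1/2 minimising internal stops.
#' @slot internalStops Number of internal stops in the best frame.
#' @slot hasInternalStop `TRUE` if even the best frame contains a stop.
#' @slot protein Translated amino-acid string of the best frame.
#' @slot lengthFlag `TRUE` when the nucleotide sequence is shorter than the
#'   NUMT length threshold.
#' @seealso [checkCoding()]
#' @export
setClass("TranslationCheck",
  representation(id = "character", bestFrame = "integer",
                 internalStops = "integer", hasInternalStop = "logical",
                 protein = "character", lengthFlag = "logical"))

#' IdentityHit class
#'
#' Best local reference match of a query barcode: subject id and species,
#' percent identity over the aligned core (terminal gaps excluded) and the
#' number of aligned columns.
#'
#' @slot queryId,subjectId Record ids.
#' @slot subjectSpecies Species label of the best-matching reference.
#' @slot identityPct Percent identity, two decimals.
#' @slot alignedColumns Alignment length (columns, terminal gaps excluded).
#' @seealso [bestMatch()]
#' @export
setClass("IdentityHit",
  representation(queryId = "character", subjectId = "character",
                 subjectSpecies = "character", identityPct = "numeric",
                 alignedColumns = "integer"))

#' MislabelingReport class
#'
#' Declared-vs-identified species tallies. `perGroup` has one row per
#' sample group (e.g. sampling year) with totals, mismatch counts and the
#' mislabeling percentage (one decimal, recomputed from the counts);
#' `substitutions` tallies declared -> identified species swaps over all
#' groups.
#'
#' @slot perGroup `data.frame` with columns `group`, `total`, `mismatched`,
#'   `percent`.
#' @slot substitutions `data.frame` with columns `declared`, `matched`,
#'   `count` (mismatched samples only).
#' @slot total,mismatched Overall sample and mismatch counts.
#' @seealso [mislabelingReport()]
#' @export
setClass("MislabelingReport",
  representation(perGroup = "data.frame", substitutions = "data.frame",
                 total = "integer", mismatched = "integer"))
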