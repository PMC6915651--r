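# Virtual agarose gel model. Sizes are double-stranded fragment lengths in
# bp; matching is always relative (fraction of the larger size) because gel
# size estimates scale with fragment length.

# Round-half-up; base round() is banker's and would send 402.5 to 402.
.roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' The package-wide default band-size tolerance
#'
#' All band comparisons (comigration merging, pattern matching, sample
#' assignment) default to the same relative size tolerance. Gel-estimated
#' sizes are approximate — published RFLP band sizes are usually rounded to
#' the nearest 5-10 bp and end effects of primer tails shift apparent sizes
#' — so the default is a deliberately generous 10% of the larger band.
#' Every user-facing function takes a `tolerance`/`params` override.
#'
#' @return A single number, `0.10`.
#' @export
defaultBandTolerance <- function() 0.10

#' Construct virtual-gel parameters
#'
#' @param minBand Minimum visible band size in bp. Default 100: on a 3%
#'   agarose gel with a 100 bp ladder, fragments below ~100 bp run off or
#'   are too faint to score.
#' @param tolerance Relative comigration/matching tolerance; see
#'   [defaultBandTolerance()].
#' @param maxBand Optional upper size cap (bands above it are not scored);
#'   `NA` disables the cap.
#' @return A [GelParams-class].
#' @examples
#' gelParams()
#' gelParams(minBand = 50, tolerance = 0.05)
#' @export
gelParams <- function(minBand = 100, tolerance = defaultBandTolerance(),
                      maxBand = NA_real_) {
  methods::new("GelParams", minBand = as.numeric(minBand),
               tolerance = as.numeric(tolerance),
               maxBand = as.numeric(maxBand))
}

#' GelParams / GelPattern accessors
#' @param x A [GelParams-class] or [GelPattern-class].
#' @return Numeric scalars or vectors.
#' @export
minBand <- function(x) {
  if (is(x, "GelPattern")) x@params@minBand else x@minBand
}

#' @rdname minBand
#' @export
bandTolerance <- function(x) {
  if (is(x, "GelPattern")) x@params@tolerance else x@tolerance
}

#' @rdname minBand
#' @export
bandSizes <- function(x) x@sizes

#' @rdname minBand
#' @export
bandCounts <- function(x) x@counts

#' @rdname minBand
#' @export
patternParams <- function(x) x@params

setMethod("show", "GelPattern", function(object) {
  if (!length(object@sizes)) {
    cat("GelPattern: no visible bands\n")
    return(invisible(NULL))
  }
  lab <- ifelse(object@counts > 1L,
                sprintf("%g(x%d)", object@sizes, object@counts),
                sprintf("%g", object@sizes))
  cat("GelPattern:", paste(lab, collapse = " - "), "bp",
      sprintf("(minBand %g, tol %g)\n", object@params@minBand,
              object@params@tolerance))
})

# Relative size difference of two bands, as a fraction of the larger.
.relDiff <- function(a, b) abs(a - b) / pmax(a, b)

#' Convert fragment sizes to a visible band pattern
#'
#' Models what a digest looks like on the gel: fragments below `minBand`
#' (and above `maxBand`, if capped) are invisible and dropped; the rest are
#' sorted largest first; any two adjacent sizes within the relative
#' `tolerance` comigrate and are merged into a single band at the
#' round-half-up mean with summed multiplicity, repeating (closest pair
#' first) until no mergeable pair remains. The result is idempotent:
#' rebuilding a pattern from its own band sizes changes nothing.
#'
#' @param fragments Numeric vector of fragment sizes (bp), all positive.
#' @param params A [GelParams-class].
#' @return A [GelPattern-class].
#' @examples
#' makePattern(c(510, 95, 43))        # sub-100 bp fragments invisible
#' makePattern(c(405, 400, 110))      # 405/400 comigrate into one band
#' @export
makePattern <- function(fragments, params = gelParams()) {
  stopifnot(is(params, "GelParams"), all(fragments > 0))
  keep <- fragments[fragments >= params@minBand]
  if (!is.na(params@maxBand)) keep <- keep[keep <= params@maxBand]
  sizes <- sort(as.numeric(keep), decreasing = TRUE)
  counts <- rep(1L, length(sizes))
  while (length(sizes) > 1L) {
    rel <- .relDiff(sizes[-length(sizes)], sizes[-1L])
    k <- which.min(rel)
    if (rel[k] > params@tolerance) break
    merged <- .roundHalfUp((sizes[k] + sizes[k + 1L]) / 2)
    sizes <- c(sizes[seq_len(k - 1L)], merged,
               sizes[setdiff(seq_along(sizes), seq_len(k + 1L))])
    counts <- c(counts[seq_len(k - 1L)], counts[k] + counts[k + 1L],
                counts[setdiff(seq_along(counts), seq_len(k + 1L))])
  }
  methods::new("GelPattern", sizes = sizes, counts = counts, params = params)
}

.checkComparable <- function(a, b) {
  stopifnot(is(a, "GelPattern"), is(b, "GelPattern"))
  if (a@params@minBand != b@params@minBand) {
    stop("patterns built with different minBand (", a@params@minBand,
         " vs ", b@params@minBand, ") are not comparable", call. = FALSE)
  }
}

#' Do two band patterns look the same on a gel?
#'
#' Two patterns match when they show the same number of bands (multiplicity
#' ignored — intensity is not scored) and, pairing bands largest-to-largest,
#' every pair lies within the relative size tolerance. The relation is
#' reflexive and symmetric; it is deliberately not transitive, which is why
#' variant clustering is defined greedily in record order.
#'
#' @param a,b [GelPattern-class] objects built with the same `minBand`.
#' @param tolerance Relative tolerance; defaults to the tolerance stored in
#'   `a`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' p1 <- makePattern(c(400, 110)); p2 <- makePattern(c(405, 108))
#' patternsMatch(p1, p2)
#' @export
patternsMatch <- function(a, b, tolerance = bandTolerance(a)) {
  .checkComparable(a, b)
  if (length(a@sizes) != length(b@sizes)) return(FALSE)
  if (!length(a@sizes)) return(TRUE)
  all(.relDiff(a@sizes, b@sizes) <= tolerance)
}

#' Dissimilarity of two band patterns
#'
#' Greedily pairs bands in descending size order (a pair is formed when the
#' two current largest unpaired bands are within tolerance; otherwise the
#' larger one is declared unmatched) and returns
#' `1 - 2 * matched / (nA + nB)`, a value in `[0, 1]` that is 0 exactly
#' when [patternsMatch()] holds and 1 when no band pairs at all. Two empty
#' patterns have distance 0 by convention.
#'
#' @inheritParams patternsMatch
#' @return A number in `[0, 1]`.
#' @examples
#' patternDistance(makePattern(c(400, 110)), makePattern(c(405)))  # 1/3
#' @export
patternDistance <- function(a, b, tolerance = bandTolerance(a)) {
  .checkComparable(a, b)
  na <- length(a@sizes); nb <- length(b@sizes)
  if (na + nb == 0L) return(0)
  i <- 1L; j <- 1L; matched <- 0L
  while (i <= na && j <= nb) {
    if (.relDiff(a@sizes[i], b@sizes[j]) <= tolerance) {
      matched <- matched + 1L; i <- i + 1L; j <- j + 1L
    } else if (a@sizes[i] > b@sizes[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  1 - (2 * matched) / (na + nb)
}

#' Read observed gel band patterns from TSV
#'
#' Input format for gel-scored samples: a TSV with columns `sample_id` and
#' `bands` (comma-separated band sizes in bp, any order). Each row becomes
#' a [GelPattern-class] via [makePattern()], so the same minimum-size
#' filtering and comigration merging applies to observed and in silico
#' patterns.
#'
#' @param path TSV file path.
#' @param params A [GelParams-class].
#' @return A named list of `GelPattern` objects.
#' @export
readBandTable <- function(path, params = gelParams()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "bands") %in% colnames(tab))) {
    stop("band table needs columns 'sample_id' and 'bands'", call. = FALSE)
  }
  pats <- lapply(strsplit(as.character(tab$bands), ","),
                 function(b) makePattern(as.numeric(b), params))
  names(pats) <- tab$sample_id
  pats
}
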