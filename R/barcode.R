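# Barcode quality control and local species identification. COI is a
# protein-coding mitochondrial locus: a genuine barcode translates without
# internal stop codons under the vertebrate mitochondrial code, and nuclear
# pseudogene copies (NUMTs) betray themselves through premature stops
# and/or short length.

#' Screen a barcode for premature stop codons and NUMT length
#'
#' Translates the sequence in all three forward frames (COI barcodes are
#' amplified from the coding strand with fixed primers, so reverse frames
#' are off by default; set `allFrames = TRUE` for arbitrary input, in which
#' case the reverse-complement frames are searched too) and reports the
#' frame with the fewest internal stop codons. The sequence passes when
#' some frame is stop-free. Under the vertebrate mitochondrial code
#' (translation table 2) TGA encodes tryptophan while AGA/AGG are stops —
#' using the standard code here would both miss real pseudogenes and flag
#' genuine mitochondrial sequences. Sequences shorter than
#' `numtLengthThreshold` are flagged: NUMT co-amplicons are typically the
#' shorter products.
#'
#' @param sequence DNA string (length >= 3).
#' @param id Record id used in the report.
#' @param geneticCode NCBI translation table id; `"2"` (vertebrate
#'   mitochondrial, the default) or `"1"` (standard), etc.
#' @param numtLengthThreshold Length flag threshold in bp (default 600).
#' @param allFrames Also search the three reverse-complement frames.
#' @return A [TranslationCheck-class].
#' @examples
#' codingPass(checkCoding("ATGTGATTT"))   # TGA = Trp under table 2
#' codingPass(checkCoding("ATGAGAGCT"))   # AGA = stop under table 2
#' @export
checkCoding <- function(sequence, id = "query", geneticCode = "2",
                        numtLengthThreshold = 600L, allFrames = FALSE) {
  if (is(sequence, "DNAStringSet")) sequence <- as.character(sequence)[1L]
  stopifnot(is.character(sequence), length(sequence) == 1L)
  len <- nchar(sequence)
  if (len < 3L) {
    stop("record '", id, "': sequence shorter than one codon", call. = FALSE)
  }
  code <- Biostrings::getGeneticCode(geneticCode)
  frames <- if (allFrames) 0:5 else 0:2
  translateFrame <- function(frame) {
    s <- if (frame >= 3L) revComp(sequence) else sequence
    off <- frame %% 3L
    ncodon <- (nchar(s) - off) %/% 3L
    if (ncodon < 1L) return("")
    sub <- Biostrings::subseq(Biostrings::DNAString(s), off + 1L,
                              off + 3L * ncodon)
    as.character(Biostrings::translate(sub, genetic.code = code,
                                       if.fuzzy.codon = "X"))
  }
  proteins <- vapply(frames, translateFrame, character(1L))
  internalStops <- vapply(proteins, function(p) {
    if (!nchar(p)) return(.Machine$integer.max)
    # a stop at the final codon is a natural terminator, not premature
    body <- substr(p, 1L, nchar(p) - 1L)
    lengths(regmatches(body, gregexpr("*", body, fixed = TRUE)))
  }, integer(1L))
  bestIdx <- which.min(internalStops)
  methods::new("TranslationCheck", id = id,
               bestFrame = as.integer(frames[bestIdx]),
               internalStops = internalStops[bestIdx],
               hasInternalStop = internalStops[bestIdx] > 0L,
               protein = proteins[bestIdx],
               lengthFlag = len < numtLengthThreshold)
}

#' TranslationCheck accessors
#' @param check A [TranslationCheck-class].
#' @return `codingPass()`: `TRUE` when the best frame is stop-free;
#'   `bestFrame()`: 0/1/2 (3-5 for reverse frames); `lengthFlagged()`:
#'   `TRUE` for sequences below the NUMT length threshold;
#'   `checkProtein()`: the translation.
#' @export
codingPass <- function(check) !check@hasInternalStop

#' @rdname codingPass
#' @export
bestFrame <- function(check) check@bestFrame

#' @rdname codingPass
#' @export
lengthFlagged <- function(check) check@lengthFlag

#' @rdname codingPass
#' @export
checkProtein <- function(check) check@protein

setMethod("show", "TranslationCheck", function(object) {
  cat(sprintf("TranslationCheck %s: frame %d, %d internal stop(s) -> %s%s\n",
              object@id, object@bestFrame, object@internalStops,
              if (object@hasInternalStop) "FAIL" else "pass",
              if (object@lengthFlag) " [short: possible NUMT]" else ""))
})

#' QC an entire record collection
#'
#' Runs [checkCoding()] on every record and tabulates the results in the
#' package's QC-table layout (`record_id`, `frame`, `internal_stops`,
#' `length_flag`, `verdict`).
#'
#' @param records A named `DNAStringSet`.
#' @inheritParams checkCoding
#' @return A `data.frame`, one row per record.
#' @export
qcRecords <- function(records, geneticCode = "2",
                      numtLengthThreshold = 600L, allFrames = FALSE) {
  stopifnot(is(records, "DNAStringSet"))
  seqs <- as.character(records)
  rows <- lapply(seq_along(seqs), function(k) {
    chk <- checkCoding(seqs[k], id = names(seqs)[k],
                       geneticCode = geneticCode,
                       numtLengthThreshold = numtLengthThreshold,
                       allFrames = allFrames)
    data.frame(record_id = chk@id, frame = chk@bestFrame,
               internal_stops = chk@internalStops,
               length_flag = chk@lengthFlag,
               verdict = if (codingPass(chk)) "pass" else "fail",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Best local reference match of a query barcode
#'
#' Aligns the query against every labelled reference with a global
#' alignment under free end gaps (match +1, mismatch -1, gap -2) and
#' returns the reference with the highest percent identity over the
#' aligned columns (terminal overhangs excluded; identity rounded
#' half-up to two decimals). Ties go to the longer alignment, then to
#' reference order. This is a local, reproducible stand-in for a database
#' similarity search: with a curated reference library the best barcode
#' hit identifies the species.
#'
#' @param query DNA string or single-record `DNAStringSet`.
#' @param references A named `DNAStringSet` with a `species` metadata
#'   column (e.g. a [ReferencePanel-class]).
#' @param queryId Id recorded in the hit.
#' @return An [IdentityHit-class].
#' @examples
#' \dontrun{
#' hit <- bestMatch(querySeq, panel)
#' identityPct(hit); hitSpecies(hit)
#' }
#' @export
bestMatch <- function(query, references, queryId = "query") {
  stopifnot(is(references, "DNAStringSet"), length(references) >= 1L)
  species <- S4Vectors::mcols(references)[["species"]]
  if (is.null(species)) {
    stop("references need a 'species' metadata column", call. = FALSE)
  }
  if (is(query, "DNAStringSet")) {
    if (!is.null(names(query))) queryId <- names(query)[1L]
    query <- as.character(query)[1L]
  }
  subjects <- Biostrings::DNAStringSet(unname(as.character(references)))
  mat <- Biostrings::pairwiseAlignment(
    pattern = rep(Biostrings::DNAStringSet(query), length(subjects)),
    subject = subjects, type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  matches <- Biostrings::nmatch(mat)
  # aligned columns incl. internal gaps; overlap alignments clip overhangs
  cols <- Biostrings::width(Biostrings::alignedPattern(mat))
  ident <- .roundHalfUp(100 * matches / cols, 2L)
  ord <- order(-ident, -cols, seq_along(ident))
  k <- ord[1L]
  methods::new("IdentityHit", queryId = queryId,
               subjectId = names(references)[k],
               subjectSpecies = as.character(species[k]),
               identityPct = ident[k], alignedColumns = as.integer(cols[k]))
}

#' IdentityHit accessors
#' @param hit An [IdentityHit-class].
#' @return See each accessor.
#' @export
identityPct <- function(hit) hit@identityPct

#' @rdname identityPct
#' @export
hitSpecies <- function(hit) hit@subjectSpecies

#' @rdname identityPct
#' @export
hitSubject <- function(hit) hit@subjectId

setMethod("show", "IdentityHit", function(object) {
  cat(sprintf("IdentityHit: %s -> %s (%s), %.2f%% over %d columns\n",
              object@queryId, object@subjectId, object@subjectSpecies,
              object@identityPct, object@alignedColumns))
})

.normSpecies <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Tabulate mislabeling from declared vs identified species
#'
#' Compares each sample's declared species label with its molecular
#' identification, normalising names for case and whitespace. Percentages
#' are always recomputed from the counts (round-half-up, one decimal);
#' substitution tallies (declared -> identified) are aggregated over all
#' groups.
#'
#' @param samples A `data.frame` with columns `id`, `declared`, `matched`
#'   and optionally `group` (e.g. sampling year; missing group = single
#'   group `"all"`).
#' @return A [MislabelingReport-class]; empty input gives an empty report.
#' @examples
#' df <- data.frame(id = c("s1", "s2", "s3"),
#'                  declared = "Xiphias gladius",
#'                  matched = c("Xiphias gladius", "Prionace glauca",
#'                              "Xiphias gladius"),
#'                  group = "2018")
#' mislabelingPerGroup(mislabelingReport(df))
#' @export
mislabelingReport <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (!nrow(samples)) {
    return(methods::new("MislabelingReport",
      perGroup = data.frame(group = character(0L), total = integer(0L),
                            mismatched = integer(0L), percent = numeric(0L)),
      substitutions = data.frame(declared = character(0L),
                                 matched = character(0L),
                                 count = integer(0L)),
      total = 0L, mismatched = 0L))
  }
  need <- c("id", "declared", "matched")
  if (!all(need %in% colnames(samples))) {
    stop("samples need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  group <- if ("group" %in% colnames(samples)) {
    as.character(samples$group)
  } else {
    rep("all", nrow(samples))
  }
  mism <- .normSpecies(samples$declared) != .normSpecies(samples$matched)
  groups <- unique(group)
  perGroup <- do.call(rbind, lapply(groups, function(g) {
    tot <- sum(group == g)
    bad <- sum(mism[group == g])
    data.frame(group = g, total = tot, mismatched = bad,
               percent = .roundHalfUp(100 * bad / tot, 1L),
               stringsAsFactors = FALSE)
  }))
  subs <- samples[mism, c("declared", "matched"), drop = FALSE]
  substitutions <- if (nrow(subs)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(subs))),
                            by = list(declared = subs$declared,
                                      matched = subs$matched), FUN = sum)
    agg[order(-agg$count, agg$matched), , drop = FALSE]
  } else {
    data.frame(declared = character(0L), matched = character(0L),
               count = integer(0L))
  }
  rownames(substitutions) <- NULL
  methods::new("MislabelingReport", perGroup = perGroup,
               substitutions = substitutions,
               total = nrow(samples), mismatched = sum(mism))
}

#' MislabelingReport accessors
#' @param report A [MislabelingReport-class].
#' @return `mislabelingPerGroup()` / `mislabelingSubstitutions()`:
#'   `data.frame`s (see [MislabelingReport-class]).
#' @export
mislabelingPerGroup <- function(report) report@perGroup

#' @rdname mislabelingPerGroup
#' @export
mislabelingSubstitutions <- function(report) report@substitutions

setMethod("show", "MislabelingReport", function(object) {
  cat(sprintf("MislabelingReport: %d/%d sample(s) mislabeled\n",
              object@mismatched, object@total))
  for (r in seq_len(nrow(object@perGroup))) {
    row <- object@perGroup[r, ]
    cat(sprintf("  %-12s %d/%d (%.1f%%)\n", row$group, row$mismatched,
                row$total, row$percent))
  }
  for (r in seq_len(nrow(object@substitutions))) {
    row <- object@substitutions[r, ]
    cat(sprintf("  substitution: %s -> %s (x%d)\n", row$declared,
                row$matched, row$count))
  }
})
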