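# Seeded generation of synthetic multi-species barcode panels with planted
# restriction-site layouts. The generator gives every pipeline stage a
# ground truth to recover: each species carries a known set of cut sites
# for one "planted" enzyme, no sequence contains a site for any other
# candidate ("decoy") enzyme, and species patterns are pairwise
# non-matching under the gel parameters by construction.

.BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# All cut positions of every enzyme, concatenated (candidates included so a
# scrubbed backbone has no ambiguity-dependent site either).
.allSiteCuts <- function(sequence, enzymes) {
  unlist(lapply(enzymes, function(e) {
    sc <- findSites(sequence, e)
    c(sc@cutPositions, sc@candidatePositions)
  }), use.names = FALSE)
}

# Remove every recognition site of every enzyme by iteratively mutating one
# random base inside each remaining site window. Whole-sequence rejection
# would practically never terminate (five 4-6 bp sites in ~700 bp leave a
# ~1e-5 acceptance rate), whereas scrubbing converges in a handful of
# passes.
.scrubSites <- function(chars, enzymes, maxPasses = 100L) {
  for (pass in seq_len(maxPasses)) {
    seqStr <- paste(chars, collapse = "")
    dirty <- FALSE
    for (e in enzymes) {
      sc <- findSites(seqStr, e)
      L <- nchar(e@pattern)
      wins <- unique(c(sc@cutPositions - e@cutOffset,
                       sc@candidatePositions - e@cutOffset,
                       (sc@cutPositions - (L - e@cutOffset)),
                       (sc@candidatePositions - (L - e@cutOffset))))
      wins <- wins[wins >= 0L & wins + L <= length(chars)]
      for (w in wins) {
        pos <- w + sample.int(L, 1L)
        chars[pos] <- sample(setdiff(.BASES, chars[pos]), 1L)
        dirty <- TRUE
      }
      if (dirty) break  # rescan from scratch after any edit
    }
    if (!dirty) return(chars)
  }
  stop("could not scrub all recognition sites (pathological input)",
       call. = FALSE)
}

# One concrete base per IUPAC pattern position (random choice within each
# code's set), used to write a planted recognition site into a backbone.
.concreteSite <- function(pattern) {
  vapply(strsplit(pattern, "")[[1L]],
         function(code) sample(.IUPAC_SETS[[code]], 1L), character(1L))
}

#' Generate a synthetic reference panel with planted restriction sites
#'
#' Builds a seeded, fully reproducible multi-species barcode panel in which
#' one enzyme (`plantedEnzyme`) carries the discriminating signal. Per
#' species, a random uniform-composition backbone is drawn and scrubbed of
#' every recognition site of every candidate enzyme; a species-specific set
#' of planted-enzyme sites is then written at positions sampled so that all
#' resulting fragments are visible (at least `minBand` apart) and the
#' species' gel patterns are pairwise non-matching under `params`.
#' Additional records per species receive random substitutions at
#' `intraspecificRate`, re-drawn (bounded attempts) whenever a mutation
#' would create or destroy a recognition site of any enzyme, so every
#' record of a species digests identically to its backbone.
#'
#' Defaults mirror a realistic COI-barcoding study: five species, ten
#' records each, 680 bp amplicons, within-species substitution rate 0.005
#' per site.
#'
#' @param seed Integer seed; identical seeds give byte-identical panels.
#' @param nSpecies Number of species (>= 2).
#' @param nPerSpecies Records per species.
#' @param length Sequence length in bp (>= 300).
#' @param enzymes Candidate enzyme list (default [defaultEnzymes()]).
#' @param plantedEnzyme Name of the enzyme carrying the planted signal;
#'   must appear in `enzymes`.
#' @param intraspecificRate Substitutions per site for within-species
#'   copies.
#' @param params A [GelParams-class] defining pattern visibility/matching.
#' @param maxAttempts Bound on the rejection-sampling loops (site placement
#'   and mutation redraws) before an infeasibility error is raised.
#' @return A list with `panel` (a [ReferencePanel-class]) and `truth`, a
#'   list recording `seed`, `plantedEnzyme`, per-species `cutPositions`,
#'   `expectedFragments`, `expectedPatterns` ([GelPattern-class]),
#'   `variantOf` (record id -> variant label) and `params`.
#' @examples
#' sim <- makePanel(seed = 7, nSpecies = 3, nPerSpecies = 2, length = 500)
#' sim$truth$cutPositions
#' @export
makePanel <- function(seed, nSpecies = 5L, nPerSpecies = 10L, length = 680L,
                      enzymes = defaultEnzymes(), plantedEnzyme = "MboI",
                      intraspecificRate = 0.005, params = gelParams(),
                      maxAttempts = 10000L) {
  stopifnot(length >= 300L, nSpecies >= 2L, nPerSpecies >= 1L,
            intraspecificRate >= 0, intraspecificRate < 1)
  enzNames <- vapply(enzymes, enzymeName, character(1L))
  if (!plantedEnzyme %in% enzNames) {
    stop("'", plantedEnzyme, "' is not among the candidate enzymes",
         call. = FALSE)
  }
  planted <- enzymes[[match(plantedEnzyme, enzNames)]]
  L <- nchar(planted@pattern)
  .withSeed(seed, {
    speciesNames <- sprintf("synthspecies%02d", seq_len(nSpecies))
    backbones <- character(nSpecies)
    cutSets <- vector("list", nSpecies)
    patterns <- vector("list", nSpecies)
    for (s in seq_len(nSpecies)) {
      done <- FALSE
      for (attempt in seq_len(maxAttempts)) {
        chars <- .scrubSites(sample(.BASES, length, replace = TRUE), enzymes)
        nCuts <- sample(0:3, 1L)
        cuts <- integer(0L)
        if (nCuts > 0L) {
          # cut coordinates spaced >= minBand so every fragment is visible
          lo <- max(params@minBand, L)
          hi <- length - max(params@minBand, L)
          if (hi <= lo) next
          cand <- sort(sample(seq(lo, hi), nCuts))
          if (nCuts > 1L && any(diff(cand) < params@minBand)) next
          cuts <- cand
        }
        for (p in cuts) {
          w <- p - planted@cutOffset
          chars[(w + 1L):(w + L)] <- .concreteSite(planted@pattern)
        }
        seqStr <- paste(chars, collapse = "")
        # planting may create sites at junctions; demand the exact layout
        sc <- findSites(seqStr, planted)
        if (!identical(sc@cutPositions, as.integer(cuts)) ||
            length(sc@candidatePositions)) next
        othersClean <- all(vapply(enzymes[enzNames != plantedEnzyme],
          function(e) {
            o <- findSites(seqStr, e)
            length(o@cutPositions) + length(o@candidatePositions) == 0L
          }, logical(1L)))
        if (!othersClean) next
        pat <- makePattern(digestSequence(seqStr, planted), params)
        clash <- s > 1L && any(vapply(patterns[seq_len(s - 1L)],
          function(q) patternsMatch(q, pat), logical(1L)))
        if (clash) next
        backbones[s] <- seqStr
        cutSets[[s]] <- as.integer(cuts)
        patterns[[s]] <- pat
        done <- TRUE
        break
      }
      if (!done) {
        stop("could not place a distinct restriction layout for species ",
             s, ": sequence length ", length, " is too short for ",
             nSpecies, " distinguishable patterns", call. = FALSE)
      }
    }
    ids <- character(0L); seqs <- character(0L); spLab <- character(0L)
    variantOf <- character(0L)
    for (s in seq_len(nSpecies)) {
      ref <- strsplit(backbones[s], "")[[1L]]
      refCuts <- lapply(enzymes, function(e)
        findSites(backbones[s], e)@cutPositions)
      for (r in seq_len(nPerSpecies)) {
        if (r == 1L || intraspecificRate == 0) {
          seqStr <- backbones[s]
        } else {
          ok <- FALSE
          for (attempt in seq_len(maxAttempts)) {
            chars <- ref
            nMut <- stats::rbinom(1L, length, intraspecificRate)
            if (nMut > 0L) {
              posns <- sample.int(length, nMut)
              for (p in posns) {
                chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
              }
            }
            seqStr <- paste(chars, collapse = "")
            same <- all(vapply(seq_along(enzymes), function(e) {
              sc <- findSites(seqStr, enzymes[[e]])
              identical(sc@cutPositions, refCuts[[e]]) &&
                length(sc@candidatePositions) == 0L
            }, logical(1L)))
            if (same) { ok <- TRUE; break }
          }
          if (!ok) {
            stop("could not mutate species ", s,
                 " without disturbing a recognition site", call. = FALSE)
          }
        }
        ids <- c(ids, sprintf("%s_r%02d", speciesNames[s], r))
        seqs <- c(seqs, seqStr)
        spLab <- c(spLab, speciesNames[s])
        variantOf <- c(variantOf, "1")
      }
    }
    records <- Biostrings::DNAStringSet(seqs)
    names(records) <- ids
    S4Vectors::mcols(records) <- S4Vectors::DataFrame(
      description = rep("", base::length(ids)), species = spLab,
      group = rep("synthetic", base::length(ids)))
    names(cutSets) <- speciesNames
    names(patterns) <- speciesNames
    expectedFragments <- lapply(seq_len(nSpecies), function(s)
      digestSequence(backbones[s], planted))
    names(expectedFragments) <- speciesNames
    names(variantOf) <- ids
    list(panel = ReferencePanel(records),
         truth = list(seed = seed, plantedEnzyme = plantedEnzyme,
                      cutPositions = cutSets,
                      expectedFragments = expectedFragments,
                      expectedPatterns = patterns,
                      variantOf = variantOf, params = params))
  })
}

#' Derive an intraspecific clade variant of a record
#'
#' Emulates a within-species lineage whose gel pattern differs from the
#' source record by gaining or losing exactly one recognition site of the
#' given enzyme, using the smallest possible number of substitutions
#' (sequence length unchanged). Candidate edits are tried in order of
#' increasing substitution count until one yields exactly one more (or one
#' fewer) cut and a pattern that no longer matches the original under
#' [patternsMatch()].
#'
#' @param sequence DNA string of the source record.
#' @param enzyme A [RestrictionEnzyme-class].
#' @param mode `"add-site"` or `"remove-site"` (the latter requires at
#'   least one existing site).
#' @param seed Integer seed (tie-breaking among equally small edits).
#' @param params A [GelParams-class] for the pattern-difference check.
#' @return The edited DNA string, same length as the input.
#' @examples
#' sim <- makePanel(seed = 3, nSpecies = 2, nPerSpecies = 1, length = 500)
#' v <- makeCladeVariant(as.character(sim$panel)[1],
#'                       defaultEnzymes()$MboI, "add-site", seed = 1)
#' nchar(v) == 500
#' @export
makeCladeVariant <- function(sequence, enzyme, mode = c("add-site",
                             "remove-site"), seed = 1L,
                             params = gelParams()) {
  mode <- match.arg(mode)
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  if (is(sequence, "DNAStringSet")) sequence <- as.character(sequence)[1L]
  .seqBits(sequence)
  L <- nchar(enzyme@pattern)
  len <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1L]]
  origScan <- findSites(sequence, enzyme)
  origCuts <- origScan@cutPositions
  origPat <- makePattern(digestSequence(sequence, enzyme), params)
  patSets <- .IUPAC_SETS[strsplit(enzyme@pattern, "")[[1L]]]
  edit <- function() {
    if (mode == "add-site") {
      wins <- 0:(len - L)
      nsubs <- vapply(wins, function(w) {
        sum(!mapply(function(base, set) base %in% set,
                    chars[(w + 1L):(w + L)], patSets))
      }, integer(1L))
      ord <- wins[order(nsubs, sample.int(length(wins)))]
      for (w in ord) {
        if (nsubs[match(w, wins)] == 0L) next  # already a site
        newChars <- chars
        for (j in seq_len(L)) {
          if (!newChars[w + j] %in% patSets[[j]]) {
            newChars[w + j] <- sample(patSets[[j]], 1L)
          }
        }
        newSeq <- paste(newChars, collapse = "")
        sc <- findSites(newSeq, enzyme)
        if (length(sc@cutPositions) != length(origCuts) + 1L) next
        newPat <- makePattern(digestSequence(newSeq, enzyme), params)
        if (patternsMatch(newPat, origPat)) next
        return(newSeq)
      }
      stop("no single-site gain changes the gel pattern of this record",
           call. = FALSE)
    }
    # remove-site
    if (!length(origCuts)) {
      stop("remove-site requires at least one existing recognition site",
           call. = FALSE)
    }
    starts <- unique(c(origCuts - enzyme@cutOffset,
                       origCuts - (L - enzyme@cutOffset)))
    starts <- starts[starts >= 0L & starts + L <= len]
    starts <- starts[vapply(starts, function(w) {
      all(mapply(function(base, set) base %in% set,
                 chars[(w + 1L):(w + L)], patSets))
    }, logical(1L))]
    for (w in starts[sample.int(length(starts))]) {
      for (j in sample.int(L)) {
        offSet <- setdiff(.BASES, patSets[[j]])
        for (b in sample(offSet)) {
          newChars <- chars
          newChars[w + j] <- b
          newSeq <- paste(newChars, collapse = "")
          sc <- findSites(newSeq, enzyme)
          if (length(sc@cutPositions) != length(origCuts) - 1L) next
          newPat <- makePattern(digestSequence(newSeq, enzyme), params)
          if (patternsMatch(newPat, origPat)) next
          return(newSeq)
        }
      }
    }
    stop("no single-substitution site loss changes the gel pattern",
         call. = FALSE)
  }
  .withSeed(seed, edit())
}

#' Serialise a synthetic truth object to JSON
#'
#' Writes the ground truth of [makePanel()] (planted enzyme, per-species
#' cut positions, expected fragments and band sizes, record variant
#' labels) as pretty-printed JSON next to the panel FASTA, so external
#' tools can verify a simulated dataset.
#'
#' @param truth The `truth` element returned by [makePanel()].
#' @param path Output path, or `NULL` to return the JSON text.
#' @return `path` invisibly, or the JSON string.
#' @export
writeTruthJSON <- function(truth, path = NULL) {
  obj <- list(
    seed = truth$seed,
    planted_enzyme = truth$plantedEnzyme,
    gel_params = list(min_band = truth$params@minBand,
                      tolerance = truth$params@tolerance),
    species = lapply(names(truth$cutPositions), function(sp) {
      list(name = sp,
           cut_positions = truth$cutPositions[[sp]],
           expected_fragments = truth$expectedFragments[[sp]],
           expected_bands = truth$expectedPatterns[[sp]]@sizes)
    }),
    variant_of = as.list(truth$variantOf))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                          digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}
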