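# Enzyme selection and sample assignment over a species-labelled reference
# panel. Species pairs are keyed as "A|B" with the two names sorted, so a
# pair key is order-independent.

.pairKey <- function(a, b) {
  paste(sort(c(a, b)), collapse = "|")
}

#' Profile the digestion patterns of every species in a panel
#'
#' Digests every reference record with one enzyme, converts the fragments
#' to gel patterns, and clusters the patterns of each species into
#' variants: records are taken in panel order, the first record seeds
#' variant 1, and each later record joins the first existing variant its
#' pattern matches (otherwise it seeds a new variant). Because
#' [patternsMatch()] is not transitive, this greedy rule — rather than some
#' global clustering — is what makes the profile deterministic for a given
#' input order. Intraspecific variants typically correspond to divergent
#' clades segregating at a recognition site.
#'
#' @param panel A [ReferencePanel-class].
#' @param enzyme A [RestrictionEnzyme-class].
#' @param params A [GelParams-class].
#' @return A list of [SpeciesProfile-class], one per species, in order of
#'   first appearance in the panel.
#' @seealso [evaluateEnzyme()], [assignSample()]
#' @export
profileSpecies <- function(panel, enzyme, params = gelParams()) {
  stopifnot(is(panel, "ReferencePanel"), is(enzyme, "RestrictionEnzyme"))
  species <- panelSpecies(panel)
  seqs <- as.character(panel)
  profiles <- list()
  for (sp in unique(species)) {
    idx <- which(species == sp)
    variants <- list()
    support <- list()
    for (k in idx) {
      pat <- tryCatch(
        makePattern(digestSequence(seqs[k], enzyme), params),
        error = function(e) {
          stop("record '", names(seqs)[k], "': ", conditionMessage(e),
               call. = FALSE)
        })
      hit <- 0L
      for (v in seq_along(variants)) {
        if (patternsMatch(variants[[v]], pat)) { hit <- v; break }
      }
      if (hit == 0L) {
        variants[[length(variants) + 1L]] <- pat
        support[[length(support) + 1L]] <- names(seqs)[k]
      } else {
        support[[hit]] <- c(support[[hit]], names(seqs)[k])
      }
    }
    profiles[[length(profiles) + 1L]] <- methods::new("SpeciesProfile",
      species = sp, enzyme = enzyme@name, variants = variants,
      supportIds = support, params = params)
  }
  profiles
}

#' Build species profiles directly from observed band patterns
#'
#' Reference profiles do not have to come from sequences: patterns scored
#' from a reference gel (one row per species variant) serve equally well
#' for sample assignment. Rows of the same species become successive
#' variants of one profile.
#'
#' @param species Character vector, one entry per pattern.
#' @param patterns List of [GelPattern-class] objects (or numeric band-size
#'   vectors, converted via [makePattern()]).
#' @param enzyme Enzyme name to record in the profiles.
#' @param params A [GelParams-class].
#' @param ids Optional supporting ids, one per pattern.
#' @return A list of [SpeciesProfile-class].
#' @export
profilesFromPatterns <- function(species, patterns, enzyme = "observed",
                                 params = gelParams(), ids = NULL) {
  stopifnot(length(species) == length(patterns))
  if (is.null(ids)) ids <- paste0(make.unique(species), ".ref")
  patterns <- lapply(patterns, function(p) {
    if (is(p, "GelPattern")) p else makePattern(as.numeric(p), params)
  })
  profiles <- list()
  for (sp in unique(species)) {
    idx <- which(species == sp)
    profiles[[length(profiles) + 1L]] <- methods::new("SpeciesProfile",
      species = sp, enzyme = enzyme, variants = patterns[idx],
      supportIds = as.list(ids[idx]), params = params)
  }
  profiles
}

#' SpeciesProfile accessors
#' @param profile A [SpeciesProfile-class].
#' @return `profileSpeciesName()`: the species; `profileVariants()`: list
#'   of [GelPattern-class]; `variantCount()`: integer.
#' @export
profileSpeciesName <- function(profile) profile@species

#' @rdname profileSpeciesName
#' @export
profileVariants <- function(profile) profile@variants

#' @rdname profileSpeciesName
#' @export
variantCount <- function(profile) length(profile@variants)

setMethod("show", "SpeciesProfile", function(object) {
  cat(sprintf("SpeciesProfile %s [%s]: %d variant(s)\n", object@species,
              object@enzyme, length(object@variants)))
  for (v in seq_along(object@variants)) {
    sz <- object@variants[[v]]@sizes
    cat(sprintf("  variant %d (%d record(s)): %s bp\n", v,
                length(object@supportIds[[v]]),
                if (length(sz)) paste(sz, collapse = " - ") else "no bands"))
  }
})

#' Evaluate whether one enzyme discriminates all species
#'
#' A species pair is distinguishable when no gel-pattern variant of one
#' species matches any variant of the other — intraspecific variants do not
#' disqualify an enzyme as long as none of them collides with another
#' species' pattern. With fewer than two species the report is vacuously
#' positive and flagged.
#'
#' @param profiles A list of [SpeciesProfile-class] sharing enzyme and
#'   gel parameters (as returned by [profileSpecies()]).
#' @return A [DiscriminationReport-class].
#' @export
evaluateEnzyme <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, is, logical(1L), "SpeciesProfile")))
  enz <- unique(vapply(profiles, function(p) p@enzyme, character(1L)))
  if (length(enz) != 1L) stop("profiles mix enzymes", call. = FALSE)
  species <- vapply(profiles, function(p) p@species, character(1L))
  n <- length(species)
  mat <- matrix(TRUE, n, n, dimnames = list(species, species))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        collide <- any(vapply(profiles[[i]]@variants, function(va) {
          any(vapply(profiles[[j]]@variants,
                     function(vb) patternsMatch(va, vb), logical(1L)))
        }, logical(1L)))
        mat[i, j] <- mat[j, i] <- !collide
      }
    }
  }
  counts <- vapply(profiles, variantCount, integer(1L))
  names(counts) <- species
  methods::new("DiscriminationReport", enzyme = enz, profiles = profiles,
               distinguishable = mat,
               discriminatesAll = all(mat[upper.tri(mat)]),
               variantCounts = counts, flagged = n < 2L)
}

#' DiscriminationReport accessors
#' @param report A [DiscriminationReport-class].
#' @return See each accessor.
#' @export
discriminatesAll <- function(report) report@discriminatesAll

#' @rdname discriminatesAll
#' @export
distinguishablePairs <- function(report) report@distinguishable

#' @rdname discriminatesAll
#' @export
variantCounts <- function(report) report@variantCounts

#' @rdname discriminatesAll
#' @export
reportEnzyme <- function(report) report@enzyme

#' @rdname discriminatesAll
#' @export
reportProfiles <- function(report) report@profiles

setMethod("show", "DiscriminationReport", function(object) {
  cat(sprintf("DiscriminationReport [%s]: %s\n", object@enzyme,
              if (object@flagged) "single species (vacuous)"
              else if (object@discriminatesAll)
                "discriminates all species simultaneously"
              else "does NOT separate every species pair"))
  cat("  variants per species:",
      paste(sprintf("%s=%d", names(object@variantCounts),
                    object@variantCounts), collapse = ", "), "\n")
  if (!object@discriminatesAll && !object@flagged) {
    m <- object@distinguishable
    bad <- which(upper.tri(m) & !m, arr.ind = TRUE)
    for (r in seq_len(nrow(bad))) {
      cat("  unresolved pair:", rownames(m)[bad[r, 1L]], "vs",
          colnames(m)[bad[r, 2L]], "\n")
    }
  }
})

# Smallest band-size difference between any equal-band-count pattern pair
# of two different species: a readability margin — patterns that differ
# only by a near-tolerance size step are harder to call on a gel. Inf when
# no cross-species pair has equal band counts (counts alone separate them).
.crossSpeciesGap <- function(profiles) {
  gap <- Inf
  n <- length(profiles)
  if (n < 2L) return(gap)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      for (va in profiles[[i]]@variants) {
        for (vb in profiles[[j]]@variants) {
          if (length(va@sizes) == length(vb@sizes) && length(va@sizes)) {
            gap <- min(gap, min(abs(va@sizes - vb@sizes)))
          }
        }
      }
    }
  }
  gap
}

# Ranking key for enzyme candidates: full discrimination first, then fewer
# intraspecific variants, then a larger cross-species band gap, then name.
.rankReports <- function(reports) {
  full <- vapply(reports, discriminatesAll, logical(1L))
  nvar <- vapply(reports, function(r) sum(r@variantCounts), integer(1L))
  gaps <- vapply(reports, function(r) .crossSpeciesGap(r@profiles),
                 numeric(1L))
  nm <- vapply(reports, reportEnzyme, character(1L))
  order(!full, nvar, -gaps, nm)
}

#' Rank enzymes and select a discriminating enzyme (or enzyme set)
#'
#' Evaluates every candidate enzyme against the panel and ranks them by
#' (discriminates all species, fewer intraspecific variants, larger
#' smallest cross-species band-size difference, name). If the top enzyme
#' separates every species pair the solution is that single enzyme;
#' otherwise a greedy set cover over the undistinguished species pairs
#' assembles a minimal-or-near-minimal enzyme set (ties broken by the same
#' ranking key). If some pair is separated by no enzyme at all the solution
#' is flagged infeasible.
#'
#' @param panel A [ReferencePanel-class] with at least two species.
#' @param enzymes List of [RestrictionEnzyme-class] candidates.
#' @param params A [GelParams-class].
#' @return A list with `reports` (ranked [DiscriminationReport-class]
#'   list) and `solution` (an [EnzymePanelSolution-class]).
#' @examples
#' \dontrun{
#' sim <- makePanel(seed = 1)
#' sel <- selectEnzymes(sim$panel, defaultEnzymes())
#' reportEnzyme(sel$reports[[1]])
#' }
#' @export
selectEnzymes <- function(panel, enzymes, params = gelParams()) {
  stopifnot(length(enzymes) >= 1L)
  if (length(panelSpeciesNames(panel)) < 2L) {
    stop("enzyme selection needs at least two species", call. = FALSE)
  }
  reports <- lapply(enzymes, function(e)
    evaluateEnzyme(profileSpecies(panel, e, params)))
  reports <- reports[.rankReports(reports)]

  anyCut <- any(vapply(reports, function(r) {
    any(vapply(r@profiles, function(p)
      any(vapply(p@variants, function(v) length(v@sizes) != 1L,
                 logical(1L))), logical(1L)))
  }, logical(1L)))

  species <- panelSpeciesNames(panel)
  allPairs <- apply(utils::combn(sort(species), 2L), 2L,
                    function(p) paste(p, collapse = "|"))
  coverOf <- lapply(reports, function(r) {
    m <- r@distinguishable
    idx <- which(upper.tri(m) & m, arr.ind = TRUE)
    if (!nrow(idx)) return(character(0L))
    vapply(seq_len(nrow(idx)), function(k)
      .pairKey(rownames(m)[idx[k, 1L]], colnames(m)[idx[k, 2L]]),
      character(1L))
  })
  names(coverOf) <- vapply(reports, reportEnzyme, character(1L))

  if (discriminatesAll(reports[[1L]])) {
    sol <- methods::new("EnzymePanelSolution",
      enzymes = reportEnzyme(reports[[1L]]),
      coveredPairs = coverOf[1L], feasible = TRUE,
      diagnostic = "single enzyme discriminates all species")
  } else {
    uncovered <- allPairs
    chosen <- character(0L)
    covered <- list()
    while (length(uncovered)) {
      gains <- vapply(coverOf, function(cv)
        length(intersect(cv, uncovered)), integer(1L))
      gains[names(gains) %in% chosen] <- -1L
      best <- which(gains == max(gains))[1L]  # reports are ranking-ordered
      if (gains[best] <= 0L) break
      enzName <- names(coverOf)[best]
      chosen <- c(chosen, enzName)
      covered[[enzName]] <- intersect(coverOf[[best]], allPairs)
      uncovered <- setdiff(uncovered, coverOf[[best]])
    }
    feasible <- length(uncovered) == 0L
    diag <- if (feasible) {
      sprintf("%d-enzyme set covers all %d species pairs",
              length(chosen), length(allPairs))
    } else if (!anyCut) {
      "infeasible: no candidate enzyme cuts any panel sequence"
    } else {
      paste("infeasible: unresolved pair(s)",
            paste(uncovered, collapse = ", "))
    }
    sol <- methods::new("EnzymePanelSolution", enzymes = chosen,
                        coveredPairs = covered, feasible = feasible,
                        diagnostic = diag)
  }
  list(reports = reports, solution = sol)
}

#' EnzymePanelSolution accessors
#' @param solution An [EnzymePanelSolution-class].
#' @return See each accessor.
#' @export
solutionEnzymes <- function(solution) solution@enzymes

#' @rdname solutionEnzymes
#' @export
solutionFeasible <- function(solution) solution@feasible

setMethod("show", "EnzymePanelSolution", function(object) {
  cat("EnzymePanelSolution:",
      if (length(object@enzymes)) paste(object@enzymes, collapse = " + ")
      else "(none)",
      if (object@feasible) "" else "[INFEASIBLE]", "\n")
  cat(" ", object@diagnostic, "\n")
})

#' Assign an unknown sample to a species by its band pattern
#'
#' Scores the observed pattern against every variant of every species
#' profile with `1 - patternDistance()`. The best-scoring variant wins when
#' its score reaches `threshold` and no other species ties it; a
#' cross-species tie at the best score returns an `"ambiguous"` call and no
#' sufficient score returns `"unassigned"`. The default threshold of 1
#' demands a full pattern match (every band paired within tolerance),
#' which is how identification on an actual gel is read.
#'
#' @param observed A [GelPattern-class], a numeric vector of band sizes, or
#'   a DNA sequence string (digested with `enzyme` first).
#' @param profiles List of [SpeciesProfile-class] (from [profileSpecies()]
#'   or [profilesFromPatterns()]).
#' @param enzyme [RestrictionEnzyme-class]; required only when `observed`
#'   is a sequence.
#' @param params A [GelParams-class] used when `observed` needs conversion.
#' @param threshold Minimum winning score in `[0, 1]` (default 1).
#' @return A list with `call` (species name, `"ambiguous"` or
#'   `"unassigned"`), `species`, `variant` (index), `score`, and
#'   `matchedIds` (reference records supporting the winning variant).
#' @examples
#' profs <- profilesFromPatterns(c("A", "B"),
#'                               list(c(400, 110), c(510)))
#' assignSample(c(405, 108), profs)$call
#' @export
assignSample <- function(observed, profiles, enzyme = NULL,
                         params = gelParams(), threshold = 1) {
  if (!length(profiles)) stop("empty profile list", call. = FALSE)
  if (is.character(observed) && length(observed) == 1L) {
    if (is.null(enzyme)) {
      stop("assigning a sequence requires 'enzyme'", call. = FALSE)
    }
    observed <- makePattern(digestSequence(observed, enzyme), params)
  } else if (is.numeric(observed)) {
    observed <- makePattern(observed, params)
  }
  stopifnot(is(observed, "GelPattern"))
  best <- data.frame(species = character(0L), variant = integer(0L),
                     score = numeric(0L))
  for (p in profiles) {
    for (v in seq_along(p@variants)) {
      sc <- 1 - patternDistance(observed, p@variants[[v]])
      best <- rbind(best, data.frame(species = p@species, variant = v,
                                     score = sc))
    }
  }
  top <- max(best$score)
  if (top < threshold) {
    return(list(call = "unassigned", species = NA_character_,
                variant = NA_integer_, score = top,
                matchedIds = character(0L)))
  }
  winners <- best[best$score == top, , drop = FALSE]
  if (length(unique(winners$species)) > 1L) {
    return(list(call = "ambiguous", species = NA_character_,
                variant = NA_integer_, score = top,
                matchedIds = character(0L)))
  }
  w <- winners[1L, ]
  prof <- profiles[[which(vapply(profiles, profileSpeciesName,
                                 character(1L)) == w$species)[1L]]]
  list(call = w$species, species = w$species,
       variant = as.integer(w$variant), score = w$score,
       matchedIds = prof@supportIds[[w$variant]])
}
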