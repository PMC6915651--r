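# Independent brute-force oracle for restriction-site scanning. Kept
# deliberately naive and separate from the package's bitmask scanner: each
# window is checked by enumerating every concrete expansion of its
# ambiguity codes.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracleRevComp <- function(x) {
  paste(rev(ORACLE_COMP[strsplit(x, "")[[1L]]]), collapse = "")
}

# window verdict: 2 = every expansion of the window matches the pattern,
# 1 = some expansion matches, 0 = none. Windows without ambiguity codes
# have a single expansion and are checked directly.
oracleWindowVerdict <- function(window, pattern) {
  wchars <- strsplit(window, "")[[1L]]
  pchars <- strsplit(pattern, "")[[1L]]
  if (all(wchars %in% c("A", "C", "G", "T"))) {
    hit <- all(vapply(seq_along(wchars),
                      function(j) wchars[j] %in% ORACLE_SETS[[pchars[j]]],
                      logical(1L)))
    return(if (hit) 2L else 0L)
  }
  expansions <- expand.grid(ORACLE_SETS[wchars], stringsAsFactors = FALSE)
  hits <- apply(expansions, 1L, function(bases) {
    all(mapply(function(b, p) b %in% ORACLE_SETS[[p]], bases, pchars))
  })
  if (all(hits)) 2L else if (any(hits)) 1L else 0L
}

# full two-strand scan with the same site-collapse convention the scanner
# documents: a window matching (or possibly matching) on the top strand
# contributes its top-strand cut; bottom-strand-only windows map through
# L - offset
oracleScan <- function(sequence, pattern, cutOffset) {
  L <- nchar(pattern)
  n <- nchar(sequence) - L + 1L
  rcpat <- oracleRevComp(pattern)
  confirmed <- integer(0L)
  candidate <- integer(0L)
  if (n >= 1L) {
    for (w in 0:(n - 1L)) {
      win <- substr(sequence, w + 1L, w + L)
      top <- oracleWindowVerdict(win, pattern)
      if (top == 2L) {
        confirmed <- c(confirmed, w + cutOffset)
        next
      }
      bot <- oracleWindowVerdict(win, rcpat)
      if (bot == 2L) {
        confirmed <- c(confirmed, w + (L - cutOffset))
      } else if (top == 1L) {
        candidate <- c(candidate, w + cutOffset)
      } else if (bot == 1L) {
        candidate <- c(candidate, w + (L - cutOffset))
      }
    }
  }
  confirmed <- sort(unique(confirmed))
  list(confirmed = confirmed,
       candidate = sort(unique(setdiff(candidate, confirmed))))
}

randomDNA <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random DNA with a few ambiguity codes sprinkled in
randomAmbiguousDNA <- function(n, nAmbig = 3L) {
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  pos <- sample.int(n, min(nAmbig, n))
  chars[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), length(pos),
                       replace = TRUE)
  paste(chars, collapse = "")
}

expectScanEqualsOracle <- function(sequence, enzyme) {
  scan <- findSites(sequence, enzyme)
  oracle <- oracleScan(sequence, enzymePattern(enzyme),
                       enzymeCutOffset(enzyme))
  expect_identical(cutPositions(scan), as.integer(oracle$confirmed),
                   label = paste0("confirmed cuts for ", enzymeName(enzyme),
                                  " on ", sequence))
  expect_identical(candidatePositions(scan), as.integer(oracle$candidate),
                   label = paste0("candidate cuts for ", enzymeName(enzyme),
                                  " on ", sequence))
}
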