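# FASTA i/o with a light label dialect: optional whitespace-separated
# "species=<name>" and "group=<name>" tokens in the description carry the
# declared species and sample group, keeping files readable by any other
# FASTA tool. Values may use '_' in place of spaces.

.parseHeaderTokens <- function(header) {
  parts <- strsplit(header, "[ \t]+")[[1L]]
  id <- parts[1L]
  rest <- parts[-1L]
  species <- NA_character_
  group <- NA_character_
  keep <- character(0L)
  for (tok in rest) {
    if (startsWith(tok, "species=")) {
      species <- gsub("_", " ", sub("^species=", "", tok))
    } else if (startsWith(tok, "group=")) {
      group <- gsub("_", " ", sub("^group=", "", tok))
    } else {
      keep <- c(keep, tok)
    }
  }
  list(id = id, description = paste(keep, collapse = " "),
       species = species, group = group)
}

.buildHeader <- function(id, description, species, group) {
  parts <- id
  if (!is.na(description) && nzchar(description))
    parts <- c(parts, description)
  if (!is.na(species) && nzchar(species))
    parts <- c(parts, paste0("species=", gsub(" ", "_", species)))
  if (!is.na(group) && nzchar(group))
    parts <- c(parts, paste0("group=", gsub(" ", "_", group)))
  paste(parts, collapse = " ")
}

#' Read COI barcode records from FASTA
#'
#' Reads a multi-record FASTA file (or literal FASTA text) into a
#' [Biostrings::DNAStringSet] whose element metadata holds the free-text
#' `description` plus the optional `species` and `group` labels parsed from
#' `species=` / `group=` tokens in the header. Sequences are uppercased and
#' validated against the 15-letter IUPAC DNA alphabet; `U` and any other
#' non-IUPAC character are rejected with a diagnostic naming the record and
#' position. Duplicate ids and empty sequences are errors.
#'
#' @param source Path to a FASTA file, or a character scalar containing
#'   FASTA text (recognised by a leading `>`).
#' @return A named `DNAStringSet` in file order with metadata columns
#'   `description`, `species`, `group`.
#' @examples
#' recs <- readFastaRecords(">a species=Xiphias_gladius\nacgtacgt\n")
#' names(recs)
#' S4Vectors::mcols(recs)$species
#' @seealso [writeFastaRecords()], [ReferencePanel()]
#' @export
readFastaRecords <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (grepl("^\\s*>", source)) {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf), add = TRUE)
    writeLines(source, tf)
    source <- tf
  }
  raw <- Biostrings::readBStringSet(source)
  headers <- names(raw)
  seqs <- toupper(as.character(raw))
  meta <- lapply(headers, .parseHeaderTokens)
  ids <- vapply(meta, `[[`, character(1L), "id")
  if (any(!nzchar(ids))) stop("FASTA record with empty id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate record id '", ids[anyDuplicated(ids)], "'",
         call. = FALSE)
  }
  for (k in seq_along(seqs)) {
    if (!nzchar(seqs[k])) {
      stop("record '", ids[k], "' has an empty sequence", call. = FALSE)
    }
    .seqBits(seqs[k], what = paste0("record '", ids[k], "'"))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    description = vapply(meta, `[[`, character(1L), "description"),
    species = vapply(meta, `[[`, character(1L), "species"),
    group = vapply(meta, `[[`, character(1L), "group"))
  out
}

#' Write barcode records to FASTA
#'
#' Serialises a labelled `DNAStringSet` (as produced by
#' [readFastaRecords()]) back to FASTA, re-emitting `species=` / `group=`
#' tokens so that a read/write round trip preserves all labels. Output is
#' deterministic.
#'
#' @param records A named `DNAStringSet`, optionally with `description`,
#'   `species`, `group` metadata columns.
#' @param path Output file path, or `NULL` to return the FASTA text.
#' @param wrap Sequence line width (positive integer).
#' @return `path` invisibly, or the FASTA text when `path` is `NULL`.
#' @seealso [readFastaRecords()]
#' @export
writeFastaRecords <- function(records, path = NULL, wrap = 70L) {
  stopifnot(is(records, "DNAStringSet"), wrap >= 1L)
  mc <- S4Vectors::mcols(records)
  getcol <- function(col) {
    if (!is.null(mc) && col %in% colnames(mc)) mc[[col]]
    else rep(NA_character_, length(records))
  }
  headers <- mapply(.buildHeader, names(records), getcol("description"),
                    getcol("species"), getcol("group"), USE.NAMES = FALSE)
  out <- Biostrings::DNAStringSet(unname(as.character(records)))
  names(out) <- headers
  if (is.null(path)) {
    if (!length(out)) return("")
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf), add = TRUE)
    Biostrings::writeXStringSet(out, tf, width = as.integer(wrap))
    return(paste0(paste(readLines(tf), collapse = "\n"), "\n"))
  }
  Biostrings::writeXStringSet(out, path, width = as.integer(wrap))
  invisible(path)
}

#' Construct a species-labelled reference panel
#'
#' Builds a [ReferencePanel-class] from barcode records. Species labels are
#' taken from the `species` argument if given, otherwise from the records'
#' `species` metadata column (e.g. set via FASTA `species=` tokens).
#'
#' @param records A named `DNAStringSet` (see [readFastaRecords()]).
#' @param species Optional character vector of species labels, recycled
#'   checked against `length(records)`.
#' @return A `ReferencePanel`.
#' @examples
#' recs <- readFastaRecords(
#'   ">r1 species=A\nACGTACGT\n>r2 species=B\nACGTTCGA\n")
#' panel <- ReferencePanel(recs)
#' panelSpecies(panel)
#' @export
ReferencePanel <- function(records, species = NULL) {
  stopifnot(is(records, "DNAStringSet"))
  mc <- S4Vectors::mcols(records)
  if (is.null(mc)) {
    mc <- S4Vectors::DataFrame(row.names = seq_along(records))
  }
  if (!is.null(species)) {
    stopifnot(length(species) == length(records))
    mc$species <- as.character(species)
  } else if (!"species" %in% colnames(mc)) {
    stop("no species labels: supply 'species' or species= FASTA tokens",
         call. = FALSE)
  }
  S4Vectors::mcols(records) <- mc
  methods::new("ReferencePanel", records)
}

#' Panel accessors
#'
#' `panelSpecies()` returns the species label of every record;
#' `panelSpeciesNames()` the distinct species in order of first appearance
#' (the order used for profiling, which makes greedy variant clustering
#' deterministic).
#'
#' @param panel A [ReferencePanel-class].
#' @return A character vector.
#' @export
panelSpecies <- function(panel) {
  stopifnot(is(panel, "ReferencePanel"))
  as.character(S4Vectors::mcols(panel)$species)
}

#' @rdname panelSpecies
#' @export
panelSpeciesNames <- function(panel) unique(panelSpecies(panel))

setMethod("show", "ReferencePanel", function(object) {
  sp <- panelSpecies(object)
  cat("ReferencePanel:", length(object), "records,",
      length(unique(sp)), "species\n")
  tab <- table(factor(sp, levels = unique(sp)))
  for (s in names(tab)) {
    cat(sprintf("  %-28s %d record(s)\n", s, tab[[s]]))
  }
})
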