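# 3' adapter clipping with insert-length inference, rRNA dusting, a toy
# exact-match aligner for desk-scale tests, and EcoP15I-style truncation.

#' Default 3' sequencing adapter
#' @return The 17-nt 3' adapter ligated to the small RNAs.
#' @export
default_adapter <- function() "CTGTAGGCACCATCAAT"

# Leftmost position (1-based) where a prefix of `adapter` of length >=
# min_match matches `read` exactly through the read's end, or where the full
# adapter matches internally. Returns NA when no such position exists.
.adapter_start <- function(read, adapter, min_match) {
  rl <- nchar(read)
  alen <- nchar(adapter)
  if (rl == 0L) return(NA_integer_)
  starts <- seq_len(rl)
  # candidate positions must leave room for at least min_match adapter bases
  starts <- starts[rl - starts + 1L >= min_match]
  for (i in starts) {
    len <- min(alen, rl - i + 1L)
    if (substr(read, i, i + len - 1L) == substr(adapter, 1L, len))
      return(i)
  }
  NA_integer_
}

#' Clip the 3' adapter from reads and infer insert lengths
#'
#' Scans each read for the leftmost position where a prefix of the adapter
#' of at least `min_match` bases matches exactly through the read's end (or
#' the full adapter matches internally). The insert is everything upstream;
#' its length is the inferred RNA length. Reads with no qualifying match are
#' flagged unmeasured: with 100-nt reads and an 8-base minimum match, only
#' inserts up to 92 nt are measurable, so unmeasured tags represent RNAs of
#' at least read length minus minimum match plus one (93 nt here).
#'
#' @param reads Character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param adapter Adapter sequence (default [default_adapter()]).
#' @param min_match Minimum number of adapter bases that must match
#'   (default 8; must be between 1 and the adapter length).
#' @param read_id Optional read identifiers (defaults to names or index).
#' @return A data frame of tags: `read_id`, `sequence` (clipped insert),
#'   `inferred_length` (integer, `NA` when unmeasured), `measured` (logical),
#'   `empty` (insert of length 0, e.g. adapter-only reads).
#' @examples
#' clip_adapter(paste0(strrep("A", 30), default_adapter()))
#' @export
clip_adapter <- function(reads, adapter = default_adapter(), min_match = 8L,
                         read_id = NULL) {
  if (methods::is(reads, "DNAStringSet")) {
    if (is.null(read_id)) read_id <- names(reads)
    reads <- as.character(reads)
  }
  if (length(reads) == 0)
    return(data.frame(read_id = character(), sequence = character(),
                      inferred_length = integer(), measured = logical(),
                      empty = logical(), stringsAsFactors = FALSE))
  if (any(!nzchar(reads))) stop("empty read")
  min_match <- as.integer(min_match)
  if (min_match < 1L || min_match > nchar(adapter))
    stop("min_match must be between 1 and the adapter length")
  if (is.null(read_id)) read_id <- names(reads)
  if (is.null(read_id)) read_id <- paste0("read", seq_along(reads))
  pos <- vapply(reads, .adapter_start, 0L, adapter = adapter,
                min_match = min_match, USE.NAMES = FALSE)
  measured <- !is.na(pos)
  insert <- ifelse(measured, substr(reads, 1L, ifelse(measured, pos - 1L, 0L)),
                   reads)
  data.frame(
    read_id = read_id,
    sequence = insert,
    inferred_length = ifelse(measured, nchar(insert), NA_integer_),
    measured = measured,
    empty = measured & nchar(insert) == 0L,
    stringsAsFactors = FALSE
  )
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Remove tags exactly matching a ribosomal DNA reference
#'
#' A tag is removed iff its clipped sequence occurs as an exact substring of
#' the rDNA reference or of its reverse complement (strand-agnostic removal,
#' the conservative reading of exact-match rRNA dusting). Tags with empty
#' sequences are kept.
#'
#' @param tags Data frame from [clip_adapter()] (or character vector of
#'   sequences).
#' @param rdna_reference A single reference sequence (character, or a
#'   `DNAStringSet` of length 1, e.g. read with
#'   `Biostrings::readDNAStringSet`).
#' @return List with `kept` and `removed`, both shaped like the input.
#' @export
rrna_filter <- function(tags, rdna_reference) {
  if (methods::is(rdna_reference, "DNAStringSet")) {
    if (length(rdna_reference) != 1L)
      stop("rdna_reference must be a single sequence")
    rdna_reference <- as.character(rdna_reference)
  }
  if (!nzchar(rdna_reference)) stop("empty reference")
  seqs <- if (is.data.frame(tags)) tags$sequence else tags
  rc <- .revcomp(rdna_reference)
  hit <- nzchar(seqs) &
    (vapply(seqs, grepl, TRUE, x = rdna_reference, fixed = TRUE,
            USE.NAMES = FALSE) |
     vapply(seqs, grepl, TRUE, x = rc, fixed = TRUE, USE.NAMES = FALSE))
  if (is.data.frame(tags)) {
    list(kept = tags[!hit, , drop = FALSE], removed = tags[hit, , drop = FALSE])
  } else {
    list(kept = tags[!hit], removed = tags[hit])
  }
}

#' Toy exact-match aligner
#'
#' Desk-scale stand-in for an external read aligner: exhaustive
#' exact-substring search of each tag against both strands of a genome.
#' Coordinates are 0-based half-open (BED-native). A tag is `unique` iff it
#' has exactly one hit genome-wide; all hits of multi-mapping tags are
#' reported with `unique = FALSE`.
#'
#' @param tags Data frame with `read_id` and `sequence` columns (or a named
#'   character vector of sequences).
#' @param genome Named character vector of chromosome sequences (or a
#'   `DNAStringSet`).
#' @return Data frame: `read_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-`), `unique`.
#' @export
toy_align <- function(tags, genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  if (is.data.frame(tags)) {
    seqs <- tags$sequence; ids <- tags$read_id
  } else {
    seqs <- as.character(tags)
    ids <- names(tags)
    if (is.null(ids)) ids <- paste0("tag", seq_along(seqs))
  }
  empty <- data.frame(read_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      unique = logical(), stringsAsFactors = FALSE)
  if (length(seqs) == 0) return(empty)
  hits_one <- function(id, s) {
    if (!nzchar(s)) return(NULL)
    out <- NULL
    for (chrom in names(genome)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") s else .revcomp(s)
        m <- gregexpr(pat, genome[[chrom]], fixed = TRUE)[[1]]
        if (m[1] == -1L) next
        out <- rbind(out, data.frame(
          read_id = id, chrom = chrom, start = as.integer(m) - 1L,
          end = as.integer(m) - 1L + nchar(s), strand = strand,
          stringsAsFactors = FALSE))
      }
    }
    if (!is.null(out)) out$unique <- nrow(out) == 1L
    out
  }
  res <- do.call(rbind, Map(hits_one, ids, seqs))
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Truncate tags to a fixed 5' length (EcoP15I-style)
#'
#' CAGE tags have a fixed size because a type III restriction enzyme cleaves
#' at a set distance from its site; tags longer than `tag_length` are cut to
#' their 5'-most `tag_length` bases, shorter tags pass unchanged.
#'
#' @param tags Character vector of sequences, or a data frame with a
#'   `sequence` column (its `inferred_length` is updated when present).
#' @param tag_length Truncation length in nt (default 27).
#' @return Same shape as the input, truncated.
#' @export
cage_truncate <- function(tags, tag_length = 27L) {
  tag_length <- as.integer(tag_length)
  if (is.data.frame(tags)) {
    tags$sequence <- substr(tags$sequence, 1L, tag_length)
    if ("inferred_length" %in% names(tags))
      tags$inferred_length <- ifelse(is.na(tags$inferred_length),
                                     NA_integer_,
                                     pmin(tags$inferred_length, tag_length))
    tags
  } else {
    substr(tags, 1L, tag_length)
  }
}
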