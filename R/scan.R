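#' Find perfect microsatellite tracts in transcript sequences
#'
#' Scans one or more nucleotide sequences for maximal perfect tandem repeats
#' with unit lengths of 1 to 6 bp, the classical definition of a
#' microsatellite. Only perfect (uninterrupted) repeats are reported;
#' positions containing `N` never participate in a tract. Each tract is
#' reported once, under the canonical form of its primitive repeat unit
#' (see [primitive_unit()]); a possible partial terminal copy counts toward
#' the tract length, so copy numbers may be fractional.
#'
#' @param sequences A named character vector of uppercase nucleotide
#'   sequences over `A`, `C`, `G`, `T`, `N` (names are the sequence
#'   identifiers), or a `Biostrings::DNAStringSet`. A single unnamed string
#'   is accepted and given the identifier `"seq1"`.
#' @param max_unit_len Maximum repeat-unit length in bp (1-6). Default 6.
#' @param min_copies Minimum number of unit copies (may be fractional).
#'   Must be at least 2. Default 3.
#' @param min_tract_len Minimum tract length in bp; must be at least
#'   `max_unit_len`. Default 6.
#'
#' @return A `data.frame` with one row per tract and columns `seq_id`,
#'   `start` (0-based inclusive), `end` (0-based exclusive), `unit`
#'   (canonical primitive unit), `copies` (tract length / unit length),
#'   sorted by `seq_id` (input order), `start`, `end`.
#'
#' @details Coordinates are 0-based half-open, as in BED. Every reported
#'   tract is maximal: extending it by one base on either side breaks the
#'   repeat phase, meets an `N`, or runs off the sequence. Overlapping
#'   descriptions of the same tract under rotated or multiplied units
#'   collapse to a single record because only primitive units are reported.
#'
#' @examples
#' find_microsatellites(c(T1 = "GGACACACACTT"))
#' @export
find_microsatellites <- function(sequences, max_unit_len = 6L,
                                 min_copies = 3, min_tract_len = 6L) {
  sequences <- .as_seq_vector(sequences)
  stopifnot(max_unit_len >= 1L, max_unit_len <= 6L)
  if (min_copies < 2)
    stop("min_copies must be >= 2")
  if (min_tract_len < max_unit_len)
    stop("min_tract_len must be >= max_unit_len")
  out <- lapply(seq_along(sequences), function(i) {
    .scan_one(sequences[[i]], names(sequences)[i],
              max_unit_len, min_copies, min_tract_len)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .empty_catalogue()
  rownames(res) <- NULL
  res
}

# scan a single sequence; returns NULL when nothing found
.scan_one <- function(seq, seq_id, max_unit_len, min_copies, min_tract_len) {
  n <- nchar(seq)
  if (n == 0L) return(NULL)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% c("A", "C", "G", "T", "N")))
  if (length(bad))
    stop(sprintf("invalid character '%s' in sequence '%s' at offset %d",
                 chars[bad[1]], seq_id, bad[1] - 1L))
  acc <- vector("list", max_unit_len)
  notN <- chars != "N"
  for (k in seq_len(max_unit_len)) {
    if (n < k + 1L) next
    ok <- chars[seq_len(n - k)] == chars[(k + 1L):n] &
      notN[seq_len(n - k)] & notN[(k + 1L):n]
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    if (!length(hit)) next
    rows <- list()
    for (h in hit) {
      i <- starts[h]                       # 1-based position of run start
      m <- r$lengths[h]
      len <- m + k
      copies <- len / k
      if (len < min_tract_len || copies < min_copies) next
      unit_obs <- substr(seq, i, i + k - 1L)
      prim <- .primitive_motif(unit_obs)
      if (nchar(prim) != k) next           # reported at the smaller period
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, start = i - 1L, end = i - 1L + len,
        unit = .min_rotation(prim), copies = copies,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) acc[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, acc)
  if (is.null(res) || nrow(res) == 0L) return(NULL)
  res[order(res$start, res$end, res$unit), , drop = FALSE]
}

#' Canonical primitive repeat unit of a motif
#'
#' Reduces a motif to the shortest string whose tandem repetition equals it,
#' then rotates that primitive string to its lexicographically smallest
#' rotation. No reverse-complement folding is applied (transcript space is
#' single-stranded).
#'
#' @param motif A non-empty character string.
#' @return The canonical primitive unit.
#' @examples
#' primitive_unit("ATAT")  # "AT"
#' primitive_unit("CA")    # "AC"
#' @export
primitive_unit <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L)
    stop("motif must be a single non-empty string")
  .min_rotation(.primitive_motif(motif))
}

.primitive_motif <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k)) {
    if (k %% d != 0L) next
    if (strrep(substr(motif, 1L, d), k / d) == motif)
      return(substr(motif, 1L, d))
  }
  motif
}

.min_rotation <- function(s) {
  k <- nchar(s)
  if (k == 1L) return(s)
  rots <- vapply(seq_len(k) - 1L, function(i)
    paste0(substr(s, i + 1L, k), substr(s, 1L, i)), character(1))
  min(rots)
}

.empty_catalogue <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             unit = character(), copies = numeric(), stringsAsFactors = FALSE)
}

.as_seq_vector <- function(sequences) {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (!is.character(sequences))
    stop("sequences must be a character vector or DNAStringSet")
  if (length(sequences) == 0L) return(stats::setNames(character(0),
                                                      character(0)))
  if (is.null(names(sequences))) {
    if (length(sequences) == 1L) {
      names(sequences) <- "seq1"
    } else {
      stop("multiple sequences must be named")
    }
  }
  if (anyDuplicated(names(sequences)))
    stop("sequence identifiers must be unique")
  toupper(sequences)
}

#' Write or read a microsatellite catalogue
#'
#' BED-like tab-delimited format with a header line and 0-based half-open
#' coordinates: columns `seq_id`, `start`, `end`, `unit`, `copies`.
#' `read_catalogue(write_catalogue(x, p))` returns `x`.
#'
#' @param catalogue A catalogue `data.frame` from [find_microsatellites()].
#' @param path File path.
#' @return `read_catalogue` returns the catalogue `data.frame`;
#'   `write_catalogue` returns `path` invisibly.
#' @export
write_catalogue <- function(catalogue, path) {
  stopifnot(all(c("seq_id", "start", "end", "unit", "copies") %in%
                  names(catalogue)))
  utils::write.table(
    catalogue[, c("seq_id", "start", "end", "unit", "copies")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(path) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "numeric"))
  if (!identical(names(cat), c("seq_id", "start", "end", "unit", "copies")))
    stop("malformed catalogue header in ", path)
  bad <- which(cat$end <= cat$start | cat$start < 0)
  if (length(bad))
    stop(sprintf("malformed catalogue record at line %d of %s: end <= start",
                 bad[1] + 1L, path))
  cat
}

#' Read transcript sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file and returns a
#' named uppercase character vector keyed by the first whitespace-delimited
#' token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_transcript_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifiers in ", path)
  seqs
}

#' Write transcript sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(sequences, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
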