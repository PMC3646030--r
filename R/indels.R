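#' Read indel calls from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped), keeps pure insertions and
#' deletions only, validates every REF allele against the reference
#' transcript sequences, and left-normalizes each retained call so that
#' repeat-associated indels land at the left edge of their tract.
#' Multi-allelic records are split per ALT allele. Substitutions, MNPs and
#' complex records (no prefix relation between REF and ALT) are skipped and
#' counted; records on transcripts absent from the reference are dropped
#' with a warning.
#'
#' @param vcf_path Path to the VCF file.
#' @param reference Named character vector of reference sequences (e.g. from
#'   [read_transcript_fasta()]).
#' @param keep_filtered Keep records whose FILTER is neither `PASS` nor `.`
#'   (default `FALSE`).
#' @param max_indel_len Drop indels longer than this many bp (default `Inf`,
#'   no cap).
#'
#' @return A `data.frame` of class `msiseq_indels` with one row per call:
#'   `seq_id`, `pos` (0-based offset of the anchor base), `ref`, `alt`,
#'   `kind` (`"insertion"`/`"deletion"`), `length` (bp), `int_start`,
#'   `int_end` (0-based half-open affected interval on the reference:
#'   the deleted bases for deletions; an empty interval immediately after
#'   the anchor for insertions) and `known` (initialized `FALSE`).
#'   Attribute `n_skipped` counts non-indel records, `n_dropped_seq`
#'   records on unknown sequences, `n_filtered` records removed by FILTER.
#' @export
read_indels <- function(vcf_path, reference, keep_filtered = FALSE,
                        max_indel_len = Inf) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  fix <- vcfR::read.vcfR(vcf_path, verbose = FALSE)@fix
  n_skipped <- 0L; n_dropped_seq <- 0L; n_filtered <- 0L
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]; pos1 <- as.integer(fix[i, "POS"])
    ref <- toupper(fix[i, "REF"]); flt <- fix[i, "FILTER"]
    if (!keep_filtered && !is.na(flt) && !(flt %in% c("PASS", "."))) {
      n_filtered <- n_filtered + 1L
      next
    }
    if (!(chrom %in% names(reference))) {
      n_dropped_seq <- n_dropped_seq + 1L
      next
    }
    seq <- reference[[chrom]]
    if (substr(seq, pos1, pos1 + nchar(ref) - 1L) != ref)
      stop(sprintf(
        "REF allele '%s' does not match reference '%s' at position %d (%s)",
        ref, chrom, pos1, vcf_path))
    for (alt in strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]) {
      call <- .classify_indel(chrom, pos1, ref, alt)
      if (is.null(call)) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (call$length > max_indel_len) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- call
    }
  }
  calls <- if (length(rows)) do.call(rbind.data.frame, rows) else
    .empty_indels()
  calls$known <- rep(FALSE, nrow(calls))
  calls <- left_normalize(calls, reference)
  if (n_dropped_seq)
    warning(n_dropped_seq, " record(s) on sequences absent from the reference",
            " were dropped")
  attr(calls, "n_skipped") <- n_skipped
  attr(calls, "n_dropped_seq") <- n_dropped_seq
  attr(calls, "n_filtered") <- n_filtered
  class(calls) <- c("msiseq_indels", "data.frame")
  calls
}

# classify one (REF, ALT) pair; NULL when not a pure indel
.classify_indel <- function(chrom, pos1, ref, alt) {
  if (grepl("[^ACGTN]", alt) || grepl("[^ACGTN]", ref)) return(NULL)
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == la) return(NULL)
  if (lr < la) {                 # candidate insertion
    if (substr(alt, 1L, lr) != ref) return(NULL)
    len <- la - lr
    anchor0 <- pos1 - 1L + lr - 1L     # last shared base, 0-based
    # re-anchor to a single-base representation
    data.frame(seq_id = chrom, pos = anchor0,
               ref = substr(ref, lr, lr),
               alt = substr(alt, lr, la),
               kind = "insertion", length = len,
               int_start = anchor0 + 1L, int_end = anchor0 + 1L,
               stringsAsFactors = FALSE)
  } else {                       # candidate deletion
    if (substr(ref, 1L, la) != alt) return(NULL)
    len <- lr - la
    anchor0 <- pos1 - 1L + la - 1L
    data.frame(seq_id = chrom, pos = anchor0,
               ref = substr(ref, la, lr),
               alt = substr(ref, la, la),
               kind = "deletion", length = len,
               int_start = anchor0 + 1L, int_end = anchor0 + 1L + len,
               stringsAsFactors = FALSE)
  }
}

.empty_indels <- function() {
  data.frame(seq_id = character(), pos = integer(), ref = character(),
             alt = character(), kind = character(), length = integer(),
             int_start = integer(), int_end = integer(),
             stringsAsFactors = FALSE)
}

#' Left-normalize indel calls against their reference sequence
#'
#' Shifts each insertion or deletion to the representation with the smallest
#' position among all representations producing the same edited sequence,
#' keeping a preceding anchor base. The operation is idempotent. This is
#' what makes repeat-associated indels land at the left edge of their
#' microsatellite tract, where [annotate_indels()] expects them.
#'
#' @param calls An indel `data.frame` as returned by [read_indels()].
#' @param reference Named character vector of reference sequences.
#' @return The calls with `pos`, `ref`, `alt`, `int_start`, `int_end`
#'   updated; row order preserved.
#' @export
left_normalize <- function(calls, reference) {
  if (nrow(calls) == 0L) return(calls)
  for (i in seq_len(nrow(calls))) {
    seq <- reference[[calls$seq_id[i]]]
    if (is.null(seq) || is.na(seq))
      stop("sequence not in reference: ", calls$seq_id[i])
    if (calls$kind[i] == "deletion") {
      a <- calls$int_start[i]; d <- calls$length[i]
      while (a >= 2L &&
             substr(seq, a, a) == substr(seq, a + d, a + d))
        a <- a - 1L
      calls$int_start[i] <- a
      calls$int_end[i] <- a + d
      calls$pos[i] <- a - 1L
      calls$ref[i] <- substr(seq, a, a + d)       # anchor + deleted bases
      calls$alt[i] <- substr(seq, a, a)
    } else {
      p <- calls$int_start[i]                      # insert before 0-based p
      x <- strsplit(calls$alt[i], "", fixed = TRUE)[[1]][-1L]
      d <- length(x)
      while (p >= 2L && substr(seq, p, p) == x[d]) {
        x <- c(substr(seq, p, p), x[-d])
        p <- p - 1L
      }
      calls$int_start[i] <- p
      calls$int_end[i] <- p
      calls$pos[i] <- p - 1L
      calls$ref[i] <- substr(seq, p, p)
      calls$alt[i] <- paste0(substr(seq, p, p), paste(x, collapse = ""))
    }
  }
  calls
}

#' Read a known-variant (dbSNP-style) set from a VCF file
#'
#' Parses and left-normalizes the variants of a population-polymorphism VCF
#' so they share the representation of sample calls, and returns the set of
#' normalized keys used by [filter_known()]. FILTER is ignored for known
#' sets.
#'
#' @param vcf_path Path to the known-variant VCF.
#' @inheritParams read_indels
#' @return A `data.frame` of normalized keys (`seq_id`, `pos`, `ref`, `alt`)
#'   of class `msiseq_known`.
#' @export
read_known_variants <- function(vcf_path, reference) {
  calls <- read_indels(vcf_path, reference, keep_filtered = TRUE)
  keys <- unique(calls[, c("seq_id", "pos", "ref", "alt")])
  rownames(keys) <- NULL
  class(keys) <- c("msiseq_known", "data.frame")
  keys
}

#' Remove indel calls matching a known-variant set
#'
#' Drops calls whose normalized `(seq_id, pos, ref, alt)` key appears in the
#' known set; both sides must have been normalized identically (they are,
#' when both come through [read_indels()] / [read_known_variants()] against
#' the same reference). Order is preserved and the number of removed calls
#' is recorded in the `n_removed` attribute.
#'
#' @param calls Indel calls `data.frame`.
#' @param known Known-variant key set from [read_known_variants()], or
#'   `NULL` for no filtering.
#' @return The retained calls, with attribute `n_removed`.
#' @export
filter_known <- function(calls, known) {
  if (is.null(known) || nrow(known) == 0L || nrow(calls) == 0L) {
    attr(calls, "n_removed") <- 0L
    return(calls)
  }
  key <- function(d) paste(d$seq_id, d$pos, d$ref, d$alt, sep = "\r")
  hit <- key(calls) %in% key(known)
  out <- calls[!hit, , drop = FALSE]
  attr(out, "n_skipped") <- attr(calls, "n_skipped")
  attr(out, "n_removed") <- sum(hit)
  out
}
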