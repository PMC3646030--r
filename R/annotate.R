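#' Read a transcript region model table
#'
#' Tab-delimited table with header and columns `seq_id`, `length`,
#' `cds_start`, `cds_end` (0-based half-open CDS on the transcript). Empty
#' CDS fields mark a non-coding transcript.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `seq_id`, `length`, `cds_start`,
#'   `cds_end` (`NA` for non-coding transcripts).
#' @export
read_transcript_models <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "integer",
                                        "integer", "integer"))
  if (!identical(names(m), c("seq_id", "length", "cds_start", "cds_end")))
    stop("malformed transcript model header in ", path)
  has <- !is.na(m$cds_start) & !is.na(m$cds_end)
  bad <- which(has & !(m$cds_start >= 0 & m$cds_start < m$cds_end &
                         m$cds_end <= m$length))
  if (length(bad))
    stop(sprintf("invalid CDS bounds at line %d of %s", bad[1] + 1L, path))
  m
}

#' Write a transcript region model table
#' @param models Transcript model `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_models <- function(models, path) {
  utils::write.table(models[, c("seq_id", "length", "cds_start", "cds_end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Assign a transcript region to an indel anchor position
#'
#' A transcript without a CDS is non-coding RNA. Otherwise the indel's
#' normalized anchor position `p` classifies it: `p < cds_start` is 5'UTR,
#' `cds_start <= p < cds_end` is CDS, `p >= cds_end` is 3'UTR. An indel
#' spanning a region boundary is assigned to its anchor's region so that
#' region proportions remain a partition.
#'
#' @param pos 0-based anchor position(s).
#' @param model One row of a transcript model `data.frame`.
#' @return Character vector over `"five_prime_utr"`, `"cds"`,
#'   `"three_prime_utr"`, `"ncRNA"`.
#' @export
assign_region <- function(pos, model) {
  if (any(pos < 0 | pos >= model$length))
    stop(sprintf("position outside [0, %d) on transcript %s",
                 model$length, model$seq_id))
  if (is.na(model$cds_start) || is.na(model$cds_end))
    return(rep("ncRNA", length(pos)))
  ifelse(pos < model$cds_start, "five_prime_utr",
         ifelse(pos < model$cds_end, "cds", "three_prime_utr"))
}

#' Intersect indel calls with the microsatellite catalogue
#'
#' Annotates each left-normalized call with microsatellite membership and,
#' when a transcript model table is supplied, its transcript region.
#' A deletion lies in a microsatellite when its affected interval overlaps
#' the tract interval `[start, end)`; an insertion when its anchor position
#' lies in `[start - 1, end)` — the left-flank position is included because
#' left-normalization parks tract-lengthening insertions there. When several
#' tracts qualify, the one with the smallest start (ties: the longest) is
#' assigned.
#'
#' @param calls Left-normalized indel calls (see [read_indels()]).
#' @param catalogue Microsatellite catalogue from [find_microsatellites()]
#'   or [read_catalogue()].
#' @param models Optional transcript model `data.frame`
#'   (see [read_transcript_models()]); when absent, `region` is `NA`.
#' @return The calls with added columns `in_ms` (logical), `ms_id`
#'   (`"seq_id:start-end"` or `NA`) and `region`.
#' @export
annotate_indels <- function(calls, catalogue, models = NULL) {
  calls <- as.data.frame(calls)
  calls$in_ms <- FALSE
  calls$ms_id <- NA_character_
  calls$region <- NA_character_
  if (nrow(calls) == 0L) {
    class(calls) <- c("msiseq_annotated", "data.frame")
    return(calls)
  }
  cat_by_seq <- split(catalogue, catalogue$seq_id)
  mod_by_seq <- if (!is.null(models)) split(models, models$seq_id) else NULL
  for (i in seq_len(nrow(calls))) {
    sid <- calls$seq_id[i]
    tr <- cat_by_seq[[sid]]
    if (!is.null(tr) && nrow(tr)) {
      hit <- if (calls$kind[i] == "deletion") {
        calls$int_start[i] < tr$end & calls$int_end[i] > tr$start
      } else {
        calls$pos[i] >= tr$start - 1L & calls$pos[i] < tr$end
      }
      if (any(hit)) {
        cand <- tr[hit, , drop = FALSE]
        cand <- cand[order(cand$start, -(cand$end - cand$start)), ,
                     drop = FALSE]
        calls$in_ms[i] <- TRUE
        calls$ms_id[i] <- sprintf("%s:%d-%d", sid, cand$start[1],
                                  cand$end[1])
      }
    }
    if (!is.null(mod_by_seq)) {
      mod <- mod_by_seq[[sid]]
      if (!is.null(mod) && nrow(mod))
        calls$region[i] <- assign_region(calls$pos[i], mod[1, ])
    }
  }
  class(calls) <- c("msiseq_annotated", "data.frame")
  calls
}

#' Number of distinct microsatellites altered by at least one indel
#'
#' Multiple indels within one tract count the tract once.
#'
#' @param annotated Annotated calls from [annotate_indels()].
#' @return Integer count of distinct altered tracts.
#' @export
altered_microsatellite_count <- function(annotated) {
  length(unique(annotated$ms_id[annotated$in_ms]))
}

#' Region proportions of microsatellite indels
#'
#' Proportions of microsatellite indels across 5'UTR, CDS, 3'UTR and ncRNA,
#' computed either over indel events (default) or over distinct altered
#' tracts (a tract's region taken from its first event). With zero
#' microsatellite indels the result is flagged undefined (all `NA`) rather
#' than silently zero.
#'
#' @param annotated Annotated calls from [annotate_indels()].
#' @param by `"event"` or `"tract"`.
#' @return Named numeric vector `c(five_prime_utr, cds, three_prime_utr,
#'   ncRNA)` summing to 1, or all-`NA` with attribute `undefined = TRUE`.
#' @export
region_proportions <- function(annotated, by = c("event", "tract")) {
  by <- match.arg(by)
  regions <- c("five_prime_utr", "cds", "three_prime_utr", "ncRNA")
  ms <- annotated[annotated$in_ms & !is.na(annotated$region), , drop = FALSE]
  if (by == "tract" && nrow(ms))
    ms <- ms[!duplicated(ms$ms_id), , drop = FALSE]
  if (nrow(ms) == 0L) {
    out <- stats::setNames(rep(NA_real_, 4L), regions)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  counts <- table(factor(ms$region, levels = regions))
  out <- as.numeric(counts) / sum(counts)
  names(out) <- regions
  attr(out, "undefined") <- FALSE
  out
}
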