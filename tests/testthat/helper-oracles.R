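# Independent oracles used to validate the implementation on small inputs.

# Exhaustive microsatellite search: enumerates every (start, end) interval
# for every unit length and keeps maximal, primitive-unit tracts. Only the
# per-position match vectors are shared with nothing in the package.
oracle_find_ms <- function(seq, max_unit_len = 6L, min_copies = 3,
                           min_tract_len = 6L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- list()
  for (k in seq_len(max_unit_len)) {
    if (n < k + 1L) next
    m <- chars[seq_len(n - k)] == chars[(k + 1L):n] &
      chars[seq_len(n - k)] != "N" & chars[(k + 1L):n] != "N"
    S <- c(0, cumsum(m))                       # S[i+1] = matches in 1..i
    for (a0 in 0:(n - min_tract_len)) {        # 0-based start
      lo <- a0 + max(min_tract_len, k + 1L)    # smallest candidate end
      if (lo > n) next
      bs <- lo:n                               # 0-based exclusive ends
      len <- bs - a0
      # period-k check: all of m[a0+1 .. b-k] are matches
      ok <- S[bs - k + 1L] - S[a0 + 1L] == len - k
      ok <- ok & (len / k >= min_copies) & (len >= min_tract_len)
      # maximality: cannot extend by one base on either side
      left_ext <- a0 > 0L && m[a0]
      ok <- ok & !left_ext
      right_ext <- bs < n
      right_ext[right_ext] <- m[bs[right_ext] - k + 1L]
      ok <- ok & !right_ext
      for (b in bs[ok]) {
        unit <- paste(chars[(a0 + 1L):(a0 + k)], collapse = "")
        if (!oracle_is_primitive(unit)) next
        out[[length(out) + 1L]] <- data.frame(
          start = a0, end = b, unit = oracle_min_rot(unit),
          copies = (b - a0) / k, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(start = integer(), end = integer(),
                      unit = character(), copies = numeric(),
                      stringsAsFactors = FALSE))
  res <- unique(res)
  res <- res[order(res$start, res$end, res$unit), , drop = FALSE]
  rownames(res) <- NULL
  res
}

oracle_is_primitive <- function(unit) {
  k <- nchar(unit)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (strrep(substr(unit, 1L, d), k / d) == unit) return(FALSE)
  }
  TRUE
}

oracle_min_rot <- function(unit) {
  k <- nchar(unit)
  min(vapply(seq_len(k), function(i)
    paste0(substr(unit, i, k), substr(unit, 1L, i - 1L)), character(1)))
}

# Apply an indel to a reference string.
apply_deletion <- function(seq, start0, len) {
  paste0(substr(seq, 1L, start0), substr(seq, start0 + len + 1L, nchar(seq)))
}
apply_insertion <- function(seq, point0, ins) {
  paste0(substr(seq, 1L, point0), ins, substr(seq, point0 + 1L, nchar(seq)))
}

# Leftmost equivalent representation (anchor base kept): enumerate every
# candidate position, apply the edit, compare edited strings.
oracle_leftmost_deletion <- function(seq, start0, len) {
  target <- apply_deletion(seq, start0, len)
  for (a in 1:start0)
    if (apply_deletion(seq, a, len) == target) return(a)
  start0
}
oracle_leftmost_insertion <- function(seq, point0, ins) {
  target <- apply_insertion(seq, point0, ins)
  d <- nchar(ins)
  for (p in 1:point0) {
    cand <- substr(target, p + 1L, p + d)
    if (apply_insertion(seq, p, cand) == target)
      return(list(point = p, ins = cand))
  }
  list(point = point0, ins = ins)
}

# Exhaustive two-sample KS statistic: max ECDF gap over the union support.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Random test sequence over ACGT (optionally with N).
random_seq <- function(n, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", if (p_n > 0) "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), if (p_n > 0) p_n)),
        collapse = "")
}

# Minimal VCF writer for fixtures.
write_test_vcf <- function(rows, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

# Small annotated-call data.frame builder for the statistics tests.
fake_annotated <- function(kind, in_ms, length = 1L, region = "cds",
                           ms_id = NULL) {
  n <- max(length(kind), length(in_ms))
  kind <- rep_len(kind, n); in_ms <- rep_len(in_ms, n)
  len <- rep_len(length, n)
  if (is.null(ms_id))
    ms_id <- ifelse(in_ms, paste0("T1:", seq_len(n) * 10, "-",
                                  seq_len(n) * 10 + 8), NA)
  data.frame(seq_id = rep("T1", n), pos = seq_len(n) * 10,
             ref = rep("A", n), alt = rep("AT", n),
             kind = kind, length = len,
             int_start = seq_len(n) * 10 + 1L,
             int_end = seq_len(n) * 10 + 1L +
               ifelse(kind == "deletion", len, 0L),
             known = rep(FALSE, n), in_ms = in_ms, ms_id = ms_id,
             region = rep_len(region, n), stringsAsFactors = FALSE)
}

# Small shared transcriptome for simulator-driven tests.
small_params <- function(status = "MSS", ...) {
  args <- list(status = status, n_transcripts = 30L, transcript_len = 900L,
               tracts_per_transcript = 3L, n_ins_total = 80L,
               n_del_total = if (status == "MSI") 160L else 80L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_params, args)
}
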