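#' Simulation parameters for synthetic MSI/MSS/normal samples
#'
#' Bundles the generator settings. Defaults emulate the indel structure of
#' transcriptome indel calling at desk scale: a few hundred indels per
#' sample, balanced insertion/deletion rates in controls, and an elevated
#' microsatellite deletion rate dominated by 1-unit events in MSI samples.
#' MSI samples default to 600 deletions with `p_ms_del = 0.6` and a 1-unit
#' deletion weight of 0.8; MSS and normal samples to 300 deletions with
#' `p_ms_del = 0.3` and weight 0.4. All statuses share `p_ms_ins = 0.3`
#' and a 1-unit insertion weight of 0.4, so insertion-length distributions
#' do not separate the groups.
#'
#' @param status `"MSS"`, `"MSI"` or `"normal"`.
#' @param n_transcripts Number of transcripts. Default 200.
#' @param transcript_len Transcript length in bp. Default 2000.
#' @param tracts_per_transcript Planted microsatellite tracts per
#'   transcript. Default 3.
#' @param n_ins_total,n_del_total Number of insertion/deletion events.
#' @param p_ms_ins,p_ms_del Probability that an insertion/deletion is
#'   placed inside a microsatellite.
#' @param msi_del_1bp_weight Probability that a microsatellite deletion
#'   removes exactly one repeat unit.
#' @param ins_1unit_weight Same weight for microsatellite insertions
#'   (status-independent). Default 0.4.
#' @param known_frac Fraction of background indels duplicated into a
#'   synthetic known-variant set (default 0).
#' @return A list of class `msiseq_sim_params`.
#' @export
sim_params <- function(status = c("MSS", "MSI", "normal"),
                       n_transcripts = 200L, transcript_len = 2000L,
                       tracts_per_transcript = 3L,
                       n_ins_total = 300L,
                       n_del_total = if (status == "MSI") 600L else 300L,
                       p_ms_ins = 0.3,
                       p_ms_del = if (status == "MSI") 0.6 else 0.3,
                       msi_del_1bp_weight =
                         if (status == "MSI") 0.8 else 0.4,
                       ins_1unit_weight = 0.4,
                       known_frac = 0) {
  status <- match.arg(status)
  p <- list(status = status, n_transcripts = as.integer(n_transcripts),
            transcript_len = as.integer(transcript_len),
            tracts_per_transcript = as.integer(tracts_per_transcript),
            n_ins_total = as.integer(n_ins_total),
            n_del_total = as.integer(n_del_total),
            p_ms_ins = p_ms_ins, p_ms_del = p_ms_del,
            msi_del_1bp_weight = msi_del_1bp_weight,
            ins_1unit_weight = ins_1unit_weight,
            known_frac = known_frac)
  stopifnot(p$n_transcripts >= 1, p$transcript_len >= 200,
            p$tracts_per_transcript >= 1,
            p$n_ins_total >= 0, p$n_del_total >= 0,
            p$p_ms_ins >= 0, p$p_ms_ins <= 1,
            p$p_ms_del >= 0, p$p_ms_del <= 1,
            p$msi_del_1bp_weight >= 0, p$msi_del_1bp_weight <= 1,
            p$known_frac >= 0, p$known_frac <= 1)
  class(p) <- "msiseq_sim_params"
  p
}

BASES <- c("A", "C", "G", "T")

# a planted tract: primitive unit of length k, integer copies, total >= 8 bp,
# flanks chosen to break the repeat phase on both sides
.draw_tract <- function() {
  repeat {
    k <- sample(6L, 1L)
    unit <- paste(sample(BASES, k, replace = TRUE), collapse = "")
    if (nchar(.primitive_motif(unit)) != k) next
    cmin <- max(3L, as.integer(ceiling(8 / k)))
    copies <- sample(cmin:(cmin + 3L), 1L)
    tract <- strrep(unit, copies)
    last <- substr(unit, k, k); first <- substr(unit, 1L, 1L)
    lf <- sample(setdiff(BASES, last), 1L)
    rf <- sample(setdiff(BASES, first), 1L)
    # local self-consistency: the padded tract must scan to exactly itself
    padded <- paste0(lf, tract, rf)
    found <- .scan_one(padded, "x", 6L, 3, 6L)
    if (!is.null(found) && nrow(found) == 1L &&
        found$start == 1L && found$end == 1L + nchar(tract))
      return(list(unit = unit, copies = copies, tract = tract,
                  lf = lf, rf = rf, k = k))
  }
}

# generate one transcript with planted tracts; returns sequence + tract df
.sim_transcript <- function(seq_id, len, n_tracts) {
  seg <- len %/% n_tracts
  if (seg < 80L) stop("tract placement impossible at this density")
  chars <- sample(BASES, len, replace = TRUE)
  planted <- vector("list", n_tracts)
  for (j in seq_len(n_tracts)) {
    tr <- .draw_tract()
    tlen <- nchar(tr$tract)
    start0 <- (j - 1L) * seg + seg %/% 3L        # away from segment edges
    chars[(start0):(start0 + tlen + 1L)] <-      # 1-based lf..tract..rf
      strsplit(paste0(tr$lf, tr$tract, tr$rf), "")[[1]]
    planted[[j]] <- data.frame(
      seq_id = seq_id, start = start0, end = start0 + tlen,
      unit = .min_rotation(tr$unit), copies = as.numeric(tr$copies),
      phase_unit = tr$unit, stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, planted)
  # protected positions (1-based): tracts plus their phase-breaking flanks
  prot <- unlist(lapply(seq_len(nrow(planted)), function(j)
    (planted$start[j]):(planted$end[j] + 1L)))
  for (iter in seq_len(200L)) {
    seq <- paste(chars, collapse = "")
    found <- find_microsatellites(stats::setNames(seq, seq_id))
    key <- function(d) paste(d$start, d$end, d$unit)
    extra <- found[!(key(found) %in% key(planted)), , drop = FALSE]
    if (nrow(extra) == 0L) {
      if (nrow(found) != nrow(planted))
        stop("planted tract lost during background repair")
      return(list(seq = seq, planted = planted))
    }
    # break each accidental background tract at a non-protected position
    for (j in seq_len(nrow(extra))) {
      cand <- setdiff((extra$start[j] + 1L):(extra$end[j]), prot)
      if (!length(cand)) stop("tract placement impossible: cannot repair")
      pos <- cand[ceiling(length(cand) / 2)]
      chars[pos] <- sample(setdiff(BASES, chars[pos]), 1L)
    }
  }
  stop("tract placement impossible: repair did not converge")
}

#' Generate a synthetic transcriptome with planted microsatellites
#'
#' Builds random ACGT transcripts with planted perfect tracts (unit length
#' 1-6 bp, at least 8 bp long, flanked so they cannot extend) at recorded
#' positions, spaced so tracts never merge. Accidental repeats in the
#' random background are broken by point changes so that the recorded
#' catalogue equals the scanner's output on the sequences exactly. CDS
#' boundaries are assigned to ~80% of transcripts; the rest are non-coding.
#'
#' @param params An `msiseq_sim_params` (only the transcriptome fields are
#'   used).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `msiseq_transcriptome` with `sequences` (named
#'   character vector), `catalogue` (as from [find_microsatellites()], plus
#'   a `phase_unit` column giving the planted phase), and `models`
#'   (transcript model `data.frame`).
#' @export
simulate_transcriptome <- function(params = sim_params(), seed = 1L) {
  set.seed(seed)
  n <- params$n_transcripts
  ids <- sprintf("TX%04d", seq_len(n))
  seqs <- character(n); cats <- vector("list", n); mods <- vector("list", n)
  for (i in seq_len(n)) {
    tx <- .sim_transcript(ids[i], params$transcript_len,
                          params$tracts_per_transcript)
    seqs[i] <- tx$seq
    cats[[i]] <- tx$planted
    len <- params$transcript_len
    coding <- stats::runif(1) < 0.8
    mods[[i]] <- data.frame(
      seq_id = ids[i], length = len,
      cds_start = if (coding) sample(50:(len %/% 4), 1L) else NA_integer_,
      cds_end = if (coding) sample((len - len %/% 4):(len - 50L), 1L)
                else NA_integer_,
      stringsAsFactors = FALSE)
  }
  structure(list(sequences = stats::setNames(seqs, ids),
                 catalogue = do.call(rbind, cats),
                 models = do.call(rbind, mods),
                 params = params, seed = seed),
            class = "msiseq_transcriptome")
}

# slippage indel at the left edge of a planted tract; already leftmost
# because the flank breaks the repeat phase
.ms_indel <- function(tract, kind, one_unit_weight) {
  u <- sample(c(1L, 2L, 3L), 1L,
              prob = c(one_unit_weight, (1 - one_unit_weight) / 2,
                       (1 - one_unit_weight) / 2))
  k <- nchar(tract$phase_unit)
  list(units = u, len = u * k)
}

# one background indel, rejection-sampled so that after left-normalization
# it does not touch any catalogued tract
.bg_indel <- function(seq_id, seq, kind, catalogue) {
  n <- nchar(seq)
  tr <- catalogue[catalogue$seq_id == seq_id, , drop = FALSE]
  for (try in 1:200) {
    len <- min(stats::rgeom(1, 0.5) + 1L, 10L)
    anchor0 <- sample(5:(n - 30L), 1L)
    if (kind == "deletion") {
      call <- data.frame(seq_id = seq_id, pos = anchor0,
                         ref = substr(seq, anchor0 + 1L, anchor0 + 1L + len),
                         alt = substr(seq, anchor0 + 1L, anchor0 + 1L),
                         kind = "deletion", length = len,
                         int_start = anchor0 + 1L,
                         int_end = anchor0 + 1L + len,
                         stringsAsFactors = FALSE)
    } else {
      ins <- paste(sample(BASES, len, replace = TRUE), collapse = "")
      call <- data.frame(seq_id = seq_id, pos = anchor0,
                         ref = substr(seq, anchor0 + 1L, anchor0 + 1L),
                         alt = paste0(substr(seq, anchor0 + 1L, anchor0 + 1L),
                                      ins),
                         kind = "insertion", length = len,
                         int_start = anchor0 + 1L, int_end = anchor0 + 1L,
                         stringsAsFactors = FALSE)
    }
    call <- left_normalize(call, stats::setNames(seq, seq_id))
    in_ms <- if (nrow(tr)) {
      if (kind == "deletion")
        any(call$int_start < tr$end & call$int_end > tr$start)
      else
        any(call$pos >= tr$start - 1L & call$pos < tr$end)
    } else FALSE
    if (!in_ms) return(call)
  }
  stop("could not place background indel away from microsatellites")
}

#' Generate one synthetic sample's indel calls
#'
#' Draws `n_ins_total` insertions and `n_del_total` deletions. Each event
#' lands inside a microsatellite with probability `p_ms_ins` /
#' `p_ms_del` (independently per event, so PI and PD are unbiased for these
#' probabilities by construction); otherwise it is placed uniformly outside
#' tracts (rejection-sampled after normalization). Microsatellite indel
#' lengths are whole multiples of the tract's repeat unit, with 1-unit
#' events weighted by `msi_del_1bp_weight` (deletions) or
#' `ins_1unit_weight` (insertions); background lengths are geometric with
#' mean 2. Microsatellite events are planted at tract left edges in
#' already-left-normalized form, so pipeline normalization leaves them
#' invariant.
#'
#' @param transcriptome An `msiseq_transcriptome` from
#'   [simulate_transcriptome()].
#' @param params An `msiseq_sim_params`.
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @return A list of class `msiseq_sim_sample` with `calls` (normalized
#'   indel `data.frame` with a `planted_ms` truth column), `known`
#'   (background calls duplicated into the synthetic known set; empty
#'   unless `known_frac > 0`) and `truth` (planted counts and the analytic
#'   `expected_PI = p_ms_ins`, `expected_PD = p_ms_del`,
#'   `expected_index = p_ms_ins / p_ms_del`).
#' @export
simulate_sample <- function(transcriptome, params = sim_params(),
                            seed = 1L, sample_id = "sample1") {
  set.seed(seed)
  seqs <- transcriptome$sequences
  cat <- transcriptome$catalogue
  draw <- function(kind, n_total, p_ms, w1) {
    if (n_total == 0L) return(NULL)
    in_ms <- stats::runif(n_total) < p_ms
    rows <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      if (in_ms[i]) {
        tr <- cat[sample(nrow(cat), 1L), , drop = FALSE]
        ev <- .ms_indel(tr, kind, w1)
        seq <- seqs[[tr$seq_id]]
        a0 <- tr$start - 1L                       # anchor = left flank
        anchor <- substr(seq, a0 + 1L, a0 + 1L)
        body <- substr(seq, tr$start + 1L, tr$start + ev$len)
        rows[[i]] <- data.frame(
          seq_id = tr$seq_id, pos = a0,
          ref = if (kind == "deletion") paste0(anchor, body) else anchor,
          alt = if (kind == "deletion") anchor else paste0(anchor, body),
          kind = kind, length = ev$len,
          int_start = tr$start,
          int_end = if (kind == "deletion") tr$start + ev$len else tr$start,
          stringsAsFactors = FALSE)
      } else {
        sid <- names(seqs)[sample(length(seqs), 1L)]
        rows[[i]] <- .bg_indel(sid, seqs[[sid]], kind, cat)
      }
    }
    out <- do.call(rbind, rows)
    out$planted_ms <- in_ms
    out
  }
  calls <- rbind(
    draw("insertion", params$n_ins_total, params$p_ms_ins,
         params$ins_1unit_weight),
    draw("deletion", params$n_del_total, params$p_ms_del,
         params$msi_del_1bp_weight))
  if (is.null(calls)) {
    calls <- .empty_indels()
    calls$planted_ms <- logical(0)
  }
  ord <- order(match(calls$seq_id, names(seqs)), calls$pos)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  known <- calls[0, , drop = FALSE]
  if (params$known_frac > 0) {
    bg <- which(!calls$planted_ms)
    n_known <- round(params$known_frac * length(bg))
    if (n_known > 0)
      known <- calls[sort(sample(bg, n_known)), , drop = FALSE]
  }
  truth <- list(sample_id = sample_id, status = params$status,
                n_ins_total = params$n_ins_total,
                n_del_total = params$n_del_total,
                n_ins_ms = sum(calls$planted_ms[calls$kind == "insertion"]),
                n_del_ms = sum(calls$planted_ms[calls$kind == "deletion"]),
                expected_PI = params$p_ms_ins,
                expected_PD = params$p_ms_del,
                expected_index = params$p_ms_ins / params$p_ms_del)
  structure(list(calls = calls, known = known, truth = truth,
                 sample_id = sample_id, params = params, seed = seed),
            class = "msiseq_sim_sample")
}

#' Write simulated indel calls as a VCF file
#'
#' Minimal VCF 4.2 with the 8 fixed columns; positions are 1-based with the
#' anchor base as in any indel VCF.
#'
#' @param calls Indel `data.frame` (e.g. `simulate_sample(...)$calls`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indel_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=msiseq-simulator",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- if (nrow(calls)) {
    paste(calls$seq_id, calls$pos + 1L, ".", calls$ref, calls$alt, ".",
          "PASS", ".", sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate a synthetic cohort on disk
#'
#' Writes a shared transcriptome (FASTA, microsatellite catalogue BED,
#' transcript model TSV), one VCF per sample for `n_per_group` samples in
#' each of the normal, MSS and MSI groups (per-sample count jitter of
#' +/-10%), and a `truth.tsv` table with planted counts and analytic
#' expectations.
#'
#' @param out_dir Output directory (created).
#' @param n_per_group Samples per status group. Default 3.
#' @param seed Master seed; the whole directory tree is reproducible from
#'   it.
#' @param base_params Named list of overrides passed to [sim_params()] for
#'   every status (e.g. `list(n_transcripts = 60)`).
#' @return Invisibly, a manifest list with the transcriptome, file paths
#'   and the truth table.
#' @export
simulate_cohort <- function(out_dir, n_per_group = 3L, seed = 1L,
                            base_params = list()) {
  stopifnot(n_per_group >= 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tp <- do.call(sim_params, c(list(status = "normal"), base_params))
  tr <- simulate_transcriptome(tp, seed = seed)
  fasta <- file.path(out_dir, "transcriptome.fa")
  bed <- file.path(out_dir, "catalogue.bed")
  mod <- file.path(out_dir, "models.tsv")
  write_transcript_fasta(tr$sequences, fasta)
  write_catalogue(tr$catalogue, bed)
  write_transcript_models(tr$models, mod)
  truth <- list(); vcfs <- character(0)
  idx <- 0L
  for (status in c("normal", "MSS", "MSI")) {
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", status, i)
      sub_seed <- (seed + 7919L * idx) %% .Machine$integer.max
      set.seed(sub_seed)
      jit <- function(n) max(1L, as.integer(round(n * stats::runif(1, 0.9,
                                                                   1.1))))
      p0 <- do.call(sim_params, c(list(status = status), base_params))
      p <- do.call(sim_params, c(
        list(status = status,
             n_ins_total = jit(p0$n_ins_total),
             n_del_total = jit(p0$n_del_total)),
        base_params[setdiff(names(base_params),
                            c("n_ins_total", "n_del_total"))]))
      smp <- simulate_sample(tr, p, seed = sub_seed + 1L, sample_id = sid)
      vcf <- file.path(out_dir, paste0(sid, ".vcf"))
      write_indel_vcf(smp$calls, vcf)
      vcfs[sid] <- vcf
      truth[[sid]] <- as.data.frame(smp$truth, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(transcriptome = tr, fasta = fasta, catalogue = bed,
                 models = mod, vcfs = vcfs, truth = truth,
                 out_dir = out_dir))
}
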