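#' Run the full scoring pipeline on files
#'
#' Orchestrates the file-based analysis: read the transcript FASTA, scan or
#' load the microsatellite catalogue, read each sample VCF (validated,
#' split, left-normalized), filter known variants, intersect with the
#' catalogue, annotate regions, build profiles and fit [msiseq()]. Stage
#' order is fixed; one log line per stage reports input/output record
#' counts to stderr. Any validation error aborts before a report is
#' written. Scoring is fully deterministic: no randomness is involved
#' outside the simulator.
#'
#' @param config A named list:
#'   \describe{
#'     \item{fasta}{transcript FASTA path (required).}
#'     \item{vcf}{named character vector of sample VCF paths (names are
#'       sample ids; unnamed paths use the file name).}
#'     \item{catalogue}{catalogue BED path; when `NULL` the FASTA is
#'       scanned with `scan_params`.}
#'     \item{model}{transcript model TSV path (optional).}
#'     \item{known_vcf}{known-variant VCF path (optional).}
#'     \item{control_vcf}{character vector of control-sample VCF paths
#'       (optional; enables the KS columns).}
#'     \item{out_dir}{output directory (required).}
#'     \item{threshold, min_ins, min_del, pseudocount, keep_filtered,
#'       max_indel_len}{scoring options with the package defaults.}
#'     \item{scan_params}{list of [find_microsatellites()] arguments.}
#'   }
#' @return Invisibly, a list with the `msiseq` fit, the `stage_log`
#'   `data.frame` (`stage`, `sample`, `n_in`, `n_out`, `n_dropped`) and the
#'   paths of the written report, manifest and (if scanned) catalogue.
#' @export
run_score <- function(config) {
  required <- c("fasta", "vcf", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config is missing: ", paste(missing, collapse = ", "))
  for (p in c(config$fasta, config$vcf, config$catalogue, config$model,
              config$known_vcf, config$control_vcf))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  threshold <- config$threshold %||% 0.9
  min_ins <- config$min_ins %||% 20L
  min_del <- config$min_del %||% 20L
  pseudocount <- config$pseudocount %||% 0
  keep_filtered <- isTRUE(config$keep_filtered)
  max_indel_len <- config$max_indel_len %||% Inf

  reference <- read_transcript_fasta(config$fasta)
  log <- list()
  note <- function(stage, sample, n_in, n_out) {
    message(sprintf("[%s] %s: in=%d out=%d dropped=%d", stage, sample,
                    n_in, n_out, n_in - n_out))
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, sample = sample, n_in = n_in, n_out = n_out,
      n_dropped = n_in - n_out, stringsAsFactors = FALSE)
  }

  if (is.null(config$catalogue)) {
    sp <- config$scan_params %||% list()
    catalogue <- do.call(find_microsatellites, c(list(reference), sp))
    note("scan", "catalogue", length(reference), nrow(catalogue))
  } else {
    catalogue <- read_catalogue(config$catalogue)
  }
  models <- if (!is.null(config$model))
    read_transcript_models(config$model) else NULL
  known <- if (!is.null(config$known_vcf))
    read_known_variants(config$known_vcf, reference) else NULL

  vcfs <- config$vcf
  if (is.null(names(vcfs)) || any(!nzchar(names(vcfs))))
    names(vcfs) <- tools::file_path_sans_ext(basename(vcfs))

  profile_one <- function(sid, path) {
    calls <- read_indels(path, reference, keep_filtered = keep_filtered,
                         max_indel_len = max_indel_len)
    n_units <- nrow(calls) + attr(calls, "n_skipped") +
      attr(calls, "n_filtered") + attr(calls, "n_dropped_seq")
    note("ingest", sid, n_units, nrow(calls))
    kept <- filter_known(calls, known)
    note("filter-known", sid, nrow(calls), nrow(kept))
    annotated <- annotate_indels(kept, catalogue, models)
    note("annotate", sid, nrow(kept), nrow(annotated))
    compute_profile(annotated, sid)
  }
  profiles <- lapply(names(vcfs), function(sid) profile_one(sid, vcfs[sid]))
  controls <- NULL
  if (!is.null(config$control_vcf)) {
    cv <- config$control_vcf
    if (is.null(names(cv)) || any(!nzchar(names(cv))))
      names(cv) <- tools::file_path_sans_ext(basename(cv))
    controls <- lapply(names(cv), function(sid) profile_one(sid, cv[sid]))
  }
  fit <- msiseq(profiles, controls = controls, threshold = threshold,
                min_ins = min_ins, min_del = min_del,
                pseudocount = pseudocount)
  note("classify", "cohort", length(profiles), nrow(fit$results))

  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- write_msiseq_report(fit, out_dir)
  stage_log <- do.call(rbind, log)
  manifest <- file.path(out_dir, "manifest.json")
  cfg <- config
  cfg$threshold <- threshold; cfg$min_ins <- min_ins
  cfg$min_del <- min_del; cfg$pseudocount <- pseudocount
  jsonlite::write_json(list(config = cfg, stages = stage_log),
                       manifest, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(list(fit = fit, stage_log = stage_log,
                 files = c(files, manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare MSI-seq statistics between sample groups
#'
#' Computes group means and two-sample t-tests (Student's pooled-variance
#' form, or paired for matched designs such as tumor/normal pairs) for the
#' MSI-seq index and the four region proportions.
#'
#' @param groups Named list (two or more entries) of per-sample results:
#'   each element a results `data.frame` (e.g. `fit$results` from
#'   [msiseq()] or a report TSV read back), or the path of a report TSV.
#' @param paired Paired design? Requires exactly two groups of equal size,
#'   matched by row order.
#' @return A `data.frame` with one row per metric: group means and, for
#'   two-group comparisons, `t` and `p`.
#' @export
run_compare <- function(groups, paired = FALSE) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  groups <- lapply(groups, function(g)
    if (is.character(g)) read_msiseq_report(g) else g)
  if (paired) {
    if (length(groups) != 2L)
      stop("paired comparison requires exactly 2 groups")
    if (nrow(groups[[1]]) != nrow(groups[[2]]))
      stop("paired groups must have equal numbers of samples")
  }
  metrics <- c("index", "prop_5utr", "prop_cds", "prop_3utr", "prop_nc")
  rows <- lapply(metrics, function(m) {
    vals <- lapply(groups, function(g) g[[m]][!is.na(g[[m]])])
    row <- data.frame(metric = m, stringsAsFactors = FALSE)
    for (gn in names(groups))
      row[[paste0("mean_", gn)]] <- mean(groups[[gn]][[m]], na.rm = TRUE)
    if (length(groups) == 2L) {
      ab <- if (paired)
        list(groups[[1]][[m]], groups[[2]][[m]]) else vals
      cmp <- if (length(ab[[1]]) >= 2 && length(ab[[2]]) >= 2)
        group_compare(ab[[1]], ab[[2]], paired = paired)
      else list(t = NA_real_, p = NA_real_)
      row$t <- cmp$t
      row$p <- cmp$p
    }
    row
  })
  do.call(rbind, rows)
}
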