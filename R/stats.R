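#' Build a per-sample indel profile
#'
#' Tallies one sample's annotated indel calls into the counts underlying the
#' PI/PD index: total and in-microsatellite insertions and deletions, the
#' length multisets of microsatellite indels, per-region counts of
#' microsatellite indel events and the number of distinct altered tracts.
#'
#' @param annotated Annotated calls for one sample
#'   (see [annotate_indels()]).
#' @param sample_id Sample identifier.
#' @return An object of class `msiseq_profile`: a list with elements
#'   `sample_id`, `n_ins_total`, `n_ins_ms`, `n_del_total`, `n_del_ms`,
#'   `ins_lengths_ms`, `del_lengths_ms`, `region_counts`, `altered_ms`,
#'   `region_props`.
#' @export
compute_profile <- function(annotated, sample_id) {
  ins <- annotated$kind == "insertion"
  del <- annotated$kind == "deletion"
  regions <- c("five_prime_utr", "cds", "three_prime_utr", "ncRNA")
  ms <- annotated$in_ms
  rc <- table(factor(annotated$region[ms], levels = regions))
  structure(list(
    sample_id = sample_id,
    n_ins_total = sum(ins),
    n_ins_ms = sum(ins & ms),
    n_del_total = sum(del),
    n_del_ms = sum(del & ms),
    ins_lengths_ms = sort(annotated$length[ins & ms]),
    del_lengths_ms = sort(annotated$length[del & ms]),
    region_counts = stats::setNames(as.integer(rc), regions),
    altered_ms = altered_microsatellite_count(annotated),
    region_props = region_proportions(annotated)
  ), class = "msiseq_profile")
}

#' Compute PI, PD and the MSI-seq index for one sample
#'
#' PI is the proportion of insertion events lying inside microsatellites
#' among all insertions; PD the analogous proportion for deletions. The
#' MSI-seq index is the ratio PI/PD, depressed in mismatch-repair-deficient
#' samples because MMR deficiency preferentially inflates short
#' microsatellite deletions. A zero denominator leaves the affected
#' component undefined (`NA`) rather than raising an error; an undefined
#' PI, PD or PD = 0 leaves the index undefined.
#'
#' @param profile An `msiseq_profile` from [compute_profile()].
#' @param pseudocount Optional count added to each of the four tallies
#'   before forming the proportions (default 0, no pseudocounts).
#' @return An object of class `msiseq_result`: a list with `sample_id`,
#'   `PI`, `PD`, `index` and (until [classify_msi()] is applied) label
#'   `"indeterminate"`.
#' @export
msi_index <- function(profile, pseudocount = 0) {
  stopifnot(inherits(profile, "msiseq_profile"), pseudocount >= 0)
  PI <- if (profile$n_ins_total + pseudocount > 0)
    (profile$n_ins_ms + pseudocount) /
      (profile$n_ins_total + pseudocount) else NA_real_
  PD <- if (profile$n_del_total + pseudocount > 0)
    (profile$n_del_ms + pseudocount) /
      (profile$n_del_total + pseudocount) else NA_real_
  index <- if (!is.na(PI) && !is.na(PD) && PD > 0) PI / PD else NA_real_
  structure(list(sample_id = profile$sample_id, PI = PI, PD = PD,
                 index = index, label = "indeterminate",
                 threshold_used = NA_real_),
            class = "msiseq_result")
}

#' Classify a sample as MSI or MSS from its MSI-seq index
#'
#' A sample is labelled MSI when its index falls below the decision
#' threshold and MSS otherwise. The default threshold of 0.9 comes from the
#' clinical-sample separation (MSI tumors up to ~0.81, MSS tumors from
#' ~0.99); the cell-line analysis supports a threshold of 1. Samples whose
#' index is undefined, or whose insertion or deletion totals fall below the
#' minimum counts, are labelled indeterminate: the index is a ratio of two
#' proportions and unstable at tiny denominators.
#'
#' @param result An `msiseq_result` from [msi_index()], or an
#'   `msiseq_profile` (the index is computed first).
#' @param threshold Decision threshold on the index (> 0). Default 0.9.
#' @param min_ins,min_del Minimum total insertion/deletion counts required
#'   to issue a label. Default 20 each.
#' @return The `msiseq_result` with `label` set to `"MSI"`, `"MSS"` or
#'   `"indeterminate"` and `threshold_used` recorded.
#' @export
classify_msi <- function(result, threshold = 0.9, min_ins = 20L,
                         min_del = 20L) {
  if (inherits(result, "msiseq_profile")) {
    profile <- result
    result <- msi_index(profile)
  } else {
    profile <- NULL
  }
  stopifnot(inherits(result, "msiseq_result"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  result$threshold_used <- threshold
  low_counts <- FALSE
  if (!is.null(profile))
    low_counts <- profile$n_ins_total < min_ins ||
      profile$n_del_total < min_del
  result$label <- if (is.na(result$index) || low_counts) {
    "indeterminate"
  } else if (result$index < threshold) "MSI" else "MSS"
  result
}

#' Two-sample Kolmogorov-Smirnov test on indel-length multisets
#'
#' Compares the empirical CDFs of two integer length multisets (e.g. one
#' sample's microsatellite deletion lengths against the pooled lengths of a
#' control cohort) with the two-sample KS statistic and its asymptotic
#' p-value. Lengths are heavily tied integers, so the p-value is
#' approximate, as in common practice. The D statistic is symmetric in its
#' arguments.
#'
#' @param sample_lengths,control_lengths Positive integer vectors.
#' @return A list with `D`, `p` and `defined` (FALSE, with `NA` values,
#'   when either multiset is empty).
#' @export
ks_length_test <- function(sample_lengths, control_lengths) {
  if (length(sample_lengths) == 0L || length(control_lengths) == 0L)
    return(list(D = NA_real_, p = NA_real_, defined = FALSE))
  kt <- suppressWarnings(
    stats::ks.test(sample_lengths, control_lengths, exact = FALSE))
  list(D = unname(kt$statistic), p = min(1, unname(kt$p.value)),
       defined = TRUE)
}

#' Compare a statistic between two groups of samples with a t-test
#'
#' Student's two-sample t-test with pooled variance (the classical form),
#' or a paired t-test for matched designs such as tumor/normal pairs.
#' Welch's unequal-variance form is available via `var_equal = FALSE`.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2; equal
#'   lengths when `paired`).
#' @param paired Paired test? Default `FALSE`.
#' @param var_equal Pool variances (Student)? Default `TRUE`.
#' @return A list with `t`, `p` (two-sided) and `degenerate` (TRUE, with
#'   `NA` statistics, when the data are essentially constant).
#' @export
group_compare <- function(values_a, values_b, paired = FALSE,
                          var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  if (paired && length(values_a) != length(values_b))
    stop("paired groups must have equal lengths")
  tt <- tryCatch(
    stats::t.test(values_a, values_b, paired = paired,
                  var.equal = var_equal),
    error = function(e) NULL)
  if (is.null(tt) || !is.finite(tt$statistic))
    return(list(t = NA_real_, p = NA_real_, degenerate = TRUE))
  list(t = unname(tt$statistic), p = unname(tt$p.value), degenerate = FALSE)
}

#' @export
print.msiseq_profile <- function(x, ...) {
  cat(sprintf("Sample %s: %d insertions (%d in microsatellites), %d deletions (%d in microsatellites)\n",
              x$sample_id, x$n_ins_total, x$n_ins_ms,
              x$n_del_total, x$n_del_ms))
  cat(sprintf("  altered microsatellites: %d\n", x$altered_ms))
  invisible(x)
}

#' @export
print.msiseq_result <- function(x, ...) {
  cat(sprintf("Sample %s: PI = %.4f, PD = %.4f, MSI-seq index = %.4f [%s]\n",
              x$sample_id, x$PI, x$PD, x$index, x$label))
  invisible(x)
}
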