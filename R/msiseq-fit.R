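#' Fit MSI-seq scores and classifications for a cohort of samples
#'
#' The central modelling function of the package. Takes per-sample indel
#' profiles (see [compute_profile()]), computes PI, PD and the MSI-seq
#' index (PI/PD) for each sample, classifies samples as MSI or MSS at the
#' decision threshold, and — when a control cohort is supplied — compares
#' each sample's microsatellite deletion and insertion length distributions
#' against the pooled control lengths with a two-sample Kolmogorov-Smirnov
#' test.
#'
#' @param profiles An `msiseq_profile` or a list of them, one per sample.
#' @param controls Optional control cohort: an `msiseq_profile` or list of
#'   them (e.g. normal samples). Their microsatellite indel lengths are
#'   pooled by concatenation for the per-sample KS comparisons.
#' @param threshold Decision threshold on the index; samples below it are
#'   labelled MSI. Default 0.9.
#' @param min_ins,min_del Minimum insertion/deletion totals to issue a
#'   label. Default 20.
#' @param pseudocount Added to each count before forming proportions
#'   (default 0).
#'
#' @return An object of class `msiseq`: a list with
#'   \describe{
#'     \item{results}{`data.frame` with one row per sample: `sample_id`,
#'       `n_ins_total`, `n_ins_ms`, `n_del_total`, `n_del_ms`, `PI`, `PD`,
#'       `index`, `label`, `altered_ms`, `prop_5utr`, `prop_cds`,
#'       `prop_3utr`, `prop_nc`, `ks_del_p`, `ks_ins_p` (KS columns `NA`
#'       without controls).}
#'     \item{profiles, controls}{the input profiles.}
#'     \item{threshold, min_ins, min_del, pseudocount}{the parameters used.}
#'   }
#'   Methods: [print.msiseq()], [summary.msiseq()], [coef.msiseq()],
#'   [plot.msiseq()].
#' @seealso [run_score()] for the file-based pipeline around this fit.
#' @export
msiseq <- function(profiles, controls = NULL, threshold = 0.9,
                   min_ins = 20L, min_del = 20L, pseudocount = 0) {
  if (inherits(profiles, "msiseq_profile")) profiles <- list(profiles)
  if (inherits(controls, "msiseq_profile")) controls <- list(controls)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "msiseq_profile")))
  pool_del <- pool_ins <- NULL
  if (!is.null(controls)) {
    pool_del <- unlist(lapply(controls, `[[`, "del_lengths_ms"))
    pool_ins <- unlist(lapply(controls, `[[`, "ins_lengths_ms"))
  }
  rows <- lapply(profiles, function(p) {
    res <- classify_msi(msi_index(p, pseudocount = pseudocount),
                        threshold = threshold)
    if (p$n_ins_total < min_ins || p$n_del_total < min_del)
      res$label <- "indeterminate"
    ks_del <- ks_ins <- NA_real_
    if (!is.null(controls)) {
      ks_del <- ks_length_test(p$del_lengths_ms, pool_del)$p
      ks_ins <- ks_length_test(p$ins_lengths_ms, pool_ins)$p
    }
    rp <- p$region_props
    data.frame(sample_id = p$sample_id,
               n_ins_total = p$n_ins_total, n_ins_ms = p$n_ins_ms,
               n_del_total = p$n_del_total, n_del_ms = p$n_del_ms,
               PI = res$PI, PD = res$PD, index = res$index,
               label = res$label, altered_ms = p$altered_ms,
               prop_5utr = unname(rp["five_prime_utr"]),
               prop_cds = unname(rp["cds"]),
               prop_3utr = unname(rp["three_prime_utr"]),
               prop_nc = unname(rp["ncRNA"]),
               ks_del_p = ks_del, ks_ins_p = ks_ins,
               stringsAsFactors = FALSE)
  })
  structure(list(results = do.call(rbind, rows),
                 profiles = profiles, controls = controls,
                 threshold = threshold, min_ins = min_ins,
                 min_del = min_del, pseudocount = pseudocount,
                 call = match.call()),
            class = "msiseq")
}

#' @describeIn msiseq Compact per-sample display.
#' @param x,object An `msiseq` fit.
#' @param ... Unused.
#' @export
print.msiseq <- function(x, ...) {
  cat("MSI-seq fit:", nrow(x$results), "sample(s), threshold",
      x$threshold, "\n\n")
  df <- x$results[, c("sample_id", "PI", "PD", "index", "label")]
  df$PI <- round(df$PI, 4); df$PD <- round(df$PD, 4)
  df$index <- round(df$index, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @describeIn msiseq Label tally and index summary.
#' @export
summary.msiseq <- function(object, ...) {
  r <- object$results
  s <- list(n = nrow(r),
            labels = table(factor(r$label,
                                  levels = c("MSI", "MSS",
                                             "indeterminate"))),
            index = summary(r$index),
            threshold = object$threshold,
            has_controls = !is.null(object$controls))
  class(s) <- "summary.msiseq"
  s
}

#' @export
print.summary.msiseq <- function(x, ...) {
  cat("MSI-seq cohort summary (", x$n, " samples, threshold ",
      x$threshold, ")\n", sep = "")
  cat("Labels:\n"); print(x$labels)
  cat("Index distribution:\n"); print(x$index)
  if (x$has_controls) cat("KS comparisons against pooled controls included\n")
  invisible(x)
}

#' @describeIn msiseq Named vector of per-sample MSI-seq indices.
#' @export
coef.msiseq <- function(object, ...) {
  stats::setNames(object$results$index, object$results$sample_id)
}

#' @describeIn msiseq Strip chart of indices by label with the decision
#'   threshold.
#' @export
plot.msiseq <- function(x, ...) {
  r <- x$results
  grp <- factor(r$label, levels = c("MSI", "MSS", "indeterminate"))
  graphics::stripchart(r$index ~ grp, vertical = TRUE, method = "jitter",
                       pch = 19, ylab = "MSI-seq index (PI/PD)",
                       xlab = "", ...)
  graphics::abline(h = x$threshold, lty = 2, col = "red3")
  invisible(x)
}

#' Write an MSI-seq cohort report
#'
#' Writes the per-sample results table as TSV and a JSON mirror with full
#' numeric precision plus the fit parameters. Reading the TSV back gives
#' the same numbers the fit holds.
#'
#' @param fit An `msiseq` fit.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the written files.
#' @export
write_msiseq_report <- function(fit, dir) {
  stopifnot(inherits(fit, "msiseq"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "report.tsv")
  json <- file.path(dir, "report.json")
  utils::write.table(fit$results, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(parameters = list(threshold = fit$threshold,
                           min_ins = fit$min_ins, min_del = fit$min_del,
                           pseudocount = fit$pseudocount),
         results = fit$results),
    json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(tsv = tsv, json = json))
}

#' Read back a cohort report TSV
#' @param path Path to a `report.tsv` written by [write_msiseq_report()].
#' @return The results `data.frame`.
#' @export
read_msiseq_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
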