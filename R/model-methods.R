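# S3 methods for the fitted model object.

#' @export
print.ekmer_model <- function(x, ...) {
  tot <- sum(x$counts)
  freq <- if (tot > 0) colSums(x$counts) / tot else rep(0, 4)
  cat("Empirical context-dependent error model (ekmer_model)\n")
  cat(sprintf("  flank width: %d (%d-base-wide single-run contexts), run-length cap: %d\n",
              x$flank_width, 2 * x$flank_width + 1, x$hp_cap))
  cat(sprintf("  contexts observed: %d;  classified spans: %.0f\n",
              nrow(x$counts), tot))
  cat(sprintf("  event frequencies: match %.4f  ins %.4f  del %.4f  sub %.4f\n",
              freq[1], freq[2], freq[3], freq[4]))
  cat(sprintf("  feature schema: %s;  bin capacity: %d (%d records held)\n",
              x$schema, x$bin_cap, nrow(x$samples)))
  cat(sprintf("  fragment lengths: n=%d, median %.0f bp;  passes: %s\n",
              length(x$fragment_lengths),
              stats::median(x$fragment_lengths),
              paste0("median ", stats::median(x$pass_counts))))
  invisible(x)
}

#' Global event frequencies of a fitted model
#'
#' @param object An `ekmer_model`.
#' @param ... Unused.
#' @return Named numeric vector: overall match/insertion/deletion/
#'   substitution frequencies across all contexts.
#' @export
coef.ekmer_model <- function(object, ...) {
  tot <- sum(object$counts)
  stats::setNames(colSums(object$counts) / tot, tolower(EVENT_TYPES))
}

#' Summarize a fitted empirical error model
#'
#' @param object An `ekmer_model`.
#' @param min_obs Observation floor for per-context accuracy statistics.
#' @param ... Unused.
#' @return An object of class `summary.ekmer_model`.
#' @export
summary.ekmer_model <- function(object, min_obs = 50L, ...) {
  h <- context_accuracy(object, min_obs = min_obs)
  out <- list(
    flank_width = object$flank_width,
    hp_cap = object$hp_cap,
    schema = object$schema,
    n_contexts = nrow(object$counts),
    n_spans = sum(object$counts),
    event_frequencies = coef(object),
    accuracy = h,
    fraction_below_80 = if (length(h$accuracy)) mean(h$accuracy < 80) else NA_real_,
    fragment_length_summary = summary(object$fragment_lengths),
    pass_count_table = table(object$pass_counts),
    metadata = object$metadata)
  class(out) <- "summary.ekmer_model"
  out
}

#' @export
print.summary.ekmer_model <- function(x, ...) {
  cat("Empirical context-dependent error model\n")
  cat(sprintf("  %d contexts over %.0f classified spans (flank %d, cap %d, schema %s)\n",
              x$n_contexts, x$n_spans, x$flank_width, x$hp_cap, x$schema))
  f <- x$event_frequencies
  cat(sprintf("  global event frequencies: match %.4f, ins %.4f, del %.4f, sub %.4f\n",
              f[1], f[2], f[3], f[4]))
  if (length(x$accuracy$accuracy)) {
    cat(sprintf("  per-context accuracy (>= %d obs): median %.1f%%, IQR %.1f-%.1f%%\n",
                x$accuracy$min_obs, stats::median(x$accuracy$accuracy),
                stats::quantile(x$accuracy$accuracy, 0.25),
                stats::quantile(x$accuracy$accuracy, 0.75)))
    cat(sprintf("  fraction of contexts below 80%% accuracy: %.3f\n",
                x$fraction_below_80))
  }
  cat("  fragment lengths (bp):\n")
  print(x$fragment_length_summary)
  cat("  pass counts:\n")
  print(x$pass_count_table)
  invisible(x)
}

#' Plot the per-context accuracy histogram of a model
#'
#' Bars give the number of sequencing contexts whose accuracy falls in
#' each 1% bin — the standard visualization of error non-uniformity. A
#' context-independent profile shows a single spike at the global
#' accuracy.
#'
#' @param x An `ekmer_model`.
#' @param min_obs Observation floor per context.
#' @param ... Passed to [graphics::barplot()].
#' @return The `accuracy_histogram`, invisibly.
#' @export
plot.ekmer_model <- function(x, min_obs = 50L, ...) {
  h <- context_accuracy(x, min_obs = min_obs)
  graphics::barplot(h$counts, names.arg = NULL, space = 0, border = NA,
                    xlab = "context accuracy (%)",
                    ylab = "number of contexts",
                    main = "Per-context accuracy", ...)
  graphics::axis(1, at = seq(0, 100, 20), labels = seq(0, 100, 20))
  invisible(h)
}

#' Simulate reads from a fitted error model
#'
#' Method for [stats::simulate()]: draws `nsim` multi-pass reads from
#' `object` against `targets`. See [simulate_reads()] for the full set of
#' controls (coverage-based stopping, custom rates, position scaling,
#' distribution overrides).
#'
#' @param object An `ekmer_model`.
#' @param nsim Number of reads (ignored when `coverage` is given).
#' @param seed Integer seed for reproducibility.
#' @param targets Target sequences (named character vector, `DNAStringSet`,
#'   or FASTA path).
#' @param ... Passed on to [simulate_reads()].
#' @return An `ekmer_sim` object.
#' @export
simulate.ekmer_model <- function(object, nsim = 1, seed = NULL, targets, ...) {
  dots <- list(...)
  if (!is.null(dots$coverage)) nsim <- NULL
  do.call(simulate_reads,
          c(list(model = object, targets = targets, nreads = nsim,
                 seed = seed), dots))
}
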