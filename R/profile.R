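# Error-profile analytics derived from a fitted model: the per-context
# accuracy histogram (how non-uniform the error landscape is across
# sequencing contexts) and homopolymer length-transition distributions
# (how often a run of true length L is read as length k).

#' Per-context accuracy histogram
#'
#' Accuracy of a context is its MATCH fraction (match events / total
#' events). Contexts with fewer than `min_obs` observations are excluded
#' (and counted); qualifying contexts are binned at 1% resolution over
#' \[0, 100\]. A context-independent error profile would put all mass in a
#' single bin at the global accuracy; real single-molecule chemistries
#' spread far wider.
#'
#' @param model An `ekmer_model`.
#' @param min_obs Minimum observations for a context to qualify
#'   (default 50).
#' @param level `"event"` (default) scores a context by its MATCH event
#'   fraction; `"base"` scores it by emitted-versus-true base identity
#'   aggregated over its emission bins.
#' @return An object of class `accuracy_histogram`: list with `breaks`
#'   (0..100), `counts` (length 100), `accuracy` (named per-context
#'   percentages), `n_excluded`, `min_obs`.
#' @export
context_accuracy <- function(model, min_obs = 50L, level = c("event", "base")) {
  stopifnot(inherits(model, "ekmer_model"))
  level <- match.arg(level)
  totals <- rowSums(model$counts)
  qual <- totals >= min_obs
  acc <- if (level == "event") {
    100 * model$counts[qual, "MATCH"] / totals[qual]
  } else {
    keys <- rownames(model$counts)[qual]
    vapply(keys, function(k) 100 * base_level_accuracy(model, k), numeric(1))
  }
  counts <- tabulate(pmin(floor(acc), 99) + 1L, 100L)
  structure(list(breaks = 0:100, counts = counts, accuracy = acc,
                 n_excluded = sum(!qual), min_obs = as.integer(min_obs)),
            class = "accuracy_histogram")
}

# edit-style base-level accuracy of one context from its emission bins:
# matching emitted bases / max(emitted, true) length, weighted by event
# frequency (bin records weighted up to their exact event counts).
base_level_accuracy <- function(model, key) {
  s <- model$samples[model$samples$key == key, , drop = FALSE]
  if (nrow(s) == 0L) return(NA_real_)
  kk <- decode_ekmer(key)
  L <- kk$hp_length
  freq <- model$counts[key, ] / sum(model$counts[key, ])
  num <- 0; den <- 0
  for (evn in EVENT_TYPES) {
    e <- s$emitted[s$event == evn]
    if (!length(e)) next
    nb <- nchar(e)
    match_b <- vapply(e, function(x) {
      ch <- str_chars(x)
      sum(ch == kk$hp_base)
    }, numeric(1), USE.NAMES = FALSE)
    match_b <- pmin(match_b, L)
    w <- freq[evn] / length(e)
    num <- num + w * sum(match_b)
    den <- den + w * sum(pmax(nb, L))
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' @export
print.accuracy_histogram <- function(x, ...) {
  n <- sum(x$counts)
  cat(sprintf("<accuracy_histogram> %d contexts (min_obs %d, %d excluded)\n",
              n, x$min_obs, x$n_excluded))
  if (n > 0)
    cat(sprintf("  accuracy: median %.1f%%, range %.1f%%-%.1f%%\n",
                stats::median(x$accuracy), min(x$accuracy), max(x$accuracy)))
  invisible(x)
}

#' Homopolymer length-transition distribution
#'
#' For a run base and true length, the distribution of emitted run lengths
#' pooled over all flanking contexts, combining exact event frequencies
#' with the emitted lengths observed in each emission bin. Under pure
#' per-base deletion at rate d this distribution is Binomial(L, 1 - d); a
#' fitted model deviates from that analytic form exactly where the
#' chemistry has context- and length-dependent bias.
#'
#' @param model An `ekmer_model`.
#' @param hp_base Run base.
#' @param true_length True run length (bucketed by the model's `hp_cap`).
#' @return Named numeric vector: probability of each emitted length
#'   `0..max`, summing to 1.
#' @export
homopolymer_transition <- function(model, hp_base, true_length) {
  stopifnot(inherits(model, "ekmer_model"))
  hp_base <- toupper(hp_base)
  true_length <- as.integer(true_length)
  comp <- parse_keys(rownames(model$counts), model$hp_cap)
  sel <- comp$base == hp_base & comp$len == true_length
  if (!any(sel))
    stop("no observations for homopolymer ", hp_base, " x ", true_length)
  keys <- rownames(model$counts)[sel]
  s <- model$samples[model$samples$key %in% keys, , drop = FALSE]
  # weight each bin record by exact_count(key, event) / bin_size(key, event)
  g <- paste(s$key, s$event, sep = "\1")
  bin_sizes <- table(g)
  exact <- model$counts[cbind(s$key, s$event)]
  w <- exact / as.numeric(bin_sizes[g])
  k <- nchar(s$emitted)
  agg <- tapply(w, k, sum)
  lens <- as.integer(names(agg))
  out <- numeric(max(lens) + 1L)
  out[lens + 1L] <- agg
  out <- out / sum(out)
  names(out) <- 0:(length(out) - 1L)
  out
}

#' Fraction of contexts below an accuracy threshold
#'
#' The mass of the per-context accuracy histogram strictly below
#' `threshold` percent — the headline summary of error non-uniformity
#' (chemistry upgrades shrink it).
#'
#' @param model An `ekmer_model`.
#' @param threshold Accuracy threshold in percent.
#' @param min_obs Minimum observations per qualifying context.
#' @return Fraction in \[0, 1\].
#' @export
fraction_below <- function(model, threshold, min_obs = 50L) {
  h <- context_accuracy(model, min_obs = min_obs)
  if (length(h$accuracy) == 0L) stop("no qualifying contexts")
  mean(h$accuracy < threshold)
}
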