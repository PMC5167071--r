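# Independent oracles and small utilities shared across the suite. These
# deliberately avoid the package's own vectorized code paths: the run-length
# oracle is a naive character loop, and goodness-of-fit uses stats::chisq.test
# with low-expectation pooling.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# naive run-length encoder: one character at a time
naive_rle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  runs <- list()
  cur <- ch[1]; len <- 1L
  for (c in ch[-1]) {
    if (c == cur) len <- len + 1L
    else { runs[[length(runs) + 1L]] <- list(base = cur, len = len)
           cur <- c; len <- 1L }
  }
  runs[[length(runs) + 1L]] <- list(base = cur, len = len)
  data.frame(base = vapply(runs, `[[`, "", "base"),
             len = vapply(runs, `[[`, 1L, "len"))
}

# chi-squared goodness of fit with pooling of low-expectation cells
# (expected < 5 merged into their neighbor), returns the p-value
chisq_gof <- function(observed, probs, min_expected = 5) {
  stopifnot(length(observed) == length(probs))
  n <- sum(observed)
  exp_ct <- n * probs
  # pool from the left (smallest-expectation tail first)
  ord <- order(exp_ct)
  obs <- observed; expv <- exp_ct
  while (length(expv) > 2 && min(expv) < min_expected) {
    i <- which.min(expv)
    j <- if (i == 1) 2 else if (i == length(expv)) i - 1 else
      if (expv[i - 1] < expv[i + 1]) i - 1 else i + 1
    obs[j] <- obs[j] + obs[i]; expv[j] <- expv[j] + expv[i]
    obs <- obs[-i]; expv <- expv[-i]
  }
  stat <- sum((obs - expv)^2 / expv)
  stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
}

# total-variation distance between two empirical distributions given as
# count tables over a shared support
tv_distance <- function(x, y) {
  sup <- sort(unique(c(as.integer(names(x)), as.integer(names(y)))))
  px <- rep(0, length(sup)); names(px) <- sup
  py <- px
  px[names(x)] <- x / sum(x)
  py[names(y)] <- y / sum(y)
  sum(abs(px - py)) / 2
}

# an error-free model learned from perfect reads over a reference
perfect_model <- function(ref, n_reads = 30, flank_width = 2,
                          fragment_lengths = 400L, seed = 99) {
  fx <- make_corrupted_reads(ref, fixture_spec(
    n_reads = n_reads, seed = seed, mode = "per_step",
    rates = c(ins = 0, del = 0, sub = 0),
    fragment_lengths = fragment_lengths, flank_width = flank_width))
  learn_error_model(fx$alignments, fx$reference, flank_width = flank_width)
}
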