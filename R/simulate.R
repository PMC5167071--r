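# Read simulation from a fitted empirical model.
#
# A molecule is simulated by drawing a fragment (length from the model's
# empirical fragment distribution, start uniform, contigs weighted by
# length), a pass count N_p, and an initial strand; each pass walks the
# fragment's homopolymer contexts in order, draws an event per context from
# the model's context-specific frequencies (or user-supplied custom rates),
# and resamples basecalls + per-base features from the matching
# (context, event) bin. Passes alternate strand and are concatenated with
# the hairpin adapter to form the full read.
#
# RNG draw order per molecule (stable across runs): fragment length ->
# contig -> start -> N_p -> initial strand -> per pass: per-step event
# uniforms, then per-step bin-record uniforms.

# ---- lookup tables ---------------------------------------------------------

# Precomputed simulation tables for a model: per-key event frequencies,
# grouped sample-bin offsets, decoded key components, and caches for
# sparse-context backoff.
sim_tables <- function(model) {
  counts <- model$counts
  keys <- rownames(counts)
  freq <- model_frequencies(model)
  s <- model$samples
  grp <- paste(s$key, s$event, sep = "\1")
  r <- rle(grp)
  first <- cumsum(r$lengths) - r$lengths + 1L
  grp_first <- stats::setNames(first, r$values)
  grp_size <- stats::setNames(r$lengths, r$values)
  # decoded key components (vectorized parse of the canonical encoding)
  comp <- parse_keys(keys, model$hp_cap)
  med_qv <- local({
    qs <- s$qv[s$qv != ""]
    if (!length(qs)) 30L
    else as.integer(stats::median(phred_values(
      paste(utils::head(qs, 2000L), collapse = ""))))
  })
  list(model = model, keys = keys, freq = freq, samples = s,
       grp_first = grp_first, grp_size = grp_size, comp = comp,
       med_qv = med_qv, cache = new.env(parent = emptyenv()))
}

# decode many keys at once into components; capped buckets get length cap+1
parse_keys <- function(keys, cap) {
  out <- data.frame(key = keys, base = NA_character_, len = NA_integer_,
                    left = NA_character_, right = NA_character_,
                    stringsAsFactors = FALSE)
  has_run <- grepl("^", keys, fixed = TRUE)
  if (any(has_run)) {
    m <- regmatches(keys[has_run],
                    regexec("^([ACGTN.]*)([ACGTN])\\^(>?)([0-9]+)([ACGTN.]*)$",
                            keys[has_run]))
    out$left[has_run] <- vapply(m, `[`, "", 2L)
    out$base[has_run] <- vapply(m, `[`, "", 3L)
    ln <- as.integer(vapply(m, `[`, "", 5L))
    gt <- vapply(m, `[`, "", 4L) == ">"
    out$len[has_run] <- ifelse(gt, ln + 1L, ln)
    out$right[has_run] <- vapply(m, `[`, "", 6L)
  }
  if (any(!has_run)) {
    k <- keys[!has_run]
    f <- (nchar(k) - 1L) %/% 2L
    out$base[!has_run] <- substr(k, f + 1L, f + 1L)
    out$len[!has_run] <- 1L
    out$left[!has_run] <- substr(k, 1L, f)
    out$right[!has_run] <- substring(k, f + 2L)
  }
  out$total <- NA_real_
  out
}

# ---- backoff for unseen contexts ------------------------------------------

# Resolve a context key that the model never observed. Chain:
#   (1) same base and flanks, nearest populated run-length bucket;
#   (2) same base and bucket, flanks shrunk symmetrically (best-populated);
#   (3) pooled per-run-length event table (best-populated emission donor).
# Returns list(freq = length-4 event probabilities, donor = model key used
# for emission bins, or NA if even level 3 found nothing).
resolve_missing <- function(tab, key) {
  cached <- tab$cache[[key]]
  if (!is.null(cached)) return(cached)
  counts <- tab$model$counts
  totals <- rowSums(counts)
  cap <- tab$model$hp_cap
  kk <- tryCatch(decode_ekmer(key), error = function(e) NULL)
  res <- NULL
  if (!is.null(kk)) {
    b <- kk$hp_base
    len <- if (kk$capped) kk$hp_length + 1L else kk$hp_length
    comp <- tab$comp
    # level 1: same flanks & base, nearest length bucket
    cand <- which(comp$base == b & comp$left == kk$left_flank &
                    comp$right == kk$right_flank)
    if (length(cand)) {
      pick <- cand[order(abs(comp$len[cand] - len), comp$len[cand])][1L]
      res <- list(freq = tab$freq[pick, ], donor = tab$keys[pick])
    }
    # level 2: shrink flank width symmetrically
    if (is.null(res)) {
      f <- nchar(kk$left_flank)
      for (w in seq(f - 1L, 0L)) {
        ls <- substring(kk$left_flank, f - w + 1L)
        rs <- substr(kk$right_flank, 1L, w)
        cand <- which(comp$base == b & comp$len == len &
                        substring(comp$left, nchar(comp$left) - w + 1L) == ls &
                        substr(comp$right, 1L, w) == rs)
        if (w == 0L) cand <- which(comp$base == b & comp$len == len)
        if (length(cand)) {
          pick <- cand[which.max(totals[cand])]
          res <- list(freq = tab$freq[pick, ], donor = tab$keys[pick])
          break
        }
      }
    }
    # level 3: pooled per-run-length table, any base
    if (is.null(res)) {
      cand <- which(tab$comp$len == len)
      if (length(cand)) {
        pooled <- colSums(counts[cand, , drop = FALSE])
        res <- list(freq = pooled / sum(pooled),
                    donor = tab$keys[cand[which.max(totals[cand])]])
      }
    }
  }
  if (is.null(res)) {
    # last resort: global table over every context
    pooled <- colSums(counts)
    res <- list(freq = pooled / sum(pooled),
                donor = tab$keys[which.max(totals)])
  }
  tab$cache[[key]] <- res
  res
}

# Find a model key able to donate an emission record for `event`, given a
# preferred donor that turned out to lack that bin. NA when nothing exists.
donor_with_event <- function(tab, donor, event) {
  ck <- paste0("ev\1", donor, "\1", event)
  cached <- tab$cache[[ck]]
  if (!is.null(cached)) return(cached)
  counts <- tab$model$counts
  evc <- counts[, event]
  res <- NA_character_
  d <- tab$comp[match(donor, tab$keys), ]
  cand <- which(tab$comp$base == d$base & tab$comp$len == d$len & evc > 0L)
  if (!length(cand)) cand <- which(tab$comp$len == d$len & evc > 0L)
  if (!length(cand)) cand <- which(evc > 0L)
  if (length(cand)) res <- tab$keys[cand[which.max(evc[cand])]]
  tab$cache[[ck]] <- res
  res
}

# Synthetic minimal emission when no bin anywhere holds the event.
synthesize_record <- function(event, base, len, med_qv) {
  other <- setdiff(DNA_BASES, base)[1L]
  emitted <- switch(event,
    MATCH = strrep(base, len),
    INSERTION = paste0(strrep(base, len), other),
    DELETION = strrep(base, max(len - 1L, 0L)),
    SUBSTITUTION = if (len >= 1L)
      paste0(strrep(base, len - 1L), other) else "")
  list(emitted = emitted, qv = phred_string(rep(med_qv, nchar(emitted))))
}

# stretch/trim a per-base feature string to n characters
fit_feature <- function(s, n) {
  m <- nchar(s)
  if (m == n) return(s)
  if (m > n) return(substr(s, 1L, n))
  filler <- if (m > 0L) substr(s, m, m) else "?"
  paste0(s, strrep(filler, n - m))
}

# Translate a donor emission onto the truth run: donor-run-base characters
# become the truth base, and the net length offset relative to the donor
# bucket is preserved relative to the true (uncapped) run length.
translate_emission <- function(emitted, donor_base, donor_len, base, len) {
  tr <- if (donor_base != base) chartr(donor_base, base, emitted) else emitted
  delta <- nchar(emitted) - donor_len
  target <- max(len + delta, 0L)
  m <- nchar(tr)
  if (m == target) return(tr)
  if (m < target) return(paste0(strrep(base, target - m), tr))
  # remove surplus copies of the truth base from the left
  ch <- str_chars(tr)
  drop <- which(ch == base)
  ndrop <- min(length(drop), m - target)
  if (ndrop > 0L) ch <- ch[-drop[seq_len(ndrop)]]
  # if still long (pathological), truncate
  if (length(ch) > target) ch <- ch[seq_len(target)]
  paste(ch, collapse = "")
}

# ---- core per-pass simulation ---------------------------------------------

#' Simulate one pass over a truth sequence
#'
#' Walks the homopolymer contexts of `truth` in order, draws one event per
#' context from the model's context-specific frequencies (or `custom_rates`),
#' and resamples basecalls and per-base features from the matching
#' (context, event) bin. Contexts the model never observed are resolved by
#' backoff: nearest populated run-length bucket for the same flanks, then
#' symmetric flank shrinking, then a pooled per-run-length table. Runs of
#' `N` are emitted verbatim with quality 0 and excluded from event
#' accounting. Uses the current RNG stream; seed upstream for
#' reproducibility.
#'
#' @param truth The (already strand-oriented) truth sequence for this pass.
#' @param model An `ekmer_model`.
#' @param custom_rates Optional `c(ins, del, sub)` probabilities replacing
#'   the per-context frequencies uniformly (match takes the complement).
#' @param position_scaling Optional function mapping relative position in
#'   `[0, 1]` to a non-negative multiplier on the three error-event
#'   probabilities (renormalized via the match complement, error sum
#'   clamped at 0.99).
#' @param tables Precomputed [sim_tables()] (computed on the fly if NULL).
#' @return List with `basecalls`, `features` (named list of per-base
#'   feature strings; `qv` is Phred+33), `event_log` (data frame `key`,
#'   `event`, `is_n`), and `cigar` (alignment of the basecalls to `truth`).
#' @export
simulate_pass <- function(truth, model, custom_rates = NULL,
                          position_scaling = NULL, tables = NULL) {
  if (is.null(tables)) tables <- sim_tables(model)
  steps <- tokenize(truth, model$flank_width)
  n <- nrow(steps)
  keys <- step_keys(steps, cap = model$hp_cap)
  is_n <- steps$hp_base == "N"
  L <- steps$hp_length
  base <- steps$hp_base

  row <- match(keys, tables$keys)
  miss <- which(is.na(row) & !is_n)
  probs <- matrix(0, n, 4L)
  seen <- !is.na(row)
  if (any(seen)) probs[seen, ] <- tables$freq[row[seen], , drop = FALSE]
  donors <- keys                     # emission donor per step
  for (i in miss) {
    res <- resolve_missing(tables, keys[i])
    probs[i, ] <- res$freq
    donors[i] <- res$donor
  }
  if (!is.null(custom_rates)) {
    cr <- unname(unlist(custom_rates))
    if (length(cr) != 3L || any(cr < 0) || sum(cr) >= 1)
      stop("custom_rates must be three non-negative values (ins, del, sub) summing to < 1")
    probs <- matrix(rep(c(1 - sum(cr), cr), each = n), n, 4L)
  }
  if (!is.null(position_scaling)) {
    rel <- (steps$ref_start + L / 2) / nchar(truth)
    mult <- vapply(rel, position_scaling, numeric(1))
    if (any(mult < 0)) stop("position_scaling must return non-negative multipliers")
    err <- probs[, 2:4, drop = FALSE] * mult
    tot <- rowSums(err)
    over <- tot > 0.99
    if (any(over)) err[over, ] <- err[over, ] * (0.99 / tot[over])
    probs <- cbind(1 - rowSums(err), err)
  }

  # per-step event draw (single uniform per step, in step order)
  u <- stats::runif(n)
  c1 <- probs[, 2L]
  c2 <- c1 + probs[, 3L]
  c3 <- c2 + probs[, 4L]
  ev <- ifelse(u < c1, 2L, ifelse(u < c2, 3L, ifelse(u < c3, 4L, 1L)))
  ev[is_n] <- 1L

  # per-step bin record draw
  u2 <- stats::runif(n)
  ev_name <- EVENT_TYPES[ev]
  grp <- paste(donors, ev_name, sep = "\1")
  size <- tables$grp_size[grp]
  first <- tables$grp_first[grp]
  feat_cols <- setdiff(names(tables$samples),
                       c("key", "event", "emitted"))
  emitted <- character(n)
  feats <- stats::setNames(rep(list(character(n)), length(feat_cols)),
                           feat_cols)
  srows <- first + floor(u2 * size)
  ok <- !is.na(srows) & !is_n
  if (any(ok)) {
    emitted[ok] <- tables$samples$emitted[srows[ok]]
    for (fc in feat_cols) feats[[fc]][ok] <- tables$samples[[fc]][srows[ok]]
  }
  # steps whose donor lacks the drawn event bin
  for (i in which(!ok & !is_n)) {
    d2 <- donor_with_event(tables, donors[i], ev_name[i])
    if (!is.na(d2)) {
      g2 <- paste(d2, ev_name[i], sep = "\1")
      j <- tables$grp_first[g2] + floor(u2[i] * tables$grp_size[g2])
      donors[i] <- d2
      emitted[i] <- tables$samples$emitted[j]
      for (fc in feat_cols) feats[[fc]][i] <- tables$samples[[fc]][j]
    } else {
      syn <- synthesize_record(ev_name[i], base[i], L[i], tables$med_qv)
      donors[i] <- NA_character_
      emitted[i] <- syn$emitted
      if ("qv" %in% feat_cols) feats$qv[i] <- syn$qv
      for (fc in setdiff(feat_cols, "qv"))
        feats[[fc]][i] <- fit_feature("", nchar(syn$emitted))
    }
  }
  # translate emissions where the donor differs from the truth context
  dcomp_idx <- match(donors, tables$keys)
  need_fix <- which(!is_n & (is.na(dcomp_idx) |
    tables$comp$base[dcomp_idx] != base |
    tables$comp$len[dcomp_idx] != L))
  # exact-key steps whose raw run length equals the bucket need no work;
  # capped steps (raw L > cap) are caught because comp$len == cap+1 != L
  for (i in need_fix) {
    if (is.na(donors[i])) next       # synthetic records already truth-based
    di <- dcomp_idx[i]
    emitted[i] <- translate_emission(emitted[i], tables$comp$base[di],
                                     tables$comp$len[di], base[i], L[i])
    for (fc in feat_cols) {
      if (fc %in% c(PHRED_FEATURES, TAG_FEATURES))
        feats[[fc]][i] <- fit_feature(feats[[fc]][i], nchar(emitted[i]))
      else {  # ip (comma-separated)
        v <- strsplit(feats[[fc]][i], ",", fixed = TRUE)[[1]]
        m <- nchar(emitted[i])
        if (length(v) >= m) v <- v[seq_len(m)]
        else v <- c(v, rep(if (length(v)) v[length(v)] else "0",
                           m - length(v)))
        feats[[fc]][i] <- paste(v, collapse = ",")
      }
    }
  }
  if (any(is_n)) {
    emitted[is_n] <- strrep("N", L[is_n])
    if ("qv" %in% feat_cols)
      feats$qv[is_n] <- vapply(L[is_n], function(l)
        phred_string(rep(0L, l)), "")
    for (fc in setdiff(feat_cols, "qv"))
      feats[[fc]][is_n] <- vapply(which(is_n), function(i)
        fit_feature("", L[i]), "")
  }

  m_len <- nchar(emitted)
  cig_op <- ifelse(m_len == L, paste0(L, "M"),
                   ifelse(m_len > L, paste0(L, "M", m_len - L, "I"),
                          ifelse(m_len > 0L, paste0(m_len, "M", L - m_len, "D"),
                                 paste0(L, "D"))))
  cigar <- collapse_cigar_str(cig_op)
  features <- list()
  for (fc in feat_cols) {
    features[[fc]] <- if (fc == "ip")
      paste(feats[[fc]][nzchar(feats[[fc]])], collapse = ",")
    else paste(feats[[fc]], collapse = "")
  }
  ev_out <- ev_name
  ev_out[is_n] <- NA_character_
  list(basecalls = paste(emitted, collapse = ""),
       features = features,
       event_log = data.frame(key = keys, event = ev_out, is_n = is_n,
                              stringsAsFactors = FALSE),
       cigar = cigar)
}

# merge adjacent identical ops in a vector of per-step cigar fragments
collapse_cigar_str <- function(frags) {
  s <- paste(frags, collapse = "")
  m <- gregexpr("[0-9]+[MID]", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  n <- nchar(toks)
  lens <- as.integer(substr(toks, 1L, n - 1L))
  ops <- substr(toks, n, n)
  collapse_cigar(lens, ops)
}

# ---- fragment drawing ------------------------------------------------------

#' Draw simulation fragments from target sequences
#'
#' Fragment lengths are sampled from the model's empirical fragment-length
#' distribution (or an override); the contig is chosen with probability
#' proportional to its length, and the start is uniform over positions
#' where the fragment fits. A contig shorter than the drawn length yields
#' the whole contig, flagged as truncated. Uses the current RNG stream.
#'
#' @param targets Named character vector, `DNAStringSet`, or FASTA path.
#' @param model An `ekmer_model` (ignored when `fragment_lengths` given).
#' @param n Number of fragments.
#' @param fragment_lengths Optional integer vector to sample lengths from
#'   (uniformly), overriding the model's distribution.
#' @param truncate When `TRUE` (default) a contig shorter than the drawn
#'   length yields the whole contig flagged as truncated, keeping draw
#'   counts unbiased; when `FALSE` such draws are retried against the
#'   contigs that fit (error if none does).
#' @return Data frame: `contig`, `start`, `end` (0-based half-open),
#'   `seq`, `truncated`.
#' @export
draw_fragment <- function(targets, model = NULL, n = 1L,
                          fragment_lengths = NULL, truncate = TRUE) {
  refs <- as_ref_set(targets)
  if (length(refs) == 0L) stop("no target sequences")
  pool <- if (!is.null(fragment_lengths)) as.integer(fragment_lengths)
  else model$fragment_lengths
  if (is.null(pool) || length(pool) == 0L)
    stop("empty fragment-length distribution")
  clens <- nchar(refs)
  if (!truncate && all(clens < min(pool)))
    stop("all contigs are shorter than the minimum drawable fragment length")
  len <- pool[1L + floor(stats::runif(n) * length(pool))]
  ci <- 1L + findInterval(stats::runif(n) * sum(clens), cumsum(clens),
                          left.open = TRUE)
  ci <- pmin(ci, length(refs))
  if (!truncate) {
    bad <- which(len > clens[ci])
    while (length(bad)) {
      len[bad] <- pool[1L + floor(stats::runif(length(bad)) * length(pool))]
      ci[bad] <- pmin(1L + findInterval(stats::runif(length(bad)) * sum(clens),
                                        cumsum(clens), left.open = TRUE),
                      length(refs))
      bad <- bad[len[bad] > clens[ci[bad]]]
    }
  }
  cl <- clens[ci]
  trunc <- len > cl
  eff <- pmin(len, cl)
  start <- as.integer(floor(stats::runif(n) * (cl - eff + 1L)))
  data.frame(contig = names(refs)[ci], start = start,
             end = start + as.integer(eff),
             seq = substring(refs[ci], start + 1L, start + eff),
             truncated = trunc, stringsAsFactors = FALSE)
}

# ---- molecule assembly -----------------------------------------------------

#' Assemble one multi-pass simulated read
#'
#' Draws the pass count from the model's pass-count distribution (or an
#' override), flips a fair coin for the strand of the first pass, simulates
#' each pass on alternating strands, and concatenates passes with the
#' adapter sequence in between (adapters separate consecutive passes and do
#' not cap the read ends). Uses the current RNG stream.
#'
#' @param fragment One row of [draw_fragment()].
#' @param model An `ekmer_model`.
#' @param molecule Molecule ordinal used in the read name
#'   (`sim/<molecule>/<qStart>_<qEnd>`).
#' @param pass_counts Optional integer vector overriding the model's
#'   pass-count distribution.
#' @param adapter Optional adapter override (default: the model's).
#' @param custom_rates,position_scaling,tables Passed to [simulate_pass()].
#' @return An object of class `simulated_read`: list with `id`, `seq`,
#'   `features`, `passes` (data frame `start`, `end`, `strand`, `cigar`),
#'   `adapters` (data frame `start`, `end`), `truth` (list `contig`,
#'   `start`, `end`, `strand`, `truncated`), and `event_log` (per-pass list
#'   of data frames).
#' @export
assemble_read <- function(fragment, model, molecule = 1L,
                          pass_counts = NULL, adapter = NULL,
                          custom_rates = NULL, position_scaling = NULL,
                          tables = NULL) {
  if (is.null(tables)) tables <- sim_tables(model)
  adapter <- toupper(adapter %||% model$adapter)
  pool <- if (!is.null(pass_counts)) as.integer(pass_counts)
  else model$pass_counts
  if (is.null(pool) || length(pool) == 0L) pool <- 1L
  np <- pool[1L + floor(stats::runif(1L) * length(pool))]
  strand0 <- if (stats::runif(1L) < 0.5) "+" else "-"
  fwd <- toupper(fragment$seq)
  rev <- revcomp(fwd)
  feat_cols <- setdiff(names(model$samples), c("key", "event", "emitted"))
  seqs <- character(0); quals <- list()
  passes <- data.frame(start = integer(np), end = integer(np),
                       strand = character(np), cigar = character(np),
                       stringsAsFactors = FALSE)
  adapters <- data.frame(start = integer(0), end = integer(0))
  event_log <- vector("list", np)
  feature_parts <- stats::setNames(rep(list(character(0)), length(feat_cols)),
                                   feat_cols)
  cursor <- 0L
  out_seq <- character(0)
  ad_qv <- phred_string(rep(tables$med_qv, nchar(adapter)))
  for (p in seq_len(np)) {
    strand <- if (p %% 2L == 1L) strand0 else setdiff(c("+", "-"), strand0)
    truth <- if (strand == "+") fwd else rev
    pr <- simulate_pass(truth, model, custom_rates = custom_rates,
                        position_scaling = position_scaling, tables = tables)
    if (p > 1L) {
      adapters <- rbind(adapters,
                        data.frame(start = cursor, end = cursor + nchar(adapter)))
      out_seq <- c(out_seq, adapter)
      for (fc in feat_cols) {
        feature_parts[[fc]] <- c(feature_parts[[fc]], switch(fc,
          qv = ad_qv,
          ip = paste(rep("0", nchar(adapter)), collapse = ","),
          dt = strrep("N", nchar(adapter)),
          st = strrep("N", nchar(adapter)),
          phred_string(rep(0L, nchar(adapter)))))
      }
      cursor <- cursor + nchar(adapter)
    }
    passes$start[p] <- cursor
    passes$end[p] <- cursor + nchar(pr$basecalls)
    passes$strand[p] <- strand
    passes$cigar[p] <- pr$cigar
    out_seq <- c(out_seq, pr$basecalls)
    for (fc in feat_cols)
      feature_parts[[fc]] <- c(feature_parts[[fc]], pr$features[[fc]])
    cursor <- cursor + nchar(pr$basecalls)
    event_log[[p]] <- pr$event_log
  }
  seq <- paste(out_seq, collapse = "")
  features <- lapply(stats::setNames(feat_cols, feat_cols), function(fc) {
    if (fc == "ip") paste(feature_parts[[fc]][nzchar(feature_parts[[fc]])],
                          collapse = ",")
    else paste(feature_parts[[fc]], collapse = "")
  })
  id <- sprintf("sim/%d/%d_%d", as.integer(molecule), 0L, nchar(seq))
  structure(list(id = id, seq = seq, features = features,
                 passes = passes, adapters = adapters,
                 truth = list(contig = fragment$contig,
                              start = fragment$start, end = fragment$end,
                              strand = strand0,
                              truncated = isTRUE(fragment$truncated)),
                 event_log = event_log),
            class = "simulated_read")
}

#' @export
print.simulated_read <- function(x, ...) {
  cat(sprintf("<simulated_read> %s  %d bp, %d pass(es), truth %s:%d-%d (%s)\n",
              x$id, nchar(x$seq), nrow(x$passes), x$truth$contig,
              x$truth$start, x$truth$end, x$truth$strand))
  invisible(x)
}

# ---- top-level driver ------------------------------------------------------

#' Simulate a read set from target sequences
#'
#' Generates molecules until either `nreads` reads have been emitted or the
#' cumulative fragment bases reach `coverage` times the total target
#' length. Fully reproducible: the same model, targets, configuration and
#' seed produce byte-identical reads.
#'
#' @param model An `ekmer_model`.
#' @param targets Named character vector, `DNAStringSet`, or FASTA path.
#' @param nreads Number of reads to simulate (exclusive with `coverage`).
#' @param coverage Target fragment coverage (exclusive with `nreads`).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param custom_rates Optional `c(ins, del, sub)` global event
#'   probabilities replacing the per-context frequencies.
#' @param position_scaling Optional function of relative position in
#'   `[0, 1]` scaling the error-event probabilities.
#' @param fragment_lengths,pass_counts Optional distribution overrides
#'   (integer vectors sampled uniformly).
#' @param adapter Optional adapter sequence override.
#' @return An object of class `ekmer_sim`: list with `reads` (list of
#'   `simulated_read`), `targets` (named lengths), `seed`, `model_hash`,
#'   and `tally` (aggregate realized event counts).
#' @export
simulate_reads <- function(model, targets, nreads = NULL, coverage = NULL,
                           seed = NULL, custom_rates = NULL,
                           position_scaling = NULL, fragment_lengths = NULL,
                           pass_counts = NULL, adapter = NULL) {
  stopifnot(inherits(model, "ekmer_model"))
  if (is.null(nreads) == is.null(coverage))
    stop("set exactly one of nreads or coverage")
  refs <- as_ref_set(targets)
  genome <- sum(nchar(refs))
  if (!is.null(seed)) set.seed(as.integer(seed))
  tables <- sim_tables(model)
  reads <- list()
  frag_bases <- 0
  tally <- stats::setNames(numeric(4L), EVENT_TYPES)
  m <- 0L
  repeat {
    if (!is.null(nreads) && m >= nreads) break
    if (!is.null(coverage) && frag_bases >= coverage * genome) break
    m <- m + 1L
    fr <- draw_fragment(refs, model, n = 1L,
                        fragment_lengths = fragment_lengths)
    rd <- assemble_read(fr, model, molecule = m,
                        pass_counts = pass_counts, adapter = adapter,
                        custom_rates = custom_rates,
                        position_scaling = position_scaling,
                        tables = tables)
    for (el in rd$event_log) {
      t <- table(factor(el$event[!el$is_n], levels = EVENT_TYPES))
      tally <- tally + as.numeric(t)
    }
    frag_bases <- frag_bases + (fr$end - fr$start)
    reads[[m]] <- rd
  }
  structure(list(reads = reads,
                 targets = stats::setNames(nchar(refs), names(refs)),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 model_hash = model_fingerprint(model),
                 tally = tally),
            class = "ekmer_sim")
}

#' @export
print.ekmer_sim <- function(x, ...) {
  nb <- sum(vapply(x$reads, function(r) nchar(r$seq), 1))
  cat(sprintf("<ekmer_sim> %d reads, %.0f bases over %d target contig(s)\n",
              length(x$reads), nb, length(x$targets)))
  tot <- sum(x$tally)
  if (tot > 0)
    cat(sprintf("  realized events: match %.4f  ins %.4f  del %.4f  sub %.4f\n",
                x$tally[1] / tot, x$tally[2] / tot, x$tally[3] / tot,
                x$tally[4] / tot))
  invisible(x)
}

# Cheap stable fingerprint of a model: md5 over the structural payload
# (keys, counts, distributions, config) without the emission bins.
model_fingerprint <- function(model) {
  payload <- jsonlite::toJSON(list(
    v = MODEL_FORMAT_VERSION, f = model$flank_width, cap = model$hp_cap,
    schema = model$schema, keys = rownames(model$counts),
    counts = as.integer(model$counts),
    fl = model$fragment_lengths, pc = model$pass_counts,
    ad = model$adapter), auto_unbox = TRUE)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(payload, tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}

# Alignment records of every pass of a simulated read set against its own
# truth sequences: the input for closed-loop re-classification with
# learn_error_model(). Returns list(alignments, reference).
pass_alignments <- function(sim, targets) {
  refs <- as_ref_set(targets)
  aln <- list(); truth_refs <- character(0)
  k <- 0L
  for (rd in sim$reads) {
    frag <- substr(refs[[rd$truth$contig]], rd$truth$start + 1L, rd$truth$end)
    for (p in seq_len(nrow(rd$passes))) {
      k <- k + 1L
      strand <- rd$passes$strand[p]
      tname <- paste0(rd$id, "|p", p)
      truth_refs[tname] <- if (strand == "+") frag else revcomp(frag)
      aln[[k]] <- data.frame(
        qname = paste0(rd$id, "/pass", p),
        flag = 0L, rname = tname, pos = 1L, mapq = 60L,
        cigar = rd$passes$cigar[p],
        seq = substr(rd$seq, rd$passes$start[p] + 1L, rd$passes$end[p]),
        qual = if (!is.null(rd$features$qv))
          substr(rd$features$qv, rd$passes$start[p] + 1L, rd$passes$end[p])
        else "*",
        stringsAsFactors = FALSE)
    }
  }
  list(alignments = do.call(rbind, aln), reference = truth_refs)
}
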