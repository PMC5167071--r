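# Synthetic training fixtures: references and error-corrupted reads with
# exhaustive ground truth, generated under fully specified parameters. These
# stand in for real single-molecule training data; every corrupted base is
# individually labeled, so the generator doubles as the statistical oracle
# for the learner and the simulator.

#' Specification for the synthetic fixture generator
#'
#' Collects every generative parameter in one validated list. Two corruption
#' mechanisms are available:
#' \describe{
#'   \item{`per_step`}{one error event is drawn per homopolymer context with
#'     the given `rates`; an insertion adds one uniformly chosen base at a
#'     uniform position inside the run, a deletion removes a uniform number
#'     of bases (1..run length), a substitution flips one run base to a
#'     different base. This mirrors how the simulator itself emits events,
#'     so learned per-context frequencies are directly comparable to the
#'     generative ones.}
#'   \item{`per_base`}{each base is independently deleted with probability
#'     `rates["del"]` (and substituted with `rates["sub"]` among survivors,
#'     if given). Under deletion-only corruption the emitted length of a
#'     run of true length L is exactly Binomial(L, 1 - del) — the analytic
#'     reference curve for the homopolymer-transition tests.}
#' }
#'
#' @param n_reads Number of reads (alignment records counts one per pass).
#' @param seed Seed for the generator's private RNG stream.
#' @param mode `"per_step"` or `"per_base"` (see above).
#' @param rates Named event probabilities. For `per_step`: `ins`, `del`,
#'   `sub` (sum < 1). For `per_base`: `del` and optionally `sub`.
#' @param rate_by_base Optional named list mapping a run base (e.g. `"G"`)
#'   to a replacement `rates` vector, to engineer base-dependent biases
#'   such as elevated G/C deletion.
#' @param fragment_lengths Integer vector of fragment lengths to draw from
#'   (uniformly, or weighted by `fragment_probs`).
#' @param fragment_probs Optional weights for `fragment_lengths`.
#' @param pass_counts Integer vector of per-molecule pass counts to draw
#'   from (uniformly, or weighted by `pass_probs`). With more than one pass
#'   a molecule emits one alignment record per pass, named in the
#'   `movie/hole/qStart_qEnd` subread convention so pass-count learning by
#'   read-name grouping is exercised.
#' @param pass_probs Optional weights for `pass_counts`.
#' @param flank_width Flank width used for the generator's own event tally.
#' @param features `"qv"` (FASTQ-style qualities only) or `"pacbio"` (adds
#'   per-base insertion/deletion/merge/substitution QVs, deletion and
#'   substitution tags, and inter-pulse duration frame counts).
#' @param qv_jitter Half-width of the uniform integer jitter added to the
#'   nominal per-base quality `round(-10 log10(total error rate))`.
#' @param keep_pairings Keep per-read exact truth pairings (memory-heavy;
#'   used by alignment-walk oracle tests).
#' @param movie Read-name prefix (the "movie" field of the subread naming
#'   convention).
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_reads = 100L, seed = 1L,
                         mode = c("per_step", "per_base"),
                         rates = c(ins = 0.02, del = 0.05, sub = 0.01),
                         rate_by_base = NULL,
                         fragment_lengths = 1000L, fragment_probs = NULL,
                         pass_counts = 1L, pass_probs = NULL,
                         flank_width = 3L,
                         features = c("qv", "pacbio"),
                         qv_jitter = 2L,
                         keep_pairings = FALSE,
                         movie = "fix") {
  mode <- match.arg(mode)
  features <- match.arg(features)
  rates <- unlist(rates)
  if (mode == "per_step") {
    for (nm in c("ins", "del", "sub"))
      if (is.na(rates[nm])) stop("per_step rates need named entries ins, del, sub")
    if (sum(rates[c("ins", "del", "sub")]) >= 1)
      stop("per_step error rates must sum to < 1")
  } else {
    if (is.na(rates["del"])) stop("per_base rates need a named 'del' entry")
    if (is.na(rates["sub"])) rates["sub"] <- 0
  }
  if (any(rates < 0) || any(rates > 1)) stop("rates must be probabilities")
  structure(list(
    n_reads = as.integer(n_reads), seed = as.integer(seed), mode = mode,
    rates = rates, rate_by_base = rate_by_base,
    fragment_lengths = as.integer(fragment_lengths),
    fragment_probs = fragment_probs,
    pass_counts = as.integer(pass_counts), pass_probs = pass_probs,
    flank_width = as.integer(flank_width), features = features,
    qv_jitter = as.integer(qv_jitter), keep_pairings = isTRUE(keep_pairings),
    movie = movie
  ), class = "fixture_spec")
}

#' Generate a random reference sequence with controllable homopolymers
#'
#' Draws an i.i.d. base sequence and optionally overwrites forced
#' homopolymer runs at recorded offsets (adjusting the immediate neighbors
#' so forced runs stay maximal). Deterministic given `seed`.
#'
#' @param length Reference length in bp.
#' @param seed RNG seed (private stream; the caller's RNG is untouched).
#' @param base_probs Sampling probabilities for A, C, G, T.
#' @param forced_runs Optional data frame with columns `offset` (0-based),
#'   `base`, `length`: homopolymer runs guaranteed to appear verbatim.
#' @return A single reference string.
#' @export
#' @examples
#' r <- make_reference(200, seed = 7,
#'   forced_runs = data.frame(offset = 100, base = "T", length = 6))
#' substr(r, 101, 106)
make_reference <- function(length, seed = 1L,
                           base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           forced_runs = NULL) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  with_local_seed(seed, {
    chars <- sample(DNA_BASES, length, replace = TRUE, prob = base_probs)
    if (!is.null(forced_runs)) {
      fr <- forced_runs[order(forced_runs$offset), , drop = FALSE]
      last_end <- -1L
      for (i in seq_len(nrow(fr))) {
        o <- as.integer(fr$offset[i]); b <- toupper(fr$base[i])
        l <- as.integer(fr$length[i])
        if (o < 0L || o + l > length) stop("forced run out of reference bounds")
        if (o <= last_end) stop("forced runs overlap (neighbor adjustment needs a gap)")
        chars[(o + 1L):(o + l)] <- b
        if (o > 0L && chars[o] == b)
          chars[o] <- setdiff(DNA_BASES, b)[1L]
        if (o + l < length && chars[o + l + 1L] == b)
          chars[o + l + 1L] <- setdiff(DNA_BASES, b)[1L]
        last_end <- o + l
      }
    }
    paste(chars, collapse = "")
  })
}

# cumulative-probability event draw: cols MATCH, INS, DEL, SUB
draw_events <- function(p_ins, p_del, p_sub, n) {
  u <- stats::runif(n)
  p_err1 <- p_ins
  p_err2 <- p_ins + p_del
  p_err3 <- p_ins + p_del + p_sub
  # order: INSERTION in [0,p_ins), DELETION, SUBSTITUTION, MATCH in tail
  ifelse(u < p_err1, 2L, ifelse(u < p_err2, 3L, ifelse(u < p_err3, 4L, 1L)))
}

# merge adjacent identical CIGAR ops and render the string
collapse_cigar <- function(lens, ops) {
  keep <- lens > 0L
  lens <- lens[keep]; ops <- ops[keep]
  if (length(ops) == 0L) return("")
  grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
  l2 <- vapply(split(lens, grp), sum, numeric(1), USE.NAMES = FALSE)
  o2 <- ops[!duplicated(grp)]
  paste0(as.integer(l2), o2, collapse = "")
}

#' Generate error-corrupted reads with exhaustive ground truth
#'
#' Draws fragments uniformly from the reference, corrupts them according to
#' the [fixture_spec()] mechanism, and emits alignment records (CIGAR
#' encodes the corruption exactly) plus the generator's own per-context
#' event tally — the oracle that learning results are compared against.
#' Corruption is applied per homopolymer context of the reference
#' tokenization; contexts only partially covered by a fragment are copied
#' through error-free (the learner skips them symmetrically).
#'
#' @param reference Reference sequence (string, named vector, DNAStringSet,
#'   or FASTA path); only the first contig is used.
#' @param spec A [fixture_spec()].
#' @return A list with elements `alignments` (a data frame with SAM-like
#'   columns `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`,
#'   `qual`, plus feature tag columns for the `pacbio` schema), `tally`
#'   (data frame `key`, `event`, `n` of generated events), `realized`
#'   (global event frequencies actually generated), `reference` (named
#'   vector), and optionally `pairings` (exact per-base truth pairings per
#'   record, when `spec$keep_pairings`).
#' @export
make_corrupted_reads <- function(reference, spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  refs <- as_ref_set(reference)
  rname <- names(refs)[1L]
  refseq <- refs[[1L]]
  rlen <- nchar(refseq)
  steps <- tokenize(refseq, spec$flank_width)
  keys <- step_keys(steps)
  run_str <- strrep(steps$hp_base, steps$hp_length)
  base_idx <- match(steps$hp_base, DNA_BASES)

  # per-step event rates, optionally base-dependent
  get_rates <- function(which_rate) {
    r <- rep(unname(spec$rates[which_rate]), nrow(steps))
    if (!is.null(spec$rate_by_base)) {
      for (b in names(spec$rate_by_base)) {
        rb <- unlist(spec$rate_by_base[[b]])
        if (!is.na(rb[which_rate])) r[steps$hp_base == b] <- rb[which_rate]
      }
    }
    r
  }

  with_local_seed(spec$seed, {
    # molecule structure: n_reads is the number of alignment records
    npass <- integer(0); mol <- integer(0)
    while (sum(npass) < spec$n_reads) {
      np <- if (length(spec$pass_counts) == 1L) spec$pass_counts else
        sample(spec$pass_counts, 1L, prob = spec$pass_probs)
      npass <- c(npass, np)
      mol <- c(mol, length(npass))
    }
    n_mol <- length(npass)

    frag_len <- if (length(spec$fragment_lengths) == 1L)
      rep(spec$fragment_lengths, n_mol)
    else sample(spec$fragment_lengths, n_mol, replace = TRUE,
                prob = spec$fragment_probs)
    frag_len <- pmin(frag_len, rlen)
    frag_start <- floor(stats::runif(n_mol) * (rlen - frag_len + 1L))  # 0-based

    qname <- character(0); poss <- integer(0); cigars <- character(0)
    seqs <- character(0); quals <- character(0)
    tally_key <- vector("list", 0); tally_ev <- vector("list", 0)
    pairings <- if (spec$keep_pairings) list() else NULL
    n_emitted <- 0L

    rec <- 0L
    for (m in seq_len(n_mol)) {
      fs <- frag_start[m]; fe <- fs + frag_len[m]     # 0-based half-open
      # interior steps: fully inside [fs, fe)
      inside <- which(steps$ref_start >= fs & steps$ref_end <= fe)
      left_edge <- if (length(inside) && steps$ref_start[inside[1L]] > fs)
        substr(refseq, fs + 1L, steps$ref_start[inside[1L]]) else
          if (!length(inside)) substr(refseq, fs + 1L, fe) else ""
      right_edge <- if (length(inside) && steps$ref_end[inside[length(inside)]] < fe)
        substr(refseq, steps$ref_end[inside[length(inside)]] + 1L, fe) else ""
      k <- length(inside)

      for (p in seq_len(npass[m])) {
        rec <- rec + 1L
        if (spec$mode == "per_step") {
          out <- corrupt_per_step(steps, inside, run_str, spec, get_rates)
        } else {
          out <- corrupt_per_base(steps, inside, refseq, fs, fe, spec)
        }
        # assemble read: left edge + per-step emissions + right edge
        seq_p <- paste0(left_edge, out$emitted_all, right_edge)
        lens <- c(nchar(left_edge), out$cig_lens, nchar(right_edge))
        ops <- c("M", out$cig_ops, "M")
        cigar <- collapse_cigar(as.integer(lens), ops)
        # per-base quality: nominal from total error prob + jitter
        p_tot <- if (spec$mode == "per_step")
          sum(spec$rates[c("ins", "del", "sub")]) else
            sum(spec$rates[c("del", "sub")])
        qv_nom <- if (p_tot <= 0) 60L else as.integer(round(-10 * log10(p_tot)))
        nb <- nchar(seq_p)
        qv <- qv_nom + sample.int(2L * spec$qv_jitter + 1L, nb, replace = TRUE) -
          spec$qv_jitter - 1L
        qv <- pmin(pmax(qv, 2L), PHRED_MAX)
        qname <- c(qname, sprintf("%s/%d/%d_%d", spec$movie, m,
                                  (p - 1L) * (frag_len[m] + 50L),
                                  (p - 1L) * (frag_len[m] + 50L) + nb))
        poss <- c(poss, fs + 1L)
        cigars <- c(cigars, cigar)
        seqs <- c(seqs, seq_p)
        quals <- c(quals, phred_string(qv))
        if (k > 0L) {
          n_emitted <- n_emitted + 1L
          tally_key[[n_emitted]] <- keys[inside]
          tally_ev[[n_emitted]] <- out$event
        }
        if (spec$keep_pairings) pairings[[rec]] <- out$pairing
      }
    }

    aln <- data.frame(qname = qname, flag = 0L, rname = rname, pos = poss,
                      mapq = 60L, cigar = cigars, seq = seqs, qual = quals,
                      stringsAsFactors = FALSE)
    if (spec$features == "pacbio") {
      nb <- nchar(aln$seq)
      aln$iq <- vapply(nb, function(n) phred_string(sample.int(30L, n, TRUE) + 5L), "")
      aln$dq <- vapply(nb, function(n) phred_string(sample.int(30L, n, TRUE) + 5L), "")
      aln$mq <- vapply(nb, function(n) phred_string(sample.int(30L, n, TRUE) + 5L), "")
      aln$sq <- vapply(nb, function(n) phred_string(sample.int(30L, n, TRUE) + 5L), "")
      aln$dt <- vapply(nb, function(n)
        paste(sample(c(DNA_BASES, "N"), n, TRUE), collapse = ""), "")
      aln$st <- vapply(nb, function(n)
        paste(sample(c(DNA_BASES, "N"), n, TRUE), collapse = ""), "")
      aln$ip <- vapply(nb, function(n)
        paste(stats::rpois(n, 12), collapse = ","), "")
    }

    all_keys <- unlist(tally_key); all_ev <- unlist(tally_ev)
    tally <- as.data.frame(table(key = all_keys,
                                 event = factor(EVENT_TYPES[all_ev],
                                                levels = EVENT_TYPES)),
                           stringsAsFactors = FALSE)
    names(tally)[3] <- "n"
    tally <- tally[tally$n > 0L, ]
    rownames(tally) <- NULL
    realized <- prop.table(table(factor(EVENT_TYPES[all_ev], levels = EVENT_TYPES)))

    out <- list(alignments = aln, tally = tally,
                realized = c(realized),
                reference = stats::setNames(refseq, rname),
                spec = spec)
    if (spec$keep_pairings) out$pairings <- pairings
    out
  })
}

# One pass of per-step corruption over the interior steps. Returns emitted
# strings + CIGAR fragments per step, the event codes, and (optionally) the
# exact per-base truth pairing.
corrupt_per_step <- function(steps, inside, run_str, spec, get_rates) {
  k <- length(inside)
  if (k == 0L)
    return(list(emitted_all = "", cig_lens = integer(0), cig_ops = character(0),
                event = integer(0), pairing = NULL))
  p_ins <- get_rates("ins")[inside]
  p_del <- get_rates("del")[inside]
  p_sub <- get_rates("sub")[inside]
  ev <- draw_events(p_ins, p_del, p_sub, k)
  L <- steps$hp_length[inside]
  b <- steps$hp_base[inside]
  emitted <- run_str[inside]
  # CIGAR: up to 2 ops per step
  cl1 <- L; co1 <- rep("M", k)
  cl2 <- integer(k); co2 <- rep("M", k)  # zero-length dummies dropped later
  ins_rows <- which(ev == 2L)
  ipos_all <- integer(k)
  if (length(ins_rows)) {
    ipos <- 1L + floor(stats::runif(length(ins_rows)) * L[ins_rows])  # after base ipos
    ibase <- DNA_BASES[1L + floor(stats::runif(length(ins_rows)) * 4)]
    ipos_all[ins_rows] <- ipos
    emitted[ins_rows] <- paste0(strrep(b[ins_rows], ipos), ibase,
                                strrep(b[ins_rows], L[ins_rows] - ipos))
    # CIGAR: ipos M, 1 I, (L-ipos) M
    cl1[ins_rows] <- ipos
    co1[ins_rows] <- "M"
    cl2[ins_rows] <- 1L
    co2[ins_rows] <- "I"
    # remainder M handled via a third slot below
  }
  del_rows <- which(ev == 3L)
  ndel <- integer(k)
  if (length(del_rows)) {
    ndel[del_rows] <- 1L + floor(stats::runif(length(del_rows)) * L[del_rows])
    emitted[del_rows] <- strrep(b[del_rows], L[del_rows] - ndel[del_rows])
    cl1[del_rows] <- L[del_rows] - ndel[del_rows]
    cl2[del_rows] <- ndel[del_rows]
    co2[del_rows] <- "D"
  }
  sub_rows <- which(ev == 4L)
  if (length(sub_rows)) {
    spos <- 1L + floor(stats::runif(length(sub_rows)) * L[sub_rows])
    # replacement drawn uniformly from the three other bases
    off <- 1L + floor(stats::runif(length(sub_rows)) * 3)
    sbase <- mapply(function(bb, o) setdiff(DNA_BASES, bb)[o],
                    b[sub_rows], off, USE.NAMES = FALSE)
    es <- emitted[sub_rows]
    substr(es, spos, spos) <- sbase
    emitted[sub_rows] <- es
    # CIGAR stays L M (mismatch inside M)
  }
  # third op slot for insertion remainder
  cl3 <- integer(k); co3 <- rep("M", k)
  if (length(ins_rows)) cl3[ins_rows] <- L[ins_rows] - cl1[ins_rows]
  cig_lens <- as.integer(rbind(cl1, cl2, cl3))
  cig_ops <- as.character(rbind(co1, co2, co3))
  pairing <- if (spec$keep_pairings)
    build_pairing(steps, inside, emitted, ev, ipos_all) else NULL
  list(emitted_all = paste(emitted, collapse = ""),
       cig_lens = cig_lens, cig_ops = cig_ops,
       event = ev, pairing = pairing)
}

# Per-base corruption over the interior region of the fragment (the span
# covered by fully-contained homopolymer steps): each base independently
# deleted, survivors independently substituted. Edge regions (partial runs
# at fragment boundaries) pass through error-free, mirroring per_step mode.
# Events are derived per interior step afterwards.
corrupt_per_base <- function(steps, inside, refseq, fs, fe, spec) {
  k <- length(inside)
  if (k == 0L)
    return(list(emitted_all = "", cig_lens = integer(0), cig_ops = character(0),
                event = integer(0), pairing = NULL))
  st_first <- steps$ref_start[inside[1L]]        # 0-based, absolute
  en_last <- steps$ref_end[inside[k]]
  chars <- str_chars(substr(refseq, st_first + 1L, en_last))
  n <- length(chars)
  d <- rep(unname(spec$rates["del"]), n)
  s <- rep(unname(spec$rates["sub"]), n)
  if (!is.null(spec$rate_by_base)) {
    for (b in names(spec$rate_by_base)) {
      rb <- unlist(spec$rate_by_base[[b]])
      if (!is.na(rb["del"])) d[chars == b] <- rb["del"]
      if (!is.na(rb["sub"])) s[chars == b] <- rb["sub"]
    }
  }
  keep <- stats::runif(n) >= d
  subbed <- keep & (stats::runif(n) < s)
  out_chars <- chars
  if (any(subbed)) {
    off <- 1L + floor(stats::runif(sum(subbed)) * 3)
    out_chars[subbed] <- mapply(function(bb, o) setdiff(DNA_BASES, bb)[o],
                                chars[subbed], off, USE.NAMES = FALSE)
  }
  # CIGAR over the interior region from the keep mask
  r <- rle(keep)
  cig_lens <- r$lengths
  cig_ops <- ifelse(r$values, "M", "D")
  # derive per-interior-step events
  st0 <- steps$ref_start[inside] - st_first      # 0-based within region
  en0 <- steps$ref_end[inside] - st_first
  kept_cum <- cumsum(keep)
  sub_cum <- cumsum(subbed)
  before <- ifelse(st0 > 0L, kept_cum[pmax(st0, 1L)], 0L)
  before[st0 == 0L] <- 0L
  n_kept <- kept_cum[en0] - before
  before_s <- ifelse(st0 > 0L, sub_cum[pmax(st0, 1L)], 0L)
  before_s[st0 == 0L] <- 0L
  n_sub <- sub_cum[en0] - before_s
  Ls <- steps$hp_length[inside]
  ev <- ifelse(n_kept < Ls, 3L, ifelse(n_sub > 0L, 4L, 1L))
  emitted_all <- paste(out_chars[keep], collapse = "")
  pairing <- if (spec$keep_pairings) {
    anchors <- (st_first + seq_len(n) - 1L)[keep]
    data.frame(base = out_chars[keep], anchor = anchors, is_ins = FALSE)
  } else NULL
  list(emitted_all = emitted_all, cig_lens = as.integer(cig_lens),
       cig_ops = cig_ops, event = ev, pairing = pairing)
}

# Exact truth pairing for one per-step-corrupted pass: one row per read
# base with its 0-based reference anchor and insertion flag. `ipos_all[j]`
# gives, for insertion steps, the number of run bases emitted before the
# inserted base (matching the emitted CIGAR exactly).
build_pairing <- function(steps, inside, emitted, ev, ipos_all) {
  rows <- lapply(seq_along(inside), function(j) {
    i <- inside[j]
    st <- steps$ref_start[i]
    em <- str_chars(emitted[j])
    m <- length(em)
    if (m == 0L) return(NULL)
    if (ev[j] == 2L) {
      ipos <- ipos_all[j]
      anchors <- integer(m); is_ins <- logical(m)
      if (ipos > 0L) anchors[seq_len(ipos)] <- st + seq_len(ipos) - 1L
      anchors[ipos + 1L] <- st + max(ipos - 1L, 0L)
      is_ins[ipos + 1L] <- TRUE
      rest <- seq_len(m - ipos - 1L)
      if (length(rest)) anchors[ipos + 1L + rest] <- st + ipos + rest - 1L
      data.frame(base = em, anchor = anchors, is_ins = is_ins,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(base = em, anchor = st + seq_len(m) - 1L, is_ins = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an alignment data frame as a SAM file
#'
#' Renders the flat alignment representation used throughout the package
#' (one row per record, feature tags as string columns) into SAM text with
#' proper `@SQ` headers, so fixtures can be consumed by external tools and
#' by the SAM/BAM learning route.
#'
#' @param alignments Data frame with columns `qname`, `flag`, `rname`,
#'   `pos`, `mapq`, `cigar`, `seq`, `qual` and optional tag columns
#'   (`iq`, `dq`, `mq`, `sq` Phred+33 strings; `dt`, `st` base strings;
#'   `ip` comma-separated integers).
#' @param reference Named character vector (or FASTA path / DNAStringSet)
#'   supplying contig names and lengths for the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reference, path) {
  refs <- as_ref_set(reference)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
  a <- alignments[order(match(alignments$rname, names(refs)), alignments$pos), ,
                  drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  a$qname, a$flag, a$rname, a$pos, a$mapq, a$cigar,
                  a$seq, a$qual)
  for (tg in c("iq", "dq", "mq", "sq", "dt", "st")) {
    if (!is.null(a[[tg]]))
      body <- paste0(body, "\t", tg, ":Z:", a[[tg]])
  }
  if (!is.null(a$ip)) body <- paste0(body, "\tip:B:S,", a$ip)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, useBytes = TRUE)
  invisible(path)
}
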