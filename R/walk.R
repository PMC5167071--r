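# Alignment walking and per-context event classification.
#
# walk_alignment() turns one aligned record (CIGAR semantics) into an exact
# per-base attribution: every read base in the aligned span is assigned to
# one reference position, or flagged as an insertion anchored at the last
# consumed reference position. classify_walk() then assigns exactly one
# event (MATCH / INSERTION / DELETION / SUBSTITUTION) to every homopolymer
# context fully covered by the walk, with insertion-priority precedence.

# parse "10M2D3I..." -> list(lengths, ops)
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar))
    stop("record has no usable CIGAR")
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR: '", cigar, "'")
  n <- nchar(toks)
  list(lengths = as.integer(substr(toks, 1L, n - 1L)),
       ops = substr(toks, n, n))
}

#' Walk one alignment record against its reference
#'
#' Expands the CIGAR of a mapped record into an exact per-read-base
#' attribution. Every read base inside the aligned span is paired with a
#' 0-based reference position; inserted bases are anchored at the last
#' reference position consumed before them (left attribution). Soft-clipped
#' bases are excluded. Mismatches are established against the reference
#' sequence itself, so no MD tag is required.
#'
#' @param record A one-row data frame or list with at least `qname`, `pos`
#'   (1-based leftmost mapped position), `cigar`, `seq`, and optionally
#'   `qual` and per-base feature tag columns (`iq`, `dq`, `dt`, `mq`, `sq`,
#'   `st` as Phred+33/base strings, `ip` as a comma-separated integer
#'   string), each aligned character-for-character with `seq`.
#' @param reference The reference sequence for the record's contig (plain
#'   string), or a named vector/`DNAStringSet`/FASTA path from which the
#'   record's `rname` is looked up.
#' @return An object of class `alignment_walk`: a list with `qname`,
#'   `ref_start`/`ref_end` (0-based half-open aligned span), and the
#'   parallel per-base vectors `base`, `anchor` (0-based reference
#'   position), `is_ins`, plus a `features` list of per-base vectors.
#' @export
walk_alignment <- function(record, reference) {
  if (is.data.frame(record)) record <- as.list(record[1L, ])
  refs <- as_ref_set(reference)
  refseq <- if (!is.null(record$rname) && record$rname %in% names(refs))
    refs[[record$rname]] else refs[[1L]]
  if (!is.null(record$flag) && bitwAnd(as.integer(record$flag), 4L) != 0L)
    stop("record '", record$qname, "' is unmapped")
  cig <- parse_cigar(record$cigar)
  lens <- cig$lengths; ops <- cig$ops
  read_ops <- ops %in% c("M", "=", "X", "I", "S")
  ref_ops <- ops %in% c("M", "=", "X", "D", "N")
  pos0 <- as.integer(record$pos) - 1L           # 0-based alignment start
  # read-length consistency
  nread <- nchar(record$seq)
  if (sum(lens[read_ops]) != nread)
    stop("CIGAR/sequence length mismatch for read '", record$qname, "'")
  ref_starts <- pos0 + c(0L, cumsum(lens * ref_ops))[seq_along(ops)]
  read_starts <- c(0L, cumsum(lens * read_ops))[seq_along(ops)]
  ref_end <- pos0 + sum(lens[ref_ops])
  if (ref_end > nchar(refseq))
    stop("alignment span of read '", record$qname,
         "' extends past the reference end")
  keep <- ops %in% c("M", "=", "X", "I")
  if (!any(keep)) {
    return(structure(list(qname = record$qname, ref_start = pos0,
                          ref_end = ref_end, base = character(0),
                          anchor = integer(0), is_ins = logical(0),
                          features = list()), class = "alignment_walk"))
  }
  ki <- which(keep)
  per_op <- rep.int(ki, lens[ki])
  within <- sequence(lens[ki])                  # 1..len within each kept op
  is_ins <- ops[per_op] == "I"
  anchor <- integer(length(per_op))
  anchor[!is_ins] <- ref_starts[per_op[!is_ins]] + within[!is_ins] - 1L
  # insertion: last consumed reference position before the op (clamped for
  # insertions at the very start of the alignment)
  anchor[is_ins] <- pmax(ref_starts[per_op[is_ins]] - 1L, pos0)
  ridx <- read_starts[per_op] + within           # 1-based read coordinates
  chars <- str_chars(record$seq)
  features <- list()
  if (!is.null(record$qual) && !is.na(record$qual) && record$qual != "*")
    features$qv <- phred_values(record$qual)[ridx]
  for (tg in c("iq", "dq", "mq", "sq")) {
    if (!is.null(record[[tg]]) && !is.na(record[[tg]]))
      features[[tg]] <- phred_values(record[[tg]])[ridx]
  }
  for (tg in c("dt", "st")) {
    if (!is.null(record[[tg]]) && !is.na(record[[tg]]))
      features[[tg]] <- str_chars(record[[tg]])[ridx]
  }
  if (!is.null(record$ip) && !is.na(record$ip))
    features$ip <- as.integer(strsplit(record$ip, ",", fixed = TRUE)[[1]])[ridx]
  structure(list(qname = record$qname, ref_start = pos0, ref_end = ref_end,
                 base = chars[ridx], anchor = anchor, is_ins = is_ins,
                 features = features),
            class = "alignment_walk")
}

#' @export
print.alignment_walk <- function(x, ...) {
  cat(sprintf("<alignment_walk> %s  span [%d, %d)  %d read bases (%d inserted)\n",
              x$qname, x$ref_start, x$ref_end, length(x$base), sum(x$is_ins)))
  invisible(x)
}

# Vectorized classification of every step fully covered by a walk.
# `steps` must be the tokenization of the walked reference. Returns a data
# frame with one row per covered step: key index into `steps`, event,
# emitted string, and per-feature strings, plus the skipped-step count as
# an attribute.
classify_walk <- function(walk, steps, cap = Inf) {
  covered <- which(steps$ref_start >= walk$ref_start &
                     steps$ref_end <= walk$ref_end)
  overlapping <- which(steps$ref_end > walk$ref_start &
                         steps$ref_start < walk$ref_end)
  n_skipped <- length(overlapping) - length(covered)
  K <- length(covered)
  if (K == 0L) {
    out <- data.frame(step = integer(0), event = character(0),
                      emitted = character(0), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  cov_start <- steps$ref_start[covered]
  cov_end <- steps$ref_end[covered]
  # map each read base to a covered step (0 / K+1 => outside covered region)
  si <- findInterval(walk$anchor, cov_start)
  in_cov <- si >= 1L & walk$anchor < cov_end[pmax(si, 1L)]
  sj <- si[in_cov]
  bases <- walk$base[in_cov]
  ins <- walk$is_ins[in_cov]
  n_bases <- tabulate(sj, K)
  n_ins <- tabulate(sj[ins], K)
  n_mis <- tabulate(sj[!ins][bases[!ins] != steps$hp_base[covered][sj[!ins]]], K)
  L <- steps$hp_length[covered]
  event <- ifelse(n_ins > 0L, 2L,
                  ifelse(n_bases < L, 3L,
                         ifelse(n_mis > 0L, 4L, 1L)))
  # emitted strings: read bases for a step form a contiguous block (anchors
  # are non-decreasing), so one paste + vectorized substring suffices
  kept_str <- paste(bases, collapse = "")
  blk <- rle(sj)
  blk_end <- cumsum(blk$lengths)
  blk_start <- blk_end - blk$lengths + 1L
  firsts <- integer(K); lasts <- integer(K)
  firsts[blk$values] <- blk_start
  lasts[blk$values] <- blk_end
  emitted <- character(K)
  nz <- n_bases > 0L
  if (any(nz)) emitted[nz] <- substring(kept_str, firsts[nz], lasts[nz])
  out <- data.frame(step = covered, event = EVENT_TYPES[event],
                    emitted = emitted, stringsAsFactors = FALSE)
  for (fn in names(walk$features)) {
    fv <- walk$features[[fn]][in_cov]
    if (fn %in% c("qv", "iq", "dq", "mq", "sq")) {
      fstr <- phred_string(fv)
      col <- character(K)
      if (any(nz)) col[nz] <- substring(fstr, firsts[nz], lasts[nz])
    } else if (fn %in% c("dt", "st")) {
      fstr <- paste(fv, collapse = "")
      col <- character(K)
      if (any(nz)) col[nz] <- substring(fstr, firsts[nz], lasts[nz])
    } else {  # ip: comma-separated integers
      col <- character(K)
      if (any(nz))
        col[nz] <- vapply(which(nz), function(i)
          paste(fv[firsts[i]:lasts[i]], collapse = ","), "")
    }
    out[[fn]] <- col
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Classify what a read did over one homopolymer context
#'
#' Assigns exactly one event to the span of a tokenizer step covered by an
#' alignment walk, with insertion-priority precedence: any inserted base
#' makes the span an `INSERTION`; otherwise fewer emitted than reference
#' bases is a `DELETION`; otherwise any mismatching base is a
#' `SUBSTITUTION`; otherwise `MATCH`. The full emitted basecall string is
#' returned alongside, so insertion-deletion cancellation with non-matching
#' bases is represented faithfully.
#'
#' @param step One row of a [tokenize()] result (the step must lie fully
#'   inside the walked span).
#' @param walk An [walk_alignment()] result over the same reference.
#' @return A list with `event`, `emitted`, and `features` (per-base feature
#'   vectors aligned with `emitted`).
#' @export
classify_span <- function(step, walk) {
  stopifnot(nrow(step) == 1L)
  if (step$ref_start < walk$ref_start || step$ref_end > walk$ref_end)
    stop("step is not fully covered by the walked span")
  res <- classify_walk(walk, step)
  if (nrow(res) == 0L) stop("step is not fully covered by the walked span")
  feats <- list()
  for (fn in setdiff(names(res), c("step", "event", "emitted"))) {
    feats[[fn]] <- if (fn %in% c("qv", "iq", "dq", "mq", "sq"))
      phred_values(res[[fn]][1L])
    else if (fn %in% c("dt", "st")) str_chars(res[[fn]][1L])
    else if (nzchar(res[[fn]][1L]))
      as.integer(strsplit(res[[fn]][1L], ",")[[1]]) else integer(0)
  }
  list(event = res$event[1L], emitted = res$emitted[1L], features = feats)
}
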