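# Fitting the empirical error model from alignments.
#
# The fitted object (class "ekmer_model") holds, for every extended-k-mer
# context key: exact event counts (match/insertion/deletion/substitution)
# and a bounded reservoir of observed emissions with per-base features; plus
# the empirical fragment-length and pass-count distributions and metadata.
# Simulation resamples from these bins, so no parametric error form is ever
# assumed.

MODEL_FORMAT_VERSION <- "1.0"
DEFAULT_NAME_REGEX <- "^(.+)/[0-9]+_[0-9]+$"
# published SMRTbell hairpin adapter
DEFAULT_ADAPTER <- "ATCTCTCTCTTTTCCTCCTCCTCCGTTGTTGTTGTTGAGAGAGAT"

PHRED_FEATURES <- c("qv", "iq", "dq", "mq", "sq")
TAG_FEATURES <- c("dt", "st")
SCHEMAS <- list(qv = "qv",
                pacbio = c("qv", "iq", "dq", "mq", "sq", "dt", "st", "ip"))

# Read a SAM or BAM file into the flat alignment data frame the learner
# consumes. SAM input is converted through Rsamtools.
read_alignments <- function(path, schema = "qv") {
  stopifnot(file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  tags <- if (identical(schema, "pacbio") ||
              (length(schema) > 1L && "ip" %in% schema))
    c("iq", "dq", "mq", "sq", "dt", "st", "ip") else character(0)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = tags)
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  df <- data.frame(qname = res$qname, flag = res$flag,
                   rname = as.character(res$rname), pos = res$pos,
                   mapq = res$mapq, cigar = res$cigar,
                   seq = as.character(res$seq), qual = as.character(res$qual),
                   stringsAsFactors = FALSE)
  for (tg in intersect(tags, c("iq", "dq", "mq", "sq", "dt", "st"))) {
    v <- res$tag[[tg]]
    if (!is.null(v)) df[[tg]] <- as.character(v)
  }
  if ("ip" %in% tags && !is.null(res$tag$ip)) {
    df$ip <- vapply(res$tag$ip, function(x)
      paste(as.integer(x), collapse = ","), "")
  }
  df
}

#' Fit an empirical context-dependent error model from alignments
#'
#' Walks every usable alignment record, classifies what the read did over
#' each homopolymer context of the reference into exactly one event
#' (insertion-priority precedence), and accumulates per-context event
#' counts plus reservoir-sampled emission records with per-base features.
#' Per-record aligned lengths form the fragment-length distribution;
#' grouping read names with `name_regex` (the `movie/hole/qStart_qEnd`
#' subread convention by default) yields the pass-count distribution.
#'
#' Learning is deterministic: reservoir sampling uses a private RNG seeded
#' per context key, so the same inputs and configuration always produce an
#' identical model, and the caller's RNG stream is never consumed.
#'
#' @param alignments Path to a SAM/BAM file, or a data frame with columns
#'   `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`, `qual` (and
#'   feature tag columns for the `pacbio` schema).
#' @param reference Named character vector of contig sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param flank_width Flanking bases per side of the homopolymer run
#'   (default 3: 7-base-wide contexts for single-base runs).
#' @param hp_cap Run lengths above this cap share one `>cap` model bucket
#'   (default 20); raw lengths are still used for simulation arithmetic.
#' @param bin_cap Reservoir capacity per (context, event) bin (default
#'   10000). Event counts stay exact beyond the cap.
#' @param schema `"qv"` (qualities only) or `"pacbio"` (adds per-base
#'   insertion/deletion/merge/substitution QVs, deletion/substitution tags,
#'   and inter-pulse durations).
#' @param name_regex Regex with one capture group extracting the molecule
#'   identifier from a read name; non-matching names count as single-pass.
#' @param min_len Minimum aligned reference length (default 50 bp).
#' @param min_mapq Minimum mapping quality (default 1).
#' @param adapter Adapter sequence stored with the model (default: the
#'   published SMRTbell hairpin).
#' @param bin_seed Salt for the per-key reservoir seeds.
#' @return An object of class `ekmer_model`.
#' @seealso [simulate.ekmer_model()], [merge_models()], [write_model()],
#'   [context_accuracy()]
#' @export
learn_error_model <- function(alignments, reference,
                              flank_width = 3L, hp_cap = 20L,
                              bin_cap = 10000L,
                              schema = c("qv", "pacbio"),
                              name_regex = DEFAULT_NAME_REGEX,
                              min_len = 50L, min_mapq = 1L,
                              adapter = DEFAULT_ADAPTER,
                              bin_seed = 0L) {
  schema <- match.arg(schema)
  feat_cols <- SCHEMAS[[schema]]
  refs <- as_ref_set(reference)
  src <- "<data.frame>"
  if (is.character(alignments) && length(alignments) == 1L) {
    src <- alignments
    alignments <- read_alignments(alignments, schema)
  }
  stopifnot(is.data.frame(alignments))
  n_in <- nrow(alignments)
  if (n_in == 0L) stop("no alignment records supplied")

  flag <- as.integer(alignments$flag)
  usable <- bitwAnd(flag, 4L) == 0L &            # mapped
    bitwAnd(flag, 256L) == 0L &                  # not secondary
    bitwAnd(flag, 2048L) == 0L &                 # not supplementary
    alignments$mapq >= min_mapq &
    !is.na(alignments$cigar) & alignments$cigar != "*"
  missing_ref <- setdiff(unique(alignments$rname[usable]), names(refs))
  if (length(missing_ref))
    stop("reference contig(s) missing: ", paste(missing_ref, collapse = ", "))
  aln <- alignments[usable, , drop = FALSE]
  if (nrow(aln) == 0L) stop("no usable alignment records after filtering")

  # tokenize each contig once; cache steps, capped keys, and N flags
  caches <- list()
  for (ct in unique(aln$rname)) {
    st <- tokenize(refs[[ct]], flank_width)
    caches[[ct]] <- list(steps = st,
                         keys = step_keys(st, cap = hp_cap),
                         is_n = st$hp_base == "N")
  }

  acc_key <- vector("list", nrow(aln)); acc_ev <- vector("list", nrow(aln))
  acc_em <- vector("list", nrow(aln))
  acc_feat <- stats::setNames(
    rep(list(vector("list", nrow(aln))), length(feat_cols)), feat_cols)
  frag_lens <- integer(nrow(aln))
  used <- logical(nrow(aln))
  n_skipped_spans <- 0L
  n_short <- 0L
  aligned_bases <- 0

  for (i in seq_len(nrow(aln))) {
    rec <- lapply(aln, function(col) col[i])
    cache <- caches[[rec$rname]]
    walk <- walk_alignment(rec, refs[rec$rname])
    span <- walk$ref_end - walk$ref_start
    if (span < min_len) { n_short <- n_short + 1L; next }
    res <- classify_walk(walk, cache$steps)
    n_skipped_spans <- n_skipped_spans + attr(res, "n_skipped")
    if (nrow(res) == 0L) next
    nrun <- cache$is_n[res$step]
    if (any(nrun)) {
      n_skipped_spans <- n_skipped_spans + sum(nrun)
      res <- res[!nrun, , drop = FALSE]
    }
    if (nrow(res) == 0L) next
    used[i] <- TRUE
    frag_lens[i] <- span
    aligned_bases <- aligned_bases + length(walk$base)
    acc_key[[i]] <- cache$keys[res$step]
    acc_ev[[i]] <- res$event
    acc_em[[i]] <- res$emitted
    for (fc in feat_cols) {
      acc_feat[[fc]][[i]] <- if (!is.null(res[[fc]])) res[[fc]]
      else rep("", nrow(res))
    }
  }

  key <- unlist(acc_key, use.names = FALSE)
  if (is.null(key) || length(key) == 0L)
    stop("zero usable classified spans; nothing to learn from")
  event <- unlist(acc_ev, use.names = FALSE)
  samples <- data.frame(key = key, event = event,
                        emitted = unlist(acc_em, use.names = FALSE),
                        stringsAsFactors = FALSE)
  for (fc in feat_cols)
    samples[[fc]] <- unlist(acc_feat[[fc]], use.names = FALSE)

  key_levels <- sort(unique(samples$key), method = "radix")  # locale-free
  counts <- table(factor(samples$key, levels = key_levels),
                  factor(samples$event, EVENT_TYPES))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(key_levels, EVENT_TYPES))

  samples <- reservoir_trim(samples, bin_cap, bin_seed)

  # pass counts via read-name grouping
  qn <- aln$qname[used]
  mol <- sub(name_regex, "\\1", qn)
  mol[!grepl(name_regex, qn)] <- qn[!grepl(name_regex, qn)]
  pass_counts <- as.integer(table(mol))

  model <- structure(list(
    flank_width = as.integer(flank_width),
    hp_cap = as.integer(hp_cap),
    bin_cap = as.integer(bin_cap),
    schema = schema,
    counts = counts,
    samples = samples,
    fragment_lengths = frag_lens[used],
    pass_counts = pass_counts,
    adapter = toupper(adapter),
    metadata = list(
      format_version = MODEL_FORMAT_VERSION,
      sources = src,
      n_records_in = n_in,
      n_records_used = sum(used),
      n_records_filtered = n_in - nrow(aln) + n_short,
      n_spans = sum(counts),
      n_spans_skipped = n_skipped_spans,
      aligned_bases = aligned_bases,
      name_regex = name_regex,
      min_len = as.integer(min_len),
      min_mapq = as.integer(min_mapq),
      bin_seed = as.integer(bin_seed),
      note = "features are learned from every usable alignment record (all passes of a molecule)",
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "ekmer_model")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-(key, event) reservoir: keeps at most `cap` records per
# bin, chosen with a private RNG seeded from the bin identity, then returns
# the samples in canonical (key, event, original) order.
reservoir_trim <- function(samples, cap, bin_seed = 0L) {
  g <- paste(samples$key, samples$event, sep = "\1")
  sizes <- table(g)
  over <- names(sizes)[sizes > cap]
  keep <- rep(TRUE, nrow(samples))
  for (gg in over) {
    idx <- which(g == gg)
    sel <- with_local_seed(string_seed(gg, bin_seed),
                           sample(length(idx), cap))
    keep[idx[-sort(sel)]] <- FALSE
  }
  out <- samples[keep, , drop = FALSE]
  ord <- order(out$key, match(out$event, EVENT_TYPES), method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-key event frequency matrix (rows sum to 1)
model_frequencies <- function(model) {
  f <- model$counts / rowSums(model$counts)
  f[is.nan(f)] <- 0
  f
}

#' Merge empirical models from multiple runs
#'
#' Run-to-run variation can be captured by training one model per
#' sequencing run and merging. Event counts and distributions are summed or
#' concatenated; emission bins are concatenated and re-reservoired at the
#' first model's bin capacity. All inputs must share flank width,
#' homopolymer cap, and feature schema.
#'
#' @param ... `ekmer_model` objects (or a single list of them).
#' @return A merged `ekmer_model`.
#' @export
merge_models <- function(...) {
  models <- list(...)
  if (length(models) == 1L && !inherits(models[[1L]], "ekmer_model"))
    models <- models[[1L]]
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, TRUE, "ekmer_model")))
  m1 <- models[[1L]]
  for (m in models[-1L]) {
    for (fld in c("flank_width", "hp_cap", "schema")) {
      if (!identical(m[[fld]], m1[[fld]]))
        stop("cannot merge models with differing ", fld)
    }
  }
  if (length(models) == 1L) return(m1)
  all_keys <- sort(unique(unlist(lapply(models, function(m) rownames(m$counts)))),
                   method = "radix")
  counts <- matrix(0L, length(all_keys), length(EVENT_TYPES),
                   dimnames = list(all_keys, EVENT_TYPES))
  for (m in models)
    counts[rownames(m$counts), ] <- counts[rownames(m$counts), ] + m$counts
  samples <- do.call(rbind, lapply(models, `[[`, "samples"))
  samples <- reservoir_trim(samples, m1$bin_cap, m1$metadata$bin_seed %||% 0L)
  out <- m1
  out$counts <- counts
  out$samples <- samples
  out$fragment_lengths <- unlist(lapply(models, `[[`, "fragment_lengths"),
                                 use.names = FALSE)
  out$pass_counts <- unlist(lapply(models, `[[`, "pass_counts"),
                            use.names = FALSE)
  out$metadata$sources <- unlist(lapply(models, function(m) m$metadata$sources))
  out$metadata$n_records_used <-
    as.integer(sum(vapply(models, function(m) m$metadata$n_records_used, 1)))
  out$metadata$aligned_bases <-
    sum(vapply(models, function(m) m$metadata$aligned_bases, 1))
  out$metadata$n_spans <- sum(counts)
  out$metadata$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  out
}

# canonical JSON serialization (used by write_model and model hashing)
model_to_json <- function(model) {
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    generator = "ekmersim",
    flank_width = model$flank_width,
    hp_cap = model$hp_cap,
    bin_cap = model$bin_cap,
    schema = model$schema,
    adapter = model$adapter,
    keys = rownames(model$counts),
    event_names = colnames(model$counts),
    counts = as.integer(model$counts),
    samples = as.list(model$samples),
    fragment_lengths = model$fragment_lengths,
    pass_counts = model$pass_counts,
    metadata = model$metadata
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Serialize / restore an empirical model
#'
#' Models round-trip bit-exactly through a versioned single-file JSON
#' archive. `read_model()` refuses to load an archive written by a newer
#' major format version.
#'
#' @param model An `ekmer_model`.
#' @param path File path (conventionally `.ekm`).
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the restored `ekmer_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ekmer_model"))
  writeLines(model_to_json(model), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  p <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                error = function(e) stop("corrupt model file: ", path,
                                         " (", conditionMessage(e), ")"))
  if (is.null(p$format_version))
    stop("not an ekmersim model archive: ", path)
  major <- as.integer(strsplit(as.character(p$format_version), ".",
                               fixed = TRUE)[[1]][1])
  have <- as.integer(strsplit(MODEL_FORMAT_VERSION, ".", fixed = TRUE)[[1]][1])
  if (is.na(major) || major > have)
    stop("model format version ", p$format_version,
         " is newer than supported (", MODEL_FORMAT_VERSION, ")")
  counts <- matrix(as.integer(p$counts), nrow = length(p$keys),
                   dimnames = list(p$keys, p$event_names))
  samples <- as.data.frame(lapply(p$samples, as.character),
                           stringsAsFactors = FALSE)
  if (nrow(samples) == 0L && length(p$samples))
    samples <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(p$samples)), names(p$samples)))
  md <- p$metadata
  int_fields <- c("n_records_in", "n_records_used", "n_records_filtered",
                  "n_spans", "n_spans_skipped", "min_len", "min_mapq",
                  "bin_seed")
  for (fld in intersect(names(md), int_fields)) md[[fld]] <- as.integer(md[[fld]])
  if (!is.null(md$aligned_bases)) md$aligned_bases <- as.numeric(md$aligned_bases)
  structure(list(
    flank_width = as.integer(p$flank_width),
    hp_cap = as.integer(p$hp_cap),
    bin_cap = as.integer(p$bin_cap),
    schema = as.character(p$schema),
    counts = counts,
    samples = samples,
    fragment_lengths = as.integer(p$fragment_lengths),
    pass_counts = as.integer(p$pass_counts),
    adapter = as.character(p$adapter),
    metadata = md
  ), class = "ekmer_model")
}

# stable content hash of a model (md5 of its canonical JSON)
model_hash <- function(model) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(model_to_json(model), tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}
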