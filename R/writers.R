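# Output writers: FASTQ (Phred+33), unaligned tagged SAM/BAM following the
# documented PacBio per-base tag conventions, and a BED + TSV ground-truth
# pair for downstream evaluation. Writers are registered behind one
# interface so additional formats slot in without touching the simulator.

#' Write simulated reads as FASTQ
#'
#' Standard four-line FASTQ with the per-base quality feature as the
#' quality string (Phred+33). Requires the model schema to include `qv`.
#'
#' @param sim An `ekmer_sim` (or a list of `simulated_read`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  reads <- sim_read_list(sim)
  lines <- character(0)
  if (length(reads)) {
    if (is.null(reads[[1]]$features$qv))
      stop("feature schema has no qv; train with schema='qv' or 'pacbio' to write FASTQ")
    ids <- vapply(reads, `[[`, "", "id")
    seqs <- vapply(reads, `[[`, "", "seq")
    quals <- vapply(reads, function(r) r$features$qv, "")
    stopifnot(all(nchar(seqs) == nchar(quals)))
    lines <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

sim_read_list <- function(sim) {
  if (inherits(sim, "ekmer_sim")) sim$reads
  else if (inherits(sim, "simulated_read")) list(sim)
  else sim
}

# SAM text for a simulated read set: unaligned records (flag 4) carrying
# per-base features as PacBio-convention tags (iq/dq/dt/mq/sq/st, ip as a
# uint16 frame-count array), plus pass structure:
#   np:i  number of passes
#   sd:Z  pass strands, e.g. "+-+"
#   ps:B:I  flattened pass intervals (start1,end1,start2,...)
#   za:B:I  flattened adapter intervals
# The header records the simulator, model fingerprint, and seed.
sim_to_sam <- function(sim) {
  reads <- sim_read_list(sim)
  hash <- if (inherits(sim, "ekmer_sim")) sim$model_hash else NA
  seed <- if (inherits(sim, "ekmer_sim")) sim$seed else NA
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@PG\tID:ekmersim\tPN:ekmersim\tVN:",
                  as.character(utils::packageVersion("ekmersim"))),
           paste0("@CO\tmodel_md5:", hash, "\tseed:", seed),
           "@CO\tper-base tags: iq/dq/mq/sq Phred+33, dt/st base tags, ip uint16 frames; pass structure: np/sd/ps/za")
  recs <- vapply(reads, function(r) {
    qual <- r$features$qv %||% strrep("!", nchar(r$seq))
    tags <- c(sprintf("np:i:%d", nrow(r$passes)),
              sprintf("sd:Z:%s", paste(r$passes$strand, collapse = "")),
              sprintf("ps:B:I,%s", paste(rbind(r$passes$start, r$passes$end),
                                         collapse = ",")))
    if (nrow(r$adapters) > 0L)
      tags <- c(tags, sprintf("za:B:I,%s",
                              paste(rbind(r$adapters$start, r$adapters$end),
                                    collapse = ",")))
    for (tg in c("iq", "dq", "mq", "sq", "dt", "st")) {
      v <- r$features[[tg]]
      if (!is.null(v) && nzchar(v)) tags <- c(tags, sprintf("%s:Z:%s", tg, v))
    }
    ip <- r$features$ip
    if (!is.null(ip) && nzchar(ip)) {
      vals <- pmin(pmax(as.integer(strsplit(ip, ",", fixed = TRUE)[[1]]), 0L),
                   65535L)
      tags <- c(tags, sprintf("ip:B:S,%s", paste(vals, collapse = ",")))
    }
    paste(c(r$id, "4", "*", "0", "0", "*", "*", "0", "0", r$seq, qual, tags),
          collapse = "\t")
  }, "")
  c(hdr, recs)
}

#' Write simulated reads as an unaligned tagged SAM or BAM
#'
#' Unaligned records (flag 4) with per-base features as PacBio-convention
#' auxiliary tags (`iq`, `dq`, `dt`, `mq`, `sq`, `st`, `ip` as uint16
#' frame counts) and the multi-pass structure as `np` (pass count), `sd`
#' (pass strands), `ps`/`za` (pass / adapter interval arrays). The header
#' records the simulator version, model fingerprint, and seed.
#'
#' @param sim An `ekmer_sim` (or list of `simulated_read`).
#' @param path Output path (`.bam` for [write_tagged_bam()]).
#' @return The written path, invisibly.
#' @export
write_tagged_sam <- function(sim, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sim_to_sam(sim), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tagged_sam
#' @export
write_tagged_bam <- function(sim, path) {
  tf <- tempfile(fileext = ".sam")
  on.exit(unlink(tf))
  write_tagged_sam(sim, tf)
  dest <- sub("\\.bam$", "", path)
  out <- Rsamtools::asBam(tf, destination = dest, overwrite = TRUE,
                          indexDestination = FALSE)
  invisible(out)
}

#' Write ground truth for a simulated read set
#'
#' Emits a BED-compatible file (`contig`, `start`, `end`, read id, pass
#' count, strand of the first pass) sorted by contig and start, plus a
#' tab-delimited sidecar (`<path>.events.tsv`) with per-read event summary
#' counts (match/insertion/deletion/substitution over all passes).
#'
#' @param sim An `ekmer_sim` (or list of `simulated_read`).
#' @param path Output BED path.
#' @param sidecar Optional sidecar path (default `<path>.events.tsv`).
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path, sidecar = paste0(path, ".events.tsv")) {
  reads <- sim_read_list(sim)
  df <- data.frame(
    contig = vapply(reads, function(r) r$truth$contig, ""),
    start = vapply(reads, function(r) r$truth$start, 1L),
    end = vapply(reads, function(r) r$truth$end, 1L),
    id = vapply(reads, `[[`, "", "id"),
    np = vapply(reads, function(r) nrow(r$passes), 1L),
    strand = vapply(reads, function(r) r$truth$strand, ""),
    stringsAsFactors = FALSE)
  ev <- t(vapply(reads, function(r) {
    tot <- stats::setNames(numeric(4), EVENT_TYPES)
    for (el in r$event_log) {
      t <- table(factor(el$event[!el$is_n], levels = EVENT_TYPES))
      tot <- tot + as.numeric(t)
    }
    tot
  }, numeric(4)))
  ord <- order(df$contig, df$start, df$id, method = "radix")
  con <- file(path, "wb")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     df$contig[ord], df$start[ord], df$end[ord],
                     df$id[ord], df$np[ord], df$strand[ord]),
             con, useBytes = TRUE)
  close(con)
  side <- data.frame(id = df$id, df[c("contig", "start", "end", "np", "strand")],
                     match = as.integer(ev[, 1]), insertion = as.integer(ev[, 2]),
                     deletion = as.integer(ev[, 3]),
                     substitution = as.integer(ev[, 4]))[ord, ]
  con2 <- file(sidecar, "wb")
  writeLines(c(paste(names(side), collapse = "\t"),
               do.call(sprintf, c(list("%s\t%s\t%d\t%d\t%d\t%s\t%d\t%d\t%d\t%d"),
                                  side))), con2, useBytes = TRUE)
  close(con2)
  invisible(path)
}
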