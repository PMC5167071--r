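# Shared low-level helpers: alphabets, Phred string codecs, seeded-RNG scopes.

EVENT_TYPES <- c("MATCH", "INSERTION", "DELETION", "SUBSTITUTION")
DNA_BASES <- c("A", "C", "G", "T")
PAD_CHAR <- "."
PHRED_MAX <- 93L

#' Event type vocabulary
#'
#' The four alignment-derived event classes recorded per sequencing context:
#' `MATCH`, `INSERTION`, `DELETION`, `SUBSTITUTION`. Exactly one event is
#' assigned to each homopolymer context spanned by an alignment.
#'
#' @return Character vector of the four event names, in canonical order.
#' @export
#' @examples
#' event_types()
event_types <- function() EVENT_TYPES

#' Reverse-complement a DNA string
#'
#' Plain-character reverse complement over the `A/C/G/T/N` alphabet (the
#' boundary padding character `.` maps to itself).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn.", "TGCANtgcan.", x)
  vapply(comp, function(s) {
    if (!nzchar(s)) return(s)
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# integer Phred values -> printable Phred+33 string (capped at 93)
phred_string <- function(q) {
  if (length(q) == 0L) return("")
  intToUtf8(pmin(pmax(as.integer(round(q)), 0L), PHRED_MAX) + 33L)
}

# Phred+33 string -> integer vector
phred_values <- function(s) {
  if (!nzchar(s)) return(integer(0))
  utf8ToInt(s) - 33L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps deterministic internals (e.g.
# reservoir sampling) from consuming or clobbering the user's RNG stream.
with_local_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a string (djb2 mod a Mersenne prime); used to
# derive per-context reservoir seeds so learning is a pure function.
string_seed <- function(x, salt = 0L) {
  vapply(x, function(s) {
    h <- 5381
    for (cc in utf8ToInt(s)) h <- (h * 33 + cc) %% 2147483647
    as.integer((h + as.numeric(salt)) %% 2147483647)
  }, integer(1), USE.NAMES = FALSE)
}

# Split a scalar string into single characters.
str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Resolve a reference/target argument into a named character vector of
# uppercase sequences. Accepts a named character vector, a Biostrings
# DNAStringSet, or a path to a FASTA file.
as_ref_set <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      !grepl("^[ACGTNacgtn.]+$", reference) && file.exists(reference)) {
    x <- Biostrings::readDNAStringSet(reference)
    refs <- toupper(as.character(x))
    names(refs) <- sub("\\s.*$", "", names(x))
    return(refs)
  }
  if (inherits(reference, "DNAStringSet")) {
    refs <- toupper(as.character(reference))
    names(refs) <- sub("\\s.*$", "", names(reference))
    return(refs)
  }
  if (is.character(reference)) {
    refs <- toupper(reference)
    if (is.null(names(refs))) {
      names(refs) <- if (length(refs) == 1L) "ref" else paste0("ref", seq_along(refs))
    }
    return(refs)
  }
  stop("reference must be a named character vector, DNAStringSet, or FASTA path")
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}
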