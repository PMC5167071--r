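# Extended-k-mer (EKmer) contexts and the homopolymer-aware tokenizer.
#
# An EKmer describes the sequencing context of a maximal homopolymer run:
# the run base, the run length, and f flanking bases on each side. Ordinary
# k-mers collapse all homopolymers longer than k; EKmers keep the run length
# as an explicit coordinate, so contexts like CG T^5 AC and CG T^9 AC stay
# distinct no matter how long the run is.

#' Construct an extended-k-mer context
#'
#' An EKmer is a central homopolymer run (base identity and length) plus
#' fixed-width flanking sequences on both sides. Flanks never extend the
#' central run: the innermost flank base on each side must differ from the
#' run base, except where the reserved boundary padding character `.`
#' appears (contexts at sequence boundaries keep shorter real flanks, padded
#' with `.`).
#'
#' @param hp_base Run base, one of `A`, `C`, `G`, `T`, `N`.
#' @param hp_length Run length, integer `>= 1`.
#' @param left_flank,right_flank Flank strings of equal length over
#'   `A/C/G/T/N` plus the padding character `.`.
#' @param capped Logical; `TRUE` marks a model-key bucket meaning
#'   "run length greater than `hp_length`" (see `hp_cap` in
#'   [learn_error_model()]).
#' @return An object of class `ekmer`.
#' @seealso [encode_ekmer()], [decode_ekmer()], [tokenize()]
#' @export
#' @examples
#' ekmer("T", 5, "CG", "AC")
ekmer <- function(hp_base, hp_length, left_flank, right_flank, capped = FALSE) {
  hp_base <- toupper(hp_base)
  if (!hp_base %in% c(DNA_BASES, "N"))
    stop("hp_base must be one of A, C, G, T, N")
  hp_length <- as.integer(hp_length)
  if (is.na(hp_length) || hp_length < 1L) stop("hp_length must be >= 1")
  left_flank <- toupper(left_flank); right_flank <- toupper(right_flank)
  if (nchar(left_flank) != nchar(right_flank))
    stop("left and right flanks must have equal length")
  ok <- function(s) !nzchar(s) || grepl("^[ACGTN.]+$", s)
  if (!ok(left_flank) || !ok(right_flank))
    stop("flanks may only contain A, C, G, T, N and the padding character '.'")
  lc <- substr(left_flank, nchar(left_flank), nchar(left_flank))
  rc <- substr(right_flank, 1L, 1L)
  if (nzchar(left_flank) && lc == hp_base)
    stop("innermost left flank base must not equal hp_base")
  if (nzchar(right_flank) && rc == hp_base)
    stop("innermost right flank base must not equal hp_base")
  structure(list(hp_base = hp_base, hp_length = hp_length,
                 left_flank = left_flank, right_flank = right_flank,
                 capped = isTRUE(capped)),
            class = "ekmer")
}

#' @export
print.ekmer <- function(x, ...) {
  cat("<ekmer> ", encode_ekmer(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.ekmer <- function(x, ...) encode_ekmer(x)

# Vectorized key encoder used throughout the package. `cap` collapses run
# lengths above the cap into one ">cap" bucket.
encode_key <- function(hp_base, hp_length, left, right, cap = Inf) {
  over <- hp_length > cap
  tok <- ifelse(over, paste0(">", cap), as.character(hp_length))
  ifelse(hp_length == 1L & !over,
         paste0(left, hp_base, right),
         paste0(left, hp_base, "^", tok, right))
}

#' Encode an EKmer as its canonical string key
#'
#' The encoding is `left` + `base` + (`^length` when the run is longer than
#' one base, with `^>L` for capped buckets) + `right`; a run of length one
#' uses the plain k-mer form, which is unambiguous because the flank width
#' is recoverable from the total string length. `decode_ekmer()` inverts it
#' exactly.
#'
#' @param x An [ekmer()] object.
#' @return A single string, e.g. `"CGT^5AC"` or `"GTACG"`.
#' @export
#' @examples
#' encode_ekmer(ekmer("T", 5, "CG", "AC"))  # "CGT^5AC"
#' decode_ekmer("GTACG")
encode_ekmer <- function(x) {
  stopifnot(inherits(x, "ekmer"))
  if (x$capped)
    paste0(x$left_flank, x$hp_base, "^>", x$hp_length, x$right_flank)
  else
    encode_key(x$hp_base, x$hp_length, x$left_flank, x$right_flank)
}

#' @rdname encode_ekmer
#' @param key A string produced by `encode_ekmer()`.
#' @export
decode_ekmer <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  if (grepl("^", key, fixed = TRUE)) {
    m <- regexec("^([ACGTN.]*)([ACGTN])\\^(>?)([0-9]+)([ACGTN.]*)$", key)
    g <- regmatches(key, m)[[1]]
    if (length(g) == 0L) stop("malformed EKmer encoding: '", key, "'")
    left <- g[2]; base <- g[3]; gt <- g[4]; len <- as.integer(g[5]); right <- g[6]
    if (nchar(left) != nchar(right))
      stop("malformed EKmer encoding (unequal flanks): '", key, "'")
    ekmer(base, len, left, right, capped = gt == ">")
  } else {
    n <- nchar(key)
    if (n < 1L || n %% 2L == 0L)
      stop("malformed EKmer encoding (even length, no run marker): '", key, "'")
    f <- (n - 1L) %/% 2L
    ekmer(substr(key, f + 1L, f + 1L), 1L,
          substr(key, 1L, f), substr(key, f + 2L, n))
  }
}

#' Tokenize a DNA sequence into extended-k-mer steps
#'
#' Partitions a sequence into its maximal homopolymer runs and annotates
#' each run with `flank_width` bases of true flanking sequence on each side.
#' Flanks that would extend past the sequence boundary are padded with the
#' reserved character `.` so that boundary contexts form their own bins and
#' the partition property stays exact. Runs of `N` are tokenized like any
#' other base but flagged via `hp_base == "N"` so downstream consumers can
#' skip them.
#'
#' @param sequence A single DNA string over `A/C/G/T/N` (case-insensitive).
#' @param flank_width Number of flanking bases per side, integer `>= 1`
#'   (default 3, i.e. 7-mer-wide contexts for single-base runs).
#' @return A data frame of class `ekmer_steps` with one row per run:
#'   `hp_base`, `hp_length`, `left_flank`, `right_flank`, and 0-based
#'   half-open coordinates `ref_start`, `ref_end` of the run within the
#'   input. Concatenating the runs reproduces the input exactly.
#' @export
#' @examples
#' tokenize("GTACGTTTTTAC", flank_width = 2)
tokenize <- function(sequence, flank_width = 3L) {
  stopifnot(length(sequence) == 1L)
  f <- as.integer(flank_width)
  if (is.na(f) || f < 1L) stop("flank_width must be an integer >= 1")
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (n < 1L) stop("cannot tokenize an empty sequence")
  chars <- str_chars(s)
  bad <- which(!chars %in% c(DNA_BASES, "N"))
  if (length(bad))
    stop(sprintf("invalid character '%s' at offset %d", chars[bad[1]], bad[1] - 1L))
  r <- rle(chars)
  ends <- cumsum(r$lengths)                 # 1-based inclusive run ends
  starts <- ends - r$lengths + 1L           # 1-based run starts
  padded <- paste0(strrep(PAD_CHAR, f), s, strrep(PAD_CHAR, f))
  # original position i sits at padded position i + f
  left <- substring(padded, starts, starts + f - 1L)
  right <- substring(padded, ends + f + 1L, ends + 2L * f)
  out <- data.frame(hp_base = r$values,
                    hp_length = r$lengths,
                    left_flank = left,
                    right_flank = right,
                    ref_start = starts - 1L,
                    ref_end = ends,
                    stringsAsFactors = FALSE)
  attr(out, "flank_width") <- f
  class(out) <- c("ekmer_steps", "data.frame")
  out
}

#' Canonical key strings for tokenizer steps
#'
#' Vectorized [encode_ekmer()] over the rows of a [tokenize()] result,
#' optionally collapsing run lengths above `cap` into the `>cap` bucket
#' used for model keys.
#'
#' @param steps An `ekmer_steps` data frame from [tokenize()].
#' @param cap Run-length cap (default none).
#' @return Character vector of context keys, one per step.
#' @export
#' @examples
#' step_keys(tokenize("GTACGTTTTTAC", 2))
step_keys <- function(steps, cap = Inf) {
  encode_key(steps$hp_base, steps$hp_length, steps$left_flank,
             steps$right_flank, cap = cap)
}

#' Number of representable interior EKmer contexts
#'
#' Counts distinct EKmers for a flank width `f` and run lengths up to `L`,
#' ignoring boundary padding: 4 choices of run base, `L` run lengths, 3
#' choices for each innermost flank base (anything but the run base), and 4
#' for every remaining flank position — `4 * L * 9 * 4^(2(f-1))`.
#'
#' @param flank_width Flank width `f >= 1`.
#' @param max_hp_length Maximum run length `L >= 1`.
#' @return Number of distinct interior contexts.
#' @export
#' @examples
#' context_count(1, 1)  # 36
#' context_count(3, 1)  # 9216 seven-base-wide contexts
context_count <- function(flank_width, max_hp_length) {
  f <- as.integer(flank_width); L <- as.integer(max_hp_length)
  if (is.na(f) || f < 1L) stop("flank_width must be >= 1")
  if (is.na(L) || L < 1L) stop("max_hp_length must be >= 1")
  4 * L * 9 * 4^(2 * (f - 1))
}
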