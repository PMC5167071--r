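# Model learning: parameter recovery, determinism, merging, serialization.

test_that("learning recovers the generator's event rates within 3 sigma", {
  ref <- make_reference(30000, seed = 51)
  fx <- make_corrupted_reads(ref, fixture_spec(
    n_reads = 300, seed = 52, fragment_lengths = 800L, flank_width = 2,
    rates = c(ins = 0.02, del = 0.05, sub = 0.01)))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  n <- sum(m$counts)
  freq <- coef(m)
  for (pair in list(c("insertion", 0.02), c("deletion", 0.05),
                    c("substitution", 0.01))) {
    p <- as.numeric(pair[2])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(freq[[pair[1]]] - p), 3 * se)
  }
  # conservation: spans held = spans counted
  expect_equal(sum(m$counts), m$metadata$n_spans)
  # per-key frequencies sum to 1
  f <- ekmersim:::model_frequencies(m)
  expect_equal(unname(rowSums(f)), rep(1, nrow(f)))
})

test_that("error-free training yields an all-match model", {
  ref <- make_reference(5000, seed = 61)
  m <- perfect_model(ref, n_reads = 40, seed = 62)
  expect_equal(sum(m$counts[, c("INSERTION", "DELETION", "SUBSTITUTION")]), 0L)
  expect_true(all(m$samples$event == "MATCH"))
  # every match emission equals its context's central run
  kk <- lapply(m$samples$key, decode_ekmer)
  expect_equal(m$samples$emitted,
               vapply(kk, function(k) strrep(k$hp_base, k$hp_length), ""))
})

test_that("learning is deterministic and independent of the caller's RNG", {
  ref <- make_reference(6000, seed = 71)
  fx <- make_corrupted_reads(ref, fixture_spec(n_reads = 40, seed = 72,
                                               fragment_lengths = 500L))
  set.seed(1); m1 <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  set.seed(999); m2 <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  m1$metadata$created <- m2$metadata$created <- NULL
  expect_identical(m1, m2)
})

test_that("learning from SAM and BAM files matches the in-memory route", {
  ref <- make_reference(4000, seed = 81)
  fx <- make_corrupted_reads(ref, fixture_spec(n_reads = 25, seed = 82,
                                               fragment_lengths = 400L))
  sam <- tempfile(fileext = ".sam")
  ekmersim:::write_sam(fx$alignments, fx$reference, sam)
  m_mem <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  m_sam <- learn_error_model(sam, fx$reference, flank_width = 2)
  expect_equal(m_sam$counts, m_mem$counts)
  # the SAM route coordinate-sorts records, so compare bins order-free
  canon <- function(s) { s <- s[do.call(order, c(s, list(method = "radix"))), ]
                         rownames(s) <- NULL; s }
  expect_equal(canon(m_sam$samples), canon(m_mem$samples))
  expect_equal(sort(m_sam$fragment_lengths), sort(m_mem$fragment_lengths))
  # and via an indexed BAM produced by Rsamtools
  bam <- Rsamtools::asBam(sam, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  m_bam <- learn_error_model(bam, fx$reference, flank_width = 2)
  expect_equal(m_bam$counts, m_mem$counts)
})

test_that("pass counts are learned from subread-style read names", {
  ref <- make_reference(20000, seed = 91)
  fx <- make_corrupted_reads(ref, fixture_spec(
    n_reads = 120, seed = 92, fragment_lengths = 400L,
    pass_counts = c(2L, 4L), pass_probs = c(0.5, 0.5)))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  expect_true(all(m$pass_counts %in% c(2L, 4L)))
  expect_gt(length(m$pass_counts), 20)
  # names that do not match the convention degenerate to single-pass
  aln2 <- fx$alignments
  aln2$qname <- paste0("plain_read_", seq_len(nrow(aln2)))
  m2 <- learn_error_model(aln2, fx$reference, flank_width = 2)
  expect_true(all(m2$pass_counts == 1L))
})

test_that("mapping-quality, length and flag filters drop records", {
  ref <- make_reference(4000, seed = 101)
  fx <- make_corrupted_reads(ref, fixture_spec(n_reads = 20, seed = 102,
                                               fragment_lengths = 400L))
  aln <- fx$alignments
  aln$mapq[1:5] <- 0L
  aln$flag[6] <- 4L      # unmapped
  aln$flag[7] <- 256L    # secondary
  m <- learn_error_model(aln, fx$reference, flank_width = 2)
  expect_equal(m$metadata$n_records_used, nrow(aln) - 7L)
  expect_error(learn_error_model(aln[0, ], fx$reference, flank_width = 2),
               "no alignment records")
  aln$rname <- "chrMissing"
  expect_error(learn_error_model(aln, fx$reference, flank_width = 2),
               "chrMissing")
})

test_that("the reservoir caps bin sizes while keeping exact counts", {
  ref <- make_reference(20000, seed = 111)
  fx <- make_corrupted_reads(ref, fixture_spec(n_reads = 120, seed = 112,
                                               fragment_lengths = 600L,
                                               flank_width = 1))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 1,
                         bin_cap = 50L)
  g <- paste(m$samples$key, m$samples$event)
  expect_lte(max(table(g)), 50L)
  # counts stay exact (match the untruncated model's counts)
  m_full <- learn_error_model(fx$alignments, fx$reference, flank_width = 1)
  expect_equal(m$counts, m_full$counts)
  expect_gt(sum(m_full$counts), sum(table(g) > 0) * 1)
})

test_that("merging models equals learning on the union of inputs", {
  ref <- make_reference(15000, seed = 121)
  fx1 <- make_corrupted_reads(ref, fixture_spec(n_reads = 60, seed = 122,
                                                fragment_lengths = 500L))
  fx2 <- make_corrupted_reads(ref, fixture_spec(n_reads = 60, seed = 123,
                                                fragment_lengths = 500L,
                                                movie = "fixb"))
  m1 <- learn_error_model(fx1$alignments, fx1$reference, flank_width = 2)
  m2 <- learn_error_model(fx2$alignments, fx2$reference, flank_width = 2)
  mu <- learn_error_model(rbind(fx1$alignments, fx2$alignments),
                          fx1$reference, flank_width = 2)
  mm <- merge_models(m1, m2)
  expect_equal(mm$counts, mu$counts)
  expect_equal(sort(mm$fragment_lengths), sort(mu$fragment_lengths))
  expect_equal(sort(mm$pass_counts), sort(mu$pass_counts))
  # identity and additivity
  expect_identical(merge_models(m1), m1)
  k <- rownames(m1$counts)[1]
  expect_equal(mm$counts[k, ],
               m1$counts[k, ] + (if (k %in% rownames(m2$counts))
                 m2$counts[k, ] else rep(0L, 4)))
  # incompatible configurations refuse to merge
  m3 <- learn_error_model(fx2$alignments, fx2$reference, flank_width = 3)
  expect_error(merge_models(m1, m3), "flank_width")
})

test_that("models round-trip through serialization exactly", {
  ref <- make_reference(8000, seed = 131)
  fx <- make_corrupted_reads(ref, fixture_spec(n_reads = 50, seed = 132,
                                               fragment_lengths = 500L,
                                               features = "pacbio"))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 2,
                         schema = "pacbio")
  p <- tempfile(fileext = ".ekm")
  write_model(m, p)
  m2 <- read_model(p)
  expect_identical(m, m2)
  # canonical serialization is stable: re-serializing gives the same bytes
  p2 <- tempfile(fileext = ".ekm")
  write_model(m2, p2)
  expect_equal(unname(tools::md5sum(p)), unname(tools::md5sum(p2)))
  # version guard
  j <- readLines(p)
  writeLines(sub("\"format_version\":\"1.0\"", "\"format_version\":\"2.0\"", j), p2)
  expect_error(read_model(p2), "newer")
  expect_error(read_model(tempfile()), "not found")
  writeLines("not json at all {", p2)
  expect_error(read_model(p2), "corrupt")
})

test_that("a homopolymer under deletion-only corruption learns the binomial law", {
  # reference salted with many isolated T6 runs; per-base deletion at d
  d <- 0.05
  set.seed(141)
  forced <- data.frame(offset = seq(20, 59920, by = 40), base = "T", length = 6)
  ref <- make_reference(60000, seed = 142, forced_runs = forced)
  fx <- make_corrupted_reads(ref, fixture_spec(
    n_reads = 450, seed = 143, mode = "per_base",
    rates = c(del = d), fragment_lengths = 1000L, flank_width = 2))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  tr <- homopolymer_transition(m, "T", 6)
  obs_n <- sum(m$counts[grepl("T\\^6", rownames(m$counts)), ])
  counts <- round(tr * obs_n)
  probs <- dbinom(as.integer(names(tr)), 6, 1 - d)
  expect_gt(chisq_gof(counts, probs), 0.01)
})
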