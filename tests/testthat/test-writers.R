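# Output writers: FASTQ, tagged SAM/BAM, truth BED + sidecar.

sim_fixture <- function(seed = 61, n = 15, schema = "qv", np = c(1L, 2L, 3L)) {
  ref <- make_reference(8000, seed = seed)
  fx <- make_corrupted_reads(ref, fixture_spec(
    n_reads = 60, seed = seed + 1, fragment_lengths = 500L,
    flank_width = 2, features = schema))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 2,
                         schema = schema)
  list(model = m, ref = c(chr1 = ref),
       sim = simulate_reads(m, c(chr1 = ref), nreads = n, seed = seed + 2,
                            pass_counts = np))
}

test_that("FASTQ encoding is exact for a known read", {
  rd <- structure(list(id = "sim/1/0_4", seq = "ACGT",
                       features = list(qv = ekmersim:::phred_string(rep(30, 4))),
                       passes = data.frame(start = 0L, end = 4L, strand = "+",
                                           cigar = "4M"),
                       adapters = data.frame(start = integer(0), end = integer(0)),
                       truth = list(contig = "c", start = 0L, end = 4L,
                                    strand = "+", truncated = FALSE),
                       event_log = list()), class = "simulated_read")
  fq <- tempfile(fileext = ".fastq")
  write_fastq(list(rd), fq)
  expect_identical(readLines(fq), c("@sim/1/0_4", "ACGT", "+", "????"))
})

test_that("empty read sets give valid empty outputs", {
  fq <- tempfile(fileext = ".fastq")
  write_fastq(list(), fq)
  expect_true(file.exists(fq))
  expect_equal(length(readLines(fq)), 0L)
  tr <- tempfile()
  write_truth(list(), tr)
  expect_equal(length(readLines(tr)), 0L)
})

test_that("FASTQ round-trips through an independent parser", {
  sf <- sim_fixture()
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sf$sim, fq)
  x <- Biostrings::readDNAStringSet(fq, format = "fastq", with.qualities = TRUE)
  expect_equal(length(x), length(sf$sim$reads))
  seqs <- vapply(sf$sim$reads, `[[`, "", "seq")
  quals <- vapply(sf$sim$reads, function(r) r$features$qv, "")
  expect_equal(unname(as.character(x)), seqs)
  expect_equal(unname(as.character(S4Vectors::mcols(x)$qualities)), quals)
  expect_equal(names(x), vapply(sf$sim$reads, `[[`, "", "id"))
})

test_that("tagged BAM round-trips reads, qualities and pass structure", {
  sf <- sim_fixture(seed = 71, schema = "pacbio")
  bam <- write_tagged_bam(sf$sim, tempfile(fileext = ".bam"))
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq", "qual"),
    tag = c("np", "sd", "ps", "za", "iq", "dq", "dt", "mq", "sq", "st", "ip")))[[1]]
  n <- length(sf$sim$reads)
  expect_equal(length(res$qname), n)
  expect_true(all(res$flag == 4L))
  for (i in seq_len(n)) {
    rd <- sf$sim$reads[[i]]
    j <- match(rd$id, res$qname)
    expect_equal(as.character(res$seq[j]), rd$seq)
    expect_equal(as.character(res$qual[j]), rd$features$qv)
    expect_equal(res$tag$np[j], nrow(rd$passes))
    expect_equal(res$tag$sd[j], paste(rd$passes$strand, collapse = ""))
    expect_equal(as.integer(res$tag$ps[[j]]),
                 as.integer(rbind(rd$passes$start, rd$passes$end)))
    if (nrow(rd$adapters) > 0)
      expect_equal(as.integer(res$tag$za[[j]]),
                   as.integer(rbind(rd$adapters$start, rd$adapters$end)))
    # per-base tags have one value per basecall, byte-for-byte
    nb <- nchar(rd$seq)
    for (tg in c("iq", "dq", "dt", "mq", "sq", "st")) {
      expect_equal(nchar(res$tag[[tg]][j]), nb)
      expect_identical(res$tag[[tg]][j], rd$features[[tg]])
    }
    expect_equal(length(res$tag$ip[[j]]), nb)
    expect_equal(as.integer(res$tag$ip[[j]]),
                 as.integer(strsplit(rd$features$ip, ",")[[1]]))
  }
})

test_that("qv-only models emit qualities but no per-base optional tags", {
  sf <- sim_fixture(seed = 81, schema = "qv", np = 1L)
  bam <- write_tagged_bam(sf$sim, tempfile(fileext = ".bam"))
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qual"), tag = c("iq", "ip")))[[1]]
  expect_true(all(vapply(res$tag$iq, is.null, TRUE)) || is.null(res$tag$iq))
  expect_false(any(as.character(res$qual) == "*"))
})

test_that("truth BED lines, sorting and conservation hold", {
  sf <- sim_fixture(seed = 91)
  tr <- tempfile(fileext = ".bed")
  write_truth(sf$sim, tr)
  lines <- readLines(tr)
  expect_equal(length(lines), length(sf$sim$reads))
  parts <- strsplit(lines, "\t")
  expect_true(all(lengths(parts) == 6L))
  starts <- as.integer(vapply(parts, `[`, "", 2))
  expect_true(all(diff(starts) >= 0))
  # one read: line matches its truth exactly
  rd <- sf$sim$reads[[1]]
  want <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", rd$truth$contig, rd$truth$start,
                  rd$truth$end, rd$id, nrow(rd$passes), rd$truth$strand)
  expect_true(want %in% lines)
  # intervals are valid against the target
  ends <- as.integer(vapply(parts, `[`, "", 3))
  expect_true(all(starts >= 0 & ends <= sf$sim$targets[["chr1"]]))
  # sidecar event counts sum to the simulator's aggregate tally
  side <- utils::read.delim(paste0(tr, ".events.tsv"))
  expect_equal(nrow(side), length(sf$sim$reads))
  expect_equal(sum(side$match), unname(sf$sim$tally["MATCH"]))
  expect_equal(sum(side$insertion), unname(sf$sim$tally["INSERTION"]))
  expect_equal(sum(side$deletion), unname(sf$sim$tally["DELETION"]))
  expect_equal(sum(side$substitution), unname(sf$sim$tally["SUBSTITUTION"]))
})

test_that("truth intervals extract fragments matching an error-free simulation", {
  ref <- make_reference(5000, seed = 101)
  m <- perfect_model(ref, seed = 102)
  sim <- simulate_reads(m, c(chr1 = ref), nreads = 8, seed = 103,
                        pass_counts = 2L)
  tr <- tempfile(); write_truth(sim, tr)
  parts <- strsplit(readLines(tr), "\t")
  for (p in parts) {
    rd <- sim$reads[[which(vapply(sim$reads, `[[`, "", "id") == p[4])]]
    frag <- substr(ref, as.integer(p[2]) + 1, as.integer(p[3]))
    pass1 <- substr(rd$seq, rd$passes$start[1] + 1, rd$passes$end[1])
    expect_identical(pass1, if (p[6] == "+") frag else revcomp(frag))
  }
})

test_that("identical seeds give byte-identical FASTQ, BAM and truth files", {
  out <- replicate(2, {
    sf <- sim_fixture(seed = 111)
    fq <- tempfile(fileext = ".fastq"); write_fastq(sf$sim, fq)
    bam <- write_tagged_bam(sf$sim, tempfile(fileext = ".bam"))
    tr <- tempfile(); write_truth(sf$sim, tr)
    vapply(c(fq, bam, tr, paste0(tr, ".events.tsv")),
           function(f) unname(tools::md5sum(f)), "")
  })
  expect_identical(out[, 1], out[, 2])
})
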