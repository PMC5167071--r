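# Simulation: fragment drawing, per-pass emission, multi-pass assembly,
# reproducibility, and statistical fidelity to the fitted model.

test_that("fragment draws follow the stated sampling rules", {
  ref <- c(chr1 = random_dna(1000))
  set.seed(201)
  fr <- draw_fragment(ref, n = 10000, fragment_lengths = 100L)
  expect_true(all(fr$end - fr$start == 100L))
  expect_true(all(fr$start >= 0 & fr$start <= 900))
  expect_false(any(fr$truncated))
  # uniform starts over the 901 valid positions
  obs <- tabulate(findInterval(fr$start, seq(0, 901, length.out = 21),
                               left.open = FALSE), 20)
  expect_gt(chisq_gof(obs, rep(1 / 20, 20)), 0.01)
  # extracted sequences match the coordinates
  idx <- sample(nrow(fr), 50)
  expect_equal(fr$seq[idx],
               substring(ref, fr$start[idx] + 1, fr$end[idx]))
})

test_that("contigs are chosen proportionally to their length", {
  refs <- c(big = random_dna(9000), small = random_dna(1000))
  set.seed(202)
  fr <- draw_fragment(refs, n = 10000, fragment_lengths = 50L)
  p <- mean(fr$contig == "big")
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(p - 0.9), 3 * se)
})

test_that("whole-contig and infeasible draws behave as documented", {
  refs <- c(chr = random_dna(500))
  set.seed(203)
  fr <- draw_fragment(refs, n = 5, fragment_lengths = 500L)
  expect_true(all(fr$start == 0 & fr$end == 500))
  fr2 <- draw_fragment(refs, n = 5, fragment_lengths = 800L)
  expect_true(all(fr2$truncated))
  expect_true(all(fr2$end - fr2$start == 500L))
  expect_error(draw_fragment(refs, n = 1, fragment_lengths = 800L,
                             truncate = FALSE), "shorter")
  expect_error(draw_fragment(c(a = "ACGT"), n = 1,
                             fragment_lengths = integer(0)), "empty")
})

test_that("an all-match model reproduces any fragment exactly", {
  ref <- make_reference(6000, seed = 211)
  m <- perfect_model(ref, seed = 212)
  set.seed(213)
  for (i in 1:10) {
    frag <- substr(ref, i * 300 + 1, i * 300 + 400)
    pr <- simulate_pass(frag, m)
    expect_identical(pr$basecalls, frag)
    expect_true(all(pr$event_log$event == "MATCH"))
    expect_equal(nchar(pr$features$qv), nchar(frag))
  }
})

test_that("custom_rates=(0,0,0) forces identity regardless of the model", {
  ref <- make_reference(10000, seed = 221)
  fx <- make_corrupted_reads(ref, fixture_spec(
    n_reads = 60, seed = 222, fragment_lengths = 800L, flank_width = 2,
    rates = c(ins = 0.05, del = 0.1, sub = 0.03)))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  frag <- substr(ref, 2001, 2600)
  set.seed(223)
  pr <- simulate_pass(frag, m, custom_rates = c(0, 0, 0))
  expect_identical(pr$basecalls, frag)
  # and nonzero custom rates are honored globally
  set.seed(224)
  n_ev <- 0L; n_match <- 0L
  for (i in 1:40) {
    pr <- simulate_pass(substr(ref, i * 200 + 1, i * 200 + 500), m,
                        custom_rates = c(0.01, 0.02, 0.005))
    tt <- table(factor(pr$event_log$event, levels = event_types()))
    n_ev <- n_ev + sum(tt)
    n_match <- n_match + tt[["MATCH"]]
  }
  p <- 1 - 0.035
  se <- sqrt(p * (1 - p) / n_ev)
  expect_lt(abs(n_match / n_ev - p), 3 * se)
  expect_error(simulate_pass(frag, m, custom_rates = c(0.5, 0.5, 0.2)),
               "custom_rates")
})

test_that("position-dependent scaling reshapes the error profile along the read", {
  ref <- make_reference(20000, seed = 231)
  fx <- make_corrupted_reads(ref, fixture_spec(
    n_reads = 100, seed = 232, fragment_lengths = 1000L, flank_width = 2))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  # errors only in the second half of the fragment
  sc <- function(x) if (x < 0.5) 0 else 3
  set.seed(233)
  first_half_err <- 0L; second_half_err <- 0L
  for (i in 1:30) {
    frag <- substr(ref, i * 600 + 1, i * 600 + 600)
    pr <- simulate_pass(frag, m, position_scaling = sc)
    steps <- tokenize(frag, 2)
    mid <- (steps$ref_start + steps$hp_length / 2) / nchar(frag)
    err <- pr$event_log$event != "MATCH"
    first_half_err <- first_half_err + sum(err[mid < 0.5])
    second_half_err <- second_half_err + sum(err[mid >= 0.5])
  }
  expect_equal(first_half_err, 0L)
  expect_gt(second_half_err, 100L)
})

test_that("multi-pass assembly alternates strands around adapters", {
  ref <- make_reference(4000, seed = 241)
  m <- perfect_model(ref, seed = 242)
  adapter <- "ATCTCTCTC"
  set.seed(243)
  fr <- draw_fragment(c(chr = ref), m, n = 1, fragment_lengths = 300L)
  rd <- assemble_read(fr, m, molecule = 7, pass_counts = 3L,
                      adapter = adapter)
  F <- fr$seq; R <- revcomp(F)
  s0 <- rd$truth$strand
  p1 <- if (s0 == "+") F else R
  p2 <- if (s0 == "+") R else F
  expected <- paste0(p1, adapter, p2, adapter, p1)
  expect_identical(rd$seq, expected)
  expect_equal(nrow(rd$passes), 3L)
  expect_equal(rd$passes$strand,
               if (s0 == "+") c("+", "-", "+") else c("-", "+", "-"))
  expect_equal(nrow(rd$adapters), 2L)
  # intervals partition the read
  ivs <- rbind(rd$passes[c("start", "end")], rd$adapters)
  ivs <- ivs[order(ivs$start), ]
  expect_equal(ivs$start, c(0L, head(ivs$end, -1)))
  expect_equal(tail(ivs$end, 1), nchar(rd$seq))
  # pass substrings equal the declared truth sequences
  for (p in 1:3)
    expect_identical(substr(rd$seq, rd$passes$start[p] + 1, rd$passes$end[p]),
                     if (p %% 2 == 1) p1 else p2)
  # single-pass reads carry no adapter
  rd1 <- assemble_read(fr, m, pass_counts = 1L)
  expect_equal(nrow(rd1$adapters), 0L)
  expect_equal(nrow(rd1$passes), 1L)
})

test_that("simulated pass-count and fragment-length histograms match the model", {
  ref <- make_reference(30000, seed = 251)
  fx <- make_corrupted_reads(ref, fixture_spec(
    n_reads = 400, seed = 252, flank_width = 2,
    fragment_lengths = c(600L, 900L, 1200L), fragment_probs = c(.3, .5, .2),
    pass_counts = c(1L, 2L, 3L, 5L), pass_probs = c(.2, .4, .3, .1)))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  sim <- simulate_reads(m, c(chr = ref), nreads = 5000, seed = 253)
  np <- vapply(sim$reads, function(r) nrow(r$passes), 1L)
  fl <- vapply(sim$reads, function(r) r$truth$end - r$truth$start, 1L)
  expect_lt(tv_distance(table(np), table(m$pass_counts)), 0.02)
  expect_lt(tv_distance(table(fl), table(m$fragment_lengths)), 0.02)
})

test_that("simulation is byte-reproducible given a seed", {
  ref <- make_reference(8000, seed = 261)
  fx <- make_corrupted_reads(ref, fixture_spec(n_reads = 50, seed = 262,
                                               fragment_lengths = 500L,
                                               flank_width = 2))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  s1 <- simulate_reads(m, c(chr = ref), nreads = 30, seed = 77)
  s2 <- simulate_reads(m, c(chr = ref), nreads = 30, seed = 77)
  expect_identical(s1$reads, s2$reads)
  s3 <- simulate_reads(m, c(chr = ref), nreads = 30, seed = 78)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("coverage-based stopping emits enough fragment bases", {
  ref <- make_reference(10000, seed = 271)
  m <- perfect_model(ref, seed = 272, fragment_lengths = 1000L)
  sim <- simulate_reads(m, c(chr = ref), coverage = 10, seed = 273,
                        fragment_lengths = 1000L, pass_counts = 1L)
  frag_bases <- sum(vapply(sim$reads, function(r) r$truth$end - r$truth$start, 1L))
  expect_gte(frag_bases, 10 * 10000)
  expect_equal(length(sim$reads), 100L)
  expect_error(simulate_reads(m, c(chr = ref), nreads = 5, coverage = 5),
               "exactly one")
})

test_that("unseen contexts are resolved by backoff instead of failing", {
  # train on a reference missing long A-runs, then simulate a target with one
  ref <- make_reference(8000, seed = 281)
  fx <- make_corrupted_reads(ref, fixture_spec(n_reads = 80, seed = 282,
                                               fragment_lengths = 600L,
                                               flank_width = 2))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  target <- paste0(substr(ref, 1, 300), strrep("A", 37), substr(ref, 301, 600))
  set.seed(283)
  pr <- simulate_pass(target, m)
  expect_gt(nchar(pr$basecalls), 0)
  st <- tokenize(target, 2)
  big <- which(st$hp_length == 37)
  # the emission for the unseen long run is still an A-run of plausible size
  em <- pr$event_log[big, ]
  expect_true(em$key %in% paste0(st$left_flank[big], "A^>20", st$right_flank[big]))
  # N runs are emitted verbatim with quality 0
  pr2 <- simulate_pass("ACGTNNNNACGT", m)
  expect_true(grepl("NNNN", pr2$basecalls))
  expect_true(is.na(pr2$event_log$event[pr2$event_log$is_n]))
})

test_that("closed loop: re-classified simulated reads match the model rates", {
  ref <- make_reference(30000, seed = 291)
  fx <- make_corrupted_reads(ref, fixture_spec(
    n_reads = 300, seed = 292, fragment_lengths = 800L, flank_width = 2,
    rates = c(ins = 0.02, del = 0.05, sub = 0.01)))
  m <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
  sim <- simulate_reads(m, c(chr = ref), nreads = 300, seed = 293)
  pa <- ekmersim:::pass_alignments(sim, c(chr = ref))
  m2 <- learn_error_model(pa$alignments, pa$reference, flank_width = 2)
  f1 <- coef(m); f2 <- coef(m2)
  n <- sum(m2$counts)
  for (evn in names(f1)) {
    se <- sqrt(max(f1[[evn]] * (1 - f1[[evn]]), 1e-12) / n)
    expect_lt(abs(f2[[evn]] - f1[[evn]]), 3 * se + 1e-9)
  }
  # the independent re-measurement agrees with the simulator's own tally
  expect_equal(unname(sim$tally / sum(sim$tally)), unname(f2), tolerance = 1e-6)
})
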