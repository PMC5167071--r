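---
title: "Empirical context-dependent simulation of long noisy reads"
author: "ekmersim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical context-dependent simulation of long noisy reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ekmersim)
```

## The problem

Single-molecule long-read platforms (PacBio SMRT sequencing being the
canonical example) read one DNA molecule many times: the insert is
circularized with hairpin adapters and traversed repeatedly on alternating
strands, producing a raw "polymerase read" whose passes are separated by
adapter copies. Errors on these platforms are not uniform. Two features
dominate:

* the error rate depends on the **short-range sequencing context** — the
  local base composition around the position being called; and
* **homopolymer run lengths are systematically mis-measured**, with a bias
  that depends on both the run base and the true run length (and, for some
  chemistries, is worse for G/C runs).

Simulators built around a parametric error model with a single global rate
miss both effects, and downstream tools (consensus builders, variant
callers) behave measurably differently on such idealized data. `ekmersim`
instead *learns* a non-parametric error model from real (or synthetic)
alignments and simulates by resampling what was actually observed, context
by context.

## The extended-k-mer context

The unit of modelling is the **extended k-mer (EKmer)**: a maximal
homopolymer run described by its base and length, plus `f` flanking bases
on each side. For runs of length one this is an ordinary `(2f+1)`-mer; for
longer runs the length is kept as an explicit coordinate, so a 12-base T
run is `CGT^12AC` rather than being collapsed into whatever k-mer window
happens to cover it. This is what lets the model represent length-dependent
homopolymer bias for runs longer than any fixed k.

`tokenize()` partitions any sequence into consecutive EKmer steps; the
partition is exact (concatenating the central runs reproduces the input)
and boundary contexts are padded with a reserved `.` character so they form
their own bins instead of being silently dropped. The canonical string
encoding (`encode_ekmer()` / `decode_ekmer()`) is invertible and is used as
the model's bin key.

**Flank width.** The default is `f = 3` (7-base-wide contexts for
single-base runs), a practical compromise: `4·9·4^(2(f-1))` interior
single-run contexts grow by a factor of 16 per extra flank base, and at
`f = 3` (9,216 such contexts) a typical long-read training set still
populates most bins. `f` is a first-class parameter; the statistical tests
in this package mostly use `f = 2` so that per-context draws are dense
enough for tight per-key comparisons.

**Run-length cap.** Run lengths above `hp_cap` (default 20) share a single
`>cap` bucket because observations become vanishingly sparse; the raw
length is still carried on each step, and emissions drawn from a bucket
are length-adjusted so net insertion/deletion offsets are preserved
relative to the true run.

## Learning

`learn_error_model()` walks every usable alignment record (mapped, primary,
above mapping-quality and length floors), attributes every read base to
exactly one reference position — insertions anchor at the last consumed
reference position, so an insertion between two runs belongs to the left
one — and classifies what the read did over each fully covered EKmer span
into exactly one event with **insertion priority**:

1. any inserted base → `INSERTION`;
2. else fewer emitted than reference bases → `DELETION`;
3. else any mismatching base → `SUBSTITUTION`;
4. else `MATCH`.

Insertion priority is the only precedence consistent with labelling a
homopolymer that gained a base an insertion even when the alignment could
be rewritten; the full emitted string is stored regardless, so
insertion–deletion cancellation with non-identical bases is represented
faithfully. Mismatches are recomputed against the reference, so no MD tag
is required. Spans only partially covered by an alignment, and runs of
`N`, are skipped and counted.

Each classified span contributes to an exact per-(context, event) count and
to a bounded **reservoir** of emission records (basecalls plus per-base
features: the overall quality `qv` always; insertion/deletion/merge/
substitution QVs, deletion/substitution tags and inter-pulse durations
under the `pacbio` schema). The reservoir capacity (default 10,000 records
per bin) bounds memory; counts stay exact beyond it. Reservoir selection is
seeded per bin key, which makes learning a pure function of its inputs —
the same data and configuration always yield a bit-identical model, and the
caller's RNG stream is untouched.

Fragment lengths are recorded per alignment record; pass counts come from
grouping read names with the `movie/hole/qStart_qEnd` subread convention
(configurable regex; non-matching names degenerate to single-pass). All
passes of a molecule contribute features, and this choice is recorded in
the model metadata. Models from different runs can be combined with
`merge_models()` (counts summed, reservoirs concatenated and re-trimmed),
and round-trip bit-exactly through a versioned JSON archive
(`write_model()` / `read_model()`).

## Simulation

For each molecule, in a fixed documented draw order (fragment length →
contig → start → pass count → initial strand → per-step event → per-step
emission): a fragment is drawn with contigs weighted by length and starts
uniform over positions where the fragment fits (a contig shorter than the
drawn length yields the whole contig, flagged, so draw counts stay
unbiased; redraw is available); a pass count `N_p` is drawn from the
empirical distribution; a fair coin chooses the first strand. Each pass
tokenizes the (strand-oriented) fragment, draws one event per step from
that context's empirical frequencies, and resamples basecalls and per-base
features from the matching (context, event) bin. Passes alternate strands
and are joined by the hairpin adapter (adapters sit between passes only —
they are what separates two traversals of the circular insert; the default
sequence is the published SMRTbell hairpin and is configurable). Passes are
drawn independently; inter-pass error correlation within a molecule is not
modelled.

**Sparse contexts.** Simulation must never dead-end on a context the
training data missed. Unseen keys back off in three stages: (1) the nearest
populated run-length bucket with the same base and flanks; (2) symmetric
flank shrinking, taking the best-populated matching context; (3) a pooled
per-run-length event table, with the best-populated context of that length
donating emissions. (A pragmatic note: at stages 1–2 the donor context's
own frequency row is used rather than a pooled aggregate — with a single
best-populated donor the two coincide, and the donor is cached per key.)
Donated emissions are translated onto the truth run (donor run base
mapped to the truth base, net length offset preserved), so a `MATCH` drawn
through backoff still reproduces the truth sequence exactly. If no bin
anywhere holds the drawn event, a minimal synthetic record is emitted and
flagged by the absence of a donor. Targets containing `N` emit `N` runs
verbatim at quality 0, excluded from event accounting.

**Custom rates and position scaling.** `custom_rates = c(ins, del, sub)`
replaces every per-context frequency vector (match takes the complement)
while emissions still come from the matching bin, so hypothetical error
profiles keep realistic emission shapes. `position_scaling` maps relative
position in `[0, 1]` to a multiplier on the three error probabilities
(clamped so their sum stays below 0.99), which is how end-of-read quality
degradation can be injected.

Every simulated read carries full ground truth: fragment coordinates and
strand, pass/adapter intervals, a per-pass event log, and a per-pass
alignment (CIGAR) against its own truth sequence. The CIGAR represents each
step's net emission (`mM`/`kI`/`kD`); within-run placement of an insertion
is not preserved, which is immaterial for run-level statistics because any
base attributed to the run yields the same event and emitted string on
re-classification.

## Outputs

`write_fastq()` emits Phred+33 FASTQ using `qv` as the quality string.
`write_tagged_sam()`/`write_tagged_bam()` emit unaligned records with
per-base features as the documented PacBio-style tags (`iq dq dt mq sq st`,
`ip` as saturating uint16 frame counts) plus pass structure (`np`, strand
string `sd`, interval arrays `ps`/`za`) and a header recording simulator
version, model fingerprint and seed. `write_truth()` emits a sorted
BED-compatible file plus a TSV sidecar of per-read event counts whose
column sums equal the simulator's aggregate tally. Phred values are capped
at 93 (the printable range). Writers sit behind one small interface, so
further formats are a plugin, not a rewrite.

## Profile analytics

`context_accuracy()` bins per-context accuracy (MATCH events / total
events) at 1% resolution; a context-independent error profile would
produce a single delta peak at the global accuracy, so the width of this
histogram *is* the non-uniformity of the chemistry. A context enters the
histogram only with at least `min_obs = 50` observations — an accuracy
"determined within 1%" is meaningless for a context seen a handful of
times; the floor is exposed because no canonical value exists. An
alternative base-level scoring (emitted-base identity rather than event
identity) is available behind `level = "base"` since the event-level
definition is a choice, not a law. Each context counts once, irrespective
of its genomic abundance. `fraction_below()` summarizes the low-accuracy
tail (monotone in its threshold by construction), and
`homopolymer_transition()` gives the distribution of emitted run lengths
for a (base, true length) pair pooled over flanks, combining exact event
counts with bin-level emitted lengths.

## The synthetic fixture generator as oracle

Real training chemistry data cannot ship with a package, so
`make_reference()` / `make_corrupted_reads()` generate references (with
forced homopolymer runs at recorded offsets) and corrupted reads under
fully specified parameters, emitting alignments directly from the
generative process — no aligner in the loop, so tests are hermetic and the
truth is exact per base, not statistical. Two corruption mechanisms are
provided because two different oracles are needed:

* **per-step** mode draws one event per EKmer context at stated rates
  (optionally per run base, e.g. elevated G/C deletion) — the direct oracle
  for parameter recovery, since learned per-event frequencies must converge
  to the generative rates;
* **per-base** mode deletes each base independently at rate `d`, under
  which the emitted length of a true length-`L` run is exactly
  `Binomial(L, 1 - d)` — the closed-form reference for the
  homopolymer-transition analytics.

Contexts only partially covered by a fragment are copied through
error-free, mirroring the learner's skip rule, so generator tallies and
learner counts correspond context-for-context. The generator emulates
context-dependent, positionally uniform errors only: no chimeric reads, no
long garbage patches, no instrument signal — so passing tests demonstrate
that the learn-and-simulate machinery is self-consistent and statistically
calibrated under those conditions, not that any particular real chemistry
is reproduced. Reproducing published chemistry-specific numbers (bulk
accuracies, low-accuracy context fractions of specific P5/P6 datasets)
would require the original proprietary data and is out of scope.

## Numerical and statistical choices

* **Problem sizes.** The statistical checks run at the sizes where their
  tolerances are meaningful: parameter recovery and the closed loop at
  ~10^6 classified spans (3 binomial σ global bands), distribution
  fidelity at 10^4 reads (total-variation distance < 0.02), the binomial
  limit at ≥ 5,000 length-6 runs per deletion rate (χ² at α = 0.01 with
  cells below expectation 5 pooled).
* **Per-context closed-loop comparison.** With ~600 contexts × 4 events,
  several thousand 3σ comparisons run at once; under the null about 0.27%
  of them exceed 3σ by chance, so the aggregate check bounds the
  exceedance fraction at 1% rather than demanding literally zero — a real
  frequency distortion pushes the fraction far past that bound, pure
  sampling noise does not.
* **Determinism.** All randomness flows through R's RNG from a single
  seed; learning itself consumes no user-visible randomness (per-key
  seeded reservoirs). Identical seed and configuration give byte-identical
  FASTQ/BAM/truth outputs; key ordering uses locale-independent radix
  sorts so models are platform-stable.
* **Degenerate inputs.** Empty sequences, invalid characters (with
  offsets), unmapped or length-mismatched records, missing contigs, empty
  bins, infeasible fragment draws and newer model-format versions all
  raise immediate, named errors; empty read sets produce valid empty
  output files.

## Limitations

Errors are conditionally independent given context: no inter-pass
correlation, no long-range error structure (chimeras, garbage patches —
both would require alignment-junction analysis), and kinetic inter-pulse
durations are carried as opaque resampled features, not modelled. Learned
feature values are resampled verbatim, so feature distributions outside
the training domain (e.g. a custom rate far from the training rate paired
with learned QVs) are extrapolations. Reverse-complement canonicalization
of contexts is deliberately not performed; strand is handled explicitly at
simulation time.
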