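# ekmersim

Empirical, context-dependent simulation of long noisy sequencing reads.

Single-molecule long-read platforms (PacBio SMRT sequencing being the
archetype) read a circularized DNA fragment several times on alternating
strands, with hairpin adapters between passes. Their errors are neither
uniform nor memoryless: the error rate depends on the local sequencing
context, and homopolymer run lengths are systematically mis-measured with
a base- and length-dependent bias. Tools developed downstream — consensus
builders, variant callers, assemblers — behave differently on data that
lacks these structures, so a simulator with a single global error rate is
a poor test bed.

`ekmersim` takes a learn-and-simulate approach. It **learns** a
non-parametric error model from read-versus-reference alignments and
**simulates** new reads from arbitrary FASTA targets by resampling what
was observed, context by context. It is aimed at bioinformaticians who
need realistic long-read test data with exact ground truth, and at
developers who want to ask "what if the error profile looked like
*this*?" via custom rates and position-dependent scaling.

## The model

The unit of modelling is the **extended k-mer (EKmer)**: a maximal
homopolymer run (base *b*, length *L*) with *f* flanking bases on each
side, written e.g. `CGT^5AC` (a T run of length 5 flanked by CG and AC)
or, for `L = 1`, the plain k-mer form `GTACG`. Unlike a fixed k-mer
window, the run length is an explicit coordinate, so runs longer than any
fixed *k* keep their identity — which is exactly where long-read
platforms err most.

Learning walks each alignment, assigns every read base to one reference
position (insertions anchor to the last consumed position), and
classifies what the read did over each EKmer span into exactly one event
with insertion priority:

```
any inserted base          -> INSERTION
else emitted < run length  -> DELETION
else any mismatch          -> SUBSTITUTION
else                       -> MATCH
```

The fitted object holds, per context key: exact event counts
(frequencies `P(event | EKmer)`), a capped reservoir of observed
emissions with per-base features (overall QV always; insertion/deletion/
merge/substitution QVs, deletion/substitution tags, and inter-pulse
durations under the `pacbio` schema), plus the empirical fragment-length
and pass-count distributions. Simulation draws, per homopolymer context
of the target: an event from `P(event | EKmer)`, then an emission from
the matching (EKmer, event) bin; passes alternate strand around adapter
copies, and every read carries exhaustive ground truth.

## Worked example

Training data normally comes from a BAM of real reads aligned to a truth
reference; here the package's own fixture generator supplies alignments
with known error rates (2% insertion, 5% deletion, 1% substitution per
context) so the output can be checked against its inputs:

```r
library(ekmersim)

ref <- make_reference(50000, seed = 42)
fx  <- make_corrupted_reads(ref, fixture_spec(
  n_reads = 500, seed = 43, fragment_lengths = 800L, flank_width = 2,
  rates = c(ins = 0.02, del = 0.05, sub = 0.01), pass_counts = c(1L, 2L, 3L)))

model <- learn_error_model(fx$alignments, fx$reference, flank_width = 2)
model
#> Empirical context-dependent error model (ekmer_model)
#>   flank width: 2 (5-base-wide single-run contexts), run-length cap: 20
#>   contexts observed: 2148;  classified spans: 300705
#>   event frequencies: match 0.9211  ins 0.0190  del 0.0498  sub 0.0100
#>   feature schema: qv;  bin capacity: 10000 (300705 records held)
#>   fragment lengths: n=502, median 800 bp;  passes: median 2
```

The learned global frequencies sit within sampling error of the
generative 2/5/1% rates, and the fragment-length and pass-count
distributions were picked up from the alignment records and the
`movie/hole/qStart_qEnd` read-name grouping. Simulating from the model
and inspecting a read:

```r
sim <- simulate(model, nsim = 50, seed = 7, targets = c(chr1 = ref))
sim
#> <ekmer_sim> 50 reads, 78274 bases over 1 target contig(s)
#>   realized events: match 0.9219  ins 0.0185  del 0.0494  sub 0.0101
sim$reads[[1]]
#> <simulated_read> sim/1/0_2419  2419 bp, 3 pass(es), truth chr1:5692-6492 (+)
```

The first molecule drew a 800 bp fragment at chr1:5692–6492, read it in
three passes (`+`, `-`, `+`) joined by two adapter copies, and realized
event frequencies across the read set match the model's. Error-profile
analytics answer the questions usually asked of a chemistry:

```r
fraction_below(model, 80)            # share of contexts under 80% accuracy
#> [1] 0
round(homopolymer_transition(model, "T", 4), 4)
#>      0      1      2      3      4      5
#> 0.0093 0.0093 0.0139 0.0104 0.9420 0.0151
```

(A true length-4 T run is read at full length 94.2% of the time here;
real chemistries show much stronger, asymmetric bias, which the model
would capture the same way.) Outputs go to standard formats:

```r
write_fastq(sim, "sim.fastq")          # Phred+33, QV as quality string
write_tagged_bam(sim, "sim.bam")       # unaligned, PacBio-style feature tags
write_truth(sim, "sim.truth.bed")      # BED + per-read event sidecar
write_model(model, "model.ekm")        # versioned JSON archive
```

A command-line front end wraps the same functions
(`exec/ekmersim learn|simulate|profile|fixtures ...`); see the script
header for options. The methods vignette
(`vignettes/ekmersim-methods.Rmd`) documents the model, the backoff rules
for sparse contexts, the fixture generator, and all numerical choices.

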