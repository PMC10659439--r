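---
title: "Modelling translation complexity with ribosome decision graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling translation complexity with ribosome decision graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdgraph)
```

## The model

Ribosome profiling shows that most eukaryotic mRNAs are translated in more
than one way: scanning ribosomes initiate leakily at upstream AUG and
near-cognate starts, post-termination small subunits re-initiate downstream
of short upstream ORFs, some stop codons are read through (selenocysteine
insertion being the canonical case), and programmed frameshift sites divert
elongating ribosomes into another reading frame. A flat "translated ORF"
annotation cannot express these alternatives, let alone their
interdependence.

`rdgraph` models one mRNA as a directed acyclic graph of ribosome states.
Scanning complexes enter at the 5' cap and move 3'-ward. Every
*non-deterministic event* is a branch node with exactly two outcomes:

* a leaky start: **initiate** vs **scan through**;
* a readthrough-permissive stop: **readthrough** vs **terminate**;
* a shift site: **shift** vs **continue in frame**.

Everything else is deterministic. An ordinary in-frame stop always ends the
translated region; we call the region decoded by one elongating ribosome
from its initiation codon to its termination a *translon* (it may span
frames via shifts and stops via readthrough, which an ORF cannot). A
termination by a *re-initiation-competent* translon hands the mRNA back to a
scanning state strictly 3' of the stop; any other termination releases the
ribosome. A scanning complex that passes the last start runs off the 3' end:
that maximal source-to-sink path with no initiation is the unproductive
ribosome path. Every source-to-sink path (*RiboPath*) is one complete
passage of a single ribosomal complex, and its ordered decisions identify it
uniquely.

On the canonical three-start example (`make_fixture("fig3")` — a short uORF
in one frame, then a CUG and an in-frame AUG sharing a stop in another) this
yields three branch nodes, three translons and exactly five ribosome paths,
one of them unproductive; the uORF translon and the CUG-extended translon
are mutually exclusive because the CUG lies inside the uORF and elongating
ribosomes do not initiate.

A modelling choice deserves emphasis: competent terminations resume scanning
*deterministically*, and "failure to re-initiate" is realized as
scan-through (or runoff) at the downstream start branch nodes. Treating the
termination itself as an additional dissociate/resume branch would double
count the decision — the three-start example would acquire a fourth branch
node and a sixth path — so the decision mass for re-initiation lives
entirely at the downstream starts.

### Re-initiation policy

Two parameters govern re-initiation, both fields of the annotation:

* `reinit_max_codons` (default **30**): a stop-terminated translon of at
  most this many codons (stop included) leaves a scanning-competent subunit.
  Re-initiation is common after short uORFs and rare after long coding
  regions; 30 codons is a conventional uORF scale, and the value is recorded
  in every serialized output. Unbounded translons (no in-frame stop before
  the 3' end) are never competent.
* `recharge_distance` (default **0** nt): the scanning distance past the
  stop needed to re-acquire the ternary complex before initiation is
  possible again. Under stress (eIF2α phosphorylation) this distance grows,
  which is the delayed re-initiation mechanism: with a short distance the
  proximal (long, inhibitory) uORF start is used, with a long distance it is
  bypassed and the distal CDS start is used.
  `reinitiation_eligible_starts()` answers this query for any distance
  without rebuilding the graph; distance is measured from the last
  nucleotide of the terminating stop to the first nucleotide of the
  candidate start.

Starts listed as `deterministic` (typically strong-context CDS starts)
initiate with probability 1 and are not branch nodes.

### Shift notation and mechanics

A shift site is written `shifts(i,s)`: `i` is the first nucleotide of the
last codon decoded in the incoming frame and `s` the re-pairing coordinate
in the new frame. The signed offset is the direct difference `s - i`:
+1 and −1 are the common frameshift classes, and large offsets encode
translational bypassing (the bacteriophage T4 gene 60 hop has `s - i = 50`).
Operationally the first *newly decoded* codon starts at `s + 3`; this single
rule reproduces −1 frameshifting (decoding resumes at `i + 2`, re-reading
one nucleotide), +1 frameshifting (`i + 4`, skipping one) and bypassing
(`s - i` nucleotides skipped) without per-class special cases. Backward
jumps beyond −3 are rejected.

## Quantification

Let `R_T` be the *translation efficiency* of translon `T`: footprints per
codon over the positions that can be attributed to `T` unambiguously.
Two filters apply:

* the first **5 codons** of the translon are excluded, because initiation
  sites carry large footprint peaks that would otherwise distort the
  density (the simulator reproduces this artifact via `start_peak_fold`, and
  the tests verify that the trim makes the estimator unbiased for folds up
  to 10);
* with `exclusive_only = TRUE` (default), codons sharing any position with
  *another translon's span* are discarded. We deliberately use the other
  translon's full span, not its trimmed span: its first five codons carry
  its initiation peak, which is exactly the signal one must not attribute to
  a neighbour. (Using trimmed spans here produced a ~0.1 bias in recovered
  probabilities on overlapping architectures.)

For a single leaky start feeding an upstream and a downstream translon, the
initiation probability is `p = Ru / (Ru + Rd)`. For a chain of leaky starts
the closed form generalizes: walking 5' to 3', each start takes its share of
the remaining flux, `p_k = R_k / Σ_{j ≥ k} R_j`, which gives `(1/3, 1/2, 1)`
for three equally efficient translons. The terminal start of a chain is
assigned probability 1: unproductive leakage past the last start cannot be
distinguished from a uniformly rescaled efficiency vector, so it is fixed to
zero and stated in the output metadata. These closed forms are scale-free
(they use only ratios of efficiencies).

Graphs with re-initiation or readthrough/shift branches are fit by bounded
least squares (`L-BFGS-B` on [0,1], three starting points plus a polishing
pass) between observed efficiencies and the translon fluxes predicted by
propagating unit flux through the graph. These fits treat the efficiencies
as absolute per-unit-flux densities (footprints per codon divided by the
depth): with an unknown overall scale the three-start example has three
unknown probabilities but only two scale-free observations and is not
identifiable. Configurations with more branch probabilities than observed
efficiencies are refused with an explicit identifiability error rather than
silently returned.

`propagate_flux()` is the forward direction: unit flux enters at the cap,
splits `p / (1 − p)` at each branch, and a translon's synthesis rate is the
flux through its initiate edge; path probabilities are products of branch
decisions and sum to 1 (verified to 1e-12 under random probability
assignments).

## Simulation

`simulate_track()` deposits each decoded codon's expected footprint count —
chunk flux × `depth`, times `start_peak_fold` on a translon's first five
codons — at the codon's first nucleotide (A-site convention), then draws
Poisson counts (or returns the exact expectation with `noise = "none"`).
Elongation is uniform: there is no codon dwell-time model, no coverage decay
along the message, and no sequence-dependent bias, because the
quantification layer only consumes density totals. Consequently, a passing
parameter-recovery test shows the estimator is correct *under this
generative model*; real libraries add dispersion beyond Poisson,
nuclease-footprint and mapping biases, and imperfect A-site offset
calibration, none of which are emulated. Tracks are reproducible: the RNG is
seeded from `seed` plus a transcript-id offset, so multi-transcript runs do
not depend on generation order, and the caller's RNG state is restored.

The built-in fixtures are deterministic synthetic sequences built from a
neutral filler codon (`GCA`, which contains no start or stop in any frame)
with the topology-defining codons spliced in: the three-start two-frame
example; an NF2-like leader (uAUG, strong in-frame AUG, CDS fed by
re-initiation, plus a documented single-base insertion that frameshifts the
uORF, creates a new uAUG, and abrogates CDS translation); a
selenoprotein-like readthrough; a −1 frameshift cassette; the minimal
delayed re-initiation architecture (short uORF / long uORF / CDS); and
leaky chains of `k` long translons for inference benchmarks. Fixture
coordinates are asserted by the test suite against the package's own
scanners, so the fixtures cannot drift from their documented topologies.

## Numerical and design choices

* **Path enumeration** is capped (default 10,000 paths) because conceptual
  graphs with many branch points explode combinatorially; `count_paths()`
  (topological-order dynamic programming, linear in edges) is always safe
  and is consulted before any materialization. Mutual exclusivity of two
  translons is decided by counting paths through both initiate edges, not
  by enumeration.
* **Path order** is lexicographic on the decision sequence with the
  non-event decision first, so the unproductive path is always path 1 and
  ids are stable across runs.
* **Translon ids** (`T1`, `T2`, …) follow first discovery along an
  initiate-first traversal from the cap. For plain leaky scanning this is
  start-position order; with re-initiation, the re-initiation target
  downstream of a uORF is numbered before starts reachable only by leaky
  scanning past it, matching the conventional numbering of the worked
  three-start example (the re-initiation path carries T1 and T2; the CUG
  translon is T3).
* **Branch node identity** is (kind, position) for starts; readthrough and
  shift nodes additionally carry their originating start, because ribosomes
  arriving from different starts have different histories (codon counts,
  hence re-initiation competence) and merging them would create invalid
  cross-origin paths.
* **Start-Stop ORF spans include the stop codon**; Stop-Stop runs exclude
  their bounding stops; runs truncated by a transcript boundary are flagged
  `unbounded` rather than clipped silently. Frames are reported relative to
  transcript position 1, plus CDS-relative frames when a CDS start is
  annotated.
* **Coordinates** are 1-based inclusive everywhere in R and in GFF3;
  BED output is 0-based half-open via `rtracklayer`. A −1 frameshift
  re-reads one nucleotide, so BED blocks (which must be disjoint) clip the
  overlap; the JSON and GFF3 exports carry the exact segments.
* **Variant analysis** re-derives start codons per allele — the point of a
  5' leader frameshift is precisely that it creates and destroys codons —
  while the re-initiation policy and deterministic-start labels are lifted
  through the coordinate map. Branch-point gains/losses are reported at the
  candidate (start codon) level so that a new uAUG inside a non-leaky
  uORF is still visible; translon gains/losses use the reachable graph.
* **Degenerate inputs**: empty annotations give a single unproductive path;
  a translon shorter than the trim is refused; efficiencies that are all
  zero raise an undefined-probability error; both-zero branch efficiencies
  cannot occur because at least one positive efficiency is required.

## Known limitations

Single mature transcripts only: no splice isoforms or genome coordinates
(a single graph describes a single mRNA sequence). No kinetic model of why
a decision is taken — branch probabilities are free parameters to be
estimated, not predicted from Kozak context or structure. Probability
inference assumes a fixed branch topology; choosing among topologies by
comparing simulated to observed tracks is out of scope. IRES entry,
StopGo/2A release and nascent-peptide stalling are not represented beyond
what a uORF branch can express. A-site tracks are taken as given; offset
calibration from raw reads is upstream of this package.

## Problem sizes used in the checks

The bundled tests run the full suite in under a minute: oracle comparisons
use 200+ random annotations on 120–240 nt transcripts (≤ 5 starts, so
exhaustive decision-vector enumeration stays below ~100 paths), and
parameter recovery uses a two-start chain at depth 50 footprints/codon with
100 Poisson replicates per true probability in {0.1, …, 0.9}, reporting the
median absolute error.
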