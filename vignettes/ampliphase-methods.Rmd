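---
title: "Methods: minor-variant calling, clonal phasing and isoform detection for long-read amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minor-variant calling, clonal phasing and isoform detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Scope and model

`ampliphase` analyses single-molecule long-read (circular consensus, CCS)
sequencing of a PCR amplicon spanning a fusion transcript — the motivating
application is the 1,578 bp BCR-ABL1 p210 amplicon used for surveillance of
tyrosine-kinase-inhibitor resistance in chronic myeloid leukemia. Because one
read corresponds to one cDNA molecule and spans the whole amplicon, three
analyses that short-read assays cannot do directly become simple counting
problems:

* **minor variant calling**: a substitution present in a fraction $f$ of
  molecules appears in a fraction $\approx f$ of reads covering its position;
* **clonal phasing**: two mutations on the same molecule (a *compound*
  mutant) co-occur within single reads, whereas mutations in *independent*
  clones do not;
* **isoform detection**: splice variants (exon-sized insertions or
  intra-exon deletions) appear as long contiguous indels in full-length
  reads.

The package also contains a first-class read simulator. No public read sets
exist for the assay it models, so all quantitative claims about the pipeline
are established on simulated clone mixtures whose ground truth is encoded in
the read names.

# Reference model

A `transcript_model` is an ordered list of exons (upstream-gene exons, then
downstream-gene exons) with a breakpoint tag (`e13a2`/`e14a2`, differing by
one 75 nt exon), a reading-frame phase, and *codon anchors*. Anchors tie the
clinical codon numbering — in which the ABL1 gatekeeper threonine is codon
315 — to transcript positions; it cannot be derived from the amplicon alone,
so the reference description supplies it. `in_silico_pcr()` extracts the
amplicon between exact, unique matches of a primer pair (the assay uses one
specific pair; degenerate matching is deliberately out of scope) and carries
the exon, junction and codon maps into amplicon coordinates. All
coordinates are 0-based half-open internally; report files print 1-based
positions.

The package ships a fully synthetic reference
(`inst/extdata/synthetic_reference.yaml`, loaded by `toy_reference()`):
random open reading frame, real amplicon architecture (11 exons, both
breakpoint variants, the published primer sites placed so the product is
exactly 1578 bp), and codon anchors placing the clinically numbered
kinase-domain codons (253, 255, 276, 315, 359, 396) at fixed offsets. It is
**not** a human sequence; analyses of real data must supply the real
reference mRNAs in the same YAML format.

# Read simulator

`simulate_sample()` draws each read from a clone according to the clone
fractions; a clone template is the amplicon with the clone's substitutions
and isoform events applied. Errors are i.i.d. per base — deletion with
probability $d$, else substitution with probability $s$ (uniform over the
three alternatives), then a single-base insertion with probability $i$ —
and about half the reads are reverse-complemented. The defaults

| parameter | default | units | rationale |
|---|---|---|---|
| substitution rate $s$ | 0.013 | per base | CCS-like accuracy that stresses the caller at its 0.5–1 % detection limits |
| insertion rate $i$ | 0.010 | per base | indels dominate raw PacBio error; consensus reduces but does not remove them |
| deletion rate $d$ | 0.005 | per base | as above |
| chimera rate | 0 | per read | PCR-mediated recombination is off unless studied explicitly |

are a deliberate stress choice: published CCS consensus accuracy is higher,
so detection limits measured here are conservative. A chimeric read takes a
prefix from one independently drawn clone template and a suffix from a
second, switching at a single uniform breakpoint — the simplest model of
PCR template switching. Qualities are a constant placeholder; nothing in
the pipeline uses base qualities (all filters are sequence-match based).

What the simulator does *not* emulate: context-dependent (homopolymer)
error profiles, per-read quality variation, multi-switch chimeras, and
coverage bias along the amplicon. Passing tests therefore demonstrate the
statistical machinery under a clean error model, not performance on any
particular instrument's artefact spectrum.

`make_dilution_series()` mirrors the wet-lab sensitivity experiment: the
mutant mixture is scaled by a dilution fraction into a wild-type background,
one sample per fraction, with per-sample seeds derived deterministically
from one master seed. Reproducibility is a contract: one seed, byte-identical
FASTQ.

# Alignment

`align_reads()` performs semi-global alignment (free end gaps on both read
and reference) with affine gap penalties, default +2/−4 match/mismatch and
−4/−1 gap open/extend, so a 35–154 nt splice event costs far less as one
long gap than as scattered mismatches. Read orientation is decided by a
13-mer vote against the reference with an exhaustive two-orientation
fallback when the vote is ambiguous.

The dynamic program is banded around the diagonal envelope
$[\min(0,\Delta) - p, \max(0,\Delta) + p]$ where $\Delta$ is the
read/reference length difference and $p$ = `band_pad` (default 12). The
envelope absorbs any single contiguous event (its length appears in
$\Delta$), and mid-read excursions of the indel random walk beyond ±12 have
probability ~10⁻⁵ per read at the default error rates. Alignments whose
identity falls below `rescue_identity` (0.9) are re-run exhaustively, so
reads violating the band assumption are not silently misaligned; reads
below `min_identity` (0.75 — permissive enough to keep isoform reads,
strict enough to drop off-target products) are reported unmapped.

Determinism matters more than any particular tie choice: equal-scoring
paths are resolved by preferring a diagonal step over a gap and a deletion
over an insertion, and indels are then *left-normalized*, sliding across
both match and mismatch columns whenever the swap is score-neutral. One
consequence discovered during development is worth recording: score-tied
parses can couple an indel error with a neighbouring substitution and park
the mismatch at a deterministic offset from its true position. At 10,000×
coverage these couplings surface as systematic artefact alleles at 0.5–1 %
frequency near true variants and homopolymer boundaries. `pileup()`
therefore masks base observations within `indel_mask` (default 5) bases of
an indel in the same read — the pileup-level analogue of indel-proximal
base-quality capping in standard pileup engines, and of this assay's own
perfect-flank rule (below). Deletion columns themselves are always tallied,
and `indel_mask = 0` restores the exact conservation property (total pileup
counts equal total reference bases consumed).

# Variant calling

For each (position, alternative base) the caller requires

1. raw frequency ≥ `min_frequency` (default 0.005 — the assay's working
   floor),
2. alternate count ≥ `min_alt_count` (default 10, a guard against
   single-read calls in shallow data),
3. a one-sided binomial tail $P(X \ge k \mid n, p_0) < \alpha / (3L)$,
   Bonferroni-corrected over all $3L$ position/alternative hypotheses
   ($\alpha$ = 0.05), where $p_0$ is the per-alternative error floor.

`estimate_error_floor()` estimates the per-position substitution rate as
the median across positions of the non-reference fraction, iteratively
excluding candidate variant alleles (frequency above five times the current
per-alternative floor, two rounds), so true variants do not inflate the
floor.

The per-alternative null $p_0$ deserves a note. Injected errors are uniform
over the three alternatives, so the obvious choice is (substitution
rate)/3. Empirically that null is slightly anti-conservative: after
alignment, residual errors concentrate onto context-dependent alternatives
(per-alternative z-scores against the uniform null have a standard
deviation of ~1.05 with context shifts up to ~+8 %), and across ~4,700
Bonferroni tests per sample this produces occasional false calls at
0.6–0.7 % frequency — incompatible with the assay's hallmark 0 %
false-positive specificity. When the floor is estimated from the data the
caller therefore uses a self-calibrating upper envelope: the median across
positions of the *largest* per-alternative mismatch rate. Under truly
uniform errors this exceeds rate/3 only by the expected maximum of three
binomial noise terms (≈ +8 % at 30,000× and shrinking with coverage), and
it widens automatically where coverage is low. An explicitly supplied
`error_floor` uses `error_floor/3`, which keeps the null exact in
controlled tests.

Two frequencies are reported. `frequency` is the raw alternate fraction,
which overstates the clone fraction by roughly the per-alternative floor
(~0.4 % at defaults). `freq_adjusted` inverts the error model:
$\hat f = (\hat q - s/3)/(1 - 4s/3)$ for observed alternate fraction
$\hat q$ and substitution rate $s$, which recovers simulated clone
fractions within binomial noise across 0.5–90 % and 10,000–30,000 reads.

Indels are never called here: events ≥ 3 nt belong to the isoform module,
1–2 nt indels are treated as sequencing noise.

# Clonal phasing

`read_signatures()` implements the perfect-flank rule: for each called
variant, a read is evaluable only if its aligned columns across the 10
flanking bases on each side (20 flanking bases total; the variant position
itself excluded) are perfect matches with no indels and the window is fully
covered. Evaluable reads contribute their allele (`ref`/`alt`); anything
else — flank mismatch, indel, uncovered window, deletion or third allele at
the site — excludes the read from composition, and excluded reads are
reported, never silently dropped. The total flank width of 20 is exposed as
`window_half_width` (= 10) because "a window of 20 bases surrounding the
site" admits both a ±10 and a ±20 reading; the symmetric ±10 interpretation
is the default here and the exclusion boundary is pinned by an enumeration
test (a single extra mismatch excludes a read exactly for offsets ±1…±10).
Reads need not be full-length for phasing — they must merely align cleanly
across every variant's window — which maximises evaluable depth.

At default error rates the rule keeps roughly $0.972^{21v}$ of reads for
$v$ variants (~70 % for one variant, ~32 % for two), which is the intended
behaviour: composition trades depth for per-read reliability. Note that
error-induced double positives survive at a low rate (a dominant-clone read
with a clean substitution error at the second site), of order 0.1–0.3 %
with two variants — the same order the original assay observed — so the
compound/independent call uses an evidence bar, not presence/absence: a
pair is *compound* if the double-positive count reaches
$\max(2, 0.5\%\ \text{of evaluable reads})$, *independent* if each single
reaches the bar while the double stays below it, *mixed* otherwise. The
0.5 % bar matches the assay's detection floor. `chimera_diagnostic()`
reports the observed double-positive rate next to the product of the
single-positive rates (the independent-assortment expectation), which is
the published way of arguing that PCR recombination is rare.

# Isoform detection

Isoforms are detected from full-length reads only (alignment spans both
primer regions within `end_tolerance` = 5 bases; consensus ends are ragged
and the published rule gives no tolerance). A non-reference isoform needs
at least `min_support` = 2 identical observations.

Two grouping modes:

* `strict` — the literal published rule: identical full-length nucleotide
  sequence after orientation normalization. Exact, but at realistic error
  rates near-duplicate full reads are rare, so strict mode is mainly useful
  on high-accuracy or simulated data.
* `event` (default) — group by identical indel-event structure (kind,
  left-normalized position, length) for events ≥ `min_event_length` = 3 nt.
  Three nt sits far below the smallest real splice event modelled (35 nt)
  and above 1–2 nt error indels. The inserted *sequence* is deliberately
  not part of the key: errors inside a 35 nt insertion would fragment the
  group. The residual cost is visible and documented: sequencing indels
  inside a long insertion jitter its length, so satellite records (e.g.
  34INS/36INS flanking a true 35INS) appear at default error rates, and
  event-mode frequency understates the true isoform fraction by the
  probability that the event region is error-free (~40 % for 35 nt at
  defaults). Detection, which is what the 5 %-floor claim concerns, is
  unaffected. Exact frequency recovery is asserted at error rate 0.

Point substitutions are never isoform-defining; variant and isoform
analyses are orthogonal. Events are annotated against the exon map (an
insertion within 3 nt of a junction is reported at that junction, e.g.
"35INS" between the two exons), frame effect is `length mod 3`, and
truncation is decided by translating the event-modified amplicon and
scanning for a premature stop — each checked against an independent
re-translation oracle in the tests.

# Sensitivity experiment

`run_sensitivity()` runs align → pileup → call on every sample of a
dilution series, marks each tracked variant detected or not, and reports
per-variant detection limits plus false positives (calls at untracked
positions). The detection limit is the smallest expected fraction reached
by an *unbroken* run of detections from the top fraction — an isolated
detection below a miss does not lower the limit, matching how dilution
panels are read.

# Problem sizes used by the test suite

The acceptance tests simulate the published experimental design directly:
dilution series at 30,000 reads per sample (fractions 50/10/1/0.5 % plus
the undiluted mixture), specificity over 20 replicate series, isoform
sensitivity at 20,000 full-length reads (fractions 20/10/5 %, ten
replicates), and a frequency-recovery grid over 0.5–90 % at 10,000–30,000
reads. Oracle-equivalence checks (alignment score vs exhaustive DP,
composition vs truth-label enumeration, truncation vs re-translation) run
on instances up to 300 nt or a few thousand reads, where the brute-force
references are fast. These sizes were chosen to match the study design
while keeping each claim's Monte-Carlo error far below the tolerance it is
tested at.

# Known limitations

* The bundled reference is synthetic; nothing here validates primer
  specificity or codon numbering against real human mRNAs.
* The caller models substitutions only; single-base indel variants are
  treated as noise by design.
* Event-mode isoform frequencies are biased downward at realistic error
  rates (see above); strict mode is unbiased only on near-error-free data.
* The chimera model is single-switch and uniform; real PCR recombination
  is length- and homology-dependent.
* The error model is position-independent; real CCS error is
  context-dependent, so real-data specificity should be re-established
  with an error floor estimated from a wild-type control rather than
  assumed from these simulations.
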